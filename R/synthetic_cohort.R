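# ---- synthetic cohort generator ----------------------------------------------
# Emulates the latent structure the latitude-stratified analysis assumes:
# two latitude groups; per-sample latent immune infiltration driving both
# marker-gene expression and survival hazard; group-specific gene mutation
# frequencies; per-sample subclonal VAF mixtures read-sampled at fixed depth.
# Every cohort carries its ground truth for parameter-recovery tests.

#' Generator settings for a synthetic latitude cohort
#'
#' Defaults describe a cohort of 100 + 100 tumor samples over 2000 genes
#' with five immune cells (20 marker genes each), all five acting as risk
#' factors on survival, and a mutation table mixing shared and
#' group-specific gene frequencies. The clinical-factor rates default to the
#' ranges reported for latitude-stratified gastric-cancer cohorts
#' (advanced stage and male excess at low latitude, higher grade at high
#' latitude).
#'
#' @param n_low,n_high Tumor samples per latitude group.
#' @param n_normal Normal samples (baseline expression, no mutations or
#'   survival; used by the differential-expression stage).
#' @param n_genes Total expressed genes.
#' @param n_cells Immune cells; `markers_per_cell` marker genes each.
#' @param markers_per_cell Marker genes per cell.
#' @param marker_effect log2 expression shift per unit latent infiltration.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param infiltration_shift_high Mean latent-infiltration shift of the
#'   high-latitude group (infiltration is higher at high latitude).
#' @param baseline_log2_range Range of per-gene baseline log2 expression.
#' @param dropout_fraction Fraction of FPKM entries set to exact 0.
#' @param count_scale Multiplier from FPKM to expected counts.
#' @param libsize_sd Log-normal SD of per-sample library-size factors.
#' @param nb_dispersion Negative-binomial dispersion of counts (0 = Poisson).
#' @param hazard_baseline Baseline exponential event rate per day.
#' @param hazard_multipliers Per-cell hazard multiplier applied as
#'   `multiplier^infiltration`; default `exp(0.4)` for every cell (all risk
#'   cells). Length `n_cells`.
#' @param censoring_rate Target fraction of censored tumor samples.
#' @param mutation_freq data.frame with columns `gene`, `p_low`, `p_high`;
#'   `NULL` for a built-in 20-gene table mixing shared and group-specific
#'   frequencies.
#' @param passenger_rate Poisson mean of passenger mutations per tumor sample.
#' @param n_passenger_genes Size of the passenger gene namespace.
#' @param silent_fraction Fraction of records classed `Silent`.
#' @param subclone_k_choices Candidate subclone counts sampled uniformly per
#'   sample.
#' @param clonal_vaf VAF center of the clonal cluster.
#' @param subclone_vaf_range Range the subclonal VAF centers are drawn from.
#' @param vaf_depth Read depth for binomial allele-count sampling.
#' @param irpm_n_pos,irpm_n_neg Genes constructed to track risk-cell
#'   infiltration positively / negatively (the IRPM ground truth).
#' @param irpm_effect log2 shift per unit mean risk-cell infiltration.
#' @param n_pathways,pathway_size Random gene sets included as "metabolic
#'   pathway" stand-ins.
#' @param tumor_de_genes,tumor_de_effect Genes shifted in tumors vs normals
#'   (log2 effect), for the differential-expression stage.
#' @param stage_advanced_p,grade3_p,male_p Named `c(low=, high=)`
#'   probabilities for the categorical clinical factors.
#' @return Validated config list (class `cohort_config`).
#' @export
cohort_config <- function(n_low = 100, n_high = 100, n_normal = 0,
                          n_genes = 2000,
                          n_cells = 5, markers_per_cell = 20,
                          marker_effect = 1.0, noise_sd = 0.5,
                          infiltration_shift_high = 0.8,
                          baseline_log2_range = c(1, 8),
                          dropout_fraction = 0.02,
                          count_scale = 5, libsize_sd = 0.1,
                          nb_dispersion = 0.15,
                          hazard_baseline = 0.002,
                          hazard_multipliers = NULL,
                          censoring_rate = 0.3,
                          mutation_freq = NULL,
                          passenger_rate = 40, n_passenger_genes = 300,
                          silent_fraction = 0.2,
                          subclone_k_choices = 1:3,
                          clonal_vaf = 0.5,
                          subclone_vaf_range = c(0.08, 0.35),
                          vaf_depth = 100,
                          irpm_n_pos = 40, irpm_n_neg = 15,
                          irpm_effect = 1.0,
                          n_pathways = 10, pathway_size = 30,
                          tumor_de_genes = 0, tumor_de_effect = 2,
                          stage_advanced_p = c(low = 0.72, high = 0.55),
                          grade3_p = c(low = 0.47, high = 0.69),
                          male_p = c(low = 0.82, high = 0.58)) {
  cfg <- as.list(environment())
  if (is.null(cfg$hazard_multipliers))
    cfg$hazard_multipliers <- rep(exp(0.4), n_cells)
  with(cfg, {
    stopifnot(n_low > 0, n_high > 0, n_normal >= 0, n_genes > 0,
              n_cells > 0, markers_per_cell >= 2, noise_sd >= 0,
              dropout_fraction >= 0, dropout_fraction < 1,
              count_scale > 0, nb_dispersion >= 0,
              hazard_baseline > 0, censoring_rate >= 0, censoring_rate < 1,
              all(subclone_k_choices >= 1),
              clonal_vaf > 0, clonal_vaf <= 1,
              all(subclone_vaf_range > 0), all(subclone_vaf_range <= 1),
              vaf_depth >= 1, irpm_n_pos >= 0, irpm_n_neg >= 0,
              silent_fraction >= 0, silent_fraction <= 1,
              tumor_de_genes >= 0)
  })
  if (length(cfg$hazard_multipliers) != n_cells)
    stop("hazard_multipliers must have length n_cells")
  if (any(cfg$hazard_multipliers <= 0)) stop("hazard multipliers must be > 0")
  if (is.null(cfg$mutation_freq)) {
    base <- seq(0.08, 0.5, length.out = 20)
    p_high <- base; p_low <- base
    p_high[1:5] <- pmin(base[1:5] + 0.25, 0.95)   # high-latitude biased
    p_low[6:10] <- pmin(base[6:10] + 0.25, 0.95)  # low-latitude biased
    cfg$mutation_freq <- data.frame(gene = sprintf("MUTG%02d", 1:20),
                                    p_low = p_low, p_high = p_high,
                                    stringsAsFactors = FALSE)
  }
  mf <- cfg$mutation_freq
  if (!all(c("gene", "p_low", "p_high") %in% colnames(mf)))
    stop("mutation_freq needs columns gene, p_low, p_high")
  if (any(mf$p_low < 0 | mf$p_low > 1 | mf$p_high < 0 | mf$p_high > 1))
    stop("mutation probabilities must lie in [0, 1]")
  needed <- n_cells * markers_per_cell + irpm_n_pos + irpm_n_neg + tumor_de_genes
  if (needed > n_genes)
    stop("n_genes too small for the requested structured genes (need >= ", needed, ")")
  structure(cfg, class = "cohort_config")
}

# solve for the exponential censoring rate hitting the target fraction
censoring_rate_for <- function(hazards, target) {
  if (target <= 0) return(0)
  f <- function(cr) mean(cr / (cr + hazards)) - target
  stats::uniroot(f, lower = 1e-10, upper = 1e6, tol = 1e-12)$root
}

#' Generate a synthetic latitude-stratified cohort
#'
#' Deterministic given `(config, seed)`: one seeded generator stream drives
#' all draws in a fixed order. See [cohort_config()] for the data model.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return `synthetic_cohort` object: list with `expression_counts`,
#'   `expression_fpkm`, `mutations`, `clinical`, `genesets`, `truth`,
#'   `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(as.integer(seed))

  ids_low <- sprintf("LOW_%03d", seq_len(cfg$n_low))
  ids_high <- sprintf("HIGH_%03d", seq_len(cfg$n_high))
  ids_norm <- if (cfg$n_normal > 0) sprintf("NORM_%03d", seq_len(cfg$n_normal)) else character(0)
  tumor_ids <- c(ids_low, ids_high)
  all_ids <- c(tumor_ids, ids_norm)
  n_t <- length(tumor_ids); n_all <- length(all_ids)
  group <- stats::setNames(rep(c("low", "high"), c(cfg$n_low, cfg$n_high)), tumor_ids)

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  cells <- sprintf("cell_%02d", seq_len(cfg$n_cells))
  names(cfg$hazard_multipliers) <- cells

  # gene role allocation (contiguous blocks, then noise genes)
  idx <- 0L
  marker_idx <- lapply(seq_len(cfg$n_cells), function(c_) {
    out <- idx + seq_len(cfg$markers_per_cell); idx <<- idx + cfg$markers_per_cell; out
  })
  names(marker_idx) <- cells
  irpm_pos_idx <- idx + seq_len(cfg$irpm_n_pos); idx <- idx + cfg$irpm_n_pos
  irpm_neg_idx <- idx + seq_len(cfg$irpm_n_neg); idx <- idx + cfg$irpm_n_neg
  de_idx <- if (cfg$tumor_de_genes > 0) idx + seq_len(cfg$tumor_de_genes) else integer(0)

  # latent infiltration (tumors only; normals sit at 0)
  shift <- ifelse(group == "high", cfg$infiltration_shift_high, 0)
  Z <- matrix(stats::rnorm(n_t * cfg$n_cells), nrow = n_t,
              dimnames = list(tumor_ids, cells)) +
    matrix(shift, nrow = n_t, ncol = cfg$n_cells)
  Zf <- rbind(Z, matrix(0, nrow = cfg$n_normal, ncol = cfg$n_cells,
                        dimnames = list(ids_norm, cells)))
  risk_cells <- cells[cfg$hazard_multipliers > 1]
  r <- if (length(risk_cells) > 0)
    rowMeans(Zf[, risk_cells, drop = FALSE]) else stats::setNames(rep(0, n_all), all_ids)

  # expression: baseline + structured effects + noise, on the log2 scale
  baseline <- stats::runif(cfg$n_genes, cfg$baseline_log2_range[1L],
                           cfg$baseline_log2_range[2L])
  E <- matrix(stats::rnorm(cfg$n_genes * n_all, sd = cfg$noise_sd),
              nrow = cfg$n_genes, dimnames = list(genes, all_ids)) + baseline
  for (c_ in cells)
    E[marker_idx[[c_]], ] <- sweep(E[marker_idx[[c_]], , drop = FALSE], 2L,
                                   cfg$marker_effect * Zf[, c_], "+")
  if (cfg$irpm_n_pos > 0)
    E[irpm_pos_idx, ] <- sweep(E[irpm_pos_idx, , drop = FALSE], 2L,
                               cfg$irpm_effect * r, "+")
  if (cfg$irpm_n_neg > 0)
    E[irpm_neg_idx, ] <- sweep(E[irpm_neg_idx, , drop = FALSE], 2L,
                               cfg$irpm_effect * r, "-")
  if (length(de_idx) > 0 && n_t > 0)
    E[de_idx, tumor_ids] <- E[de_idx, tumor_ids, drop = FALSE] + cfg$tumor_de_effect

  fpkm <- 2^E
  if (cfg$dropout_fraction > 0) {
    drop_n <- round(cfg$dropout_fraction * length(fpkm))
    if (drop_n > 0) fpkm[sample.int(length(fpkm), drop_n)] <- 0
  }
  lib <- exp(stats::rnorm(n_all, sd = cfg$libsize_sd))
  mu <- sweep(fpkm * cfg$count_scale, 2L, lib, "*")
  counts_v <- if (cfg$nb_dispersion > 0)
    stats::rnbinom(length(mu), size = 1 / cfg$nb_dispersion, mu = mu)
  else stats::rpois(length(mu), lambda = mu)
  counts <- matrix(as.numeric(counts_v), nrow = cfg$n_genes,
                   dimnames = dimnames(mu))

  # survival for tumors: exponential with infiltration-linked hazard
  log_h <- log(cfg$hazard_baseline) +
    as.vector(Z %*% log(cfg$hazard_multipliers))
  h <- exp(log_h)
  t_event <- stats::rexp(n_t, rate = h)
  cr <- censoring_rate_for(h, cfg$censoring_rate)
  t_cens <- if (cr > 0) stats::rexp(n_t, rate = cr) else rep(Inf, n_t)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.numeric(t_event <= t_cens)

  latitude <- c(stats::runif(cfg$n_low, 0, 45), stats::runif(cfg$n_high, 46, 90))
  p_of <- function(p) unname(p[group])
  clinical <- data.frame(
    sample_id = all_ids,
    os_time = c(round(os_time, 2), rep(NA_real_, cfg$n_normal)),
    os_event = c(os_event, rep(NA_real_, cfg$n_normal)),
    latitude_deg = c(latitude, rep(NA_real_, cfg$n_normal)),
    sample_type = rep(c("tumor", "normal"), c(n_t, cfg$n_normal)),
    stage = c(ifelse(stats::runif(n_t) < p_of(cfg$stage_advanced_p), "III-IV", "I-II"),
              rep(NA_character_, cfg$n_normal)),
    grade = c(ifelse(stats::runif(n_t) < p_of(cfg$grade3_p), "G3", "G1-2"),
              rep(NA_character_, cfg$n_normal)),
    gender = c(ifelse(stats::runif(n_t) < p_of(cfg$male_p), "male", "female"),
               rep(NA_character_, cfg$n_normal)),
    stringsAsFactors = FALSE
  )

  # mutations: group-frequency genes + passengers, VAFs from subclone mixtures
  ks <- cfg$subclone_k_choices[sample.int(length(cfg$subclone_k_choices), n_t,
                                          replace = TRUE)]
  centers <- lapply(seq_len(n_t), function(i) {
    k <- ks[i]
    if (k == 1) cfg$clonal_vaf
    else c(cfg$clonal_vaf,
           sort(stats::runif(k - 1, cfg$subclone_vaf_range[1L],
                             cfg$subclone_vaf_range[2L]), decreasing = TRUE))
  })
  weights <- lapply(seq_len(n_t), function(i) {
    k <- ks[i]
    if (k == 1) 1 else c(0.5, rep(0.5 / (k - 1), k - 1))
  })
  names(ks) <- tumor_ids; names(centers) <- tumor_ids; names(weights) <- tumor_ids

  mf <- cfg$mutation_freq
  pass_genes <- sprintf("PASS%04d", seq_len(cfg$n_passenger_genes))
  rec <- vector("list", n_t)
  for (i in seq_len(n_t)) {
    sid <- tumor_ids[i]
    p <- if (group[sid] == "low") mf$p_low else mf$p_high
    g_mut <- mf$gene[stats::runif(nrow(mf)) < p]
    n_pass <- stats::rpois(1L, cfg$passenger_rate)
    g_pass <- if (n_pass > 0) sample(pass_genes, n_pass, replace = TRUE) else character(0)
    g_all <- c(g_mut, g_pass)
    if (length(g_all) == 0L) next
    comp <- sample.int(ks[i], length(g_all), replace = TRUE, prob = weights[[i]])
    vaf <- centers[[i]][comp]
    alt <- stats::rbinom(length(g_all), cfg$vaf_depth, vaf)
    cls <- ifelse(stats::runif(length(g_all)) < cfg$silent_fraction,
                  "Silent", "Missense_Mutation")
    rec[[i]] <- data.frame(
      sample_id = sid, gene = g_all, variant_classification = cls,
      chrom = as.character(sample.int(22L, length(g_all), replace = TRUE)),
      position = sample.int(1e8L, length(g_all), replace = TRUE),
      ref_count = cfg$vaf_depth - alt, alt_count = alt,
      stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, rec)
  if (is.null(mutations))
    mutations <- data.frame(sample_id = character(0), gene = character(0),
                            variant_classification = character(0),
                            chrom = character(0), position = numeric(0),
                            ref_count = numeric(0), alt_count = numeric(0),
                            stringsAsFactors = FALSE)
  mutations$synonymous <- mutations$variant_classification %in% SYNONYMOUS_CLASSES
  mutations$known_class <- TRUE

  gs <- lapply(marker_idx, function(ix) genes[ix])
  if (cfg$n_pathways > 0) {
    pw <- lapply(seq_len(cfg$n_pathways), function(i)
      genes[sample.int(cfg$n_genes, min(cfg$pathway_size, cfg$n_genes))])
    names(pw) <- sprintf("pathway_%02d", seq_len(cfg$n_pathways))
    gs <- c(gs, pw)
  }

  truth <- list(
    group = group,
    infiltration = Zf,
    hazard_multipliers = cfg$hazard_multipliers,
    risk_cells = risk_cells,
    mutation_freq = mf,
    subclone_k = ks,
    vaf_centers = centers,
    vaf_weights = weights,
    irpm_pos_genes = genes[irpm_pos_idx],
    irpm_neg_genes = genes[irpm_neg_idx],
    tumor_de_genes = genes[de_idx],
    marker_genes = gs[cells],
    hazard = stats::setNames(h, tumor_ids),
    censoring_rate = cfg$censoring_rate
  )

  structure(list(
    expression_counts = expression_matrix(counts, "counts"),
    expression_fpkm = expression_matrix(fpkm, "fpkm"),
    mutations = mutations,
    clinical = clinical,
    genesets = gs,
    truth = truth,
    config = cfg,
    seed = as.integer(seed)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d low + %d high latitude tumors, %d normals, %d genes, %d immune cells, %d mutation records (seed %d)\n",
    x$config$n_low, x$config$n_high, x$config$n_normal, x$config$n_genes,
    x$config$n_cells, nrow(x$mutations), x$seed))
  invisible(x)
}

#' Ground truth of a synthetic cohort
#' @param cohort A [generate_cohort()] result.
#' @return The stored truth list, unchanged.
#' @export
truth_report <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort") || is.null(cohort$truth))
    stop("cohort carries no ground truth")
  cohort$truth
}

#' Simulate a single sample's VAF records
#'
#' Draws variant allele fractions from a declared mixture of VAF centers and
#' read-samples them at fixed depth, returning mutation-table records. Used
#' to test subclone inference against a known truth.
#'
#' @param sample_id Sample identifier for the records.
#' @param centers VAF cluster centers in (0, 1].
#' @param weights Mixture weights (recycled to uniform if NULL).
#' @param n_variants Number of variant records.
#' @param depth Read depth (default 100).
#' @return Mutation-table data.frame.
#' @export
simulate_vaf_records <- function(sample_id, centers, weights = NULL,
                                 n_variants = 50, depth = 100) {
  stopifnot(all(centers > 0), all(centers <= 1), n_variants >= 1, depth >= 1)
  if (is.null(weights)) weights <- rep(1 / length(centers), length(centers))
  comp <- sample.int(length(centers), n_variants, replace = TRUE, prob = weights)
  alt <- stats::rbinom(n_variants, depth, centers[comp])
  data.frame(sample_id = sample_id,
             gene = sprintf("VARG%04d", seq_len(n_variants)),
             variant_classification = "Missense_Mutation",
             chrom = "1", position = seq_len(n_variants),
             ref_count = depth - alt, alt_count = alt,
             synonymous = FALSE, known_class = TRUE,
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Emits the package's standard on-disk formats: counts and FPKM expression
#' TSVs, MAF-subset TSV, clinical TSV, gene sets as GMT, config as YAML.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "expression_counts.tsv"),
    fpkm = file.path(dir, "expression_fpkm.tsv"),
    maf = file.path(dir, "mutations.maf.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    genesets = file.path(dir, "genesets.gmt"),
    config = file.path(dir, "config.yaml")
  )
  write_expression_matrix(cohort$expression_counts, paths["counts"])
  write_expression_matrix(cohort$expression_fpkm, paths["fpkm"])
  write_maf(cohort$mutations, paths["maf"])
  write_clinical(cohort$clinical, paths["clinical"])
  write_gmt(cohort$genesets, paths["genesets"])
  cfg <- cohort$config
  cfg$mutation_freq <- as.list(cfg$mutation_freq)
  yaml::write_yaml(c(unclass(cfg), list(seed = cohort$seed)), paths["config"])
  paths
}
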