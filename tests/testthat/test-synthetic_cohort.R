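small_cfg <- function(...) {
  cohort_config(n_low = 25, n_high = 25, n_genes = 200, markers_per_cell = 5,
                n_cells = 3, irpm_n_pos = 8, irpm_n_neg = 4,
                passenger_rate = 15, n_pathways = 2, ...)
}

test_that("generation is deterministic under a fixed seed, distinct across seeds", {
  a <- generate_cohort(small_cfg(), seed = 5)
  b <- generate_cohort(small_cfg(), seed = 5)
  expect_identical(a, b)
  c_ <- generate_cohort(small_cfg(), seed = 6)
  expect_false(identical(a$expression_fpkm, c_$expression_fpkm))
  expect_false(identical(a$mutations, c_$mutations))
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(n_low = 0), "n_low")
  expect_error(cohort_config(censoring_rate = 1.2))
  expect_error(cohort_config(mutation_freq = data.frame(
    gene = "A", p_low = 1.4, p_high = 0.2)), "probabilities")
  expect_error(cohort_config(n_genes = 10), "too small")
  expect_error(cohort_config(hazard_multipliers = c(1, 2)), "length n_cells")
})

test_that("cohort components share sample ids and respect layouts", {
  co <- generate_cohort(small_cfg(n_normal = 5), seed = 3)
  ids <- co$clinical$sample_id
  expect_identical(colnames(co$expression_fpkm), ids)
  expect_identical(colnames(co$expression_counts), ids)
  expect_true(all(co$mutations$sample_id %in% ids))
  expect_identical(expr_layout(co$expression_counts), "counts")
  expect_identical(expr_layout(co$expression_fpkm), "fpkm")
  expect_true(all(co$expression_counts >= 0))
  expect_true(all(co$mutations$ref_count + co$mutations$alt_count > 0))
  # normals carry no survival or mutations
  norm <- co$clinical[co$clinical$sample_type == "normal", ]
  expect_true(all(is.na(norm$os_time)))
  expect_false(any(co$mutations$sample_id %in% norm$sample_id))
})

test_that("noiseless single-cell config makes markers track infiltration exactly", {
  cfg <- cohort_config(n_low = 30, n_high = 30, n_genes = 50, n_cells = 1,
                       markers_per_cell = 10, noise_sd = 0,
                       dropout_fraction = 0, irpm_n_pos = 0, irpm_n_neg = 0,
                       n_pathways = 0)
  co <- generate_cohort(cfg, seed = 2)
  tr <- truth_report(co)
  markers <- tr$marker_genes$cell_01
  mean_marker <- colMeans(log2(co$expression_fpkm[markers, ]))
  rho <- cor(mean_marker, tr$infiltration[names(mean_marker), "cell_01"],
             method = "spearman")
  expect_equal(rho, 1)
})

test_that("marker-infiltration correlation clears the noise-implied threshold", {
  # Monte-Carlo oracle: simulate the declared observation model directly
  # (log2 mean = baseline + effect * z + Gaussian noise, FPKM = 2^mean with
  # dropout zeros, observed as log2(FPKM + 1)) and take a conservative lower
  # bound for the per-cell mean Pearson r across marker genes.
  cfg <- cohort_config()   # 200 samples, 2000 genes, 5 cells
  n <- cfg$n_low + cfg$n_high
  set.seed(123)
  sim_means <- vapply(1:10, function(rep) {
    z <- rnorm(n)
    g <- vapply(seq_len(cfg$markers_per_cell), function(i) {
      x <- runif(1, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2]) +
        cfg$marker_effect * z + rnorm(n, sd = cfg$noise_sd)
      fp <- 2^x
      fp[runif(n) < cfg$dropout_fraction] <- 0
      log2(fp + 1)
    }, numeric(n))
    mean(cor(g, z))
  }, numeric(1))
  threshold <- min(sim_means) - 3 * sd(sim_means)

  co <- generate_cohort(cfg, seed = 7)
  tr <- truth_report(co)
  lg <- log2(co$expression_fpkm + 1)
  for (cell in names(tr$marker_genes)) {
    r_bar <- mean(cor(t(lg[tr$marker_genes[[cell]], ]),
                      tr$infiltration[colnames(lg), cell]))
    expect_gt(r_bar, threshold)
  }
})

test_that("mutation frequencies converge to group probabilities at n = 1000", {
  mf <- data.frame(gene = c("A", "B", "C"),
                   p_low = c(0.1, 0.4, 0.25),
                   p_high = c(0.3, 0.4, 0.05), stringsAsFactors = FALSE)
  cfg <- cohort_config(n_low = 500, n_high = 500, n_genes = 60, n_cells = 1,
                       markers_per_cell = 5, irpm_n_pos = 0, irpm_n_neg = 0,
                       mutation_freq = mf, passenger_rate = 0, n_pathways = 0,
                       dropout_fraction = 0)
  co <- generate_cohort(cfg, seed = 11)
  tr <- truth_report(co)
  mm <- mutation_matrix(co$mutations, mf$gene, names(tr$group))
  for (i in seq_len(nrow(mf))) {
    for (grp in c("low", "high")) {
      ids <- names(tr$group)[tr$group == grp]
      phat <- mean(mm[mf$gene[i], ids])
      p <- mf[[paste0("p_", grp)]][i]
      ci <- qbinom(c(0.0005, 0.9995), length(ids), p) / length(ids)
      expect_gte(phat, ci[1]); expect_lte(phat, ci[2])
    }
  }
  # censoring fraction lands within 5 points of the configured rate
  tumors <- co$clinical[co$clinical$sample_type == "tumor", ]
  expect_lt(abs(mean(tumors$os_event == 0) - cfg$censoring_rate), 0.05)
})

test_that("truth report exposes the generating parameters unchanged", {
  cfg <- small_cfg(hazard_multipliers = rep(1, 3), subclone_k_choices = 3)
  co <- generate_cohort(cfg, seed = 9)
  tr <- truth_report(co)
  expect_identical(length(tr$group), 50L)
  expect_true(all(tr$hazard_multipliers == 1))
  expect_identical(length(tr$risk_cells), 0L)
  expect_true(all(vapply(tr$vaf_centers, length, integer(1)) == 3L))
  expect_error(truth_report(list(a = 1)), "no ground truth")
})

test_that("a cohort written to disk reads back equivalently", {
  co <- generate_cohort(small_cfg(n_normal = 3), seed = 4)
  dir <- file.path(tempdir(), "cohort_rt")
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  fpkm <- read_expression_matrix(paths["fpkm"], "fpkm")
  expect_equal(unclass(fpkm), unclass(co$expression_fpkm), ignore_attr = TRUE,
               tolerance = 1e-6)
  maf <- read_maf(paths["maf"])
  expect_identical(nrow(maf), nrow(co$mutations))
  expect_identical(sort(unique(maf$gene)), sort(unique(co$mutations$gene)))
  cl <- read_clinical(paths["clinical"])
  expect_identical(cl$sample_id, co$clinical$sample_id)
  sets <- read_gmt(paths["genesets"])
  expect_identical(sets, co$genesets)
})
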