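# ---- mutation profiling ------------------------------------------------------

#' Drop synonymous variants from a mutation table
#'
#' Records whose `variant_classification` is in the synonymous vocabulary
#' (default `Silent`, `Synonymous_Variant`) are removed. Classes outside the
#' recognised vocabulary are retained with a warning.
#'
#' @param mut Mutation table (see [read_maf()]).
#' @param synonymous_classes Character vector of classes treated as synonymous.
#' @return Filtered mutation table.
#' @export
remove_synonymous <- function(mut, synonymous_classes = SYNONYMOUS_CLASSES) {
  unknown <- setdiff(unique(mut$variant_classification),
                     union(KNOWN_VARIANT_CLASSES, synonymous_classes))
  if (length(unknown) > 0L)
    warning("unknown variant class(es) retained: ", paste(unknown, collapse = ", "))
  out <- mut[!mut$variant_classification %in% synonymous_classes, , drop = FALSE]
  if (nrow(out) == 0L) warning("no records remain after removing synonymous variants")
  rownames(out) <- NULL
  out
}

#' Tumor mutation burden per sample
#'
#' TMB = number of (nonsynonymous) somatic mutations divided by the size in
#' megabases of the interrogated territory. Synonymous variants are expected
#' to have been removed already (see [remove_synonymous()]). Samples listed
#' in `samples` but absent from the table get TMB 0.
#'
#' @param mut Mutation table.
#' @param capture_size_mb Interrogated territory in Mb (default 38, a common
#'   whole-exome convention).
#' @param samples Optional character vector of all cohort sample ids.
#' @return data.frame with `sample_id`, `n_mutations`, `tmb`.
#' @export
compute_tmb <- function(mut, capture_size_mb = 38, samples = NULL) {
  if (capture_size_mb <= 0) stop("capture_size_mb must be positive")
  if (is.null(samples)) samples <- sort(unique(mut$sample_id))
  counts <- table(factor(mut$sample_id, levels = samples))
  data.frame(sample_id = samples,
             n_mutations = as.integer(counts),
             tmb = as.numeric(counts) / capture_size_mb,
             stringsAsFactors = FALSE)
}

#' Most frequently mutated genes
#'
#' Genes ordered by the number of distinct mutated samples (ties broken
#' alphabetically by gene symbol).
#'
#' @param mut Mutation table.
#' @param n Number of genes to return (default 25); capped at the gene count.
#' @param samples Optional cohort sample ids, used for the fraction denominator.
#' @return data.frame with `gene`, `n_samples`, `fraction`.
#' @export
top_mutated_genes <- function(mut, n = 25, samples = NULL) {
  if (is.null(samples)) samples <- unique(mut$sample_id)
  n_total <- length(samples)
  per_gene <- tapply(mut$sample_id, mut$gene, function(s) length(unique(s)))
  if (length(per_gene) == 0L)
    return(data.frame(gene = character(0), n_samples = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  ord <- order(-per_gene, names(per_gene))
  per_gene <- per_gene[ord]
  head_n <- min(n, length(per_gene))
  data.frame(gene = names(per_gene)[seq_len(head_n)],
             n_samples = as.integer(per_gene[seq_len(head_n)]),
             fraction = as.numeric(per_gene[seq_len(head_n)]) / n_total,
             stringsAsFactors = FALSE)
}

#' Binary gene-by-sample mutation indicator matrix
#' @param mut Mutation table.
#' @param genes Genes to include (rows).
#' @param samples Samples to include (columns).
#' @return Logical matrix genes x samples.
#' @export
mutation_matrix <- function(mut, genes, samples) {
  m <- matrix(FALSE, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  sel <- mut$gene %in% genes & mut$sample_id %in% samples
  if (any(sel)) m[cbind(mut$gene[sel], mut$sample_id[sel])] <- TRUE
  m
}

#' Pairwise co-occurrence / mutual exclusivity of mutated genes
#'
#' For each gene pair, a two-sided Fisher's exact test on the 2x2 table of
#' samples mutated in both, only one, or neither gene. Pairs with p below
#' `p_threshold` are labelled `co-occurring` when the cross-product odds
#' ratio exceeds 1 and `exclusive` when it is below 1; all others (and pairs
#' involving a gene absent from the table) are `none`. BH q-values are
#' reported but labels follow raw p, matching the usual oncoplot convention.
#'
#' @param mut Mutation table.
#' @param genes Genes to test pairwise (>= 2).
#' @param samples Optional cohort sample ids (defaults to samples in `mut`).
#' @param p_threshold Label threshold on raw p (default 0.05).
#' @return data.frame with `gene_a`, `gene_b`, `n_both`, `n_a_only`,
#'   `n_b_only`, `n_neither`, `odds_ratio`, `p`, `q`, `label`.
#' @export
somatic_interactions <- function(mut, genes, samples = NULL, p_threshold = 0.05) {
  if (length(genes) < 2L) stop("need at least 2 genes")
  if (is.null(samples)) samples <- unique(mut$sample_id)
  mm <- mutation_matrix(mut, genes, samples)
  pairs <- utils::combn(genes, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    va <- mm[a, ]; vb <- mm[b, ]
    tab <- matrix(c(sum(va & vb), sum(va & !vb),
                    sum(!va & vb), sum(!va & !vb)), nrow = 2L, byrow = TRUE)
    fr <- fisher_or(tab)
    label <- "none"
    if (any(va) && any(vb) && fr$p_value < p_threshold) {
      if (is.finite(fr$odds_ratio) && fr$odds_ratio < 1) label <- "exclusive"
      else if (fr$odds_ratio > 1) label <- "co-occurring"
    }
    data.frame(gene_a = a, gene_b = b,
               n_both = tab[1, 1], n_a_only = tab[1, 2],
               n_b_only = tab[2, 1], n_neither = tab[2, 2],
               odds_ratio = fr$odds_ratio, p = fr$p_value, label = label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("gene_a", "gene_b", "n_both", "n_a_only", "n_b_only", "n_neither",
          "odds_ratio", "p", "q", "label")]
}

#' Infer subclone structure from a sample's VAF distribution
#'
#' Variant allele fractions (alt / (ref + alt)) of one sample are fitted with
#' 1-D Gaussian mixtures for k = 1..`k_max`; k is chosen by BIC. Components
#' holding fewer than `min_cluster_size` variants are merged into the nearest
#' remaining component. The highest-VAF cluster is flagged as the putative
#' clonal population; the subclone count reported is the total number of
#' mixture components after merging.
#'
#' @param mut Mutation table with allele counts.
#' @param sample Sample id.
#' @param k_max Maximum number of mixture components (default 5).
#' @param min_cluster_size Minimum variants per component (default 3).
#' @param min_vaf_count Minimum variants with allele counts required to fit
#'   (default 10); below it the result is flagged not evaluable.
#' @return List: `sample_id`, `evaluable`, `vaf`, `k`, `means` (decreasing),
#'   `sizes`, `clonal_mean` (highest-VAF cluster), `bic` (smaller is better,
#'   one entry per candidate k).
#' @importFrom mclust Mclust mclustBIC
#' @export
infer_subclones <- function(mut, sample, k_max = 5, min_cluster_size = 3,
                            min_vaf_count = 10) {
  rec <- mut[mut$sample_id == sample & !is.na(mut$ref_count) &
               !is.na(mut$alt_count), , drop = FALSE]
  vaf <- rec$alt_count / (rec$ref_count + rec$alt_count)
  vaf <- vaf[is.finite(vaf)]
  if (length(vaf) < min_vaf_count)
    return(list(sample_id = sample, evaluable = FALSE, vaf = vaf,
                k = NA_integer_, means = numeric(0), sizes = integer(0),
                clonal_mean = NA_real_, bic = numeric(0)))
  if (stats::sd(vaf) == 0) {
    return(list(sample_id = sample, evaluable = TRUE, vaf = vaf, k = 1L,
                means = mean(vaf), sizes = length(vaf),
                clonal_mean = mean(vaf), bic = NA_real_))
  }
  fit <- mclust::Mclust(vaf, G = seq_len(k_max), modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit))
    fit <- mclust::Mclust(vaf, G = seq_len(k_max), modelNames = "E",
                          verbose = FALSE)
  means <- as.numeric(fit$parameters$mean)
  cls <- fit$classification
  # merge undersized clusters into the nearest surviving component
  repeat {
    sizes <- tabulate(cls, nbins = length(means))
    present <- which(sizes > 0L)
    small <- present[sizes[present] < min_cluster_size]
    if (length(small) == 0L || length(present) == 1L) break
    victim <- small[which.min(sizes[small])]
    others <- setdiff(present, victim)
    target <- others[which.min(abs(means[others] - means[victim]))]
    cls[cls == victim] <- target
  }
  present <- sort(unique(cls))
  cl_means <- vapply(present, function(g) mean(vaf[cls == g]), numeric(1L))
  ord <- order(-cl_means)
  bic_trace <- -as.numeric(fit$BIC)[seq_len(k_max)]  # standard sign: minimize
  names(bic_trace) <- paste0("k", seq_len(k_max))
  list(sample_id = sample, evaluable = TRUE, vaf = vaf,
       k = length(present),
       means = cl_means[ord],
       sizes = tabulate(cls, nbins = max(cls))[present][ord],
       clonal_mean = max(cl_means),
       bic = bic_trace)
}

#' Frequency-based driver gene selection
#'
#' Selects genes mutated in at least `max(min_fraction * n, min_samples)`
#' samples, ordered by mutated-sample count (ties alphabetical).
#'
#' @param mut Mutation table.
#' @param samples Optional cohort sample ids (denominator for the fraction).
#' @param min_fraction Minimum mutated-sample fraction (default 0.05).
#' @param min_samples Minimum mutated-sample count (default 5).
#' @return Character vector of gene symbols.
#' @export
select_driver_genes <- function(mut, samples = NULL, min_fraction = 0.05,
                                min_samples = 5) {
  if (nrow(mut) == 0L) return(character(0))
  if (is.null(samples)) samples <- unique(mut$sample_id)
  per_gene <- tapply(mut$sample_id, mut$gene, function(s) length(unique(s)))
  cutoff <- max(min_fraction * length(samples), min_samples)
  sel <- per_gene[per_gene >= cutoff]
  if (length(sel) == 0L) return(character(0))
  names(sel)[order(-sel, names(sel))]
}
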