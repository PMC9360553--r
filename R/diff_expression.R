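# ---- count normalization and rank-based differential expression -------------

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values normalization factors against a reference sample
#' (30% trim on log-ratios, 5% on average abundance), rescaled so their
#' geometric mean is 1. Factors multiply library sizes to give effective
#' sizes. Computed with edgeR's TMM implementation.
#'
#' @param counts Counts-layout expression matrix (>= 2 samples).
#' @return Named numeric vector of scaling factors, one per sample.
#' @export
tmm_normalize <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2L)
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample(s) with all-zero counts: ",
                              paste(colnames(counts)[libsize == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = 0.3, sumTrim = 0.05)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Normalized log2 counts-per-million
#' @param counts Counts matrix.
#' @param factors TMM factors from [tmm_normalize()] (recomputed if NULL).
#' @param prior Pseudo-CPM added before log2 (default 1).
#' @return log2-CPM matrix.
#' @export
log2_cpm <- function(counts, factors = NULL, prior = 1) {
  if (is.null(factors)) factors <- tmm_normalize(counts)
  eff <- colSums(counts) * factors[colnames(counts)]
  log2(sweep(counts, 2L, eff, "/") * 1e6 + prior)
}

#' Rank-based differential expression between two sample groups
#'
#' A dependency-light count pipeline: TMM-normalized log2-CPM, per-gene
#' two-sided Wilcoxon rank-sum test (normal approximation), BH adjustment.
#' log2 fold change is the difference of group means on the log2-CPM scale
#' (tumor minus normal). Genes are called `up`/`down` when
#' `|logFC| >= lfc_min` and `q <= q_max`.
#'
#' @param counts Counts matrix.
#' @param group_tumor,group_normal Disjoint sample-id vectors, each >= 3.
#' @param lfc_min Absolute log2-fold-change threshold (default 1).
#' @param q_max BH q threshold (default 0.05).
#' @return data.frame: `gene`, `logFC`, `stat`, `p`, `q`, `call`.
#' @export
differential_expression <- function(counts, group_tumor, group_normal,
                                    lfc_min = 1, q_max = 0.05) {
  if (length(intersect(group_tumor, group_normal)) > 0L)
    stop("tumor and normal groups overlap")
  if (length(group_tumor) < 3L || length(group_normal) < 3L)
    stop("each group needs at least 3 samples")
  miss <- setdiff(c(group_tumor, group_normal), colnames(counts))
  if (length(miss) > 0L) stop("samples absent from counts: ",
                              paste(miss, collapse = ", "))
  sub <- counts[, c(group_tumor, group_normal), drop = FALSE]
  lcpm <- log2_cpm(sub)
  it <- seq_along(group_tumor)
  io <- length(group_tumor) + seq_along(group_normal)
  logfc <- rowMeans(lcpm[, it, drop = FALSE]) - rowMeans(lcpm[, io, drop = FALSE])
  pw <- apply(lcpm, 1L, function(v) {
    x <- v[it]; y <- v[io]
    if (length(unique(c(x, y))) == 1L) return(c(length(x) * length(y) / 2, 1))
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    c(unname(wt$statistic), wt$p.value)
  })
  p <- pw[2L, ]
  q <- stats::p.adjust(p, method = "BH")
  call <- rep("none", nrow(sub))
  call[q <= q_max & logfc >= lfc_min] <- "up"
  call[q <= q_max & logfc <= -lfc_min] <- "down"
  data.frame(gene = rownames(sub), logFC = logfc, stat = pw[1L, ],
             p = p, q = q, call = call, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Decompose two DE tables into shared and group-specific calls
#'
#' @param de_high,de_low DE tables over the same gene universe.
#' @return List with per-direction (`up`, `down`) gene sets `shared`,
#'   `high_specific`, `low_specific`, `neither`.
#' @export
de_overlap <- function(de_high, de_low) {
  if (!setequal(de_high$gene, de_low$gene))
    stop("DE tables cover different gene universes")
  de_low <- de_low[match(de_high$gene, de_low$gene), ]
  out <- lapply(c(up = "up", down = "down"), function(dir) {
    h <- de_high$gene[de_high$call == dir]
    l <- de_low$gene[de_low$call == dir]
    list(shared = intersect(h, l),
         high_specific = setdiff(h, l),
         low_specific = setdiff(l, h),
         neither = setdiff(de_high$gene, union(h, l)))
  })
  out
}
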