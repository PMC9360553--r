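# ---- single-sample gene set enrichment ---------------------------------------

#' ssGSEA activity scores
#'
#' For each sample, genes are ranked by expression (average ranks for ties;
#' the running sum walks genes in decreasing expression order, ties broken by
#' gene id for determinism). The enrichment score of a set is the sum over
#' all ranked positions of the difference between the weighted in-set ECDF
#' (weights `rank^alpha`) and the unweighted out-of-set ECDF. With
#' `normalize = TRUE` every score is divided by the range (max - min) of the
#' whole score matrix, the usual ssGSEA normalisation.
#'
#' Scores depend on expression only through within-sample ranks, so any
#' strictly monotone per-sample transform leaves them unchanged.
#'
#' @param mat Expression matrix (`log2` or `fpkm` layout), genes x samples.
#' @param sets Named list of gene sets.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide by the score-matrix range (default TRUE).
#' @param min_overlap Sets with fewer genes present in `mat` are dropped with
#'   a warning (default 2).
#' @return Score matrix (sets x samples) with attribute `normalized`.
#' @export
ssgsea_scores <- function(mat, sets, alpha = 0.25, normalize = TRUE,
                          min_overlap = 2) {
  stopifnot(is.matrix(mat), is.list(sets), length(sets) > 0L)
  genes <- rownames(mat)
  keep <- vapply(sets, function(s) sum(s %in% genes) >= min_overlap, logical(1L))
  if (!all(keep))
    warning("dropping gene set(s) with < ", min_overlap, " genes present: ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  if (length(sets) == 0L) stop("no gene set overlaps the expression matrix")
  n <- nrow(mat)
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(mat),
                   dimnames = list(names(sets), colnames(mat)))
  set_idx <- lapply(sets, function(s) which(genes %in% s))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    if (length(unique(x)) == 1L)
      stop("sample '", colnames(mat)[j], "' has constant expression")
    r <- rank(x, ties.method = "average")
    ord <- order(-x, genes)            # decreasing expression, ties by gene id
    w <- r[ord]^alpha
    for (i in seq_along(set_idx)) {
      inset <- ord %in% set_idx[[i]]
      m <- sum(inset)
      p_in <- cumsum(w * inset) / sum(w[inset])
      p_out <- cumsum(!inset) / (n - m)
      scores[i, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores)
    scores <- scores / (rng[2L] - rng[1L])
  }
  attr(scores, "normalized") <- normalize
  scores
}

#' ESTIMATE-style composite scores
#'
#' Computes unnormalised ssGSEA scores for a stromal and an immune gene
#' signature and their per-sample sum (the "estimate" score, a proxy for the
#' non-tumor content of a sample).
#'
#' @param mat Expression matrix.
#' @param stromal_set,immune_set Character vectors of gene symbols.
#' @param alpha Rank-weighting exponent passed to [ssgsea_scores()].
#' @return Score matrix with rows `stromal`, `immune`, `estimate`.
#' @export
estimate_scores <- function(mat, stromal_set, immune_set, alpha = 0.25) {
  s <- ssgsea_scores(mat, list(stromal = stromal_set, immune = immune_set),
                     alpha = alpha, normalize = FALSE)
  out <- rbind(s, estimate = s["stromal", ] + s["immune", ])
  attr(out, "normalized") <- FALSE
  out
}

# ---- group comparison --------------------------------------------------------

#' Compare activity scores between two sample groups
#'
#' Per feature, a two-sided Wilcoxon rank-sum test between the two groups:
#' exact enumeration when both groups have at most 10 samples and the values
#' are tie-free, the normal approximation otherwise. Directions come from
#' group medians; BH-adjusted q-values are reported alongside raw p.
#'
#' @param scores Feature x sample score matrix.
#' @param groups Named character vector mapping sample ids to two group
#'   labels (conventionally "low" / "high").
#' @param p_threshold Significance level used for the `direction` call
#'   (default 0.05).
#' @return data.frame with columns `feature`, per-group medians, `stat`, `p`,
#'   `q`, `direction` (`higher_in_<label>` or `"none"`).
#' @export
compare_groups <- function(scores, groups, p_threshold = 0.05) {
  common <- intersect(colnames(scores), names(groups))
  g <- factor(groups[common])
  if (nlevels(g) != 2L) stop("need exactly two groups, got ", nlevels(g))
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  lv <- levels(g)
  sc <- scores[, common, drop = FALSE]
  res <- lapply(rownames(sc), function(f) {
    x <- sc[f, g == lv[1L]]
    y <- sc[f, g == lv[2L]]
    if (length(unique(c(x, y))) == 1L) {
      stat <- length(x) * length(y) / 2; p <- 1
    } else {
      exact <- length(x) <= 10L && length(y) <= 10L &&
        !anyDuplicated(c(x, y))
      wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                               correct = !exact)
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    med <- c(stats::median(x), stats::median(y))
    dir <- if (p >= p_threshold || med[1L] == med[2L]) "none"
      else paste0("higher_in_", lv[which.max(med)])
    data.frame(feature = f, median_1 = med[1L], median_2 = med[2L],
               stat = stat, p = p, direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  colnames(out)[2:3] <- paste0("median_", lv)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("feature", paste0("median_", lv), "stat", "p", "q", "direction")]
}
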