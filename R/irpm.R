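# ---- immune-related prognostic model (IRPM) ----------------------------------
# Three-step construction: (1) rank immune cells by univariate Cox
# significance and keep the top n; (2) take the genes most correlated with
# the selected cells' infiltration and split them by correlation sign; (3)
# score each sample with the Welch t statistic contrasting the expression of
# positive vs negative signature genes, dichotomized at the training median.

#' Rank immune cells by univariate prognostic significance
#'
#' Fits a univariate Cox model per immune cell (continuous infiltration
#' score vs overall survival) and returns the `n_cells` most significant
#' cells. A warning is raised when any selected cell is not a risk factor
#' (HR < 1), since the model construction assumes risk-cell infiltration.
#'
#' @param immune_scores Cell x sample infiltration score matrix.
#' @param clinical Clinical table with `os_time`, `os_event`.
#' @param n_cells Number of cells to keep (default 5).
#' @return data.frame ordered by p: `cell`, `beta`, `hr`, `z`, `p`, plus the
#'   full ranking in attribute `"ranking"`.
#' @export
rank_prognostic_cells <- function(immune_scores, clinical, n_cells = 5) {
  common <- intersect(colnames(immune_scores), clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), ]
  if (sum(cl$os_event, na.rm = TRUE) < 1) stop("no events in cohort")
  if (nrow(immune_scores) < n_cells)
    stop("fewer immune cells than n_cells")
  fits <- lapply(rownames(immune_scores), function(cell) {
    res <- tryCatch(cox_univariate(immune_scores[cell, common],
                                   cl$os_time, cl$os_event),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(cell = cell, beta = res$beta, hr = res$hr, z = res$z,
               p = res$p, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, fits)
  if (is.null(fits) || nrow(fits) == 0L) stop("all Cox fits failed")
  fits <- fits[order(fits$p), ]
  rownames(fits) <- NULL
  top <- utils::head(fits, n_cells)
  if (any(top$hr < 1))
    warning("selected immune cell(s) with HR < 1 (protective): ",
            paste(top$cell[top$hr < 1], collapse = ", "))
  attr(top, "ranking") <- fits
  top
}

#' Select signature marker genes by correlation with immune infiltration
#'
#' Per gene, the Spearman correlation with each selected cell's infiltration
#' score is computed and averaged across cells; the `top_fraction` of genes
#' by absolute mean correlation form the signature, partitioned by the sign
#' of the mean correlation. Constant genes are excluded with a message.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param cell_scores Score matrix restricted to the selected cells.
#' @param top_fraction Fraction of genes retained (default 0.05).
#' @param method Correlation method (default `"spearman"`).
#' @return [irpm_signature()] with selection metadata (`meta$correlation` is
#'   the named mean-correlation vector of the selected genes).
#' @export
select_marker_genes <- function(expr, cell_scores, top_fraction = 0.05,
                                method = "spearman") {
  common <- intersect(colnames(expr), colnames(cell_scores))
  if (length(common) < 3L) stop("too few shared samples")
  e <- expr[, common, drop = FALSE]
  s <- cell_scores[, common, drop = FALSE]
  const <- apply(e, 1L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    message("select_marker_genes: excluding ", sum(const), " constant gene(s)")
    e <- e[!const, , drop = FALSE]
  }
  cors <- stats::cor(t(e), t(s), method = method)   # genes x cells
  mean_cor <- rowMeans(cors)
  n_keep <- max(1L, ceiling(top_fraction * length(mean_cor)))
  sel <- names(sort(abs(mean_cor), decreasing = TRUE))[seq_len(n_keep)]
  pos <- sel[mean_cor[sel] > 0]
  neg <- sel[mean_cor[sel] < 0]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("selected genes all share one correlation sign; cannot form a signed signature")
  irpm_signature(pos, neg, source = "constructed",
                 meta = list(cells = rownames(cell_scores),
                             correlation = mean_cor[sel]))
}

#' IRPM score of a single expression profile
#'
#' The Welch two-sample t statistic comparing the sample's expression of the
#' signature's positive genes against its negative genes (positive mean
#' minus negative mean): a high score means the positively immune-correlated
#' genes are relatively overexpressed.
#'
#' @param expr_sample Named numeric vector of one sample's expression.
#' @param sig [irpm_signature()].
#' @return Numeric score. Zero-variance degenerate profiles yield 0 for
#'   equal means and signed `Inf` otherwise.
#' @export
irpm_score <- function(expr_sample, sig) {
  stopifnot(inherits(sig, "irpm_signature"))
  pos <- expr_sample[names(expr_sample) %in% sig$positive]
  neg <- expr_sample[names(expr_sample) %in% sig$negative]
  if (length(pos) < 2L)
    stop("fewer than 2 positive signature genes present; missing: ",
         paste(setdiff(sig$positive, names(expr_sample)), collapse = ", "))
  if (length(neg) < 2L)
    stop("fewer than 2 negative signature genes present; missing: ",
         paste(setdiff(sig$negative, names(expr_sample)), collapse = ", "))
  if (stats::sd(pos) == 0 && stats::sd(neg) == 0) {
    d <- mean(pos) - mean(neg)
    return(if (d == 0) 0 else sign(d) * Inf)
  }
  unname(stats::t.test(pos, neg, var.equal = FALSE)$statistic)
}

#' IRPM scores for every sample of an expression matrix
#' @param expr log2 expression matrix.
#' @param sig [irpm_signature()].
#' @return Named numeric vector of scores.
#' @export
irpm_score_matrix <- function(expr, sig) {
  vapply(colnames(expr), function(s) irpm_score(expr[, s], sig), numeric(1L))
}

#' Stratify samples by IRPM score and validate against survival
#'
#' Risk is "high" iff score > cutoff (ties go to low risk, since high risk
#' requires a strictly greater score); when `cutoff` is `NULL` the median of
#' the supplied scores is used, mirroring the training-cohort convention.
#' Kaplan-Meier curves per risk group and the log-rank p-value are returned.
#'
#' @param scores Named per-sample score vector.
#' @param clinical Clinical table.
#' @param cutoff Score cutoff (default: median of `scores`).
#' @return List: `scores`, `cutoff`, `risk` (named high/low), `km` (list of
#'   per-group [km_estimate()] curves), `logrank` ([logrank_test()] result).
#' @export
stratify_and_validate <- function(scores, clinical, cutoff = NULL) {
  common <- intersect(names(scores), clinical$sample_id)
  if (length(common) == 0L) stop("scores and clinical share no samples")
  sc <- scores[common]
  if (is.null(cutoff)) cutoff <- stats::median(sc)
  risk <- stats::setNames(ifelse(sc > cutoff, "high", "low"), common)
  if (length(unique(risk)) == 1L)
    stop("all samples fall on one side of the cutoff (", cutoff, ")")
  cl <- clinical[match(common, clinical$sample_id), ]
  km <- lapply(split(common, risk[common]), function(ids) {
    i <- match(ids, cl$sample_id)
    km_estimate(cl$os_time[i], cl$os_event[i])
  })
  lr <- logrank_test(cl$os_time, cl$os_event, risk[common])
  list(scores = sc, cutoff = cutoff, risk = risk, km = km, logrank = lr)
}

#' Build the IRPM end-to-end on a training cohort
#'
#' Runs the three construction steps on one cohort: prognostic-cell ranking,
#' signed marker-gene selection, per-sample scoring; the cutoff is the
#' median training score.
#'
#' @param expr log2 expression matrix.
#' @param immune_scores Immune-cell infiltration score matrix.
#' @param clinical Clinical table.
#' @param n_cells,top_fraction,method Passed through to the construction steps.
#' @return List: `cells` (selected-cell table), `signature`, `scores`,
#'   `cutoff`, `validation` (output of [stratify_and_validate()]).
#' @export
build_irpm <- function(expr, immune_scores, clinical, n_cells = 5,
                       top_fraction = 0.05, method = "spearman") {
  cells <- rank_prognostic_cells(immune_scores, clinical, n_cells)
  sig <- select_marker_genes(expr, immune_scores[cells$cell, , drop = FALSE],
                             top_fraction, method)
  scores <- irpm_score_matrix(expr, sig)
  val <- stratify_and_validate(scores, clinical)
  list(cells = cells, signature = sig, scores = scores,
       cutoff = val$cutoff, validation = val)
}
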