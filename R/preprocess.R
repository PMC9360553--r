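# ---- expression preprocessing ------------------------------------------------

#' Remove genes with excessive zero fractions
#'
#' Genes whose fraction of zero values is strictly greater than
#' `zero_fraction` are dropped; the zeros that remain in retained genes are
#' converted to `NA` so that the imputation step can distinguish "to impute"
#' from a genuine measured zero elsewhere in the pipeline.
#'
#' @param mat Expression matrix, `fpkm` layout.
#' @param zero_fraction Removal threshold on the per-gene zero fraction
#'   (default 0.7: zero in more than 70% of samples).
#' @return Filtered matrix with zeros replaced by `NA`.
#' @export
filter_low_expression <- function(mat, zero_fraction = 0.7) {
  stopifnot(is.matrix(mat))
  if (!identical(expr_layout(mat), "fpkm"))
    stop("filter_low_expression expects an fpkm-layout matrix")
  zf <- rowMeans(mat == 0, na.rm = TRUE)
  keep <- zf <= zero_fraction
  if (!any(keep)) stop("all genes removed by the zero-fraction filter")
  out <- mat[keep, , drop = FALSE]
  out[which(out == 0)] <- NA
  expression_matrix(out, "fpkm")
}

#' Impute missing expression values by K nearest genes
#'
#' Each missing entry of gene g at sample s is replaced by the mean value at
#' s of the k genes nearest to g. Distance between two genes is the
#' root-mean-square Euclidean distance over their mutually observed samples
#' (normalising by overlap keeps gene pairs with different missingness
#' comparable). Only genes observed at s are candidate neighbours; ties at
#' the k-th distance are all included, so the result is deterministic. A gene
#' with no usable neighbour falls back to its own observed mean, with a
#' message.
#'
#' @param mat Expression matrix with `NA` for missing entries.
#' @param k Number of nearest neighbour genes (default 10).
#' @return Matrix of the same shape with no missing values; observed entries
#'   are untouched.
#' @export
knn_impute <- function(mat, k = 10) {
  stopifnot(is.matrix(mat), k >= 1)
  layout <- expr_layout(mat)
  if (!anyNA(mat)) return(mat)
  out <- mat
  miss_genes <- which(rowSums(is.na(mat)) > 0L)
  obs <- !is.na(mat)
  for (g in miss_genes) {
    gv <- mat[g, ]
    gobs <- obs[g, ]
    # RMS distance to every other gene over mutually observed samples
    diffs <- sweep(mat, 2L, gv)         # rows: candidate genes
    sq <- diffs^2
    mutual <- obs & matrix(gobs, nrow = nrow(mat), ncol = ncol(mat), byrow = TRUE)
    sq[!mutual] <- NA
    n_mut <- rowSums(mutual)
    d <- sqrt(rowSums(sq, na.rm = TRUE) / pmax(n_mut, 1L))
    d[n_mut == 0L] <- NA
    d[g] <- NA
    for (s in which(!gobs)) {
      cand <- which(obs[, s] & !is.na(d))
      if (length(cand) == 0L) {
        fallback <- mean(gv, na.rm = TRUE)
        if (is.nan(fallback)) stop("gene '", rownames(mat)[g],
                                   "' has no observed values to fall back on")
        message("knn_impute: gene '", rownames(mat)[g], "' sample '",
                colnames(mat)[s], "' has no complete neighbour; using gene mean")
        out[g, s] <- fallback
        next
      }
      dc <- d[cand]
      kth <- sort(dc, partial = min(k, length(dc)))[min(k, length(dc))]
      nb <- cand[dc <= kth]             # includes the whole tie set
      out[g, s] <- mean(mat[nb, s])
    }
  }
  if (!is.na(layout)) attr(out, "layout") <- layout
  out
}

#' Log2-transform an expression matrix
#'
#' @param mat Expression matrix with non-negative values (`counts` or `fpkm`).
#' @param pseudocount Added before taking log2 (default 1).
#' @return Matrix with `log2` layout.
#' @export
log2_transform <- function(mat, pseudocount = 1) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0, na.rm = TRUE)) stop("negative values cannot be log2-transformed")
  if (pseudocount <= 0 && any(mat == 0, na.rm = TRUE))
    stop("zero values with non-positive pseudocount")
  expression_matrix(log2(mat + pseudocount), "log2")
}

#' Standard FPKM preprocessing chain
#'
#' Convenience wrapper: zero-fraction filter, KNN imputation, log2 transform.
#'
#' @inheritParams filter_low_expression
#' @inheritParams knn_impute
#' @inheritParams log2_transform
#' @return `log2`-layout matrix.
#' @export
preprocess_expression <- function(mat, zero_fraction = 0.7, k = 10, pseudocount = 1) {
  log2_transform(knn_impute(filter_low_expression(mat, zero_fraction), k),
                 pseudocount)
}

# ---- latitude grouping -------------------------------------------------------

#' Assign samples to low / high latitude groups
#'
#' Latitudes in `[0, boundary_deg]` are "low", above the boundary "high"
#' (the published grouping uses 0-45 degrees vs 46-90 degrees, so a sample at
#' exactly 45 is low). Samples without latitude are dropped with a message.
#'
#' @param clinical Clinical table with a numeric `latitude_deg` column.
#' @param boundary_deg Boundary in degrees (default 45).
#' @return Named character vector (`"low"` / `"high"`) keyed by sample_id.
#' @export
assign_latitude_group <- function(clinical, boundary_deg = 45) {
  if (!"latitude_deg" %in% colnames(clinical))
    stop("clinical table has no latitude_deg column")
  lat <- clinical$latitude_deg
  keep <- !is.na(lat)
  if (any(!keep))
    message("assign_latitude_group: dropping ", sum(!keep),
            " sample(s) without latitude")
  grp <- ifelse(lat[keep] <= boundary_deg, "low", "high")
  stats::setNames(grp, clinical$sample_id[keep])
}

# ---- clinical contingency ----------------------------------------------------

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The p-value comes from the hypergeometric distribution (all tables with
#' fixed margins whose probability does not exceed the observed table's). The
#' odds ratio is the sample cross-product `(a*d)/(b*c)`; when a margin is
#' zero the OR is undefined and flagged, while the p-value is still returned.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `table`, `odds_ratio` (may be `Inf` or `NaN`),
#'   `or_defined`, `p_value`.
#' @export
fisher_or <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  margin_zero <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- (a * d) / (b * c_)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, odds_ratio = or, or_defined = !margin_zero, p_value = p)
}

#' Fisher contingency tests of a clinical factor against latitude groups
#'
#' Dichotomizes `factor` at the supplied level split and crosses it with the
#' low/high latitude grouping, one 2x2 Fisher test per requested split.
#'
#' @param clinical Clinical table.
#' @param factor Column name of the categorical factor.
#' @param groups Named low/high vector from [assign_latitude_group()].
#' @param split Character vector of factor levels forming the "positive" side
#'   of the dichotomy.
#' @return A [fisher_or()] result with the 2x2 table oriented
#'   (rows: low, high latitude; columns: in-split, out-of-split).
#' @export
clinical_contingency_test <- function(clinical, factor, groups, split) {
  if (!factor %in% colnames(clinical)) stop("no clinical column '", factor, "'")
  common <- intersect(clinical$sample_id, names(groups))
  cl <- clinical[match(common, clinical$sample_id), ]
  g <- groups[common]
  val <- cl[[factor]]
  ok <- !is.na(val)
  pos <- val[ok] %in% split
  gl <- g[ok]
  tab <- matrix(c(sum(gl == "low" & pos), sum(gl == "low" & !pos),
                  sum(gl == "high" & pos), sum(gl == "high" & !pos)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(latitude = c("low", "high"),
                                level = c("in_split", "out_of_split")))
  fisher_or(tab)
}
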