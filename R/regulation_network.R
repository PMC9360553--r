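# ---- driver-gene regulation networks -----------------------------------------

#' Build a driver-gene regulation network over activity scores
#'
#' Within each latitude group, every driver gene splits the samples into
#' mutated and wild-type; for every score feature (metabolic pathway or
#' immune cell) a two-sided Wilcoxon rank-sum test compares the two splits.
#' An edge is emitted when raw p < `p_threshold`, signed `positive` when the
#' mutated-group median is higher, `negative` otherwise. Edges found in both
#' latitude groups with the same sign collapse to one edge with context
#' `both`; opposite-signed findings stay as separate group edges. BH
#' q-values (per latitude context) are reported alongside raw p for users,
#' but edge emission follows raw p.
#'
#' @param drivers Character vector of driver gene symbols.
#' @param mut Mutation table.
#' @param scores Feature x sample score matrix.
#' @param groups Named low/high group vector keyed by sample id.
#' @param p_threshold Edge threshold on raw p (default 0.05).
#' @param min_group Minimum samples on each side of the mutated/wild-type
#'   split (default 3); drivers below it are skipped with a message.
#' @return data.frame of edges: `driver`, `feature`, `context`, `sign`, `p`,
#'   `q`, `n_mutated`, `n_wildtype`.
#' @export
build_regulation_network <- function(drivers, mut, scores, groups,
                                     p_threshold = 0.05, min_group = 3) {
  common <- intersect(colnames(scores), names(groups))
  if (length(common) == 0L) stop("no samples shared between scores and groups")
  per_ctx <- list()
  for (ctx in unique(groups[common])) {
    ids <- common[groups[common] == ctx]
    mm <- mutation_matrix(mut, drivers, ids)
    rows <- list()
    for (d in drivers) {
      is_mut <- mm[d, ]
      if (sum(is_mut) < min_group || sum(!is_mut) < min_group) {
        message("build_regulation_network: skipping driver '", d,
                "' in group '", ctx, "' (split below ", min_group, ")")
        next
      }
      for (f in rownames(scores)) {
        x <- scores[f, ids[is_mut]]
        y <- scores[f, ids[!is_mut]]
        if (length(unique(c(x, y))) == 1L) next  # constant feature: no edge
        p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
        rows[[length(rows) + 1L]] <- data.frame(
          driver = d, feature = f, context = ctx,
          sign = if (stats::median(x) > stats::median(y)) "positive" else "negative",
          p = p, n_mutated = sum(is_mut), n_wildtype = sum(!is_mut),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) next
    tab <- do.call(rbind, rows)
    tab$q <- stats::p.adjust(tab$p, method = "BH")
    per_ctx[[ctx]] <- tab[tab$p < p_threshold, , drop = FALSE]
  }
  if (length(per_ctx) == 0L)
    return(data.frame(driver = character(0), feature = character(0),
                      context = character(0), sign = character(0),
                      p = numeric(0), q = numeric(0),
                      n_mutated = integer(0), n_wildtype = integer(0),
                      stringsAsFactors = FALSE))
  edges <- do.call(rbind, per_ctx)
  rownames(edges) <- NULL
  # collapse same-signed edges present in both latitude contexts
  if (length(per_ctx) == 2L) {
    key <- paste(edges$driver, edges$feature, edges$sign, sep = "\r")
    dupd <- key[duplicated(key)]
    if (length(dupd) > 0L) {
      keep <- !duplicated(key)
      edges$context[key %in% dupd] <- "both"
      agg_p <- tapply(edges$p, key, max)      # report the weaker evidence
      agg_q <- tapply(edges$q, key, max)
      edges <- edges[keep, , drop = FALSE]
      k2 <- paste(edges$driver, edges$feature, edges$sign, sep = "\r")
      edges$p <- as.numeric(agg_p[k2])
      edges$q <- as.numeric(agg_q[k2])
    }
  }
  edges[order(edges$driver, edges$feature),
        c("driver", "feature", "context", "sign", "p", "q",
          "n_mutated", "n_wildtype")]
}
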