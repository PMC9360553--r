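# Independent oracle implementations and toy fixtures used across the suite.
# Oracles are deliberately written as explicit loops / enumerations so they
# share no code path with the package implementation.

# brute-force weighted running-sum enrichment score for one gene set
ssgsea_oracle <- function(mat, set_genes, alpha) {
  n <- nrow(mat)
  genes <- rownames(mat)
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    rk <- rank(x, ties.method = "average")
    ord <- order(-x, genes)
    inset <- genes[ord] %in% set_genes
    m <- sum(inset)
    denom <- 0
    for (i in seq_len(n)) if (inset[i]) denom <- denom + rk[ord[i]]^alpha
    p_in <- 0; p_out <- 0; es <- 0
    for (i in seq_len(n)) {
      if (inset[i]) p_in <- p_in + rk[ord[i]]^alpha / denom
      else p_out <- p_out + 1 / (n - m)
      es <- es + (p_in - p_out)
    }
    out[j] <- es
  }
  out
}

# full hypergeometric enumeration of the two-sided Fisher p for a 2x2 table
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating all group assignments
wilcox_p_oracle <- function(x, y) {
  vals <- c(x, y)
  m <- length(x); n <- length(y)
  rk <- rank(vals)
  idx <- utils::combn(m + n, m)
  stats <- apply(idx, 2L, function(i) sum(rk[i]) - m * (m + 1) / 2)
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  mid <- m * n / 2
  p <- if (u_obs > mid) 2 * mean(stats >= u_obs) else 2 * mean(stats <= u_obs)
  min(1, p)
}

# Welch t statistic by the direct formula
welch_t_oracle <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# hand product-limit estimator on sorted unique event times
km_oracle <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  list(time = ts, surv = out)
}

# six-gene two-sample toy expression matrix used by the ssGSEA oracle suite
toy6 <- function() {
  m <- matrix(c(5, 4, 3, 2, 1, 0.5,
                1, 2, 6, 3, 2.5, 0.1),
              nrow = 6, dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  attr(m, "layout") <- "log2"
  m
}

toy_expr <- function(values, layout = "fpkm", genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, layout)
}

toy_maf_df <- function(samples, genes, classes = "Missense_Mutation",
                       ref = NA_real_, alt = NA_real_) {
  data.frame(sample_id = samples, gene = genes,
             variant_classification = classes,
             chrom = "1", position = seq_along(samples),
             ref_count = ref, alt_count = alt,
             synonymous = classes %in% SYNONYMOUS_CLASSES,
             known_class = TRUE, stringsAsFactors = FALSE)
}

toy_clinical <- function(n, times = NULL, events = NULL, latitude = NULL) {
  data.frame(sample_id = paste0("s", seq_len(n)),
             os_time = if (is.null(times)) rep(100, n) else times,
             os_event = if (is.null(events)) rep(1, n) else events,
             latitude_deg = if (is.null(latitude)) rep(30, n) else latitude,
             stringsAsFactors = FALSE)
}
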