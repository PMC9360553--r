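test_that("ssGSEA equals the brute-force running sum on every 3-gene subset", {
  m <- toy6()
  subsets <- combn(rownames(m), 3, simplify = FALSE)
  for (alpha in c(0, 0.25, 1)) {
    sets <- setNames(subsets, paste0("set", seq_along(subsets)))
    sc <- ssgsea_scores(m, sets, alpha = alpha, normalize = FALSE)
    for (i in seq_along(sets)) {
      expect_equal(unname(sc[i, ]), ssgsea_oracle(m, sets[[i]], alpha),
                   tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA scores are within-sample rank statistics", {
  set.seed(11)
  m <- toy_expr(matrix(rnorm(200), nrow = 40), "log2")
  sets <- list(a = rownames(m)[1:8], b = rownames(m)[15:40])
  base <- ssgsea_scores(m, sets, normalize = FALSE)
  # strictly monotone per-sample transforms leave scores unchanged
  for (f in list(function(x) 10 * x, function(x) exp(x), function(x) x^3 + 5)) {
    mt <- toy_expr(apply(m, 2, f), "log2")
    expect_equal(ssgsea_scores(mt, sets, normalize = FALSE), base,
                 tolerance = 1e-10)
  }
  # identical samples give identical score columns
  m2 <- toy_expr(cbind(m[, 1], m[, 1]), "log2")
  s2 <- ssgsea_scores(m2, sets, normalize = FALSE)
  expect_equal(s2[, 1], s2[, 2])
})

test_that("ssGSEA guards degenerate inputs and normalizes by the matrix range", {
  m <- toy6()
  expect_warning(sc <- ssgsea_scores(m, list(a = c("g1", "g2", "g3"),
                                             none = c("zz1", "zz2"))),
                 "dropping")
  expect_identical(rownames(sc), "a")
  expect_error(ssgsea_scores(toy_expr(matrix(1, 3, 2), "log2"),
                             list(a = c("g1", "g2"))), "constant")
  raw <- ssgsea_scores(m, list(a = c("g1", "g2", "g3"), b = c("g4", "g5")),
                       normalize = FALSE)
  nrm <- ssgsea_scores(m, list(a = c("g1", "g2", "g3"), b = c("g4", "g5")),
                       normalize = TRUE)
  expect_equal(unclass(nrm), unclass(raw / diff(range(raw))),
               ignore_attr = TRUE)
})

test_that("composite scores are the sum of stromal and immune enrichment", {
  set.seed(4)
  m <- toy_expr(matrix(rnorm(300), nrow = 30), "log2")
  es <- estimate_scores(m, rownames(m)[1:5], rownames(m)[10:16])
  expect_identical(rownames(es), c("stromal", "immune", "estimate"))
  expect_equal(es["estimate", ], es["stromal", ] + es["immune", ])
  expect_true(all(is.finite(es)))
})

test_that("immune composite is elevated in the high-infiltration group", {
  co <- generate_cohort(cohort_config(n_low = 100, n_high = 100, n_genes = 600,
                                      dropout_fraction = 0),
                        seed = 31)
  expr <- log2_transform(co$expression_fpkm)
  tr <- truth_report(co)
  immune_genes <- unlist(tr$marker_genes, use.names = FALSE)
  stromal_genes <- setdiff(rownames(expr), immune_genes)[1:40]
  es <- estimate_scores(expr, stromal_genes, immune_genes)
  g <- tr$group[colnames(es)]
  p <- wilcox.test(es["immune", g == "high"], es["immune", g == "low"])$p.value
  expect_lt(p, 0.05)
  expect_gt(median(es["immune", g == "high"]), median(es["immune", g == "low"]))
})

test_that("group comparison matches exact enumeration and calibrates directions", {
  set.seed(9)
  sc <- matrix(rnorm(200), nrow = 2, dimnames = list(c("f1", "f2"), paste0("s", 1:100)))
  same <- setNames(rep(c("low", "high"), 50), colnames(sc))
  flat <- matrix(1, 2, 100, dimnames = dimnames(sc))
  res0 <- compare_groups(flat, same)
  expect_true(all(res0$p == 1))
  expect_true(all(res0$direction == "none"))

  # big shift: p tiny and direction follows the medians
  shift <- sc
  shift[1, same == "high"] <- shift[1, same == "high"] + 10
  res <- compare_groups(shift, same)
  expect_lt(res$p[res$feature == "f1"], 1e-6)
  expect_identical(res$direction[res$feature == "f1"], "higher_in_high")

  # exact enumeration for small tie-free groups
  x <- c(1.2, 3.4, 2.2); y <- c(0.1, 4.4, 2.9, 5.1)
  small <- matrix(c(x, y), nrow = 1, dimnames = list("f", paste0("s", 1:7)))
  gs <- setNames(rep(c("a", "b"), c(3, 4)), colnames(small))
  pr <- compare_groups(small, gs)
  expect_equal(pr$p, wilcox_p_oracle(x, y), tolerance = 1e-12)
})
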