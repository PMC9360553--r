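test_that("synonymous removal follows the declared vocabulary", {
  mut <- toy_maf_df(paste0("s", 1:5), paste0("g", 1:5),
                    c("Missense_Mutation", "Silent", "Missense_Mutation",
                      "Silent", "Missense_Mutation"))
  out <- remove_synonymous(mut)
  expect_identical(nrow(out), 3L)
  expect_false(any(out$variant_classification == "Silent"))

  allsil <- toy_maf_df("s1", "g1", "Silent")
  expect_warning(empty <- remove_synonymous(allsil), "no records remain")
  expect_identical(nrow(empty), 0L)

  weird <- toy_maf_df(c("s1", "s2"), c("g1", "g2"), c("Weird", "Silent"))
  expect_warning(kept <- remove_synonymous(weird), "Weird")
  expect_identical(kept$variant_classification, "Weird")
})

test_that("TMB is count over territory, linear, and order-invariant", {
  mut <- toy_maf_df(rep("s1", 380), paste0("g", 1:380))
  expect_equal(compute_tmb(mut)$tmb, 10)

  two <- toy_maf_df(rep(c("s1", "s2"), c(38, 76)), paste0("g", 1:114))
  expect_equal(compute_tmb(two)$tmb, c(1, 2))
  # record order never matters
  shuf <- two[sample(nrow(two)), ]
  expect_equal(compute_tmb(shuf), compute_tmb(two))
  # doubling records doubles TMB
  expect_equal(compute_tmb(rbind(two, two))$tmb, 2 * compute_tmb(two)$tmb)

  empty <- two[0, ]
  expect_equal(compute_tmb(empty, samples = c("s1", "s2"))$tmb, c(0, 0))
  expect_error(compute_tmb(two, capture_size_mb = 0), "positive")
})

test_that("top mutated genes order by sample count with alphabetical ties", {
  mut <- toy_maf_df(
    c(paste0("s", 1:5), paste0("s", 1:3), paste0("s", 1:3), "s9"),
    c(rep("X", 5), rep("Y", 3), rep("B", 3), "A"))
  top <- top_mutated_genes(mut)
  expect_identical(top$gene, c("X", "B", "Y", "A"))  # B before Y on the tie
  expect_identical(top$n_samples, c(5L, 3L, 3L, 1L))
  expect_identical(top_mutated_genes(mut, n = 1)$gene, "X")
  expect_identical(nrow(top_mutated_genes(mut, n = 100)), 4L)
})

test_that("pairwise interactions label perfect patterns and invert on swap", {
  samples <- paste0("s", 1:20)
  # co-mutated in 10 samples, never singly
  co <- toy_maf_df(rep(samples[1:10], 2), rep(c("A", "B"), each = 10))
  rco <- somatic_interactions(co, c("A", "B"), samples = samples)
  expect_identical(rco$label, "co-occurring")
  tab_co <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(rco$p, fisher_p_oracle(tab_co), tolerance = 1e-12)

  # 10 A-only, 10 B-only, 0 both
  ex <- toy_maf_df(samples, rep(c("A", "B"), each = 10))
  rex <- somatic_interactions(ex, c("A", "B"), samples = samples)
  expect_identical(rex$label, "exclusive")
  expect_equal(rex$p, fisher_p_oracle(matrix(c(0, 10, 10, 0), 2)),
               tolerance = 1e-12)

  # swapping the pair inverts the OR, keeps p and label
  half <- toy_maf_df(c(samples[1:8], samples[5:14]),
                     rep(c("A", "B"), c(8, 10)))
  r1 <- somatic_interactions(half, c("A", "B"), samples = samples)
  r2 <- somatic_interactions(half, c("B", "A"), samples = samples)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$odds_ratio, r2$odds_ratio, tolerance = 1e-12)  # symmetric table
  expect_identical(r1$label, r2$label)

  # gene absent from the table: all-zero row, label none
  rab <- somatic_interactions(co, c("A", "ZZ"), samples = samples)
  expect_identical(rab$label, "none")
  expect_identical(rab$n_both + rab$n_b_only, 0L)
})

test_that("independent mutation pairs are rarely labelled at n = 1000", {
  labs <- vapply(1:40, function(i) {
    set.seed(400 + i)
    samples <- paste0("s", 1:1000)
    a <- samples[runif(1000) < 0.3]
    b <- samples[runif(1000) < 0.3]
    mut <- toy_maf_df(c(a, b), rep(c("A", "B"), c(length(a), length(b))))
    somatic_interactions(mut, c("A", "B"), samples = samples)$label
  }, character(1))
  expect_gte(mean(labs == "none"), 0.9)
})

test_that("subclone inference handles degenerate and undersized inputs", {
  flat <- toy_maf_df(rep("s1", 12), paste0("g", 1:12), ref = 50, alt = 50)
  r <- infer_subclones(flat, "s1")
  expect_true(r$evaluable)
  expect_identical(r$k, 1L)
  expect_equal(r$means, 0.5)

  few <- toy_maf_df(rep("s1", 5), paste0("g", 1:5), ref = 60, alt = 40)
  rf <- infer_subclones(few, "s1")
  expect_false(rf$evaluable)
  expect_true(is.na(rf$k))
})

test_that("subclone inference separates well-spaced VAF mixtures", {
  set.seed(77)
  mut <- simulate_vaf_records("s1", c(0.45, 0.10), c(0.6, 0.4),
                              n_variants = 60, depth = 100)
  r <- infer_subclones(mut, "s1")
  expect_identical(r$k, 2L)
  expect_equal(r$means, c(0.45, 0.10), tolerance = 0.05)
  expect_equal(r$clonal_mean, 0.45, tolerance = 0.05)
  expect_true(all(diff(order(-r$means)) > 0))  # means reported decreasing
})

test_that("driver selection applies the frequency rule", {
  samples <- paste0("s", 1:200)
  mut <- toy_maf_df(c(samples[1:20], samples[1:2], samples[1:12]),
                    rep(c("FREQ", "RARE", "MID"), c(20, 2, 12)))
  drv <- select_driver_genes(mut, samples = samples)
  expect_identical(drv, c("FREQ", "MID"))   # 10% and 6% in, 1% out
  expect_identical(select_driver_genes(mut[0, ]), character(0))
})
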