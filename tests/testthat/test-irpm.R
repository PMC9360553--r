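test_that("prognostic-cell ranking orders by Cox significance", {
  set.seed(12)
  n <- 120
  ids <- paste0("s", seq_len(n))
  risky <- rnorm(n)
  noise <- rnorm(n)
  h <- 0.01 * exp(0.8 * risky)
  tt <- rexp(n, h)
  cl <- data.frame(sample_id = ids, os_time = tt, os_event = 1,
                   stringsAsFactors = FALSE)
  sc <- rbind(risk_cell = risky, null_cell = noise)
  colnames(sc) <- ids
  top <- rank_prognostic_cells(sc, cl, n_cells = 1)
  expect_identical(top$cell, "risk_cell")
  expect_gt(top$hr, 1)

  single <- sc["risk_cell", , drop = FALSE]
  expect_identical(rank_prognostic_cells(single, cl, n_cells = 1)$cell,
                   "risk_cell")
  cl0 <- cl; cl0$os_event <- 0
  expect_error(rank_prognostic_cells(sc, cl0), "no events")

  # protective cells trigger the risk-factor warning
  sc_prot <- rbind(prot_cell = -risky, null_cell = noise)
  colnames(sc_prot) <- ids
  expect_warning(rank_prognostic_cells(sc_prot, cl, n_cells = 1), "HR < 1")
})

test_that("marker-gene selection finds perfectly tracking genes, drops constants", {
  set.seed(13)
  n <- 60
  ids <- paste0("s", seq_len(n))
  cellscore <- matrix(rnorm(n), nrow = 1, dimnames = list("cellA", ids))
  expr <- matrix(rnorm(40 * n), nrow = 40,
                 dimnames = list(paste0("g", 1:40), ids))
  expr["g1", ] <- cellscore["cellA", ]          # perfect positive tracker
  expr["g2", ] <- -cellscore["cellA", ]         # perfect negative tracker
  expr["g3", ] <- 7                              # constant
  expect_message(
    sig <- select_marker_genes(expr, cellscore, top_fraction = 0.06),
    "constant")
  expect_true("g1" %in% sig$positive)
  expect_true("g2" %in% sig$negative)
  expect_false("g3" %in% c(sig$positive, sig$negative))
  expect_equal(unname(sig$meta$correlation["g1"]), 1)
})

test_that("genes independent of infiltration enter the signature at chance rate", {
  set.seed(14)
  rates <- vapply(1:20, function(i) {
    n <- 50
    ids <- paste0("s", seq_len(n))
    cs <- matrix(rnorm(2 * n), nrow = 2, dimnames = list(c("c1", "c2"), ids))
    expr <- matrix(rnorm(200 * n), nrow = 200,
                   dimnames = list(paste0("g", 1:200), ids))
    # guarantee one gene of each sign so the signed split always succeeds
    expr["g1", ] <- colMeans(cs); expr["g2", ] <- -colMeans(cs)
    sig <- select_marker_genes(expr, cs, top_fraction = 0.05)
    (length(sig$positive) + length(sig$negative)) / 200
  }, numeric(1))
  expect_equal(mean(rates), 0.05, tolerance = 0.2)
})

test_that("the IRPM score is the Welch t contrast of signature sides", {
  sig <- irpm_signature(paste0("p", 1:3), paste0("n", 1:3))
  prof_eq <- setNames(c(1, 2, 3, 1, 2, 3), c(paste0("p", 1:3), paste0("n", 1:3)))
  expect_equal(irpm_score(prof_eq, sig), 0)

  prof <- setNames(c(5, 6, 7, 1, 2, 3), c(paste0("p", 1:3), paste0("n", 1:3)))
  expect_equal(irpm_score(prof, sig), welch_t_oracle(c(5, 6, 7), c(1, 2, 3)),
               tolerance = 1e-12)

  # invariant to a constant shift of the whole profile; sign flips on swap
  expect_equal(irpm_score(prof + 10, sig), irpm_score(prof, sig),
               tolerance = 1e-12)
  swapped <- irpm_signature(sig$negative, sig$positive)
  expect_equal(irpm_score(prof, swapped), -irpm_score(prof, sig),
               tolerance = 1e-12)

  # degenerate zero-variance sides
  flat0 <- setNames(rep(1, 6), names(prof))
  expect_identical(irpm_score(flat0, sig), 0)
  flat2 <- setNames(c(2, 2, 2, 1, 1, 1), names(prof))
  expect_identical(irpm_score(flat2, sig), Inf)

  short <- setNames(c(5, 1, 2, 3), c("p1", paste0("n", 1:3)))
  expect_error(irpm_score(short, sig), "positive signature genes")
})

test_that("scoring the published signature uses exactly the printed genes", {
  sig <- load_table1_signature()
  genes <- c(sig$positive, sig$negative)
  set.seed(15)
  prof <- setNames(rnorm(length(genes)), genes)
  s1 <- irpm_score(prof, sig)
  expect_equal(s1, welch_t_oracle(prof[sig$positive], prof[sig$negative]),
               tolerance = 1e-12)
  # extra genes outside the signature never change the score
  prof2 <- c(prof, setNames(rnorm(10), paste0("extra", 1:10)))
  expect_equal(irpm_score(prof2, sig), s1, tolerance = 1e-12)
})

test_that("risk stratification dichotomizes at the cutoff and validates", {
  s <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  cl <- toy_clinical(4, times = c(10, 20, 30, 40), events = c(1, 1, 1, 1))
  r <- stratify_and_validate(s, cl)   # median cutoff 2.5
  expect_identical(unname(r$risk), c("low", "low", "high", "high"))
  expect_identical(r$cutoff, 2.5)
  expect_named(r$km, c("high", "low"))
  expect_true(r$logrank$p >= 0 && r$logrank$p <= 1)
  # ties at the cutoff go to low risk (risk requires strictly greater)
  r2 <- stratify_and_validate(s, cl, cutoff = 3)
  expect_identical(sum(r2$risk == "high"), 1L)
  expect_error(stratify_and_validate(s, cl, cutoff = 10), "one side")
})

test_that("IRPM construction recovers generator truth on one synthetic cohort", {
  co <- generate_cohort(cohort_config(n_low = 150, n_high = 150, n_genes = 1000,
                                      dropout_fraction = 0),
                        seed = 99)
  tr <- truth_report(co)
  expr <- log2_transform(co$expression_fpkm)
  cells <- grep("^cell_", names(co$genesets), value = TRUE)
  sc <- ssgsea_scores(expr, co$genesets[cells])
  tumor <- co$clinical[co$clinical$sample_type == "tumor", ]
  fit <- build_irpm(expr, sc, tumor)
  pos_rec <- mean(tr$irpm_pos_genes %in% fit$signature$positive)
  neg_rec <- mean(tr$irpm_neg_genes %in% fit$signature$negative)
  expect_gte(pos_rec, 0.8)
  expect_gte(neg_rec, 0.8)
  expect_lt(fit$validation$logrank$p, 0.05)
  # the high-risk group carries the higher hazard
  risk <- fit$validation$risk
  cl <- tumor[match(names(risk), tumor$sample_id), ]
  cx <- cox_univariate(as.numeric(risk == "high"), cl$os_time, cl$os_event)
  expect_gt(cx$hr, 1)
})
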