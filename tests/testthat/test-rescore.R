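test_that("target-decoy q-values match hand enumeration", {
  q <- tdc_qvalues(c(10, 9, 8, 8.5), c(FALSE, FALSE, FALSE, TRUE))
  # at score 9: FDR = (0 + 1) / 2 = 0.5
  expect_equal(q[2], 0.5)
  expect_equal(q[1], 0.5) # running minimum propagates upward
  # no decoy above the top target: raw FDR at the top threshold is
  # (0 + 1) / 1 = 1, and the q-value is the running minimum over looser
  # thresholds, here (0 + 1) / 3 accepting all three targets
  q2 <- tdc_qvalues(c(5, 4, 3, 2), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(q2[1], 1 / 3)
  expect_equal(q2[3], 1 / 3)
  expect_error(tdc_qvalues(c(1, 2), c(TRUE, TRUE)), "all-decoy")
})

test_that("q-values are monotone non-increasing in score", {
  set.seed(41)
  for (k in 1:10) {
    s <- rnorm(200)
    d <- runif(200) < 0.5
    d[which.max(s)] <- FALSE
    q <- tdc_qvalues(s, d)
    ord <- order(s, decreasing = TRUE)
    expect_true(all(diff(q[ord]) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("a perfectly separating feature accepts all targets at 1% FDR", {
  set.seed(42)
  bench <- generate_psm_benchmark(
    n_true = 150, n_false = 0, n_decoy = 150,
    effect_size = 20, seed = 42
  )
  res <- semi_supervised_rescore(bench$features, bench$is_decoy, seed = 1)
  expect_identical(sum(res$psms$accepted), 150L)
})

test_that("rescoring rejects engine_score as a feature", {
  bench <- generate_psm_benchmark(50, 0, 50, seed = 2)
  bad <- dplyr::mutate(bench$features, engine_score = 1)
  expect_error(
    semi_supervised_rescore(bad, bench$is_decoy),
    "engine_score"
  )
})

test_that("cross-validated rescoring beats the initial single-feature ranking", {
  # no-harm property over seeded simulations
  for (seed in 1:5) {
    bench <- generate_psm_benchmark(
      n_true = 200, n_false = 200, n_decoy = 400,
      effect_size = 1.5, seed = seed
    )
    single_best <- max(vapply(bench$features, function(f) {
      sum(!bench$is_decoy & tdc_qvalues(f, bench$is_decoy) <= 0.01)
    }, numeric(1)))
    res <- semi_supervised_rescore(bench$features, bench$is_decoy, seed = seed)
    expect_gte(sum(res$psms$accepted), single_best * 0.9)
  }
})

test_that("the empirical FDP is calibrated on the null benchmark", {
  accepted_total <- 0L
  false_total <- 0L
  for (seed in 1:6) {
    bench <- generate_psm_benchmark(
      n_true = 300, n_false = 300, n_decoy = 600,
      effect_size = 2.5, seed = seed
    )
    res <- semi_supervised_rescore(bench$features, bench$is_decoy, seed = seed)
    acc <- !res$psms$is_decoy & res$psms$qvalue <= 0.05
    accepted_total <- accepted_total + sum(acc)
    false_total <- false_total + sum(acc & !bench$is_true)
  }
  fdp <- false_total / accepted_total
  ci <- stats::binom.test(false_total, accepted_total, p = 0.05)$conf.int
  expect_true(ci[1] <= 0.05 * 2.0) # FDP not grossly anti-conservative
  expect_lt(fdp, 0.12)
})

test_that("pretrained models transfer with their standardization", {
  bench <- generate_psm_benchmark(150, 50, 200, effect_size = 3, seed = 9)
  res <- semi_supervised_rescore(bench$features, bench$is_decoy, seed = 9)
  # identity: applying the model to its own features reproduces model scores
  again <- apply_pretrained(res, bench$features)
  expect_equal(again$score, res$psms$model_score, tolerance = 1e-12)
  # linearity: shifting one feature by a constant shifts scores by a constant
  shifted <- dplyr::mutate(bench$features, f1 = .data$f1 + 2)
  s2 <- apply_pretrained(res, shifted)$score
  expect_equal(sd(s2 - again$score), 0, tolerance = 1e-10)
  # feature mismatch is a hard, named error
  expect_error(
    apply_pretrained(res, dplyr::rename(bench$features, x9 = "f1")),
    "x9"
  )
})

test_that("peptide-level reduction keeps the best PSM per modified sequence", {
  psms <- tibble::tibble(
    modified_sequence = c("AAA", "AAA", "AAA", "BBB", "CCC"),
    score = c(1, 3, 2, 5, -1),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  peps <- peptide_qvalues(psms)
  expect_identical(nrow(peps), 3L)
  expect_equal(peps$score[peps$modified_sequence == "AAA"], 3)
  expect_lte(nrow(peps), nrow(psms))
})

test_that("set comparison conserves cardinalities", {
  cmp <- compare_sets(c("A", "B"), c("B", "C"))
  expect_equal(unlist(cmp$counts), c(lost = 1L, shared = 1L, gained = 1L))
  expect_identical(cmp$shared, "B")
  same <- compare_sets(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unlist(same$counts), c(lost = 0L, shared = 3L, gained = 0L))
  set.seed(10)
  for (k in 1:10) {
    ref <- sample(LETTERS, 12)
    new <- sample(LETTERS, 15)
    cmp <- compare_sets(ref, new)
    expect_identical(cmp$counts$lost + cmp$counts$shared, length(unique(ref)))
    expect_identical(cmp$counts$shared + cmp$counts$gained, length(unique(new)))
  }
})
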