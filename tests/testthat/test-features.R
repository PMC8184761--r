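test_that("spectral angle closed forms are exact", {
  expect_equal(spectral_angle(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  expect_equal(spectral_angle(c(1, 0), c(0, 1)), 0, tolerance = 1e-12)
  expect_equal(spectral_angle(c(1, 0), c(1, 1)), 0.5, tolerance = 1e-12)
  # all-zero observed defined as 0
  expect_identical(spectral_angle(c(1, 1), c(0, 0)), 0)
})

test_that("spectral angle is symmetric, scale-invariant and maximal iff proportional", {
  set.seed(14)
  for (k in 1:25) {
    a <- runif(12)
    b <- runif(12)
    expect_equal(spectral_angle(a, b), spectral_angle(b, a), tolerance = 1e-12)
    expect_equal(spectral_angle(a, 7.3 * b), spectral_angle(a, b),
      tolerance = 1e-9
    )
    expect_equal(spectral_angle(a, 2 * a), 1, tolerance = 1e-6)
    expect_lt(spectral_angle(a, b), 1)
  }
})

test_that("spectral angle respects the shared mask and rejects mismatches", {
  p <- peptide("PEPTIDEK", charge = 2)
  fm1 <- simulate_fragmentation(p)
  fm2 <- simulate_fragmentation(p, nce = 35)
  expect_gt(spectral_angle(fm1, fm2), 0.8) # same peptide, tilted energies
  other <- simulate_fragmentation(peptide("AAAAKAAAA", charge = 2))
  expect_error(spectral_angle(fm1, other), "metadata")
})

test_that("sa_distributions summarizes groups deterministically", {
  df <- tibble::tibble(
    spectral_angle = c(0.4, 0.6, 0.95),
    kind = c("spliced", "spliced", "canonical")
  )
  out <- sa_distributions(df, kind)
  expect_identical(out$kind, c("canonical", "spliced"))
  expect_equal(out$median_sa, c(0.95, 0.5))
  expect_equal(out$frac_below_0.5[out$kind == "spliced"], 0.5)
  expect_equal(out$frac_at_least_0.9[out$kind == "canonical"], 1)
  single <- sa_distributions(tibble::tibble(spectral_angle = 0.7))
  expect_equal(single$median_sa, 0.7)
  # noiseless self-prediction gives median SA 1
  cfg <- noiseless_cfg(seed = 2)
  sim <- simulate_dataset(10, cfg)
  sas <- purrr::imap_dbl(sim$peptides[1:10], function(p, i) {
    spectral_angle(sim$truth[[i]], annotate(sim$spectra[[i]], p))
  })
  expect_equal(median(sas), 1, tolerance = 1e-9)
})

test_that("feature vectors never contain the engine score and match hand computation", {
  p <- peptide("PEPTIDEK", charge = 1)
  # 3-peak fixture: b1 and y1 observed, b2 missing
  mz <- c(
    fragment_mz(p, "b", 1, 1), fragment_mz(p, "y", 1, 1),
    fragment_mz(p, "y", 2, 1)
  )
  sp <- raw_spectrum(
    c(mz[1], mz[2], mz[3], 400.0), c(50, 100, 25, 10),
    precursor_mz = 500, precursor_charge = 1
  )
  obs <- annotate(sp, p)
  pred <- simulate_fragmentation(p)
  psm <- tibble::tibble(
    sequence = "PEPTIDEK", modified_sequence = "PEPTIDEK", charge = 1L,
    retention_time = NA_real_
  )
  f <- build_features(psm, pred, obs)
  expect_false("engine_score" %in% names(f))
  expect_identical(f$n_matched_b, 1)
  expect_identical(f$n_matched_y, 2)
  # 185 of 185 annotated intensity units over TIC 185 + 10 noise
  expect_equal(f$frac_intensity_annotated, 175 / 185)
  expect_equal(f$length, 8L, ignore_attr = TRUE)
  expect_equal(f$charge_1, 1)
  expect_equal(sum(dplyr::select(f, dplyr::starts_with("charge_"))), 1)
  # hand-computed SA between pred and obs on shared valid dims
  mask <- respectra:::fragment_mask(8L, 1L)
  pv <- pmax(pred$values[mask], 0)
  ov <- pmax(obs$values[mask], 0)
  expect_equal(
    f$spectral_angle,
    1 - 2 * acos(sum(pv * ov) / sqrt(sum(pv^2) * sum(ov^2))) / pi
  )
  expect_equal(f$abs_delta_rt, 0)
  expect_equal(f$rt_missing, 1)
})

test_that("perfect prediction yields saturated features; all-zero obs degrades", {
  cfg <- noiseless_cfg(seed = 6)
  sim <- simulate_dataset(5, cfg)
  p <- sim$peptides[[1]]
  obs <- annotate(sim$spectra[[1]], p)
  psm <- sim$psms[1, ]
  f <- build_features(psm, sim$truth[[1]], obs)
  expect_equal(f$spectral_angle, 1, tolerance = 1e-9)
  expect_equal(f$pearson, 1, tolerance = 1e-9)
  expect_equal(f$frac_pred_matched, 1)
  zero_obs <- respectra:::empty_fragment_matrix(
    nchar(p$sequence), p$charge
  )
  f0 <- build_features(psm, sim$truth[[1]], zero_obs)
  expect_identical(f0$spectral_angle, 0)
  expect_identical(f0$frac_pred_matched, 0)
})
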