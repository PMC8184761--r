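test_that("masked dimension count follows the length/charge rule", {
  expect_identical(valid_dimension_count(10, 2), 36L)
  expect_identical(valid_dimension_count(30, 3), 174L)
  expect_identical(valid_dimension_count(7, 1), 12L)
  # brute force over the mask for a grid of cases
  for (L in c(7L, 10L, 18L, 30L)) {
    for (z in 1:6) {
      expect_identical(
        valid_dimension_count(L, z),
        sum(respectra:::fragment_mask(L, z))
      )
    }
  }
})

test_that("base-peak normalization is idempotent and flags all-zero input", {
  fm <- respectra:::empty_fragment_matrix(8, 2)
  fm$values[1, "b", 1] <- 2
  fm$values[2, "y", 1] <- 4
  nn <- base_peak_normalize(fm)
  expect_equal(unname(nn$values[1, "b", 1]), 0.5)
  expect_equal(unname(nn$values[2, "y", 1]), 1.0)
  expect_equal(base_peak_normalize(nn)$values, nn$values)
  zero <- respectra:::empty_fragment_matrix(8, 2)
  z2 <- base_peak_normalize(zero)
  expect_true(isTRUE(attr(z2, "no_matched_fragments")))
  expect_equal(z2$values, zero$values)
})

test_that("a constructed equal-intensity ladder annotates to all ones", {
  p <- peptide("PEPTIDEK", charge = 1)
  mz <- c(
    vapply(1:7, function(i) fragment_mz(p, "b", i, 1), 0),
    vapply(1:7, function(i) fragment_mz(p, "y", i, 1), 0)
  )
  sp <- raw_spectrum(mz, rep(100, 14), precursor_mz = 500, precursor_charge = 1)
  fm <- annotate(sp, p)
  expect_equal(unname(respectra:::valid_values(fm)), rep(1, 14))
  expect_identical(attr(fm, "stats")$n_matched, 14L)
})

test_that("a spectrum with no matching peaks yields an all-zero matrix", {
  p <- peptide("PEPTIDEK", charge = 2)
  sp <- raw_spectrum(c(50.123, 60.456), c(10, 20),
    precursor_mz = 500, precursor_charge = 2
  )
  fm <- annotate(sp, p)
  expect_true(all(respectra:::valid_values(fm) == 0))
  expect_identical(attr(fm, "stats")$n_matched, 0L)
})

test_that("annotation inverts the simulator in the noiseless limit", {
  # Exact recovery holds for every ion whose theoretical m/z is isolated;
  # ions closer than twice the tolerance to another theoretical ion share a
  # matching window, and the most-intense rule then assigns both the larger
  # peak (the documented shared-peak contract).
  cfg <- noiseless_cfg(seed = 21)
  sim <- simulate_dataset(25, cfg)
  for (i in seq_len(25)) {
    p <- sim$peptides[[i]]
    ann <- annotate(sim$spectra[[i]], p)
    theo <- respectra:::theoretical_ions(p)
    isolated <- vapply(seq_len(nrow(theo)), function(k) {
      d_ppm <- abs(theo$mz[-k] - theo$mz[k]) / theo$mz[k] * 1e6
      all(d_ppm > 50)
    }, logical(1))
    for (k in which(isolated)) {
      expect_equal(
        unname(ann$values[theo$position[k], theo$ion[k], theo$charge[k]]),
        unname(sim$truth[[i]]$values[theo$position[k], theo$ion[k], theo$charge[k]]),
        tolerance = 1e-9
      )
    }
  }
  # a collision-free peptide round-trips its full tensor exactly
  p <- peptide("PEPTIDEK", charge = 2)
  fm <- simulate_fragmentation(p, 30)
  set.seed(1)
  sp <- render_spectrum(fm, p, cfg)
  expect_equal(annotate(sp, p)$values, fm$values, tolerance = 1e-9)
})

test_that("fast annotation equals the brute-force all-pairs matcher", {
  cfg <- sim_config(seed = 33, ppm_sigma = 8, noise_rate = 3)
  sim <- simulate_dataset(50, cfg)
  for (i in seq_len(50)) {
    fast <- annotate(sim$spectra[[i]], sim$peptides[[i]])
    slow <- brute_force_annotate(sim$spectra[[i]], sim$peptides[[i]])
    expect_equal(fast$values, slow$values, tolerance = 0)
  }
})

test_that("matched-peak count is monotone in the tolerance", {
  cfg <- sim_config(seed = 4, ppm_sigma = 20, noise_rate = 2)
  sim <- simulate_dataset(10, cfg)
  for (i in seq_len(10)) {
    counts <- vapply(c(5, 15, 25, 50, 100), function(tol) {
      attr(annotate(sim$spectra[[i]], sim$peptides[[i]], tol_ppm = tol), "stats")$n_matched
    }, integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("annotate never writes a masked entry and rejects long peptides", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_dataset(10, cfg)
  for (i in seq_len(10)) {
    fm <- annotate(sim$spectra[[i]], sim$peptides[[i]])
    mask <- respectra:::fragment_mask(fm$length, fm$charge)
    expect_true(all(fm$values[!mask] == -1))
  }
  too_long <- paste(rep("A", 31), collapse = "")
  sp <- sim$spectra[[1]]
  expect_error(
    annotate(sp, peptide(too_long, charge = 2, validate_domain = FALSE)),
    "longer than 30"
  )
})
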