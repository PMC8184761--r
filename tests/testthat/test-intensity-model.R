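test_that("the cyclic learning-rate schedule hits its published anchors", {
  cfg <- train_config()
  expect_equal(clr_schedule(0, cfg), 1e-7)
  expect_equal(clr_schedule(4, cfg), 1e-3)
  # upper limit decays by 0.95 every 8 epochs: peak of the third cycle
  expect_equal(clr_schedule(20, cfg), 1e-3 * 0.95^2)
  expect_error(train_config(clr_low = 1e-2, clr_high0 = 1e-3), "clr_low")
  # lr always within [low, current high]
  lrs <- vapply(seq(0, 40, by = 0.5), clr_schedule, numeric(1), cfg = cfg)
  expect_true(all(lrs >= 1e-7 - 1e-15 & lrs <= 1e-3 + 1e-15))
})

test_that("sequence-disjoint splitting is exact, seeded and leak-free", {
  recs <- tibble::tibble(sequence = sprintf("PEPTID%02d", 1:10))
  sets <- split_by_sequence(recs, seed = 5)
  expect_identical(vapply(sets, nrow, integer(1)),
    c(train = 7L, test = 2L, holdout = 1L))
  sets2 <- split_by_sequence(recs, seed = 5)
  expect_identical(sets$train$sequence, sets2$train$sequence)
  # PSM replicates of one sequence never straddle sets
  recs_multi <- recs[rep(1:10, each = 3), , drop = FALSE]
  sets3 <- split_by_sequence(recs_multi, seed = 1)
  seq_sets <- purrr::map(sets3, function(s) unique(s$sequence))
  expect_length(intersect(seq_sets$train, seq_sets$test), 0)
  expect_length(intersect(seq_sets$train, seq_sets$holdout), 0)
  expect_length(intersect(seq_sets$test, seq_sets$holdout), 0)
  expect_error(
    split_by_sequence(tibble::tibble(sequence = c("A", "A"))),
    "3 unique"
  )
})

test_that("top-k PSM selection is per acquisition group with stable ties", {
  recs <- tibble::tibble(
    rawfile = "r", scan = 1:10,
    sequence = rep(c("AAAAAAA", "CCCCCCC"), each = 5),
    modified_sequence = sequence,
    charge = 2L,
    nce = rep(c(25, 30, 25, 30, 25), 2),
    engine_score = c(10, 9, 8, 7, 6, 5, 5, 5, 4, 3)
  )
  out <- select_training_psms(recs, k = 3)
  # groups split further by NCE, so each (sequence, nce) keeps <= 3
  grp <- dplyr::count(out, .data$sequence, .data$nce)
  expect_true(all(grp$n <= 3))
  # a 2-member group is kept whole
  two <- recs[recs$sequence == "AAAAAAA" & recs$nce == 30, ]
  kept <- out[out$sequence == "AAAAAAA" & out$nce == 30, ]
  expect_identical(sort(kept$scan), sort(two$scan))
  # ties break by (rawfile, scan): scans 6,7,8 share score 5
  kept_c <- out[out$sequence == "CCCCCCC" & out$nce == 25, ]
  expect_identical(kept_c$scan, c(6L, 8L, 10L))
})

test_that("spectral contrast loss has its closed forms and a flat minimum", {
  t <- c(0.5, 1, 0.25, -1, -1)
  expect_equal(sa_loss(t, t), 0, tolerance = 1e-12)
  expect_equal(sa_loss(c(1, 0, 0, -1), c(0, 1, 0, -1)), 1, tolerance = 1e-12)
  expect_equal(sa_loss(2 * t, t), 0, tolerance = 1e-12) # scale invariance
  # central finite differences at pred = true vanish
  pred <- c(0.5, 1, 0.25)
  true <- c(0.5, 1, 0.25)
  h <- 1e-6
  for (i in 1:3) {
    up <- pred
    dn <- pred
    up[i] <- up[i] + h
    dn[i] <- dn[i] - h
    fd <- (sa_loss(up, true) - sa_loss(dn, true)) / (2 * h)
    expect_equal(fd, 0, tolerance = 1e-3)
  }
})

test_that("tape gradients agree with finite differences on a small model", {
  cfg <- model_config(recurrent_units = 4)
  w <- respectra:::init_weights(cfg, seed = 3)
  data <- tibble::tibble(
    sequence = c("PEPTIDEK", "AAAKPLLR"),
    modified_sequence = sequence, charge = 2L, nce = 30
  )
  data$target <- purrr::map(data$sequence, function(s) {
    simulate_fragmentation(peptide(s, charge = 2))
  })
  enc <- respectra:::encode_dataset(data, cfg)
  loss_at <- function(w) {
    tp <- respectra:::tape_new()
    wid <- purrr::map(w, respectra:::tp_input, tp = tp)
    eb <- respectra:::encode_batch(enc$tokens, enc$meta, 1:2, cfg, tp)
    pred <- respectra:::model_forward(tp, wid, eb$xs, eb$meta, cfg)
    respectra:::tp_value(tp, respectra:::tp_sa_loss(tp, pred, enc$targets))
  }
  tp <- respectra:::tape_new()
  wid <- purrr::map(w, respectra:::tp_input, tp = tp)
  eb <- respectra:::encode_batch(enc$tokens, enc$meta, 1:2, cfg, tp)
  pred <- respectra:::model_forward(tp, wid, eb$xs, eb$meta, cfg)
  loss <- respectra:::tp_sa_loss(tp, pred, enc$targets)
  grads <- respectra:::tape_backward(tp, loss)
  h <- 1e-5
  set.seed(99)
  for (nm in c(
    "enc1f_Wzr", "enc1b_Un", "enc2_Wn", "att_v", "meta_W",
    "decf_Uzr", "decb_bn", "datt_v", "out_W", "out_b"
  )) {
    g <- grads[[wid[[nm]]]]
    i <- sample(length(w[[nm]]), 1)
    wp <- w
    wm <- w
    wp[[nm]][i] <- wp[[nm]][i] + h
    wm[[nm]][i] <- wm[[nm]][i] - h
    fd <- (loss_at(wp) - loss_at(wm)) / (2 * h)
    expect_equal(as.vector(g)[i], fd, tolerance = 1e-3)
  }
})

test_that("the model overfits a 50-sample set and respects output contracts", {
  cfg <- noiseless_cfg(seed = 13)
  sim <- simulate_dataset(60, cfg)
  data <- training_data_from_sim(sim)
  mcfg <- model_config(recurrent_units = 32)
  tcfg <- train_config(
    batch_size = 10, max_epochs = 25, patience = 25, seed = 13,
    clr_high0 = 5e-3
  )
  model <- train_intensity_model(data[1:50, ], data[51:60, ], mcfg, tcfg)
  # loss decreases substantially on the training set (capacity check)
  tl <- model$history$train_loss
  expect_lt(min(tl), tl[1] * 0.7)
  expect_true(all(is.finite(tl)))
  preds <- predict_fragments(model, data[51:60, ])
  for (k in seq_along(preds)) {
    fm <- preds[[k]]
    mask <- respectra:::fragment_mask(fm$length, fm$charge)
    expect_true(all(fm$values[!mask] == -1)) # masked stay masked
    v <- fm$values[mask]
    expect_true(all(v >= 0 & v <= 1)) # base-peak normalized
    expect_equal(max(v), 1, tolerance = 1e-9)
  }
})

test_that("CE calibration recovers the generating NCE from the oracle", {
  cfg <- sim_config(seed = 55, nce = 30, ppm_sigma = 3, noise_rate = 1)
  sim <- simulate_dataset(60, cfg)
  observed <- purrr::imap(sim$peptides[1:60], function(p, i) {
    annotate(sim$spectra[[i]], p)
  })
  cal <- calibrate_ce(oracle_predictor(), sim$psms, observed, grid = 24:36)
  expect_lte(abs(cal$best_nce - 30), 1)
  expect_identical(nrow(cal$curve), 13L)
  # single-value grid returns that value
  cal1 <- calibrate_ce(oracle_predictor(), sim$psms, observed, grid = 28)
  expect_identical(cal1$best_nce, 28)
  expect_error(
    calibrate_ce(oracle_predictor(), sim$psms[0, ], list()),
    "empty"
  )
})
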