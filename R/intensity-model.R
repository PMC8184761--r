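#' Intensity-predictor architecture configuration
#'
#' The predictor is a recurrent encoder-decoder. The peptide encoder has
#' three layers: a bidirectional GRU, a unidirectional GRU and an attention
#' pooling, each optionally followed by dropout. Precursor charge (one-hot,
#' length 6) and NCE (scaled to \[0, 1\]) pass through a single dense layer to
#' the latent size and are fused with the peptide latent vector by
#' element-wise multiplication. The decoder is a length-29 bidirectional GRU
#' with per-position attention emitting 6 intensities per position
#' (b/y x fragment charge 1..3), 174 output dimensions in total. The output
#' activation (softplus) keeps intensities non-negative before base-peak
#' normalization.
#'
#' Desk-scale default is 64 recurrent units; 512 reproduces the
#' publication-scale capacity without changing the architecture.
#'
#' @param recurrent_units GRU width (latent size equals it).
#' @param dropout Dropout rate applied after the encoder layers (0 disables).
#' @param max_length Maximum peptide length (30).
#' @return List of class `model_config`.
#' @export
model_config <- function(recurrent_units = 64L, dropout = 0,
                         max_length = 30L) {
  vocab <- c(names(mass_constants$residues), "M(ox)", "C(cam)")
  structure(
    list(
      vocab = vocab, max_length = as.integer(max_length),
      recurrent_units = as.integer(recurrent_units),
      latent_dim = as.integer(recurrent_units), dropout = dropout,
      decoder_length = 29L, outputs_per_position = 6L
    ),
    class = "model_config"
  )
}

#' Training configuration with cyclic learning-rate schedule
#'
#' The learning rate cycles triangularly between a constant lower limit
#' (1e-7) and an upper limit (initially 1e-3) that is scaled by 0.95 every 8
#' epochs; one full cycle spans 8 epochs with the peak at 4.
#'
#' @param clr_low,clr_high0 Cycle limits.
#' @param clr_decay,decay_every Upper-limit decay factor and period (epochs).
#' @param batch_size Samples per optimizer step.
#' @param max_epochs,patience Epoch budget and early-stopping patience on the
#'   test loss.
#' @param seed Seed for initialization and shuffling.
#' @return List of class `train_config`.
#' @export
train_config <- function(clr_low = 1e-7, clr_high0 = 1e-3, clr_decay = 0.95,
                         decay_every = 8L, batch_size = 64L, max_epochs = 50L,
                         patience = 10L, seed = 1L) {
  stopifnot(clr_low < clr_high0)
  structure(
    list(
      clr_low = clr_low, clr_high0 = clr_high0, clr_decay = clr_decay,
      decay_every = as.integer(decay_every),
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Cyclic learning rate at a given epoch
#'
#' @param epoch 0-based epoch index (fractional values interpolate within an
#'   epoch; pass `epoch + step / steps_per_epoch`).
#' @param cfg A `train_config`.
#' @return Learning rate.
#' @examples
#' clr_schedule(0, train_config()) # 1e-7, cycle start
#' clr_schedule(4, train_config()) # 1e-3, first peak
#' @export
clr_schedule <- function(epoch, cfg = train_config()) {
  high <- cfg$clr_high0 * cfg$clr_decay^(floor(epoch / cfg$decay_every))
  half <- cfg$decay_every / 2
  pos <- epoch %% cfg$decay_every
  tri <- 1 - abs(pos - half) / half
  cfg$clr_low + (high - cfg$clr_low) * tri
}

#' Normalized spectral contrast loss
#'
#' `1 - spectral_angle(pred, true)` over unmasked dimensions; 0 iff the
#' vectors are positively proportional, 1 for orthogonal vectors.
#'
#' @param pred,true Numeric vectors (or flattened 174-vectors).
#' @param mask Logical vector of dimensions to include; defaults to
#'   `true >= 0` (the -1 sentinel convention).
#' @return Scalar loss in `[0, 1]`.
#' @export
sa_loss <- function(pred, true, mask = NULL) {
  if (is.null(mask)) mask <- true >= 0
  1 - sa_from_vectors(pred[mask], true[mask])
}

#' Sequence-disjoint train/test/holdout split
#'
#' Partitions records by unmodified peptide sequence so that all PSMs of one
#' sequence land in exactly one set; set sizes match the fractions on unique
#' sequences within rounding.
#'
#' @param records Tibble with a `sequence` column.
#' @param fractions Length-3 fractions summing to 1 (train, test, holdout).
#' @param seed Integer seed.
#' @return Named list `train`, `test`, `holdout` of record subsets.
#' @export
split_by_sequence <- function(records, fractions = c(0.70, 0.20, 0.10),
                              seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  seqs <- unique(records$sequence)
  if (length(seqs) < 3L) {
    stop("need at least 3 unique sequences to split", call. = FALSE)
  }
  set.seed(seed)
  seqs <- sample(seqs)
  n <- length(seqs)
  bounds <- round(cumsum(fractions) * n)
  assign <- rep(c("train", "test", "holdout"), times = diff(c(0L, bounds)))
  sets <- split(seqs, factor(assign, levels = c("train", "test", "holdout")))
  purrr::map(sets, function(s) records[records$sequence %in% s, , drop = FALSE])
}

#' Restrict to the top-k PSMs per acquisition group
#'
#' Keeps at most `k` highest-scoring PSMs per combination of peptide
#' sequence, modification status, precursor charge and any of the acquisition
#' columns (`fragmentation`, `nce`, `analyzer`) present in the table. Ties are
#' broken stably by (rawfile, scan).
#'
#' @param records PSM tibble with `engine_score`.
#' @param k Maximum records per group.
#' @return Filtered tibble.
#' @export
select_training_psms <- function(records, k = 3L) {
  keys <- intersect(
    c("sequence", "modified_sequence", "charge", "fragmentation", "nce", "analyzer"),
    names(records)
  )
  records |>
    dplyr::arrange(
      dplyr::across(dplyr::all_of(keys)),
      dplyr::desc(.data$engine_score), .data$rawfile, .data$scan
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}

# ---- weights ----------------------------------------------------------------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

gru_params <- function(prefix, in_dim, u) {
  p <- list(
    glorot(in_dim, 2L * u), glorot(u, 2L * u), rep(0, 2L * u),
    glorot(in_dim, u), glorot(u, u), rep(0, u)
  )
  names(p) <- paste0(prefix, c("_Wzr", "_Uzr", "_bzr", "_Wn", "_Un", "_bn"))
  p
}

init_weights <- function(cfg, seed = 1L) {
  set.seed(seed)
  u <- cfg$recurrent_units
  d <- length(cfg$vocab)
  c(
    gru_params("enc1f", d, u), gru_params("enc1b", d, u),
    gru_params("enc2", 2L * u, u),
    list(
      att_v = glorot(u, 1L), att_b = 0,
      meta_W = glorot(7L, u), meta_b = rep(0, u)
    ),
    gru_params("decf", u + 29L, u), gru_params("decb", u + 29L, u),
    list(
      datt_v = glorot(2L * u, 1L), datt_b = 0,
      # output head sees the decoder state plus the encoder states flanking
      # the cleavage site (residues i and i+1): fragmentation chemistry is
      # local, and the direct path lets the head read it without squeezing
      # everything through the pooled latent
      out_W = glorot(6L * u, cfg$outputs_per_position),
      out_b = rep(0.1, cfg$outputs_per_position)
    )
  )
}

# ---- forward pass -----------------------------------------------------------

gru_layer <- function(tp, wid, prefix, xs, u, reverse = FALSE) {
  B <- nrow(tp_value(tp, xs[[1]]))
  h <- tp_input(tp, matrix(0, B, u))
  order_t <- if (reverse) rev(seq_along(xs)) else seq_along(xs)
  out <- vector("list", length(xs))
  g <- function(nm) wid[[paste0(prefix, nm)]]
  for (t in order_t) {
    h <- tp_gru_step(
      tp, xs[[t]], h,
      g("_Wzr"), g("_Uzr"), g("_bzr"), g("_Wn"), g("_Un"), g("_bn")
    )
    out[[t]] <- h
  }
  out
}

tp_dropout <- function(tp, a, rate) {
  if (rate <= 0) {
    return(a)
  }
  A <- tp_value(tp, a)
  keep <- matrix(stats::rbinom(length(A), 1L, 1 - rate), nrow(A)) / (1 - rate)
  m <- tp_input(tp, keep)
  tp_mul(tp, a, m)
}

model_forward <- function(tp, wid, xs, meta_id, cfg, training = FALSE) {
  u <- cfg$recurrent_units
  rate <- if (training) cfg$dropout else 0
  h1f <- gru_layer(tp, wid, "enc1f", xs, u, reverse = FALSE)
  h1b <- gru_layer(tp, wid, "enc1b", xs, u, reverse = TRUE)
  h1 <- purrr::map2(h1f, h1b, function(a, b) tp_cbind2(tp, a, b))
  h1 <- purrr::map(h1, tp_dropout, tp = tp, rate = rate)
  h2 <- gru_layer(tp, wid, "enc2", h1, u, reverse = FALSE)
  # attention pooling over time
  e <- purrr::map(h2, function(h) {
    tp_add_bias(tp, tp_matmul(tp, h, wid$att_v), wid$att_b)
  })
  A <- tp_softmax_rows(tp, tp_cbind_list(tp, unlist(e)))
  ctx <- NULL
  for (t in seq_along(h2)) {
    term <- tp_scale_rows(tp, h2[[t]], tp_slice_cols(tp, A, t))
    ctx <- if (is.null(ctx)) term else tp_add(tp, ctx, term)
  }
  ctx <- tp_dropout(tp, ctx, rate)
  gate <- tp_sigmoid(tp, tp_add_bias(
    tp, tp_matmul(tp, meta_id, wid$meta_W), wid$meta_b
  ))
  fused <- tp_mul(tp, ctx, gate)
  # decoder input: fused latent decorated with a positional one-hot, so the
  # constant-input recurrence can still emit sharply position-specific values
  B <- nrow(tp_value(tp, meta_id))
  dec_in <- purrr::map(seq_len(cfg$decoder_length), function(t) {
    pos <- matrix(0, B, cfg$decoder_length)
    pos[, t] <- 1
    tp_cbind2(tp, fused, tp_input(tp, pos))
  })
  df <- gru_layer(tp, wid, "decf", dec_in, u, reverse = FALSE)
  db <- gru_layer(tp, wid, "decb", dec_in, u, reverse = TRUE)
  dd <- purrr::map2(df, db, function(a, b) tp_cbind2(tp, a, b))
  ed <- purrr::map(dd, function(h) {
    tp_add_bias(tp, tp_matmul(tp, h, wid$datt_v), wid$datt_b)
  })
  Ad <- tp_softmax_rows(tp, tp_cbind_list(tp, unlist(ed)))
  outs <- purrr::imap(dd, function(h, t) {
    hw <- tp_scale_rows(tp, h, tp_slice_cols(tp, Ad, t))
    head_in <- tp_cbind2(tp, tp_cbind2(tp, hw, h1[[t]]), h1[[t + 1L]])
    tp_softplus(tp, tp_add_bias(
      tp, tp_matmul(tp, head_in, wid$out_W), wid$out_b
    ))
  })
  tp_cbind_list(tp, unlist(outs))
}

# ---- encoding ---------------------------------------------------------------

tokenize_peptide <- function(sequence, modifications, cfg) {
  chars <- strsplit(sequence, "")[[1]]
  if (nrow(modifications) > 0L) {
    tagged <- paste0(
      chars[modifications$position],
      c(ox = "(ox)", cam = "(cam)")[modifications$mod]
    )
    chars[modifications$position] <- c(
      "M(ox)" = "M(ox)", "C(cam)" = "C(cam)"
    )[tagged]
  }
  idx <- match(chars, cfg$vocab)
  c(idx, rep(0L, cfg$max_length - length(idx)))
}

encode_batch <- function(tokens, meta, rows, cfg, tp) {
  B <- length(rows)
  d <- length(cfg$vocab)
  xs <- vector("list", cfg$max_length)
  for (t in seq_len(cfg$max_length)) {
    X <- matrix(0, B, d)
    tok <- tokens[rows, t]
    nz <- which(tok > 0L)
    if (length(nz) > 0L) X[cbind(nz, tok[nz])] <- 1
    xs[[t]] <- tp_input(tp, X)
  }
  list(xs = xs, meta = tp_input(tp, meta[rows, , drop = FALSE]))
}

# Precompute token / metadata / target matrices for a dataset tibble with
# columns sequence, modified_sequence, charge, nce and list-column target.
encode_dataset <- function(data, cfg) {
  n <- nrow(data)
  tokens <- matrix(0L, n, cfg$max_length)
  for (i in seq_len(n)) {
    mods <- parse_modified_sequence(data$modified_sequence[i])$modifications
    tokens[i, ] <- tokenize_peptide(data$sequence[i], mods, cfg)
  }
  meta <- cbind(
    vapply(1:6, function(z) as.numeric(data$charge == z), numeric(n)),
    data$nce / 100
  )
  targets <- NULL
  if (!is.null(data$target)) {
    targets <- do.call(rbind, purrr::map(data$target, flatten_fragment_matrix))
  }
  list(tokens = tokens, meta = meta, targets = targets)
}

# ---- training ---------------------------------------------------------------

#' Train the fragment-intensity predictor
#'
#' Optimizes the spectral-contrast loss with Adam under the cyclic
#' learning-rate schedule. The model is fitted on `train`, and `test` controls
#' overfitting via early stopping; the weights with the best test loss are
#' returned. Aborts if the loss turns non-finite.
#'
#' @param train,test Dataset tibbles with columns `sequence`,
#'   `modified_sequence`, `charge`, `nce` and a `target` list-column of
#'   ground-truth `fragment_matrix` objects (see [training_data_from_sim()]).
#' @param model_cfg A `model_config`.
#' @param train_cfg A `train_config`.
#' @param verbose Print per-epoch losses.
#' @return Object of class `intensity_model`: weights, configs, loss history.
#' @export
train_intensity_model <- function(train, test, model_cfg = model_config(),
                                  train_cfg = train_config(), verbose = FALSE) {
  set.seed(train_cfg$seed)
  w <- init_weights(model_cfg, seed = train_cfg$seed)
  enc_tr <- encode_dataset(train, model_cfg)
  enc_te <- encode_dataset(test, model_cfg)
  adam_m <- purrr::map(w, function(x) x * 0)
  adam_v <- purrr::map(w, function(x) x * 0)
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  step <- 0L
  n <- nrow(train)
  history <- tibble::tibble(
    epoch = integer(), train_loss = numeric(), test_loss = numeric(),
    lr = numeric()
  )
  best <- list(loss = Inf, w = w, epoch = -1L)
  steps_per_epoch <- max(1L, ceiling(n / train_cfg$batch_size))
  for (epoch in seq_len(train_cfg$max_epochs) - 1L) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      lr <- clr_schedule(epoch + (step %% steps_per_epoch) / steps_per_epoch,
        cfg = train_cfg
      )
      tp <- tape_new()
      wid <- purrr::map(w, tp_input, tp = tp)
      eb <- encode_batch(enc_tr$tokens, enc_tr$meta, b, model_cfg, tp)
      pred <- model_forward(tp, wid, eb$xs, eb$meta, model_cfg, training = TRUE)
      loss <- tp_sa_loss(tp, pred, enc_tr$targets[b, , drop = FALSE])
      lval <- tp_value(tp, loss)
      if (!is.finite(lval)) {
        stop(
          "divergent loss at epoch ", epoch, " (loss = ", lval,
          "); try a lower learning rate",
          call. = FALSE
        )
      }
      ep_loss <- ep_loss + lval * length(b)
      grads <- tape_backward(tp, loss)
      step <- step + 1L
      for (nm in names(w)) {
        g <- grads[[wid[[nm]]]]
        if (is.null(g)) next
        if (is.null(dim(w[[nm]]))) g <- as.vector(g)
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    te_loss <- dataset_loss(w, enc_te, model_cfg)
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, train_loss = ep_loss / n, test_loss = te_loss,
      lr = clr_schedule(epoch, train_cfg)
    ))
    if (verbose) {
      message(sprintf(
        "epoch %3d  train %.4f  test %.4f", epoch, ep_loss / n, te_loss
      ))
    }
    if (te_loss < best$loss) {
      best <- list(loss = te_loss, w = w, epoch = epoch)
    } else if (epoch - best$epoch >= train_cfg$patience) {
      break
    }
  }
  structure(
    list(
      weights = best$w, model_cfg = model_cfg, train_cfg = train_cfg,
      history = history, best_epoch = best$epoch, best_test_loss = best$loss
    ),
    class = "intensity_model"
  )
}

dataset_loss <- function(w, enc, cfg, chunk = 256L) {
  n <- nrow(enc$tokens)
  tot <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    tp <- tape_new()
    wid <- purrr::map(w, tp_input, tp = tp)
    eb <- encode_batch(enc$tokens, enc$meta, b, cfg, tp)
    pred <- model_forward(tp, wid, eb$xs, eb$meta, cfg, training = FALSE)
    loss <- tp_value(tp, tp_sa_loss(tp, pred, enc$targets[b, , drop = FALSE]))
    tot <- tot + loss * length(b)
  }
  tot / n
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("<intensity_model> ", x$model_cfg$recurrent_units, " units, best epoch ",
    x$best_epoch, " (test loss ", signif(x$best_test_loss, 4), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
glance.intensity_model <- function(x, ...) {
  tibble::tibble(
    recurrent_units = x$model_cfg$recurrent_units,
    n_parameters = sum(vapply(x$weights, length, integer(1))),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_test_loss = x$best_test_loss
  )
}

#' @export
tidy.intensity_model <- function(x, ...) x$history

#' Predict fragment matrices for peptides
#'
#' Generic over predictor backends: a trained [train_intensity_model()] model
#' or the rule-based [oracle_predictor()].
#'
#' @param predictor Predictor object.
#' @param data Tibble with `sequence`, `modified_sequence`, `charge`, `nce`.
#' @param ... Method-specific arguments.
#' @return List of base-peak-normalized `fragment_matrix` (masked dims -1).
#' @export
predict_fragments <- function(predictor, data, ...) {
  UseMethod("predict_fragments")
}

#' @rdname predict_fragments
#' @export
predict_fragments.intensity_model <- function(predictor, data, ...) {
  cfg <- predictor$model_cfg
  enc <- encode_dataset(data, cfg)
  n <- nrow(data)
  out <- vector("list", n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / 256L))) {
    tp <- tape_new()
    wid <- purrr::map(predictor$weights, tp_input, tp = tp)
    eb <- encode_batch(enc$tokens, enc$meta, b, cfg, tp)
    pred <- tp_value(tp, model_forward(tp, wid, eb$xs, eb$meta, cfg))
    for (k in seq_along(b)) {
      i <- b[k]
      fm <- fragment_matrix(
        pmax(pred[k, ], 0),
        length = nchar(data$sequence[i]), charge = data$charge[i]
      )
      mask <- fragment_mask(fm$length, fm$charge)
      fm$values[!mask] <- -1
      out[[i]] <- base_peak_normalize(fm)
    }
  }
  out
}

#' Rule-based oracle predictor
#'
#' Wraps the synthetic fragmentation rule as a predictor, so any pipeline
#' stage that consumes predictions can be exercised against exact ground
#' truth.
#'
#' @return Object of class `oracle_predictor`.
#' @export
oracle_predictor <- function() structure(list(), class = "oracle_predictor")

#' @rdname predict_fragments
#' @export
predict_fragments.oracle_predictor <- function(predictor, data, ...) {
  purrr::pmap(
    list(data$modified_sequence, data$charge, data$nce),
    function(ms, z, nce) {
      simulate_fragmentation(peptide(ms, charge = z), nce = nce)
    }
  )
}

#' Calibrate the collision energy against confident identifications
#'
#' Predicts spectra for a calibration set of high-scoring PSMs at each NCE of
#' the grid and picks the NCE maximizing the median spectral angle against
#' the observed (annotated) matrices; ties go to the lower NCE.
#'
#' @param predictor A predictor for [predict_fragments()].
#' @param psms PSM tibble (`sequence`, `modified_sequence`, `charge`,
#'   `engine_score`).
#' @param observed List of observed `fragment_matrix`, parallel to `psms`.
#' @param grid NCE grid (default 20:40).
#' @param top_n Calibration-set size: the `top_n` highest engine scores (all
#'   if fewer).
#' @return List of class `ce_calibration`: `best_nce`, `curve` (tibble of
#'   `nce`, `median_sa`).
#' @export
calibrate_ce <- function(predictor, psms, observed, grid = 20:40,
                         top_n = 1000L) {
  stopifnot(nrow(psms) == length(observed))
  if (nrow(psms) == 0L) stop("empty calibration set", call. = FALSE)
  if (nrow(psms) < 20L) {
    warning("fewer than 20 confident PSMs for CE calibration", call. = FALSE)
  }
  keep <- order(-psms$engine_score)[seq_len(min(top_n, nrow(psms)))]
  psms <- psms[keep, , drop = FALSE]
  observed <- observed[keep]
  curve <- purrr::map_dfr(grid, function(nce) {
    preds <- predict_fragments(predictor, dplyr::mutate(psms, nce = nce))
    sas <- purrr::map2_dbl(preds, observed, spectral_angle)
    tibble::tibble(nce = nce, median_sa = median(sas))
  })
  best <- curve$nce[which.max(curve$median_sa)]
  structure(list(best_nce = best, curve = curve), class = "ce_calibration")
}

#' @export
print.ce_calibration <- function(x, ...) {
  cat("<ce_calibration> best NCE ", x$best_nce, " (median SA ",
    signif(max(x$curve$median_sa), 4), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Build a training dataset tibble from a simulated dataset
#'
#' @param sim Result of [simulate_dataset()].
#' @param nce NCE recorded for each PSM.
#' @return Tibble with the columns [train_intensity_model()] expects.
#' @export
training_data_from_sim <- function(sim, nce = 30) {
  keep <- !sim$psms$is_decoy
  tibble::tibble(
    sequence = sim$psms$sequence[keep],
    modified_sequence = sim$psms$modified_sequence[keep],
    charge = sim$psms$charge[keep],
    nce = nce,
    target = sim$truth[which(keep)]
  )
}
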