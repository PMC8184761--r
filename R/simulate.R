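#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate an
#' Orbitrap HCD acquisition of an HLA class I immunopeptidome: lengths 8-12
#' with the canonical 9-mer mode, charges 1-3 dominated by 2+, NCE 30, 5 ppm
#' mass jitter, one unannotated noise peak per 100 Th, and log-normal
#' intensity scatter. All generators are pure functions of (config, seed).
#'
#' @param seed Integer seed.
#' @param preset `"hla1"` (8-12), `"hla2"` (10-25), `"aspn"` / `"lysn"`
#'   (7-25 with D / K at the N-terminus).
#' @param nce Normalized collision energy.
#' @param ppm_sigma Gaussian m/z jitter, ppm.
#' @param noise_rate Expected noise peaks per 100 Th.
#' @param intensity_sigma Log-normal sd of multiplicative intensity noise.
#' @param charge_probs Probabilities for precursor charges 1..6.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, preset = c("hla1", "hla2", "aspn", "lysn"),
                       nce = 30, ppm_sigma = 5, noise_rate = 1,
                       intensity_sigma = 0.3,
                       charge_probs = c(0.2, 0.6, 0.2, 0, 0, 0)) {
  preset <- match.arg(preset)
  structure(
    list(
      seed = as.integer(seed), preset = preset, nce = nce,
      ppm_sigma = ppm_sigma, noise_rate = noise_rate,
      intensity_sigma = intensity_sigma,
      charge_probs = charge_probs / sum(charge_probs)
    ),
    class = "sim_config"
  )
}

preset_lengths <- function(preset) {
  switch(preset,
    hla1 = list(lengths = 8:12, probs = c(0.15, 0.5, 0.15, 0.1, 0.1)),
    hla2 = list(lengths = 10:25, probs = rep(1 / 16, 16)),
    aspn = ,
    lysn = list(lengths = 7:25, probs = rep(1 / 19, 19))
  )
}

# Background amino-acid frequencies used for random peptide sampling.
aa_background <- function() {
  aa <- names(mass_constants$residues)
  setNames(rep(1 / length(aa), length(aa)), aa)
}

#' Sample random peptide sequences
#'
#' @param n Number of sequences.
#' @param cfg A `sim_config`; the preset fixes the length distribution and,
#'   for AspN / LysN, the N-terminal residue.
#' @return Character vector of sequences (not necessarily unique).
#' @export
sample_sequences <- function(n, cfg = sim_config()) {
  pl <- preset_lengths(cfg$preset)
  lens <- sample(pl$lengths, n, replace = TRUE, prob = pl$probs)
  aa <- names(aa_background())
  vapply(lens, function(L) {
    s <- sample(aa, L, replace = TRUE)
    if (cfg$preset == "aspn") s[1] <- "D"
    if (cfg$preset == "lysn") s[1] <- "K"
    paste(s, collapse = "")
  }, "")
}

#' Rule-based ground-truth fragmentation
#'
#' A deterministic stand-in for HCD fragmentation chemistry encoding three
#' real phenomena so that model recovery is a meaningful test:
#' enhanced cleavage N-terminal to proline (x3 on the site propensity),
#' charge retention by basic residues (b ions x0.3 when only the y fragment
#' holds K/R/H; fragment charge drawn toward `1 + n_basic / 2`), and a
#' collision-energy tilt favouring smaller fragments at higher NCE. Site
#' propensity is a Gaussian bump over cleavage position,
#' `exp(-(i - L/2)^2 / (2 (L/4)^2))`, and the y series carries twice the base
#' intensity of the b series. The result is base-peak normalized with masked
#' dimensions at -1. Constants are arbitrary but fixed.
#'
#' @param p A `peptide`.
#' @param nce Normalized collision energy.
#' @return Ground-truth `fragment_matrix`.
#' @export
simulate_fragmentation <- function(p, nce = 30) {
  seq_chars <- strsplit(p$sequence, "")[[1]]
  L <- length(seq_chars)
  fm <- empty_fragment_matrix(L, p$charge)
  m <- residue_masses(p)
  prec_mass <- sum(m) + mass_constants$water
  basic <- seq_chars %in% c("K", "R", "H")
  n_basic_prefix <- cumsum(basic)
  max_z <- min(3L, p$charge)

  for (i in seq_len(min(L - 1L, 29L))) {
    s <- exp(-(i - L / 2)^2 / (2 * (L / 4)^2))
    if (seq_chars[i + 1L] == "P") s <- s * 3
    nb_b <- n_basic_prefix[i]
    nb_y <- n_basic_prefix[L] - nb_b
    b_base <- s
    y_base <- 2 * s
    if (nb_b == 0L && nb_y > 0L) b_base <- b_base * 0.3
    for (ion in c("b", "y")) {
      base <- if (ion == "b") b_base else y_base
      nb <- if (ion == "b") nb_b else nb_y
      frag_mass <- if (ion == "b") sum(m[1:i]) else {
        sum(m[(L - i + 1L):L]) + mass_constants$water
      }
      tilt <- (frag_mass / prec_mass)^(-0.5 * (nce - 30) / 10)
      for (z in seq_len(max_z)) {
        w <- exp(-abs(z - (1 + nb / 2)))
        fm$values[i, ion, z] <- base * w * tilt
      }
    }
  }
  base_peak_normalize(fm)
}

#' Render a noisy spectrum from a fragment matrix
#'
#' Peaks are placed at the theoretical fragment m/z perturbed by Gaussian ppm
#' jitter, intensities are scaled by log-normal noise, and Poisson-count
#' uniform noise peaks are added across the observed m/z span. With zero
#' jitter and zero noise, [annotate()] recovers the matrix exactly.
#'
#' @param fm Ground-truth `fragment_matrix`.
#' @param p The `peptide` it belongs to.
#' @param cfg A `sim_config` (jitter / noise / NCE settings).
#' @param scan,rawfile Identifiers stored in the spectrum.
#' @return A `raw_spectrum`.
#' @export
render_spectrum <- function(fm, p, cfg = sim_config(), scan = 1L,
                            rawfile = "synthetic") {
  ions <- tidy.fragment_matrix(fm, peptide = p)
  ions <- ions[ions$intensity > 0, , drop = FALSE]
  mz <- ions$mz * (1 + rnorm(nrow(ions), 0, cfg$ppm_sigma * 1e-6))
  intensity <- ions$intensity * 100 *
    exp(rnorm(nrow(ions), 0, cfg$intensity_sigma))
  span_lo <- 100
  span_hi <- max(c(mz, 500)) * 1.05
  n_noise <- rpois(1, cfg$noise_rate * (span_hi - span_lo) / 100)
  if (n_noise > 0) {
    mz <- c(mz, runif(n_noise, span_lo, span_hi))
    intensity <- c(intensity, runif(n_noise, 0, 20))
  }
  prec_mz <- (peptide_mass(p) + p$charge * mass_constants$proton) / p$charge
  raw_spectrum(
    mz = mz, intensity = intensity, precursor_mz = prec_mz,
    precursor_charge = p$charge, nce = cfg$nce, analyzer = "FTMS",
    scan = scan, rawfile = rawfile
  )
}

#' Full-reversal decoy peptide
#'
#' Non-tryptic peptides have no C-terminal anchor to preserve, so the decoy is
#' the full sequence reversal; palindromic sequences are perturbed by one
#' internal swap so the decoy never equals the target.
#'
#' @param p A `peptide` (or sequence string).
#' @return A `peptide` (or string, matching the input type).
#' @export
generate_decoy <- function(p) {
  is_pep <- inherits(p, "peptide")
  s <- if (is_pep) p$sequence else p
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  if (rev_s == s) {
    ch <- strsplit(s, "")[[1]]
    i <- which(ch[-length(ch)] != ch[-1])[1]
    if (!is.na(i)) { # homopolymers have no distinct permutation
      ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]
      rev_s <- paste(ch, collapse = "")
    }
  }
  if (is_pep) {
    peptide(rev_s, charge = p$charge, validate_domain = FALSE)
  } else {
    rev_s
  }
}

#' Simulate a labeled PSM dataset with spectra
#'
#' Generates `n` unique target peptides, renders one spectrum per target from
#' the rule-based fragmentation truth, and (optionally) adds a reversed-decoy
#' PSM per target annotated against the same spectrum. Engine scores are a
#' noisy monotone surrogate so that top-k selection and score-based
#' calibration subsets behave like real search output.
#'
#' @param n Number of target peptides.
#' @param cfg A `sim_config`.
#' @param decoys Add one decoy PSM per target.
#' @return List with `psms` (tibble; adds `is_decoy`, `engine_score`),
#'   `spectra` (list of `raw_spectrum`, one per scan), `truth` (list of
#'   ground-truth `fragment_matrix` per target PSM), `peptides` (list of
#'   `peptide` per PSM row).
#' @export
simulate_dataset <- function(n, cfg = sim_config(), decoys = FALSE) {
  set.seed(cfg$seed)
  seqs <- unique(sample_sequences(3L * n, cfg))
  stopifnot(length(seqs) >= n)
  seqs <- seqs[seq_len(n)]
  charges <- sample(1:6, n, replace = TRUE, prob = cfg$charge_probs)
  peps <- purrr::map2(seqs, charges, function(s, z) peptide(s, charge = z))
  truth <- purrr::map(peps, simulate_fragmentation, nce = cfg$nce)
  spectra <- purrr::imap(peps, function(p, i) {
    render_spectrum(truth[[i]], p, cfg, scan = i)
  })
  psms <- tibble::tibble(
    rawfile = "synthetic", scan = seq_len(n),
    modified_sequence = seqs, sequence = seqs, charge = charges,
    engine = "simulator",
    engine_score = 100 + rnorm(n, 0, 10),
    is_decoy = FALSE,
    retention_time = NA_real_, rank = 1L
  )
  if (decoys) {
    dseqs <- unname(vapply(seqs, generate_decoy, ""))
    dpsms <- dplyr::mutate(psms,
      modified_sequence = dseqs, sequence = dseqs,
      is_decoy = TRUE, engine_score = .data$engine_score - rnorm(n, 30, 10)
    )
    psms <- dplyr::bind_rows(psms, dpsms)
    peps <- c(peps, purrr::map2(dseqs, charges, function(s, z) {
      peptide(s, charge = z)
    }))
    truth <- c(truth, vector("list", n))
  }
  list(psms = psms, spectra = spectra, truth = truth, peptides = peps)
}

#' Generate spliced/canonical isobaric confusion pairs
#'
#' Builds pairs of distinct sequences that are isobaric within 25 ppm via the
#' substitution catalog (GVA<->NL, GG<->N, GA<->Q, I<->L). The spectrum of
#' each pair is rendered from the canonical truth, so a downstream spliced
#' re-assessment sees exactly the ambiguity class in which a proposed spliced
#' peptide competes with a canonical explanation of the same spectrum.
#'
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param cfg A `sim_config` for rendering.
#' @return Tibble with `scan`, `canonical`, `spliced` (pipe-marked),
#'   `spliced_plain`, `substitution`, plus list-columns `spectrum` and
#'   `canonical_peptide`.
#' @export
generate_confusion_pairs <- function(n, seed = 1L, cfg = sim_config(seed = seed)) {
  set.seed(seed)
  catalog <- isobaric_catalog()
  aa <- setdiff(names(mass_constants$residues), c("I", "L"))
  rows <- purrr::map(seq_len(n), function(i) {
    k <- sample(nrow(catalog), 1L)
    from <- catalog$from[k] # goes into the spliced proposal
    to <- catalog$to[k] # canonical truth
    stem_len <- sample(6:9, 1L)
    stem <- paste(sample(aa, stem_len, replace = TRUE), collapse = "")
    canonical <- paste0(stem, to)
    spliced_plain <- paste0(stem, from)
    cut <- sample(seq_len(nchar(spliced_plain) - 1L), 1L)
    spliced <- paste0(
      substr(spliced_plain, 1, cut), "|",
      substr(spliced_plain, cut + 1L, nchar(spliced_plain))
    )
    tibble::tibble(
      scan = i, canonical = canonical, spliced = spliced,
      spliced_plain = spliced_plain, substitution = paste0(from, "<->", to)
    )
  })
  out <- dplyr::bind_rows(rows)
  charge <- 2L
  out$canonical_peptide <- purrr::map(out$canonical, peptide, charge = charge)
  out$spectrum <- purrr::imap(out$canonical_peptide, function(p, i) {
    render_spectrum(simulate_fragmentation(p, cfg$nce), p, cfg, scan = i)
  })
  out
}

#' Generate a labeled PSM benchmark for FDR calibration
#'
#' True targets receive features shifted by `effect_size`; false targets and
#' decoys are drawn from the same null distribution (exchangeability), so the
#' observed false-discovery proportion of any acceptance rule is computable
#' exactly from the `is_true` label.
#'
#' @param n_true,n_false,n_decoy Group sizes.
#' @param effect_size Mean shift of true-target features (standard deviations).
#' @param n_features Number of feature columns.
#' @param informative How many features carry the shift.
#' @param seed Integer seed.
#' @return List with `features` (tibble), `is_decoy`, `is_true`, and a `psms`
#'   tibble with unique (rawfile, scan) keys.
#' @export
generate_psm_benchmark <- function(n_true, n_false, n_decoy, effect_size = 2,
                                   n_features = 5L, informative = 2L,
                                   seed = 1L) {
  set.seed(seed)
  n <- n_true + n_false + n_decoy
  X <- matrix(rnorm(n * n_features), n, n_features)
  if (n_true > 0L && informative > 0L) {
    X[seq_len(n_true), seq_len(informative)] <-
      X[seq_len(n_true), seq_len(informative)] + effect_size
  }
  colnames(X) <- paste0("f", seq_len(n_features))
  is_true <- c(rep(TRUE, n_true), rep(FALSE, n_false + n_decoy))
  is_decoy <- c(rep(FALSE, n_true + n_false), rep(TRUE, n_decoy))
  ms <- sprintf("PEPTIDE%05d", seq_len(n))
  psms <- tibble::tibble(
    rawfile = "benchmark", scan = seq_len(n),
    modified_sequence = ms, sequence = ms, charge = 2L,
    engine = "simulator", engine_score = 0, is_decoy = is_decoy,
    retention_time = NA_real_, rank = 1L
  )
  list(
    features = tibble::as_tibble(as.data.frame(X)),
    is_decoy = is_decoy, is_true = is_true, psms = psms
  )
}

#' Sample peptides from a position weight matrix
#'
#' @param pwm A `pwm` object (see [build_pwm()]).
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
sample_from_pwm <- function(pwm, n, seed = 1L) {
  set.seed(seed)
  aa <- rownames(pwm$matrix)
  vapply(seq_len(n), function(i) {
    paste(
      vapply(seq_len(pwm$length), function(j) {
        sample(aa, 1L, prob = pwm$matrix[, j])
      }, ""),
      collapse = ""
    )
  }, "")
}
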