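make_candidates <- function(q, score, comp_scores, spliced = NULL,
                            comp_seq = NULL) {
  n <- length(q)
  if (is.null(spliced)) spliced <- sprintf("PEPT|IDEK%02d", seq_len(n))
  tibble::tibble(
    spliced = spliced, qvalue = q, score = score,
    competitors = purrr::map(seq_len(n), function(i) {
      if (is.na(comp_scores[i])) {
        tibble::tibble(sequence = character(), score = numeric())
      } else {
        tibble::tibble(
          sequence = if (is.null(comp_seq)) "AAAAAAAA" else comp_seq[i],
          score = comp_scores[i]
        )
      }
    })
  )
}

test_that("consecutive filters reject at the first applicable stage", {
  # constructed to fail (2, 1, 3, 1) at stages i..iv, 3 retained
  cands <- dplyr::bind_rows(
    make_candidates(q = c(0.5, 0.2), score = c(5, 5), comp_scores = c(1, 1)),
    make_candidates(
      q = 0.001, score = 5, comp_scores = 1,
      spliced = "PEPTI|DEI", comp_seq = "PEPTIDEL"
    ),
    make_candidates(q = rep(0.001, 3), score = c(2, 2, 2), comp_scores = c(3, 2.5, 2)),
    make_candidates(q = 0.001, score = 3, comp_scores = 2.5),
    make_candidates(q = rep(0.001, 3), score = c(9, 8, 7), comp_scores = c(1, 2, NA))
  )
  out <- assess_spliced(cands, q_threshold = 0.01, margin = 1.0)
  expect_equal(unname(out$report$rejected), c(2L, 1L, 3L, 1L))
  expect_identical(out$report$retained, 3L)
  expect_identical(out$report$total, 10L)
  # conservation
  expect_identical(
    out$report$total,
    out$report$rejected_total + out$report$retained + out$report$non_assessable
  )
  # rejected-at-i candidates are never labeled with later stages
  expect_identical(out$verdicts$verdict[1:2], rep("not_confident", 2))
})

test_that("the published spliced-peptide accounting reproduces from stage counts", {
  rep_ <- accounting_report(1230, c(
    not_confident = 596, il_isomer = 90,
    better_canonical = 315, insufficient_margin = 66
  ))
  expect_identical(rep_$rejected_total, 1067L)
  expect_equal(rep_$rejected_fraction, 1067 / 1230)
  expect_equal(round(100 * rep_$rejected_fraction), 87)
  expect_identical(rep_$retained, 163L)
})

test_that("a small score margin rejects the spliced proposal at stage iv", {
  # shared-scale scores 2.9 (spliced) vs 2.5 (canonical)
  cands <- make_candidates(q = 0.001, score = 2.9, comp_scores = 2.5)
  out <- assess_spliced(cands, margin = 1.0)
  expect_identical(out$verdicts$verdict, "insufficient_margin")
  # with margin 0 stage iv never rejects
  out0 <- assess_spliced(cands, margin = 0)
  expect_identical(out0$verdicts$verdict, "retained")
})

test_that("stage-iv rejections grow monotonically with the margin", {
  set.seed(61)
  cands <- make_candidates(
    q = rep(0.001, 30), score = runif(30, 2, 6),
    comp_scores = runif(30, 1, 5)
  )
  rej <- vapply(c(0, 0.5, 1, 2, 4), function(m) {
    assess_spliced(cands, margin = m)$report$rejected_total
  }, integer(1))
  expect_true(all(diff(rej) >= 0))
})

test_that("the canonical control applies only stages i and iii", {
  cands <- tibble::tibble(
    sequence = sprintf("CANON%03dK", 1:20),
    qvalue = c(rep(0.5, 4), rep(0.001, 16)),
    score = c(rep(5, 4), rep(2, 6), rep(5, 10)),
    competitors = purrr::map(1:20, function(i) {
      if (i >= 5 && i <= 10) {
        tibble::tibble(sequence = "X", score = 4)
      } else {
        tibble::tibble(sequence = character(), score = numeric())
      }
    })
  )
  out <- assess_canonical(cands)
  expect_equal(unname(out$report$rejected), c(4L, 6L))
  expect_identical(out$report$retained, 10L)
  # published control numbers: 179 + 296 of 3,994 leaves 3,519
  ctl <- accounting_report(3994, c(not_confident = 179, better_canonical = 296))
  expect_identical(ctl$retained, 3519L)
  expect_equal(round(100 * 179 / 3994), 4)
  # degenerate inputs
  empty <- assess_canonical(cands[0, ])
  expect_identical(empty$report$total, 0L)
  no_comp <- assess_canonical(dplyr::mutate(cands[11:20, ],
    competitors = purrr::map(1:10, function(i) NULL)
  ))
  expect_identical(unname(no_comp$report$rejected["better_canonical"]), 0L)
})

test_that("best-PSM ranking prefers canonical on ties", {
  psms <- tibble::tibble(
    rawfile = "r", scan = c(1L, 1L, 2L, 3L, 3L),
    sequence = c("SPLICEDAA", "CANONAAAA", "ONLYONEAA", "AAA", "BBB"),
    score = c(2.9, 2.5, 1.0, 2.0, 2.0),
    is_spliced = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  best <- rank_best_psm_per_spectrum(psms)
  expect_identical(best$sequence[best$scan == 1], "SPLICEDAA")
  expect_identical(best$sequence[best$scan == 2], "ONLYONEAA")
  expect_identical(best$sequence[best$scan == 3], "AAA") # lexicographic tie
  tie <- tibble::tibble(
    rawfile = "r", scan = 1L,
    sequence = c("SPL", "CAN"), score = c(2, 2), is_spliced = c(TRUE, FALSE)
  )
  expect_identical(rank_best_psm_per_spectrum(tie)$sequence, "CAN")
})

test_that("the end-to-end audit on canonical-truth spectra rejects nearly all spliced", {
  audit <- run_splice_audit(n_pairs = 40, seed = 5)
  expect_identical(audit$report$total, 40L)
  expect_lte(audit$report$retained, 2)
  expect_identical(
    audit$report$total,
    audit$report$rejected_total + audit$report$retained +
      audit$report$non_assessable
  )
})
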