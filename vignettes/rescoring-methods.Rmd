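---
title: "Intensity-prediction-assisted rescoring: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-prediction-assisted rescoring: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respectra)
```

# The problem

Search engines identify peptides from tandem mass spectra by comparing
observed fragment masses against theoretical b/y ladders, but they largely
ignore fragment *intensities*. For tryptic peptides this is workable; for
HLA-presented ligands — short peptides with non-tryptic termini produced by
unspecific proteolysis — the candidate space explodes and the score
distributions of true and false matches overlap badly. respectra implements
the intensity-aware remedy: predict the fragment-intensity pattern of every
candidate peptide, score the agreement between prediction and observation
with the normalized spectral contrast angle (SA), and re-estimate confidence
with a semi-supervised target-decoy discriminant that uses *only* these
spectral features, never the original engine score. The same machinery
supports a re-assessment of proposed proteasomally spliced peptides and a
motif-based plausibility check of newly gained identifications.

# The fragment-intensity tensor

All intensity information lives in a fixed tensor indexed by fragment
position (1–29), ion series (b, y) and fragment charge (1–3). An entry is
*masked* (sentinel −1) when the position is at or beyond the peptide length
or the fragment charge exceeds the precursor charge; valid entries are
base-peak normalized to [0, 1]. A length-10, 2+ peptide therefore has
9 × 2 × 2 = 36 valid dimensions of the 174 total. The flattened layout —
position-major, b before y, charge fastest — is the file contract for
prediction vectors and the input/output format of the predictor.

Observed tensors come from `annotate()`: theoretical b/y m/z at fragment
charges 1–3 are matched against the peak list at 25 ppm (Orbitrap/FTMS) or
0.4 Da (ion trap/ITMS). The 25 ppm value follows standard high-resolution
practice; the ITMS fallback is a conventional ion-trap window, since no
single tolerance serves both analyzers. Where several peaks fall inside the
window the most intense wins, with ties broken by smaller mass error; one
peak may serve several theoretical ions (no deduplication — the simplest
defensible contract, and the one the brute-force oracle in the test suite
verifies exactly).

# The predictor

The predictor is a recurrent encoder–decoder trained with the spectral
contrast loss `1 − SA`:

* **Peptide encoder** — token embedding as one-hot over 22 symbols (20
  residues plus oxidized-M and carbamidomethyl-C), a bidirectional GRU, a
  second GRU, and attention pooling into a latent vector; dropout is
  configurable (default 0 at desk scale, where the data are noiseless and
  runs must be deterministic).
* **Metadata encoder** — precursor charge (one-hot, length 6; charges above
  6 are outside the domain) and NCE scaled to [0, 1], through one dense
  layer with sigmoid gating.
* **Fusion** — element-wise multiplication of the peptide latent and the
  metadata gate.
* **Decoder** — a length-29 bidirectional GRU whose input at every step is
  the fused latent concatenated with a positional one-hot, followed by
  per-position softmax attention and a dense head emitting 6 intensities
  (b/y × charge 1–3) per position, with softplus keeping outputs
  non-negative before masking and base-peak normalization.

Two wiring choices deserve explanation, because the design space was
genuinely open. First, the positional one-hot in the decoder input: a
recurrence over a *constant* repeated latent settles toward a fixed point,
which makes mid-sequence outputs nearly position-independent; the one-hot
restores sharp positional addressing. Second, the output head at position
*i* additionally reads the first-layer bidirectional encoder states of
residues *i* and *i+1* — the residues flanking the cleavage site. Backbone
fragmentation chemistry is local (enhanced cleavage N-terminal to proline,
charge retention at basic residues), and this skip path lets the head read
those local determinants directly instead of squeezing them through the
pooled latent. Empirically the skip path is decisive at desk scale: without
it the 64-unit model plateaus near loss 0.26 on the synthetic recovery task;
with it the same budget reaches below 0.1.

Training uses Adam under a cyclic learning rate: a triangular cycle between
1e-7 and an upper limit starting at 1e-3, the cycle spanning 8 epochs (peak
at 4) with the upper limit scaled by 0.95 every 8 epochs. The cycle *shape*
(triangular, half-cycle 4) is a package choice; the limits and decay are the
published schedule. Splits are sequence-disjoint 70/20/10 — every unmodified
sequence lands in exactly one of training/test/holdout — and training data
are restricted to the top-3 highest-scoring PSMs per (sequence,
modification, charge, fragmentation settings) group. Early stopping watches
the test loss; the best-test-loss weights are returned. Desk-scale defaults
are 64 recurrent units and batch 64; 512 units reproduce the
publication-scale capacity without any structural change.

The gradients come from a small tape-based reverse-mode autodiff engine
written for this package (no deep-learning framework is required). Each GRU
step is a single fused tape node with a hand-derived backward; all
backward rules are verified against central finite differences in the test
suite (worst relative error ~5e-6 on a seeded model).

# Retention time

A composition-linear model (per-residue coefficients plus intercept) stands
in for a learned hydrophobicity predictor: it is additive, identifiable
(the explicit length term is off by default because length equals the sum of
the residue counts, an exact collinearity), and its absolute prediction
error enters rescoring exactly as a learned predictor's would. Alignment of
predicted to observed times uses Siegel repeated-median regression, robust
to gross outliers; agreement is summarized by ΔRT95, the linear-interpolation
95th percentile of absolute residuals. The published chromatographic
agreement number for the original learned model is not a target of this
stand-in.

# Rescoring

`semi_supervised_rescore()` re-implements the Percolator scheme with an
L2-regularized linear discriminant: per cross-validation fold (3 folds, 10
iterations), the starting direction is the single feature accepting the most
targets at q ≤ 0.01; each iteration labels targets at q ≤ 0.01 as positives
(relaxing the working threshold early on when no positives exist yet) and
all decoys as negatives, refits, and rescores. Every PSM's final score comes
from the fold that never trained on it, standardized per fold before
pooling. The feature vector contains spectral similarity (SA, Pearson,
Spearman, matched-ion fractions), mass and chromatography terms, length and
charge indicators — and never the engine score, which is rejected by name if
present.

q-values use target-decoy competition with the conservative +1 numerator:
`FDR(s) = (#decoys ≥ s + 1) / max(1, #targets ≥ s)`, monotonized from the
lowest score upward. Peptide-level estimates re-run the same estimator on
the best PSM per modified sequence (charge excluded from peptide identity).
A consolidated model refit on all PSMs — weights plus standardization — is
what `apply_pretrained()` transfers to another engine's features, putting
PSMs from different engines on one shared confidence scale; by construction
it reproduces its own (consolidated) training scores exactly, while the
primary per-PSM scores remain cross-validated. PIN export keeps the external
Percolator program usable for parity checks.

# Spliced-peptide re-assessment

`assess_spliced()` applies four consecutive filters, charging each candidate
to the first that rejects it: (i) not confident after rescoring
(q > threshold); (ii) I/L isomer of a canonical peptide (checked against
same-spectrum competitors *and* a supplied canonical universe, since I/L
isomers are mass-indistinguishable); (iii) a canonical competitor explains
the same spectrum at least as confidently; (iv) the spliced score exceeds
the canonical one by no more than a margin δ. The margin default is 1.0 on
the standardized score scale: "substantially better" has no published
number, but the documented showcase rejects a 0.4-point gap, so δ must
exceed 0.4; 1.0 is exposed as a tunable, and with δ = 0 stage iv rejects
nothing. The canonical control (`assess_canonical()`) applies only stages i
and iii. Accounting always conserves: total = Σ rejected + retained +
non-assessable, and candidates without a rescore result are counted
non-assessable, never silently retained.

# Motifs

`build_pwm()` builds column-stochastic position-weight matrices;
`js_divergence()` compares two motifs by the mean over positions of the
base-2 Jensen–Shannon divergence (0 identical, 1 disjoint support — the
aggregation across positions and the log base are package choices, so
published single-number divergences are not claimed reproducible).
`emission_probability()` scores peptides against length-matched motifs by
ranking positions by their column maximum (anchor positions first) and
summing the peptide's residue frequencies at the top 5; the raw sum is
reported (not divided by k), and averaging happens only across lengths.
Display PWMs use pseudocount 0; emission scoring defaults to 0.5 to avoid
hard zeros on unseen residues.

# The synthetic-data generator

Because real training corpora and instrument data are out of reach at desk
scale, every component is exercised against `simulate_fragmentation()`, a
deterministic rule encoding three real phenomena: a Gaussian site-propensity
bump over cleavage position, tripled cleavage N-terminal to proline, a y:b
intensity ratio of 2 with b ions attenuated (×0.3) when only the y fragment
retains a basic residue, fragment-charge weights drawn toward
1 + n_basic/2, and an NCE tilt `(m_frag/m_prec)^(−0.5 (NCE−30)/10)`
favouring small fragments at high energy. The constants are arbitrary but
fixed; what matters is that the rule is rich enough that model recovery is a
meaningful test rather than a vacuous one. `render_spectrum()` adds Gaussian
ppm jitter, log-normal intensity scatter and Poisson-count uniform noise
peaks; with all noise at zero, annotation inverts simulation exactly — the
keystone oracle of the test suite. Decoys are full sequence reversals
(non-tryptic peptides have no C-terminal anchor worth preserving), with one
internal swap for palindromes. Confusion pairs substitute isobaric residue
combinations (GVA↔NL, GG↔N, GA↔Q, I↔L) into random stems and render the
spectrum from the canonical truth, so retained spliced candidates in the
audit are known false positives.

Default study conditions emulate an Orbitrap HLA class I acquisition:
lengths 8–12 peaked at 9-mers, charges 1–3 dominated by 2+, NCE 30, 5 ppm
jitter, one noise peak per 100 Th, log-normal intensity σ 0.3. What passing
tests on these data show is that the *pipeline machinery* is correct and
calibrated; they do not show that the predictor matches real HCD chemistry,
which requires the real corpora.

# Problem sizes and numerical choices

The shipped experiments use sizes chosen for a single-CPU desk run: model
recovery trains on 2,000 noiseless spectra (70/20/10 split, ≤ 50 epochs,
64 units, batch 64) and reaches holdout median SA well above 0.9;
collision-energy calibration uses 500 PSMs over the integer grid 20–40 and
recovers the generating NCE 30 within ±1 (ties resolved to the lower NCE);
FDR calibration pools ten seeded benchmarks of 300 true / 600 false targets
against 600 decoys (false targets and decoys exchangeable by construction);
the splice audit runs 100 confusion pairs. Mass constants are standard
monoisotopic values at 5 decimals (proton 1.0072765 Da, water 18.010565 Da),
accurate to ≲3e-5 Da against a full-precision calculator — two orders below
the 25 ppm matching window. Percentiles use linear interpolation (R type 7).
Degenerate inputs are defined, not left to chance: an all-zero observed
vector has SA 0; an all-zero matrix passes base-peak normalization unchanged
with a flag; Pearson/Spearman on constant vectors map to 0; a missing RT
prediction contributes |ΔRT| = 0 plus a missingness indicator.

# Known limitations

The predictor is trained and evaluated on rule-generated spectra; no claim
transfers to real instruments without retraining on real corpora. Only b/y
ions are scored — a-ions, internal fragments and neutral losses may be
present in spectra but never enter the tensor. The RT model is a linear
stand-in. Protein-level FDR, spliced-candidate database generation, and
binding-affinity prediction are out of scope. The RT-deviation filter for
retained spliced candidates (a further filter one could apply) is noted but
deliberately not implemented.
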