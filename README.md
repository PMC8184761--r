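# respectra

Intensity-prediction-assisted identification of tryptic and non-tryptic
(HLA ligand) peptides from tandem mass spectra.

Search engines score candidate peptides against MS/MS spectra mostly by
fragment *masses*; the *intensities* of those fragments carry the
information that separates hard cases, and for non-tryptic HLA ligands —
short peptides from unspecific proteolysis with enormous candidate spaces —
ignoring them costs a large share of true identifications. respectra
implements the intensity-aware workflow end to end:

* **b/y fragment annotation** of MGF peak lists at 25 ppm (FTMS) / 0.4 Da
  (ITMS) into a masked, base-peak-normalized 29 × {b,y} × charge-1..3
  intensity tensor;
* a **trainable recurrent encoder–decoder intensity predictor** (GRU
  encoder with attention pooling, metadata fusion by element-wise
  multiplication, length-29 bidirectional GRU decoder) optimized with the
  normalized spectral contrast loss under a cyclic learning-rate schedule,
  with sequence-disjoint 70/20/10 splits and top-3 PSM selection — built on
  a small, finite-difference-verified autodiff engine, no deep-learning
  framework required;
* **collision-energy calibration** by scanning NCE 20–40 against confident
  identifications;
* an additive **retention-time model** with robust alignment and the ΔRT95
  agreement metric;
* **feature-only semi-supervised target-decoy rescoring**
  (Percolator-style, 3-fold cross-validated L2 discriminant; the engine
  score is never a feature), PSM- and peptide-level q-values with
  target-decoy competition, PIN export, and pre-trained-model transfer so
  several engines share one confidence scale;
* a four-stage consecutive-filter **re-assessment of proposed proteasomally
  spliced peptides** against canonical competitors (confidence, I/L
  isomery, better canonical PSM, score margin) with full accounting;
* **PWM motif scoring** (emission probabilities over the top-5 anchor
  positions, Jensen–Shannon divergence between motifs);
* a **rule-based synthetic spectrum generator** (proline-enhanced cleavage,
  basic-residue charge retention, NCE tilt, ppm jitter, noise peaks,
  reversed decoys, isobaric spliced/canonical confusion pairs) that serves
  as exact ground truth for every component.

The central score is the normalized spectral contrast angle between the
L2-normalized predicted and observed intensity vectors over the shared
valid tensor dimensions:

    SA = 1 − 2·arccos(⟨p̂, ô⟩)/π  ∈ [0, 1]

## A worked example

Simulate a small HLA class I dataset, annotate its spectra, and rescore it
with decoys:

```r
library(respectra)
library(purrr)

cfg <- sim_config(seed = 7, preset = "hla1", nce = 30)
sim <- simulate_dataset(300, cfg, decoys = TRUE)

# observed fragment tensors for every PSM (targets and reversed decoys)
obs <- imap(sim$peptides, function(p, i) {
  annotate(sim$spectra[[(i - 1) %% 300 + 1]], p)
})

# predictions from the rule-based oracle; features; rescoring
pred <- predict_fragments(
  oracle_predictor(),
  dplyr::mutate(sim$psms, nce = cfg$nce)
)
feats <- map_dfr(seq_len(nrow(sim$psms)), function(i) {
  build_features(sim$psms[i, ], pred[[i]], obs[[i]])
})
res <- semi_supervised_rescore(feats, sim$psms$is_decoy, seed = 7)
glance(res)
#> # A tibble: 1 × 5
#>   n_psms n_targets n_decoys accepted   fdr
#>    <int>     <int>    <int>    <int> <dbl>
#> 1    600       300      300      300  0.01
```

All 300 targets are recovered at 1% FDR and no decoys: with spectra
rendered from the targets' own fragmentation truth, spectral-angle features
separate targets from reversed decoys essentially perfectly — the expected
behaviour of the machinery under ideal predictions, not a claim about real
data. On the same footing, the consecutive-filter audit of spliced
proposals (`run_splice_audit(100, seed = 11)`) rejects 100% of isobaric
spliced explanations of canonically generated spectra:

```r
audit <- run_splice_audit(n_pairs = 100, seed = 11)
audit$report
#> <accounting_report> 100 candidates: 100 rejected (100%), 0 retained
#>   - not_confident: 0
#>   - il_isomer: 27
#>   - better_canonical: 73
#>   - insufficient_margin: 0
```

## Command line

A thin CLI over the same functions ships in `inst/cli/respectra.R`:

```sh
Rscript inst/cli/respectra.R simulate --preset hla1 --n 2000 --seed 7 --out data/
Rscript inst/cli/respectra.R annotate --mgf data/spectra.mgf --psms data/psms.tsv --tol-ppm 25
Rscript inst/cli/respectra.R rescore --pin features.pin --fdr 0.01
Rscript inst/cli/respectra.R assess-splicing --candidates cand.tsv --margin 1.0
```

## Scope

The predictor here is trained on rule-generated spectra: it demonstrates
that the architecture, loss, calibration and rescoring machinery are
correct and calibrated, not that they reproduce instrument chemistry.
Applying the workflow to real data requires training on real spectral
corpora. Only b/y ions are scored; vendor raw files, mzML, protein-level
FDR and binding-affinity prediction are out of scope. See the methods
vignette (`vignettes/rescoring-methods.Rmd`) for the models, parameters,
design decisions and limitations.
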