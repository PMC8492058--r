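---
title: "Motif information content and MPRA activity classes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif information content and MPRA activity classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpraic)
library(dplyr)
```

`mpraic` analyses massively parallel reporter assays (MPRAs) of candidate
cis-regulatory sequences centered on a single "centering" transcription
factor (TF) — the motivating system is CRX-targeted elements in mouse
photoreceptors — and asks what sequence features separate enhancers from
silencers when both are bound by the same TF. This vignette documents the
models, their assumptions, the tunable parameters, and the design choices
made where the published protocol left the design open.

## 1. Activity calling from barcode counts

Each library element carries several barcodes; sequencing yields one DNA
(plasmid pool) count and three cDNA replicate counts per barcode.
Processing follows the standard reporter protocol:

* **Barcode filters.** In the basal-promoter assay, barcodes with a DNA
  raw count below 10 are treated as missing and removed; barcodes with a
  cDNA raw count below 5 in *any* replicate are considered present in the
  pool but below detection and set to zero in *all* replicates. The
  promoterless (polylinker) assay, where most constructs are expected to
  be silent, uses a DNA floor of 50 raw counts and a cDNA floor of 8 RPM.
* **RPM and expression.** Counts are scaled to reads per million per
  sample; a barcode's expression is cDNA RPM / DNA RPM, and a construct's
  replicate expression is the mean over its surviving barcodes. RPM
  totals are computed after filtering, so DNA and cDNA denominators
  reflect the same barcode universe (the protocol is silent on the order;
  consistent filtering keeps the ratio interpretable).
* **Testing.** Expression is approximately log-normal, so each construct
  is compared to the basal promoter by Welch's unequal-variance t-test on
  natural-log expression. The observation unit is the **barcode ×
  replicate** value (up to 3 × 3 = 9 per element, 18 × 3 = 54 for basal).
  The alternative — replicate-level means, n = 3 vs 3 — would make the
  high fraction of significant calls seen in real libraries essentially
  unattainable, so the finer unit is used; its cost is discussed in §6.
  Statistical testing happens on unnormalized expression; normalization
  by the replicate-specific basal mean happens afterwards, matching the
  stated order of operations. Zero-variance groups get a variance floor
  equal to the squared pseudocount so that degenerate inputs yield finite
  p-values rather than NaN.
* **Classification.** Benjamini–Hochberg q-values are computed within a
  library batch. Enhancers are at least twofold above basal with
  q < 0.05; silencers at least twofold below with q < 0.05; inactive
  sequences are strictly within the twofold band with q ≥ 0.05; all other
  combinations are ambiguous. Enhancers above the 95th percentile of the
  scrambled controls' basal-normalized activities are strong, the rest
  weak. The percentile is computed on the linear activity scale — the
  same scale as the fold cutoffs.
* **Autonomous calls.** In the promoterless assay a construct is
  autonomous when its replicate-averaged log2(RNA/DNA) is strictly
  positive. The reported log2 expression adds the promoterless
  pseudocount (1e-2); the decision itself uses the raw ratio so that a
  ratio of exactly 1 is not autonomous (the pseudocount would otherwise
  nudge it over the boundary).

Key defaults (`mpra_config()`): fold cutoff 2, FDR 0.05, strong percentile
95, pseudocounts 1e-3 (basal assay) and 1e-2 (promoterless), all
overridable.

## 2. Predicted TF occupancy

A motif's letter-probability matrix is converted to an energy weight
matrix by normalizing each position by its most probable letter, taking
the negative natural log, and multiplying by `RT = 2.5` (the gas constant
times ~300 K in these units): the consensus letter has energy exactly 0
and every other letter a positive penalty. A probability pseudocount
(default 1e-4) keeps database zeros finite without disturbing the
consensus.

A window of energy `E` is bound with probability
`p = 1 / (1 + exp((E - mu) / 2.5))` at chemical potential `mu = 9`. The
published description fixes the energy scaling and `mu` but not whether
the exponent is itself RT-scaled; the scaled (Fermi) form used here is
pinned by an internal consistency check: it puts half-occupancy at a
relative dissociation constant of `exp(-9/2.5) ≈ 0.027 ≈ 0.03` of the
optimal site, exactly the stated property, whereas an unscaled exponent
would give ~1e-4. Predicted occupancy of a sequence is the sum of `p`
over all `L − w + 1` windows on the forward strand and all windows on the
reverse complement; overlapping windows all count, and a palindromic
consensus site deliberately counts on both strands (the protocol sums
strands unconditionally). Occupancy is therefore bounded by
`2 (L − w + 1)` and is exactly reverse-complement invariant.

A TF's motifs are "present" in a sequence when its total predicted
occupancy exceeds 0.5 molecules (strict inequality at the boundary). For
site-level analyses, an "occupied site" is a window whose single-site
binding probability exceeds 0.5; forward and reverse hits covering
overlapping positions of the same TF are collapsed into one site, because
a physical site is one locus.

## 3. Boltzmann-entropy information content

Treating each TF as a molecular species whose copy number on a sequence is
its predicted occupancy `N_i` (total `N`), the number of distinguishable
arrangements of the bound molecules is `W = Γ(N+1) / ∏ Γ(N_i+1)` and the
information content is `I = log2 W` bits. Fractional occupancies pass
through the Gamma continuation unrounded. Everything is computed in
log-Gamma space; forming `W` itself would overflow near occupancy ~170.
`I` is zero whenever at most one TF is bound — copies of a single TF carry
no arrangement information — and, at fixed total occupancy, is maximized
by the most balanced composition. Residual information content removes
the centering TF's dimension before computing `I` (numerically identical
to setting it to zero, since `Γ(1) = 1`), quantifying the information
carried by partner motifs alone.

The genomic-uniqueness helper implements the Poisson window model for
spurious motifs: a `w` bp window holds `k` total motifs for `m` TFs with
probability `Poisson(k; λ)`, `λ = p·m·w`, and the expected number of such
windows in an `N`-bp genome is that probability times `N`. All five
quantities are explicit parameters. Note that the published numerical
illustration of this formula is not internally consistent (its stated
`p`, `m` and `w` give `λ = 1.23`, an order of magnitude larger than the
quoted value, and no normalization of the genome length reproduces the
quoted expected count); the function therefore implements the formula as
defined and makes no attempt to match those illustrative numbers.

## 4. Classifiers

* **Logistic regression** (glmnet ridge, matching the
  `sum loss + ||β||²/(2C)` objective) on occupancy features, standardized
  per training fold (regularized models need a scale convention; the
  protocol is silent). `C` is selected from `10^-4 … 10^4` by mean F1
  over stratified cross-validation folds, then fold-wise AUROC/AUPR are
  reported as mean ± sd across folds (the "±" convention is taken to be
  fold-sd). When comparing feature sets (e.g. the information-content-
  only model), the `C` chosen on the reference occupancy panel is reused
  rather than re-tuned, following the published practice.
* **Spectrum SVM.** The gapped-k-mer SVM with `l = k = 6` degenerates to
  the spectrum kernel, and the published description of the model is
  "all 2080 non-redundant 6-mers"; it is therefore implemented as a
  linear SVM on canonical (reverse-complement-collapsed) 6-mer counts,
  with per-feature weights exposed. The original tool's mismatch flag at
  `l = k` has no documented effect on the feature map and is not
  replicated.
* **Random-motif null.** The curated panel's performance is judged
  against repeatedly drawing the same number of motifs at random from a
  larger pool, refitting at fixed `C`, and recording mean CV AUROC/AUPR;
  a one-tailed Z-test compares the observed statistic to this null.

AUPR is computed as average precision (precision at each positive,
weighted by the recall step); AUROC via pROC with fixed orientation
(larger score = positive class), never auto-flipped.

## 5. The synthetic MPRA generator

The generator exists so that every downstream stage is testable offline;
it encodes the qualitative findings of the motivating study as the
simplest parametric rule that makes recovery falsifiable:

* **Sequences.** Uniform-random 164 bp backgrounds with consensus sites
  planted at positions drawn uniformly over all non-overlapping
  arrangements, each on a random strand. Intended silencers get 3–4
  centering-TF sites and no partners; strong enhancers 1–2 centering
  sites plus one site for each of 2–3 distinct partners; weak enhancers
  one partner; inactive at most one centering site; 150 scrambled
  controls get nothing.
* **Expression rule.** `m = beta_act · D − beta_sil · [centering ≥ 2 and
  D = 0]` in log2 units, where `D` is the number of distinct partner TFs
  planted. Defaults `beta_act = 1.5`, `beta_sil = 2`: diversity
  activates, high centering-TF occupancy alone silences. No equation of
  this form is published; the two-parameter rule is this package's
  minimal encoding of the observed pattern.
* **Counts.** DNA per barcode is negative-binomial (mean 500, size 4) —
  plasmid pools are overdispersed, and the raw-count filters need
  realistic dropout to exercise. Each cDNA replicate draws Poisson
  counts around `DNA · 2^(m + ε)` with `ε ~ N(0, noise_sd)` per construct
  × replicate. The Poisson draw realizes the stated mean as a count
  while providing the within-replicate barcode variability that the
  barcode × replicate Welch test relies on. `noise_sd = 0.25` is a
  convention chosen to be consistent with the high replicate
  reproducibility of real libraries (with between-construct log2 signal
  variance of ~3–4, replicate-replicate R² works out above 0.96).
* **Toy motifs.** Each TF gets a random consensus with probability mass
  `sharpness` per position (default 0.95, width 8). At 0.95 the
  off-consensus penalty is ~10 energy units, so random 164-mers carry
  ~0.07 spurious molecules per TF (~1.6% spurious presence calls) —
  background occupancy comparable to real inactive sequences — while a
  planted consensus site contributes ~0.97 molecules. At `sharpness = 1`
  motifs are one-hot and planted counts are recovered to ±0.5 molecules,
  which the tests exploit as ground truth.

What the simulator does **not** emulate: chromatin state, sequencing
error, PCR jackpotting, dinucleotide-preserving scrambling (scrambled
controls are fresh random sequences here), affinity-graded (non-consensus)
planted sites, and TF–TF cooperativity. Passing recovery tests therefore
shows the pipeline is faithful to its own model of the data, not that the
biological conclusions transfer to any particular real library.

One deliberate consequence of the design: simulated scrambled controls
cluster tightly around basal, so their 95th percentile falls below the
twofold enhancer cutoff, and essentially every called enhancer is
classified strong. Intended "weak" enhancers are thus recovered as
enhancers but not as a distinct weak tier; recovery assertions are made
for strong enhancers and silencers, where the generative rule pins the
expected call.

## 6. Numerical conventions and caveats

* Boundary conventions: enhancer/silencer fold cutoffs are inclusive
  (≥ 2, ≤ 0.5); the inactive band and the strong/weak percentile split
  are strict; motif presence is strictly above threshold; autonomy is
  strictly positive.
* Ambiguity codes (N) are rejected at ingestion rather than scored:
  binding energies are undefined for them and designed libraries are
  N-free. Sequence length is not constrained to 164 bp anywhere outside
  the simulator default; scanner and metrics are length-generic.
* MEME motif rows off by ≤ 1e-3 are renormalized (database truncation);
  larger deviations are errors. Motif matrices must be width ≥ 1 with
  rows summing to 1 ± 1e-6.
* The barcode × replicate Welch observation unit treats observations
  within a replicate as independent, but replicate-level noise makes
  them correlated; the test is therefore anticonservative for
  constructs, exactly as in the original protocol. Under the default
  generator this inflates *significance* but rarely produces spurious
  *class* calls, because an enhancer/silencer call also requires a
  twofold excursion (a ~4-sd event at the default noise). The suite
  tests q-value calibration under independent noise (noise_sd → 0, where
  Poisson sampling dominates) and false class calls under the default
  correlated noise; both are properties a user should know when
  interpreting q-values from real, replicate-correlated data.
* Problem sizes in the test suite were chosen to keep the full run in
  the tens of seconds on one core while leaving the statistical
  assertions well-powered: 800 planted constructs (200 per intended
  class) plus 150 scrambled for pipeline recovery, 550 constructs for
  null calibration, 1000 random sequences for reverse-complement and
  shuffled-label checks, and exhaustive enumeration (≤ 4 TFs, total
  occupancy ≤ 12) for the entropy oracle.

## 7. Session info

```{r}
sessionInfo()
```
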