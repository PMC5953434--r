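---
title: "Evaluating brain-microvessel RT-qPCR: reference genes, quantification and purity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating brain-microvessel RT-qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Freshly isolated brain microvessels (BrMV) are the closest practical model
of the blood–brain barrier, but every isolation drags along other members
of the neurovascular unit — pericytes, astrocyte end-feet, neuronal
endings, microglia — in proportions that vary from preparation to
preparation. Two measurement questions follow:

1. **Normalisation.** RT-qPCR on BrMV needs a reference gene (RG) whose
   expression is stable both *across* preparations and *between* the
   microvessel fraction and the capillary-depleted brain (CDB) it is
   compared against. A reference gene confounded with the preparation
   biases every downstream fold change.
2. **Purity.** The endothelial content of a BrMV isolate can be read out
   from endothelial marker genes (MG) — claudin-5 (*Cldn5*), CD31
   (*Pecam1*), GLUT1 (*Slc2a1*) — provided their fold change over CDB is
   calibrated against known mixtures. *Plvap*, which barrier endothelium
   silences but fenestrated (choroid-plexus, meningeal) endothelium
   expresses, acts as a contamination indicator rather than a purity
   marker.

`bbbqc` implements the full evaluation chain — stability scoring,
standard-curve quantification, purity calibration, immunofluorescence
cross-checks — together with a seeded generative model of the measurement
process so that every stage can be exercised end to end without any
external data.

## Stability scoring

### geNorm

Ct values are first converted to relative quantities with min-Ct
anchoring, $q_{gs} = e_g^{\min_s \mathrm{Ct}_g - \mathrm{Ct}_{gs}}$, where
$e_g$ is the amplification factor (2 unless per-gene efficiencies are
supplied; with measured efficiencies of roughly 93–108% the distortion
from assuming 2 is below 5%). For genes $j,k$ the pairwise variation
$V_{jk}$ is the standard deviation across samples of
$\log_2(q_{js}/q_{ks})$, and the stability measure is
$M_j = \mathrm{mean}_{k \ne j} V_{jk}$. Lower $M$ is more stable;
$M < 0.5$ is the conventional acceptability bound in homogeneous sample
sets. Stepwise mode repeatedly removes the gene with the largest $M$ and
recomputes until two genes remain; those two have equal $M$ by
construction and are reported jointly most stable, ordered by their
full-panel $M$ (lexicographic on exact ties). Both the stepwise exclusion
order and the full-panel single-pass $M$ values are reported, since the
two variants cannot be distinguished from published rankings alone;
classic geNorm is implemented rather than any later modified algorithm.
The $V_{n/n+1}$ pairwise-variation sequence (SD of the log-ratio of
normalisation factors built from the top $n$ and $n+1$ genes) is provided
for deciding how many reference genes to carry.

### BestKeeper

BestKeeper works on the raw Ct scale. Per gene we report geometric and
arithmetic mean, extrema, a dispersion statistic `sd_ct` and
`cv_pct = 100 * sd_ct / arith_mean_ct`, plus the Pearson correlation of
the gene's Ct with the BestKeeper index (per-sample geometric mean Ct
across the panel) with a two-sided $t$-distribution p-value (df = n − 2).
Published descriptions of the tool are ambiguous about the dispersion
statistic; we define `sd_ct` as the **mean absolute deviation around the
arithmetic mean** (the variant around the geometric mean is available via
`sd_around = "geometric"`). Genes are ranked by ascending `sd_ct`. A
constant-Ct gene has an undefined index correlation and is reported as
absent with the note `"constant input"` instead of erroring. The
published "coefficient of correction" is interpreted as this Pearson
index correlation; nothing beyond Pearson r is computed.

### Combining the two

`combine_rankings()` averages the geNorm and BestKeeper ranks (the final
stepwise pair shares rank 1.5), breaks ties by the lower geNorm $M$, and
optionally demotes genes whose BrMV-vs-CDB t-test rejects at `p_veto`
(default 0.05) below all non-vetoed genes — a gene that differs between
the two preparations is a poor normaliser regardless of its within-group
stability. No multiple-testing correction is applied to these p-values,
matching common practice for this design.

## Quantification

Standard curves are ordinary least squares of Ct on
$\log_{10}(\text{quantity})$; the amplification efficiency is
$E\% = 100\,(10^{-1/\text{slope}} - 1)$, so the perfect 10-fold series
with a Ct step of $\log_2 10 \approx 3.32$ cycles gives exactly 100%.
Quantities are recovered by inversion,
$\hat{x} = 10^{(\mathrm{Ct} - b)/m}$; Ct values outside the fitted range
are extrapolated with a warning rather than refused, because unknown
samples are not guaranteed in-range.

Relative quantification uses the ddCt method with amplification factor 2
for both genes by default; the efficiency-corrected Pfaffl form is
opt-in. Replicates are aggregated duplicates → run mean → sample mean
before any subtraction, matching the duplicate-by-three-runs design, and
group-level fold changes are computed per sample against the **mean**
calibrator ΔCt of the reference group (unpaired form; the pairing used in
published group ratios is generally unstated). Absolute quantification
interpolates copies from a plasmid curve and divides by the RNA input,
either nominal (default) or re-estimated from a reference-gene curve —
both modes exist because published copy-per-ng figures rarely state which
was used.

Censoring is handled asymmetrically by design: a censored gene of
interest (no amplification by the 40-cycle cap, e.g. a knockout) yields
fold 0 / 0 copies with a censored flag, while a censored *reference* gene
is a hard error — a normaliser that does not amplify invalidates the
reaction. All aggregation functions exclude censored replicates and
report how many they dropped. SDs use the n − 1 denominator everywhere
(replicate counts are small).

## Purity

A mixing series — a designated "100%" BrMV sample serially diluted into
the "0%" CDB pool — defines the purity scale. Marker fold changes over
the pool are regressed on the design purity with a **free intercept**,
with the (0%, fold 1) point included as data (the pool is the ddCt
calibrator, so its fold is 1 by construction; whether published fits were
anchored is unstated, and the free intercept lets the data decide).
Scoring inverts the line, `purity = (fold - intercept) / slope`; values
above 100% (purer than the standard) or below 0% are reported verbatim
with notes, never clipped. The consensus purity is the arithmetic mean of
the *Cldn5* and *Pecam1* purities; *Slc2a1* is scored and reported but
excluded from the consensus because its broader expression across brain
cell types makes it less coordinated with endothelial content. A marker
whose fitted slope is not positive is rejected as invalid — it is not
enriched in the target fraction.

The *Plvap* indicator flags a sample when its fold over the CDB pool
**strictly exceeds 40** (the boundary value 40 does not flag); the pool
itself is checked against a background Ct of 30, since a pool with
clearly detectable *Plvap* is itself contaminated with fenestrated
vessels and cannot serve as calibrator.

Immunofluorescence counts are converted to fractions of total DAPI+
nuclei with the unlabeled remainder assigned to `other`; totals of 500 or
fewer nuclei are flagged under-sampled (warning only), honouring the
more-than-500-nuclei counting rule. Pearson correlation (Spearman as a
robustness option) relates qPCR purity to the lectin+ fraction. Because
the purity scale is relative to an arbitrary standard, `rescale_to_brec()`
proportionally anchors it to an immunofluorescence-measured endothelial
content through one anchor pair.

## The generative model

`simulate_ct()` implements the measurement process the analysis assumes:

* **Mixture.** A sample is a probability vector over seven cell classes
  (BrEC, pericyte, astrocyte, neuron, microglia, fenestrated endothelium,
  other). Bulk abundance is the composition-weighted expression
  $m_{gs} = \sum_c f_{cs} x_{gc}$, scaled by `allele_count / 2` for the
  gene of interest.
* **Ct law.** Noiseless Ct is
  $\mathrm{Ct}^0 = b_g - \log(m_{gs}\,\text{input}_{ng}) / \log e_g$.
  Intercepts $b_g$ in `default_panel()` are calibrated so a typical BrMV
  mixture (66% BrEC) measured at 25 ng lands at the midpoint of the
  conventional Ct window for each assay (Actb 14–17 through Plvap 25–28,
  Idua 24–26), and a parenchymal sample shows near-background Plvap
  (Ct > 30). Expression levels per cell class are otherwise arbitrary
  units chosen to reproduce the qualitative orderings (Slc2a1 the most
  abundant marker with the weakest BrMV/CDB contrast, ~9-fold; Cldn5 the
  strongest, ~30-fold; Plvap expressed *only* in fenestrated
  endothelium) — they are not claims about absolute transcript counts.
* **Noise.** Three seeded components: per-replicate technical noise on Ct
  (default SD 0.3 cycles, which puts replicate CVs at the 1–2% level
  around Ct 20, the reproducibility regime reported for Taqman
  duplicates); per-sample×gene biological noise on log2 abundance
  (default 0.15); and an optional per-gene instability SD (cycles) to
  emulate genes that are differentially regulated across samples. A
  `group_ct_shift` knob models a reference gene confounded with the
  experimental group. Fenestrated endothelium is a separate cell class
  rather than a flag so Plvap contamination and BrEC purity can vary
  independently.
* **Censoring.** Zero abundance, or any Ct beyond the 40-cycle cap, is
  recorded as "no amplification" — censored, not missing at random.
* **Determinism.** Every stochastic operation is a pure function of
  (specification, seed); re-running with the same seed is byte-identical.

Compositions are specified directly so tests are reproducible; a
Dirichlet sampler (`sample_compositions()`) provides cohort-level Monte
Carlo. Immunofluorescence counts are multinomial draws with the two
endothelial classes pooled into lectin+ (lectin stains all endothelium).

### What the generator does and does not show

Passing the pipeline on generated data demonstrates internal consistency:
the stability ranking finds an injected unstable gene, purity scoring
inverts the mixing design it was calibrated on, dosage ratios recover the
built-in 2:1, and a confounded reference gene biases them — all under a
noise structure matching the replicate CVs and calibration linearity a
careful bench study reports. It does **not** validate behaviour under
effects the model omits: plate-position and inter-plate effects,
amplification inhibitors, primer-dimer artifacts, RNA degradation
gradients, or cell-type expression profiles that differ from the assumed
matrix. Real studies should treat the generator as a test harness, not as
evidence about any particular tissue.

One modelling point deserves emphasis. With purely multiplicative fold
noise, a weakly enriched marker loses surprisingly little purity
precision — the noise scales down with the calibration slope. What
actually degrades a broadly expressed marker like *Slc2a1* is
*expression variability across samples* in the non-endothelial
compartment, which decouples its fold change from endothelial content.
The Monte-Carlo tests therefore model Slc2a1 with a per-sample
instability SD (0.5 cycles) on top of technical-noise-dominated folds
(biological SD 0.05 log2), in nine-sample cohorts whose endothelial
fraction spreads like a real isolation series (roughly 50–90%,
Dirichlet concentration 15). Under those conditions the Cldn5-derived
purity out-correlates the Slc2a1-derived one in ≈99% of cohorts, with
mean r² ≈ 0.74 vs ≈ 0.25 — the qualitative pattern a well-run study
reports.

## Numerical and interface choices

* Log base 10 for standard-curve axes, log base 2 for expression ratios.
* CSV dialect: comma-separated, header required, UTF-8; a censored Ct is
  an empty field or the literal `"Undetermined"` (case-insensitive), and
  is written back out as `"Undetermined"` so round-trips are exact.
* Replicate keys `(sample_id, gene, run_id, replicate)` must be unique;
  duplicates are an integrity error listing the offending keys.
* The intra-assay CV is the per-run CV of duplicates averaged over runs;
  the inter-assay CV is the CV of run-level means. Published CV tables do
  not always state whether pooling crosses RT products, so both levels
  are exposed and neither is asserted as canonical.
* Group comparisons default to the equal-variance Student t-test (the
  test usually named for this design); Welch is a flag.
* QC gate defaults: OD260/280 in [1.9, 2.2], OD260/230 ≥ 1.8,
  28S/18S > 1.0; an absent ratio skips its check and is recorded as
  "not assessed" rather than failing.
* Stepwise geNorm ties break lexicographically; invalid-marker detection
  uses a slope tolerance of 1e-10 to absorb floating-point zeros.

## Problem sizes

The shipped test-suite and analysis scripts run at deliberate desk scale:
cohorts of 8–20 samples with the 3-runs × 2-duplicates replicate design,
200-seed Monte-Carlo sweeps for the stability bounds, 100-seed sweeps for
purity recovery and calibration linearity, and 1,000 random tables for
the brute-force oracle equivalence checks. These sizes keep the whole
suite under a couple of minutes while leaving the Monte-Carlo acceptance
margins wide.

## Known limitations

* Classic geNorm only; NormFinder and ΔCt-method stability are out of
  scope, as is any aggregate meta-ranking across tools.
* BestKeeper's dispersion statistic is a reimplementation choice (MAD
  around the arithmetic mean); numbers from other implementations may
  differ in the third decimal.
* Purity calibration assumes fold change linear in mixing proportion,
  which holds through the ddCt algebra when the calibrator pool
  expression is well above background; markers near background in CDB
  (like Plvap) produce valid but noisier lines.
* The composition correlation treats lectin+ as ground truth; counting
  error in the immunofluorescence itself is modelled only as multinomial
  sampling.
* No raw fluorescence processing, melt curves, plate effects or
  image segmentation — inputs begin at Ct values and nuclei counts.
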