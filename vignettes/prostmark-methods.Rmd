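---
title: "Methods: biomarker prioritization, qPCR validation and organoid morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker prioritization, qPCR validation and organoid morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`prostmark` implements a multi-stage prostate-cancer biomarker workflow:
candidate prioritization from a grouped expression matrix, spike-in
standardized absolute qRT-PCR validation, siRNA functional-assay
quantification, and organoid morphometry. Every stage is exercisable on
synthetic data whose generators emulate the statistical structure the
analysis assumes — including the cancer-adjacent "field effect" by which
marker transcripts are already elevated in histologically benign tissue
from cancerous glands. This vignette records the models, the tunable
parameters, the numerical choices, and what the synthetic experiments do
and do not demonstrate.

## The prioritization cascade

The input is a log2 expression matrix over three sample groups — N
(benign prostate), T (primary prostate cancer), M (metastasis) — plus a
tissue-specificity score table, a literature citation-count table, and
per-sample survival annotations. The cascade runs:

1. **Per-gene statistics**, per contrast (T vs N, M vs T): log2 fold
   change computed on linear-scale group means,
   $\mathrm{FC} = \log_2\frac{\bar a + c}{\bar b + c}$ with pseudocount
   $c$ (default 0); Welch's *t* with Welch–Satterthwaite degrees of
   freedom; a *z* score; the Mann–Whitney *U*; the three-group one-way
   ANOVA *F*; and a SAM-style moderated difference
   $d = (\bar a - \bar b)/(s + s_0)$ with pooled standard error $s$.
2. **Significance gate and truncation**: genes with Bonferroni-adjusted
   *t* p-values below $\alpha$ (default 0.05) are ordered by $|$FC$|$
   (ties broken lexicographically by gene id) and truncated to the top
   $K = 300$ per contrast.
3. **Combined ranking**: the T-vs-N order is the base; genes also present
   in the M-vs-T top list have their rank score reduced by a boost
   (default $K$), so markers of both tumorigenesis and progression rise
   to the head of the list. The re-sort is stable.
4. **Tissue filter**: keep a gene iff its prostate score divided by the
   median of its non-prostate scores is at least `tissue_ratio_min`
   (default 2, boundary inclusive).
5. **Survival filter**: patients are split at the `risk_quantile`
   (default 0.85) of the gene's expression — the top 15% form the
   high-risk stratum — and the gene passes iff the two-group log-rank
   test is significant at $\alpha$ *and* the high-expression stratum has
   the worse survival (more observed than expected events). The
   directionality requirement encodes that a useful progression marker is
   one whose overexpression predicts reduced survival.
6. **Literature filter**: genes cited more than `citation_max` (default
   5) times are excluded as already well described; the filter keeps
   counts of exactly 5 and rejects 6.

Every removal is attributed to exactly one *first-failing* filter, and the
full per-gene ledger (ranks, statistics, verdicts) is returned as a
`candidate_trace`.

### Decisions taken where the design was open

* **"Z-score" test.** Implemented as the difference of group means divided
  by the standard deviation of the reference (normal) group, with a
  two-sided normal p-value. This is one admissible reading of a z-score
  screen; it is configurable only in the sense that the other statistics
  are computed alongside and can be gated on instead.
* **SAM fudge factor.** $s_0$ defaults to the median of the per-gene
  pooled standard errors of the T-vs-N comparison. The full SAM
  permutation FDR is not implemented; Benjamini–Hochberg FDR is available
  as the alternative gate (in practice the two approaches select similar
  gene sets, which is why a single gate suffices here).
* **Gate before truncation.** The significance gate is applied before the
  top-$K$ cut, so the list never contains non-significant genes padded in
  by rank. The reverse order would make $K$ genes always survive
  regardless of evidence.
* **Ties.** All orderings break ties by lexicographic gene id, making
  every list deterministic.
* **85/15 stratification and ties.** The high-risk stratum has exactly
  `round(n * 0.15)` members; ties at the threshold are resolved by stable
  input order. With all-equal expression the first 15% of patients in
  input order are labelled high-risk — an arbitrary but reproducible rule.

## qPCR validation

Raw triplicate copy counts are converted to copies per microgram of total
RNA via the internal-standard spike-in: an artificial transcript is added
at a known amount before extraction, `recovery = spike_measured /
spike_added`, and `copies/µg = raw / (recovery × rna_µg)`. This makes the
quantification absolute and robust to extraction losses, unlike
housekeeping-gene normalization. A sample is *positive* only if all three
replicates lie strictly above the lowest assay detection limit (LDL); the
LDL and the spike-in amount are assay properties supplied as input columns
(defaults in the generator: 50 copies/reaction and 10^6 copies — free
parameters, as the real values are assay-specific and unpublished).

The validation report assembles: the detection table (gene × group
positives and nearest-integer percentages, halves rounded away from
zero); the Mann–Whitney contrast battery over the four groups (CP-B,
CP-IPCa, RP-B, RP-PCa; CP = cystoprostatectomy, RP = radical
prostatectomy) and their unions; clinical dichotomizations (Gleason ≥ 7
vs < 7, pT2 vs pT3/pT4, PSA relapse vs none, tumor content strictly over
33% vs at most 33%, unknowns excluded); and ROC/AUC for RP-PCa vs CP and
RP-B vs CP. The AUC is computed from ranks with half-credit for ties and
is therefore exactly $U/(n_1 n_2)$ — this identity is enforced by a
shared-oracle test against the Mann–Whitney implementation and against an
independent pairwise-comparison count.

Where patients contribute two samples, the per-patient reduction
(consistently preferring the right lobe, then the smaller sample id)
applies to the clinical splits and the ROC comparisons only; the group
contrasts use all samples. Percentages use nearest-integer rounding
throughout: published detection tables of this kind sometimes mix
truncation and rounding between cells, and a single documented convention
is preferable to mimicking an inconsistency.

## Functional assays

Knockdown efficiency is `100 × (1 − treated/control)` on normalized
expression; negative values (upregulation) are reported and flagged, not
clamped. Viability and apoptosis readouts are summarized per condition as
percent of the control condition's mean (the control is anchored at
exactly 100%), with replicate standard deviations carried alongside.
Wound-healing series yield per-frame wound width (mean per-row gap extent
inside the wound strip), wound confluence (percent of the wound region
occupied), and relative wound density
`RWD(t) = 100 (w(t) − w(0)) / (c(t) − w(0))` comparing density inside the
wound to the surrounding monolayer, clamped to [0, 100]. Densities are
occupied-pixel fractions of binary masks; grayscale inputs must be
thresholded upstream.

## Morphometry

Images are 2-D maximum-intensity projections (per-pixel maximum over the
stack); no 3-D meshing is attempted. Segmentation is a global threshold
(Otsu by default), 8-connected component labeling with deterministic
label order by top-left pixel, and a minimum-area filter. Per organoid:

* **Area** — pixel count; exactly conserved under translation.
* **Perimeter** — Moore boundary-step (chain-code) estimator: axial steps
  weigh 1, diagonal steps √2. For a 21×21 square this gives exactly 80.
  For smooth contours the chain code systematically overestimates length
  by about 5%; a rasterized disk of radius 20 therefore measures
  roundness ≈ 0.91 rather than 1. We keep the plain estimator because it
  is exact on axis-aligned shapes and its bias is a fixed, documented
  property that cancels in control-relative comparisons; roundness is
  additionally clamped at 1 against discretization overshoot.
* **Roundness** — `min(1, 4π·area/perimeter²)`; anticorrelated with
  invasive morphology.
* **Roughness** — mean absolute radial deviation of the boundary outline
  from the outline of the morphologically opened mask, normalized by the
  equivalent radius; captures small single-cell-scale protrusions.
* **Protrusions** — the body is the morphological opening with a disk of
  `opening_radius` (default: a quarter of the median equivalent radius of
  the segmented organoids); protrusions are 8-connected components of
  mask∖body with at least `min_spike_area` (default 5) pixels. The count
  is the MaxApp-style statistic; the protrusion-area fraction of the mask
  is the AppIndex-style statistic. Both are documented approximations of
  descriptors whose reference definitions are not public; they are
  validated against synthetic ground truth, not against the original
  software.
* **Live/dead signals** — mean live intensity over the mask (density),
  and mean/total dead-channel (ethidium-homodimer-like) and
  apoptosis-reporter signals. When no separate apoptosis channel exists,
  the dead channel serves both readouts.
* **Cell number** — nuclei-blob count within the mask when a nuclear
  stain is available, else `round(area / typical_cell_area)`.

Condition-level summaries (mean apoptosis, total apoptosis, mean EthD,
total EthD, summed area — each percent of control) mirror the shape of a
silencing-impact table; the control row is identically 100%.

## Synthetic data: what it emulates, and what it does not

The generators draw everything from one integer seed through a
hierarchical stream (one child stream per generator), so identical
configurations give byte-identical artifacts and adding a generator never
perturbs another's draws.

* **Expression cohort.** Log2-normal noise (default SD 0.5) around group
  means; planted marker genes get +2 log2 in T over N, three of the eight
  an additional +1.5 in M over T, prostate-specific tissue scores (ratio
  10), at most five citations, and a survival association. Decoy genes
  (default 400) carry genuine T-vs-N effects drawn from [1.2, 1.8] but
  non-specific tissue profiles and more than five citations — they
  emulate well-known cancer genes that populate fold-change rankings and
  must be removed by the downstream filters. Survival is exponential with
  log-hazard linear in the mean standardized expression of the prognostic
  planted genes (coefficient 2 per SD) and administrative censoring at
  120 months; the default group sizes (20/20/20) keep the whole cascade
  under a couple of seconds while giving the survival filter adequate
  power.
* **qPCR cohort.** Per-gene true copies/µg are log-normal (between-sample
  SD 1 log2 unit) around `base_copies` (10^4) times a group multiplier: 1
  for CP-B, 2 for CP-IPCa, 3 for RP-B (the field effect) and 10 for
  RP-PCa, encoding the ordering CP-B < RP-B < RP-PCa. Triplicates add 15%
  multiplicative CV; spike-in recovery is uniform on [0.3, 0.9] per
  sample; RP patients contribute paired benign/cancer samples with lobe
  labels. The default four-group sizes (7/12/20/20) keep the CP arms at
  the published cohort's scale and the RP arms at a reduced scale.
* **Images.** Organoids are disks (radius 14–20 px) with rectangular
  protrusions (width 3, length 15 px) on a 192-px canvas; the dead
  channel speckles 10% of in-mask pixels. Wound series close a 60-px
  strip at a configured per-frame rate.

Passing tests on these data demonstrate that the *rules* are implemented
correctly and that the cascade recovers planted structure under realistic
noise — they do not validate the biological claims on real cohorts. The
generators deliberately omit: probe-level microarray artifacts,
patient-level correlation in expression noise, PCR amplification curves
and efficiency drift, image background, illumination gradients and
out-of-focus light, and cell-level texture inside organoids.

## Problem sizes and calibration checks

The shipped test suite runs the cascade at 5,000 genes × 60 samples
(single run, seconds), a 20-seed parameter-recovery study at 2,000 genes
with 30 samples per group and a null background, and a 200-seed null
calibration of the qPCR contrast battery (all group multipliers 1, 20 vs
20 samples) checked against uniformity of p-values by a Kolmogorov–
Smirnov test at α = 0.01. Exact Mann–Whitney p-values are verified
against exhaustive enumeration for all group sizes up to 6, and the
AUC–U identity on 1,000 random datasets with ties.

## Known limitations

* The survival filter tests one gene at a time; no multivariate or
  adjusted survival modelling is attempted.
* The SAM permutation null and its FDR are not implemented.
* Wound metrics assume binary confluence masks aligned across frames.
* The morphometric descriptors are this package's documented definitions;
  absolute values are not interchangeable with other software's, though
  control-relative comparisons are.
* Detection percentages follow a single rounding convention and may
  differ by one point from tables produced with truncation.
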