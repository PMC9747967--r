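---
title: "Cytokine microenvironments on the Visium hex grid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytokine microenvironments on the Visium hex grid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotniche)
```

## The problem

In chronic inflammatory skin diseases — psoriasis, atopic dermatitis,
lichen planus — a handful of effector cytokine transcripts (*IL17A*,
*IL13*, *IFNG*) drive disease although they are vanishingly rare in
spatial transcriptomics data: single UMIs on single 55 µm spots.  The
question this package addresses is *how far the transcriptional response
to one such transcript reaches*: the cytokine's **radius of action** on
the hexagonal Visium array.

The core procedure:

1. flag **leukocyte-positive** spots (≥ 1 UMI of CD2, CD3D, CD3E, CD3G,
   CD247 or PTPRC) and **cytokine-positive** spots (≥ 1 UMI of the
   cytokine; a single transcript counts, double-positive spots are kept
   in both sets);
2. connect cytokine-positive spots of a section into a graph (Euclidean
   distance ≤ 2.0 in array-index space) and take connected components as
   **cluster seeds**;
3. expand each component by the hexagonal ring neighborhood of radius
   *r* — the neighborhood of a center collects offsets `(j, i)` with
   `j ∈ [−r, r]`, `i ∈ [−2r+|j|, 2r−|j|]`, `i + j` even, i.e. the
   centered hexagonal number `3r² + 3r + 1` of spots — and merge
   clusters that share any spot;
4. read out per cluster the summed cytokine UMIs (over seeds) and the
   summed responder-signature UMIs (over all members), and compute a
   **weighted Spearman correlation** across clusters, weighted by the
   cytokine counts;
5. sweep `r = 0..9` and select the radius maximizing the correlation
   (ties break toward the smaller radius).

Responder signatures come from in-vitro cytokine stimulation of
keratinocytes: genes passing `p < 0.05`, `padj < 0.05` and
`log2FC > 1.5` (IFN-γ, IL-17A) or `> 1` (IL-13), intersected with the
spatially derived DEG list of cytokine-positive epidermal spots, purified
so that no gene sits in two cytokines' signatures, and (for IL-13)
supplemented from a configurable literature list
(`inst/extdata/literature_il13.yaml`).

## Statistical components

**Weighted Spearman.** Zero-weight units are dropped, both variables are
replaced by mid-ranks, and a weighted Pearson correlation of the rank
vectors is computed; with uniform weights this is exactly the classical
Spearman coefficient.  The two-sided p-value uses a t statistic with
`n − 2` degrees of freedom.  The weighted null is not exactly t, so a
seeded permutation p-value (`p_method = "permutation"`) is available;
for the effect sizes this pipeline cares about the two agree closely.

**Differential expression.** Raw counts are modeled per gene as negative
binomial with log link, `log(size factor)` offset, and fixed-effect
covariates (centered cellular detection rate, project, patient, layer
annotation, condition).  Coefficients are fit by IRLS, the per-gene
dispersion by method-of-moments initialization plus profile maximum
likelihood (floored at `1e-8`, so Poisson data land on a Poisson GLM to
numerical accuracy); inference is a two-sided Wald test on the condition
coefficient with Benjamini–Hochberg correction, and genes are called at
`|log2FC| ≥ 1`, `p ≤ 0.05` (both cutoffs inclusive).  No
quasi-likelihood or dispersion shrinkage is applied; at the several
hundred spots per contrast typical here the Wald test is calibrated
(type-I error ≈ 0.05 in the acceptance suite).

**Normalization.** Size factors are library sizes divided by their
geometric mean — deliberately *not* a reimplementation of pooled
deconvolution factors; any externally computed positive factor vector
can be substituted.  The log transform is `log10(count/sf + 1)`; note
the base-10 logarithm, not the field's usual natural-log `log1p`.  All
downstream counting (cluster readouts, DEG) uses raw counts.

**Layer enrichment.** Per sample, cytokine UMIs are summed over two
disjoint layer groups; the paired per-sample sums enter a two-sided
Wilcoxon signed-rank test (exact for ≤ 25 informative pairs, normal
approximation with continuity correction above; zero differences are
dropped, and an all-zero comparison returns p = 1 with a warning).
Samples, not spots, are the pairing unit: spots within a section are not
exchangeable.

## The synthetic world

No public count data ships with this package; every test runs on
simulated Visium-like data with planted ground truth.  The defaults of
`sim_config()` state one fixed world:

* **40 small sections of 17 × 9 spots** (≈ 3200 epidermal spots pooled),
  horizontal layer bands from upper epidermis (3 rows) through
  junction to dermis 7 — the many-small-biopsies design of clinical
  Visium cohorts.  Many small sections (rather than a few large ones)
  keep clusters from merging into section-spanning blobs, which is the
  regime in which the radius estimator is well-posed (below).
* **Cytokine spots**: each epidermal spot is positive with probability
  0.03 per cytokine, carrying 1–15 UMIs (uniform), and at least one
  leukocyte-marker transcript is planted on every positive spot.
* **Responder genes** (30 per cytokine): constitutive NB mean 0.6 per
  gene per spot, near-Poisson dispersion (θ = 10), modulated by a
  spatially correlated patch field (Poisson(2) Gaussian blobs per gene
  and section, amplitude 20, scale 1.2 index units) that emulates the
  strong spatial autocorrelation of real tissue expression.
* **Dose response**: each cytokine transcript carries a fixed total
  induced response, distributed over the epidermal spots that exist
  within the planted radius of its seed; a spot's mean fold over
  baseline is `1 + (amplification − 1) × dose`, with `amplification = 3`
  and `amplification = 1` switching the effect off entirely.  Two
  choices here deserve emphasis.  First, the induced mean scales with
  the local transcript dose (the observation motivating the method is
  precisely that more cytokine transcripts produce more responder
  transcripts; a dose-independent bump would carry no cytokine–responder
  correlation across clusters and would make radius recovery impossible
  in principle).  Second, the per-transcript response mass is
  *conserved*: a seed near a section border concentrates its response
  on the spots that exist rather than losing it.  Without conservation,
  border clipping injects cluster-area noise that systematically drags
  the estimated radius toward zero.
* **Housekeeping**: GAPDH at mean 50; ten mitochondrial genes at mean 2
  (≈ 12% MT fraction, under the 25% QC cut); background genes at mean
  0.5 with θ = 10.
* The planted radii default to 4 (IFNG), 3 (IL13) and 0 (IL17A).

Per-sample RNG streams derive from the master seed by fixed offsets, so
subsetting samples does not change their data.

The stimulation-table generator plants, per cytokine: true responders
passing all three filters with margin; cross-reactive genes passing for
*every* cytokine (these must be removed by the purification step);
and decoys cycling through the three rejection modes (low fold change,
poor p, poor adjusted p), so each filter arm is exercised.

### What the generator does *not* emulate

Real gene–gene correlation structure beyond the shared patch field;
cell-type mixtures within spots; image data; segment-specific capture
efficiencies; batch effects (a two-level project covariate exists in the
metadata but is not used to perturb counts).  A green test therefore
establishes algorithmic correctness and statistical calibration under a
stated NB world — not biological validity on any particular tissue.

## Behavior and limits of the radius estimator

The sweep objective — weighted Spearman of per-cluster cytokine versus
responder counts — is a *rank* statistic.  Ranks are invariant to how
much of the induced mass a sub-radius cluster captures, so the profile
of the objective around the true radius is intrinsically shallow: for a
planted radius of 4, adjacent radii typically differ by ~0.01 in *r*,
and with the ~25–50 clusters that ~3000 epidermal spots support, the
argmax is decided by sampling jitter.  In our acceptance measurements
the exact-recovery rate is ≈ 1.0 for a planted radius of 0 (the first
ring multiplies cluster area sevenfold, so the profile is sharp there),
but only ≈ 0.6–0.75 for planted radii 2 and 4 — short of the 80% bar
the acceptance suite asserts, which is therefore left failing with this
analysis rather than weakened.  Off-by-one errors dominate the misses.
This mirrors the near-flat radius profiles reported for IFN-γ in real
data; single-radius resolution at desk scale is beyond what the
statistic delivers.

Two further estimator properties worth knowing:

* **Cluster-size confound.**  Merged clusters have more seeds *and*
  more member area, so their responder sums grow with their cytokine
  sums even without any induced effect.  At seed densities where
  merging is common, the clustered correlation is genuinely positive
  under the null.  Null calibration holds in the sparse, singleton-
  cluster regime.
* **Pseudo-bulk saturation.**  The advantage of density clustering over
  per-section pseudo-bulk is only expressible when sections contain
  several niches plus substantial non-niche responder mass; with
  niche-sized sections both estimators saturate.  The spatial-gain
  acceptance check therefore uses larger multi-niche sections (12 of
  17 × 80, seed rate 0.004, planted radius 1), where pseudo-bulk lands
  around *r* ≈ 0.6 and clustering around 0.97 — the qualitative analogue
  of the published per-slice versus clustered improvements.

## Numerical and design choices

* Geometry lives in 0-based array-index space.  The published ≤ 2.0
  adjacency rule therefore also links spots two rows apart in the same
  column (index distance 2), which are not physical hex neighbors; this
  faithful behavior is the default, `adjacency_mode = "hex6"` restricts
  to the 6 physical neighbors.
* Adjacency is boundary-inclusive (`d ≤ 2.0`), with a `1e-9` tolerance
  against floating-point representation of √2-type distances.
* Ring membership is computed from seed spots only, never iteratively
  from ring spots; only seeds carry cytokine evidence.
* Cluster seeds must also be leukocyte-positive by default
  (`require_leukocyte = TRUE`), since the anchor is the cytokine-
  *producing leukocyte* spot.
* Cluster ids are `"<sample>:<radius>:<smallest seed key>"`, making
  merging independent of processing order and outputs byte-stable.
* Radius ties break toward the smaller radius (parsimony).
* QC order is fixed — spot rules first, then the ≥ 20-spots-per-gene
  rule — and all thresholds are boundary-inclusive for keeping
  (a spot at exactly UMI 50 or MT fraction 0.25 survives).
* Strict inequalities in the stimulation filter (`log2FC > 1.5`,
  `p < 0.05`) versus inclusive cutoffs in the spatial DEG caller
  (`|log2FC| ≥ 1`, `p ≤ 0.05`) are both deliberate and follow the
  respective procedure descriptions.
* Whether the spatial side of the signature cascade uses adjusted or
  raw p-values is exposed as `use_adjusted` (default adjusted).
* The dispersion floor `1e-8` (on the reciprocal size) caps θ at `1e8`;
  IRLS divergence (`max η > 50`) or a singular information matrix marks
  a gene non-converged, flagged with `p = 1`.

## Known limitations

* The spot-level signature contrast (cytokine-positive versus negative
  epidermal spots) loses power as amplified zones tile the epidermis:
  at the default seed density and a planted radius of 4, most negative
  spots are themselves inside some zone and the contrast washes out —
  the same dilution that left the published IL-13 in-vivo signature
  with only 4 genes.  The pipeline warns and continues with an empty
  signature for such cytokines instead of failing.
* Exact single-radius recovery for large radii is not achievable at
  desk scale (above).
* The Wilcoxon layer test falls back to the normal approximation in the
  presence of ties even for few pairs.
* `scran`-style pooled deconvolution size factors are not implemented.
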