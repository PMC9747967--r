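# spotniche

Cytokine microenvironment analysis for 10x Visium spatial
transcriptomics of inflamed skin.

In chronic inflammatory skin diseases (psoriasis, atopic dermatitis,
lichen planus), the disease-driving effector cytokines *IL17A*, *IL13*
and *IFNG* appear in spatial transcriptomics data as a handful of
transcripts on a handful of 55 µm spots — yet each transcript triggers a
local amplification cascade of responder genes in the surrounding
epidermis.  `spotniche` quantifies that cascade: it anchors
density-based clusters on cytokine transcript-positive leukocyte spots,
expands them ring by ring on the hexagonal array, and selects the
cytokine's **radius of action** as the hex radius *r* that maximizes a
weighted Spearman correlation between per-cluster cytokine counts and
responder-signature counts.

The hex neighborhood of radius *r* in array-index space collects the
offsets

    C_n = sum_{j=-r}^{r} sum_{i=-2r+|j|}^{2r-|j|} s_ji ,   i + j even,

i.e. the centered hexagonal number `3r^2 + 3r + 1` of spots.  Cytokine
spots within Euclidean index distance 2.0 are joined into cluster seeds;
overlapping clusters merge; per-cluster counts enter a weighted Spearman
(weighted Pearson on mid-ranks, weights = cytokine counts), swept over
`r = 0..9`.

The package also implements the supporting stages: Visium-dialect I/O
(MTX + barcodes/features TSV + `tissue_positions_list.csv`), spot/gene
QC (≥ 30 detected genes, UMI in [50, 500000], mitochondrial fraction
≤ 25%, genes in ≥ 20 spots), size-factor normalization with `log10(x+1)`
transform, leukocyte/cytokine spot labeling, Wilcoxon signed-rank layer
enrichment, responder-signature derivation from in-vitro keratinocyte
stimulation tables (filter → spatial intersection → cross-signature
purification → literature supplementation), per-gene negative-binomial
GLM differential expression (IRLS + per-gene dispersion MLE, Wald test,
BH correction), and a synthetic Visium-like data generator with planted
ground truth so the whole pipeline is testable without any downloads.

## Worked example

Simulate the default synthetic cohort (40 small lesional sections,
planted radii 4/3/0 for IFNG/IL13/IL17A), run QC, label spots, and sweep
the radius for IFNG:

```r
library(spotniche)

sim    <- simulate_dataset(sim_config(seed = 42))
qc     <- apply_qc(sim$dataset)
labels <- label_spots(qc$dataset)
labels
#> spot_labels: 6120 spots, 1679 leukocyte+
#>   IFNG: 102 positive spots, 763 UMIs
#>   IL13: 100 positive spots, 818 UMIs
#>   IL17A: 91 positive spots, 729 UMIs

sw <- radius_sweep(qc$dataset, labels, "IFNG",
                   sim$truth$responder_genes$IFNG)
sw
#> radius_sweep for IFNG: optimal radius 4 (r = 0.996, p = 2.05e-42)
#>  radius         r      p_value n_clusters significant pearson_r   ok
#>       0 0.4750465 8.810320e-07         97        TRUE 0.5733745 TRUE
#>       1 0.7652999 2.327520e-17         84        TRUE 0.8199357 TRUE
#>       2 0.9531440 2.785683e-31         59        TRUE 0.9654830 TRUE
#>       3 0.9854872 7.425582e-38         49        TRUE 0.9901550 TRUE
#>       4 0.9964318 2.051342e-42         40        TRUE 0.9980882 TRUE
#>       5 0.9956896 7.387677e-41         40        TRUE 0.9978664 TRUE
#>       ...
```

The sweep recovers the planted radius of action (4): the correlation
climbs while the rings still capture induced responder mass, peaks at
the true radius, and flattens beyond it.  `n_clusters` falls with *r* as
overlapping clusters merge.  For comparison, the spatially blind
per-section pseudo-bulk correlation for the same data:

```r
pseudo_bulk_correlation(qc$dataset, labels, "IFNG",
                        sim$truth$responder_genes$IFNG)
#> weighted_spearman: r = 0.9941, p = 3.26e-38 (n = 40)

# zero-intercept least squares: responder transcripts per cytokine UMI
cl <- sw$clusters
fit_origin_line(vapply(cl, `[[`, 0, "cytokine_count"),
                vapply(cl, `[[`, 0, "responder_count"))
#> [1] 2287.659
```

Each cytokine UMI accounts for ~2300 responder transcripts in its
cluster — the amplification-cascade readout.  (In this saturated
single-niche-per-section world pseudo-bulk is nearly as correlated as
clustering; the spatial gain appears with larger multi-niche sections,
see the methods vignette.)

The end-to-end pipeline — simulate/load, QC, normalize, label, derive
signatures from a stimulation table, sweep radii, correlate, and run the
non-cluster DEG contrast, writing all artifacts plus a run manifest:

```r
res <- run_pipeline(list(out_dir = "out", seed = 7))
```

or from the shell (exit codes: 0 ok, 2 config, 3 data, 4 stage):

```sh
Rscript inst/cli/spotniche.R run-all --out out --seed 7
Rscript inst/cli/spotniche.R simulate --out simdir --seed 7
```

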