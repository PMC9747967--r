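# Synthetic Visium-like data with planted ground truth.
#
# The generator states a simple world: a hex grid of spots split into
# horizontal skin-layer bands; rare cytokine transcript-positive spots in
# the epidermis carrying 1-15 UMIs and a co-located leukocyte marker;
# responder genes whose negative-binomial mean is amplified within a
# planted hex radius of matching cytokine spots; overdispersed background
# genes, mitochondrial genes and a high-expression housekeeping gene
# (GAPDH).  Every distributional choice is a stand-in — the real study
# gives no generative model — and is documented in the methods vignette.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_dataset()].  Defaults
#' state a world of 40 small biopsy sections of 17 x 9 spots (about 3200
#' epidermal spots pooled, mirroring the many-small-sections design of
#' clinical Visium cohorts), sparse cytokine spots with 1-15 UMIs each,
#' and a per-transcript 3-fold responder amplification inside the planted
#' radius of action: 4, 3 and 0 hex rings for IFNG, IL13 and IL17A.
#'
#' @param n_samples Number of tissue sections.
#' @param n_rows,n_cols Grid extent: `n_rows` array rows with `n_cols`
#'   spots each (array columns step by 2 for hex parity).
#' @param layers Named integer vector of row-band widths for the 11
#'   tissue layers, top to bottom; must sum to `n_rows`.
#' @param n_genes Total gene count (background genes fill beyond the
#'   responder/marker/MT/housekeeping genes).
#' @param n_responder_genes Responder genes per cytokine.
#' @param cytokine_names Cytokine gene symbols.
#' @param cytokine_spot_rate Probability that an epidermal spot is
#'   cytokine-positive, per cytokine.
#' @param cytokine_umi_range Integer interval for UMIs at a positive spot.
#' @param true_radius Named integer vector: planted radius of action per
#'   cytokine.
#' @param amplification Per-transcript amplification: each cytokine UMI
#'   within the radius multiplies the local responder-gene rate, so a spot
#'   with local cytokine dose `u` has mean fold `1 + (amplification - 1) * u`
#'   over the constitutive responder baseline (`amplification = 1`
#'   disables the effect everywhere).  This dose response mirrors the
#'   observation that a handful of cytokine transcripts induce orders of
#'   magnitude more responder transcripts.
#' @param nb_dispersion NB dispersion `theta` (variance `mu + mu^2/theta`).
#' @param baseline_mean Baseline NB mean per background gene per spot.
#' @param responder_baseline_mean Constitutive NB mean of responder genes
#'   outside any cytokine's radius of action.  Default is near zero:
#'   strongly induced responder genes (e.g. the IFN-gamma chemokine axis)
#'   are essentially silent in unstimulated epidermis, and the
#'   `amplification` fold is defined relative to this level.
#' @param patch_rate,patch_amp,patch_sigma Spatially correlated baseline
#'   heterogeneity: per gene and section, `Poisson(patch_rate)` Gaussian
#'   patches of amplitude `patch_amp` (multiplicative, on top of 1) and
#'   spatial scale `patch_sigma` (array-index units) modulate the baseline
#'   mean of responder and background genes.  This emulates the patchy
#'   constitutive expression of real tissue (keratinocyte states, spatial
#'   autocorrelation); `patch_rate = 0` disables it.
#' @param marker_genes Leukocyte marker gene symbols.
#' @param marker_background_rate Poisson mean of marker counts at
#'   non-cytokine spots.
#' @param mt_gene_count,mt_mean Number and NB mean of mitochondrial genes.
#' @param hk_mean NB mean of the housekeeping gene (GAPDH).
#' @param n_decoy_genes,n_cross_genes Extra genes in the simulated
#'   stimulation table: decoys failing the filters, and cross-reactive
#'   genes passing for several cytokines (removed by purification).
#' @param seed Master RNG seed; per-sample streams use fixed offsets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 40L,
                       n_rows = 17L, n_cols = 9L,
                       layers = c("upper epidermis" = 3L,
                                  "middle epidermis" = 3L,
                                  "basal epidermis" = 3L,
                                  "junction" = 1L,
                                  "dermis 1" = 1L, "dermis 2" = 1L,
                                  "dermis 3" = 1L, "dermis 4" = 1L,
                                  "dermis 5" = 1L, "dermis 6" = 1L,
                                  "dermis 7" = 1L),
                       n_genes = 200L,
                       n_responder_genes = 30L,
                       cytokine_names = default_cytokines(),
                       cytokine_spot_rate = 0.03,
                       cytokine_umi_range = c(1L, 15L),
                       true_radius = c(IFNG = 4L, IL13 = 3L, IL17A = 0L),
                       amplification = 3,
                       nb_dispersion = 10,
                       baseline_mean = 0.5,
                       responder_baseline_mean = 0.6,
                       patch_rate = 2, patch_amp = 20, patch_sigma = 1.2,
                       marker_genes = default_leukocyte_markers(),
                       marker_background_rate = 0.05,
                       mt_gene_count = 10L, mt_mean = 2,
                       hk_mean = 50,
                       n_decoy_genes = 20L, n_cross_genes = 3L,
                       seed = 1L) {
  cfg <- as.list(environment())
  .assert(sum(layers) == n_rows,
          "layer band widths must sum to n_rows (%d != %d); grid too small",
          sum(layers), n_rows)
  .assert(all(names(layers) %in% setdiff(skin_layers(), "excluded")),
          "unknown layer in band specification")
  .assert(cytokine_spot_rate >= 0 && cytokine_spot_rate <= 1,
          "cytokine_spot_rate must lie in [0, 1]")
  .assert(all(true_radius >= 0) &&
            setequal(names(true_radius), cytokine_names),
          "true_radius must be a named nonnegative vector over the cytokines")
  .assert(amplification >= 1, "amplification must be >= 1")
  .assert(all(c(baseline_mean, mt_mean, hk_mean, nb_dispersion) > 0),
          "means and dispersion must be positive")
  .assert(length(cytokine_umi_range) == 2 &&
            cytokine_umi_range[1] >= 1 &&
            cytokine_umi_range[1] <= cytokine_umi_range[2],
          "cytokine_umi_range must be an integer interval with lower >= 1")
  structure(cfg, class = "sim_config")
}

# layer label per 0-based array row
.row_layers <- function(cfg) {
  rep(names(cfg$layers), times = cfg$layers)
}

.sim_gene_names <- function(cfg) {
  resp <- lapply(cfg$cytokine_names, function(cy)
    sprintf("RSP%s%02d", gsub("[^A-Z0-9]", "", cy), seq_len(cfg$n_responder_genes)))
  names(resp) <- cfg$cytokine_names
  cross <- if (cfg$n_cross_genes > 0) sprintf("XRS%02d", seq_len(cfg$n_cross_genes)) else character(0)
  mt <- sprintf("MT-G%02d", seq_len(cfg$mt_gene_count))
  fixed <- c(unlist(resp), cross, cfg$cytokine_names, cfg$marker_genes, mt, "GAPDH")
  n_bg <- cfg$n_genes - length(fixed)
  .assert(n_bg >= cfg$n_decoy_genes,
          "n_genes too small for the configured special genes (need >= %d)",
          length(fixed) + cfg$n_decoy_genes)
  bg <- sprintf("BG%04d", seq_len(n_bg))
  list(responders = resp, cross = cross, mt = mt, background = bg,
       all = unname(c(unlist(resp), cross, cfg$cytokine_names,
                      cfg$marker_genes, mt, "GAPDH", bg)))
}

#' Simulate a Visium-like dataset with planted ground truth
#'
#' Generates `cfg$n_samples` hex-grid sections with layer-band
#' annotations, plants cytokine-positive epidermal spots (each with a
#' co-located leukocyte marker transcript), and draws responder-gene
#' counts from a negative binomial whose mean is amplified for spots
#' within the planted hex radius of a matching cytokine spot, scaled by
#' the local cytokine UMI dose.  Background, mitochondrial and
#' housekeeping genes are populated everywhere.  Fully reproducible under
#' a fixed seed; each sample consumes an independent RNG stream derived
#' from the master seed by a fixed offset.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `dataset` (a [spot_dataset()]), `truth`
#'   (ground truth: cytokine spot tables, radii, responder/cross gene
#'   lists, planted stimulation log2FCs) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  gn <- .sim_gene_names(cfg)
  row_layer <- .row_layers(cfg)
  umis <- seq.int(cfg$cytokine_umi_range[1], cfg$cytokine_umi_range[2])
  theta <- cfg$nb_dispersion
  per_sample <- vector("list", cfg$n_samples)
  truth_spots <- setNames(vector("list", length(cfg$cytokine_names)),
                          cfg$cytokine_names)
  for (s in seq_len(cfg$n_samples)) {
    sid <- sprintf("S%02d", s)
    set.seed(cfg$seed + 7919L * s)  # fixed per-sample stream offset
    rows <- rep(seq_len(cfg$n_rows) - 1L, each = cfg$n_cols)
    cols0 <- rep(2L * (seq_len(cfg$n_cols) - 1L), times = cfg$n_rows)
    cols <- cols0 + rows %% 2L  # row+col even everywhere
    n <- length(rows)
    barcode <- sprintf("BC%05d-%d", seq_len(n), s)
    layer <- row_layer[rows + 1L]
    key <- .spot_key(sid, barcode)
    epi <- layer %in% epidermis_layers()
    coord_key <- paste(rows, cols)
    m <- matrix(0, nrow = n, ncol = length(gn$all),
                dimnames = list(key, gn$all))
    # patchy multiplicative baseline field (>= 1) per gene: spatially
    # correlated constitutive expression, emulating real ST autocorrelation
    patch_field <- function() {
      fld <- rep(1, n)
      k <- rpois(1, cfg$patch_rate)
      if (k > 0 && cfg$patch_amp > 0) {
        ctr <- sample.int(n, k, replace = TRUE)
        for (p in ctr) {
          d2 <- (rows - rows[p])^2 + (cols - cols[p])^2
          fld <- fld + cfg$patch_amp * exp(-d2 / (2 * cfg$patch_sigma^2))
        }
      }
      fld
    }
    # background + cross genes: NB over the patchy baseline
    for (g in c(gn$background, gn$cross)) {
      m[, g] <- rnbinom(n, mu = cfg$baseline_mean * patch_field(),
                        size = theta)
    }
    # mitochondrial and housekeeping genes
    for (g in gn$mt) m[, g] <- rnbinom(n, mu = cfg$mt_mean, size = theta)
    m[, "GAPDH"] <- rnbinom(n, mu = cfg$hk_mean, size = max(theta, 10))
    # marker background
    for (g in cfg$marker_genes) {
      m[, g] <- rpois(n, cfg$marker_background_rate)
    }
    any_pos <- rep(FALSE, n)
    for (cy in cfg$cytokine_names) {
      pos <- epi & (runif(n) < cfg$cytokine_spot_rate)
      umi <- integer(n)
      umi[pos] <- sample(umis, sum(pos), replace = TRUE)
      m[, cy] <- umi
      any_pos <- any_pos | pos
      # dose field: each cytokine transcript carries a fixed total induced
      # response, distributed over the epidermal spots that exist within
      # the planted radius of its seed (keratinocytes are the responding
      # cells, and section borders concentrate rather than destroy the
      # response), so the per-ball dose integrates to umi * C_rho exactly
      dose <- numeric(n)
      r_true <- cfg$true_radius[[cy]]
      c_rho <- 3 * r_true^2 + 3 * r_true + 1
      for (i in which(pos)) {
        hood <- hex_neighborhood(c(rows[i], cols[i]), r_true)
        hit <- match(paste(hood[, 1], hood[, 2]), coord_key)
        hit <- hit[!is.na(hit)]
        hit <- hit[epi[hit]]
        if (length(hit) == 0) hit <- i
        dose[hit] <- dose[hit] + umi[i] * c_rho / length(hit)
      }
      fold <- 1 + (cfg$amplification - 1) * dose
      # one shared constitutive field per cytokine module: responder genes
      # of a cytokine are co-expressed, so their patchiness is correlated;
      # the induced (dose) component is additive and field-free
      field_cy <- patch_field()
      for (g in gn$responders[[cy]]) {
        m[, g] <- rnbinom(n, mu = cfg$responder_baseline_mean *
                            (field_cy + fold - 1),
                          size = theta)
      }
      if (any(pos)) {
        truth_spots[[cy]] <- rbind(truth_spots[[cy]],
          data.frame(sample_id = sid, barcode = barcode[pos], key = key[pos],
                     array_row = rows[pos], array_col = cols[pos],
                     umi = umi[pos], stringsAsFactors = FALSE))
      }
    }
    # plant >= 1 leukocyte marker transcript at every cytokine+ spot
    if (any(any_pos)) {
      pick <- sample(cfg$marker_genes, sum(any_pos), replace = TRUE)
      idx <- which(any_pos)
      for (k in seq_along(idx)) {
        m[idx[k], pick[k]] <- m[idx[k], pick[k]] + 1L + rpois(1, 0.5)
      }
    }
    per_sample[[s]] <- list(
      counts = m,
      spots = data.frame(barcode = barcode, sample_id = sid, in_tissue = 1L,
                         array_row = rows, array_col = cols, layer = layer,
                         stringsAsFactors = FALSE))
  }
  counts <- methods::as(Matrix::Matrix(
    do.call(rbind, lapply(per_sample, `[[`, "counts")), sparse = TRUE),
    "CsparseMatrix")
  spots <- do.call(rbind, lapply(per_sample, `[[`, "spots"))
  sids <- sprintf("S%02d", seq_len(cfg$n_samples))
  meta <- data.frame(
    sample_id = sids,
    patient_id = sprintf("P%02d", 1L + (seq_len(cfg$n_samples) - 1L) %/% 2L),
    project_id = sprintf("slide%d", 1L + (seq_len(cfg$n_samples) - 1L) %% 2L),
    disease = rep(c("Pso", "AD", "LP"), length.out = cfg$n_samples),
    condition = "lesional", stringsAsFactors = FALSE)
  ds <- spot_dataset(counts, spots, meta)
  truth <- list(cytokine_spots = truth_spots,
                true_radius = as.list(cfg$true_radius),
                responder_genes = gn$responders,
                cross_genes = gn$cross,
                # what the spatial DEG side of the signature cascade should
                # call for each cytokine: its responders plus any
                # cross-reactive genes
                spatial_genes = lapply(gn$responders, function(g)
                  sort(c(g, gn$cross))),
                decoy_pool = gn$background[seq_len(cfg$n_decoy_genes)])
  list(dataset = ds, truth = truth, config = cfg)
}

#' Simulate an in-vitro stimulation DEG table
#'
#' Emulates the whole-genome expression arrays of cytokine-stimulated
#' keratinocytes: planted responder genes pass the per-cytokine filter
#' thresholds (with margin) only for their own cytokine; cross-reactive
#' genes pass for every cytokine (and are later removed by cross-signature
#' purification); decoy genes fail at least one filter each, cycling
#' through the three failure modes (low fold change, poor p-value, poor
#' adjusted p-value).
#'
#' @param truth Ground truth from [simulate_dataset()].
#' @param noise_sd Jitter applied to planted log2 fold changes.
#' @param fc_cut Named fold-change thresholds per cytokine (defaults to
#'   [default_fc_cuts()] for the cytokines present).
#' @param seed RNG seed for the table.
#' @return `data.frame` with columns `gene`, `cytokine`, `log2fc`,
#'   `p_value`, `adj_p_value` (one row per gene x cytokine), of class
#'   `stim_deg_table`.
#' @export
simulate_stim_table <- function(truth, noise_sd = 0.1, fc_cut = NULL,
                                seed = 1L) {
  cytokines <- names(truth$responder_genes)
  if (is.null(fc_cut)) fc_cut <- default_fc_cuts(cytokines)
  set.seed(seed + 104729L)
  genes <- sort(unique(c(unlist(truth$responder_genes), truth$cross_genes,
                         truth$decoy_pool)))
  rows <- list()
  jit <- function(n) rnorm(n, 0, noise_sd)
  for (cy in cytokines) {
    thr <- fc_cut[[cy]]
    lfc <- numeric(length(genes))
    p <- numeric(length(genes))
    padj <- numeric(length(genes))
    own <- genes %in% truth$responder_genes[[cy]]
    cross <- genes %in% truth$cross_genes
    decoy <- !(own | cross)
    np <- sum(own | cross)
    lfc[own | cross] <- pmax(thr + 0.3, thr + 1 + jit(np))
    p[own | cross] <- runif(np, 1e-8, 1e-4)
    padj[own | cross] <- pmin(0.01, p[own | cross] * 50)
    # decoys cycle through the three rejection modes
    di <- which(decoy)
    mode <- (seq_along(di) - 1L) %% 3L
    lowfc <- di[mode == 0L]
    lfc[lowfc] <- pmin(thr - 0.2, thr - 0.8 + jit(length(lowfc)))
    p[lowfc] <- runif(length(lowfc), 1e-6, 1e-3)
    padj[lowfc] <- pmin(0.04, p[lowfc] * 50)
    badp <- di[mode == 1L]
    lfc[badp] <- thr + 1 + abs(jit(length(badp)))
    p[badp] <- runif(length(badp), 0.06, 0.9)
    padj[badp] <- pmin(1, p[badp] * 2)
    badq <- di[mode == 2L]
    lfc[badq] <- thr + 1 + abs(jit(length(badq)))
    p[badq] <- runif(length(badq), 0.001, 0.04)
    padj[badq] <- runif(length(badq), 0.06, 0.5)
    rows[[cy]] <- data.frame(gene = genes, cytokine = cy, log2fc = lfc,
                             p_value = p, adj_p_value = padj,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stim_deg_table", "data.frame")
  out
}

#' Write a simulated dataset in the on-disk layout the loaders read
#'
#' Emits the exact file set [load_dataset()] consumes, plus
#' `ground_truth.json`, `stim_deg.csv` and the configuration as YAML.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory.
#' @param stim Optional stimulation table from [simulate_stim_table()].
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir, stim = NULL) {
  save_dataset(sim$dataset, dir)
  truth <- sim$truth
  truth$cytokine_spots <- lapply(truth$cytokine_spots, function(df) {
    if (is.null(df)) list() else df
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "list")
  cfg <- unclass(sim$config)
  cfg$layers <- as.list(cfg$layers)
  cfg$true_radius <- as.list(cfg$true_radius)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  if (!is.null(stim)) {
    write.csv(stim, file.path(dir, "stim_deg.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(dir)
}
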