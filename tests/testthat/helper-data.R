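# Programmatic fixtures.

# Minimal single-sample dataset from a plain count matrix; spots laid out
# on a valid parity grid, all annotated as basal epidermis.
make_flat_dataset <- function(m, layer = "basal epidermis") {
  n <- nrow(m)
  rows <- (seq_len(n) - 1L) %/% 50L
  cols <- ((seq_len(n) - 1L) %% 50L) * 2L + rows %% 2L
  spots <- data.frame(barcode = sprintf("BC%04d", seq_len(n)),
                      sample_id = "S01", in_tissue = 1L,
                      array_row = rows, array_col = cols, layer = layer,
                      stringsAsFactors = FALSE)
  rownames(m) <- paste0("S01:", spots$barcode)
  meta <- data.frame(sample_id = "S01", patient_id = "P1",
                     project_id = "pr1", disease = "Pso",
                     condition = "lesional", stringsAsFactors = FALSE)
  spot_dataset(m, spots, meta)
}

# Hand-sized two-sample dataset with explicit coordinates and layers.
make_two_sample_dataset <- function(counts_list, coords_list, layers_list) {
  mats <- list(); spots <- NULL
  for (i in seq_along(counts_list)) {
    sid <- sprintf("S%02d", i)
    m <- counts_list[[i]]
    rownames(m) <- paste0(sid, ":", sprintf("BC%03d", seq_len(nrow(m))))
    mats[[i]] <- m
    spots <- rbind(spots, data.frame(
      barcode = sprintf("BC%03d", seq_len(nrow(m))), sample_id = sid,
      in_tissue = 1L, array_row = coords_list[[i]][, 1],
      array_col = coords_list[[i]][, 2], layer = layers_list[[i]],
      stringsAsFactors = FALSE))
  }
  meta <- data.frame(sample_id = sprintf("S%02d", seq_along(counts_list)),
                     patient_id = sprintf("P%02d", seq_along(counts_list)),
                     project_id = "pr1",
                     disease = rep(c("Pso", "AD", "LP"),
                                   length.out = length(counts_list)),
                     condition = "lesional", stringsAsFactors = FALSE)
  spot_dataset(do.call(rbind, mats), spots, meta)
}

# Small, fast simulation configuration for pipeline-level tests.
tiny_sim_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_samples = 8L, n_genes = 60L, n_responder_genes = 5L,
         cytokine_spot_rate = 0.05, n_decoy_genes = 12L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# QC fixture with planted violations per rule, disjoint by construction:
# normal spots detect 60 genes (~150 UMIs, ~10% MT); planted spots break
# exactly one rule each.
build_qc_fixture <- function() {
  genes <- c(sprintf("G%03d", 1:56), sprintf("MT-%d", 1:4))
  n_normal <- 40
  rows <- list()
  normal_row <- function() {
    v <- setNames(rep(0, 60), genes)
    v[sprintf("G%03d", 1:52)] <- 2.0
    v[sprintf("MT-%d", 1:4)] <- 3      # MT fraction 12/116 ~ 10%
    v[sprintf("G%03d", 53:56)] <- 1    # padding detected genes
    v
  }
  for (i in seq_len(n_normal)) rows[[length(rows) + 1]] <- normal_row()
  # 3 spots with 29 detected genes (UMI 87, in range)
  for (i in 1:3) {
    v <- setNames(rep(0, 60), genes)
    v[sprintf("G%03d", 1:29)] <- 3
    rows[[length(rows) + 1]] <- v
  }
  # 2 spots with UMI 49 (35 detected genes)
  for (i in 1:2) {
    v <- setNames(rep(0, 60), genes)
    v[sprintf("G%03d", 1:35)] <- c(rep(2, 14), rep(1, 21))
    rows[[length(rows) + 1]] <- v
  }
  # 1 spot above the UMI ceiling (custom ceiling 1000 in the test)
  v <- normal_row(); v["G001"] <- 1200
  rows[[length(rows) + 1]] <- v
  # 2 spots with MT fraction 0.26 (share 26/100)
  for (i in 1:2) {
    v <- setNames(rep(0, 60), genes)
    v[sprintf("G%03d", 1:37)] <- 2
    v[sprintf("MT-%d", 1:4)] <- c(7, 7, 6, 6)  # 26 MT of 100 total
    rows[[length(rows) + 1]] <- v
  }
  m <- do.call(rbind, rows)
  colnames(m) <- genes
  # 4 rare genes present in only 5 spots each
  rare <- matrix(0, nrow(m), 4, dimnames = list(NULL, sprintf("RARE%d", 1:4)))
  rare[1:5, ] <- 1
  make_flat_dataset(cbind(m, rare))
}
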