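# Visium-dialect input/output and the central dataset container.
#
# A spot_dataset bundles the raw UMI matrix (spots x genes, sparse), the
# spot table (array coordinates + layer annotation) and per-sample
# metadata.  All geometry downstream operates in 0-based array-index
# space (array_row, array_col), where physical hex neighbors differ by
# (|drow|, |dcol|) = (0, 2) or (1, 1) and row+col is always even.

#' Construct a spot dataset
#'
#' Assembles and validates the central container holding a sparse
#' spots-by-genes raw UMI count matrix, the spot table with array
#' coordinates and layer annotation, and per-sample metadata.
#'
#' @param counts Sparse (or dense) nonnegative integer matrix, spots in
#'   rows, genes in columns. Row names must be spot keys
#'   (`"<sample_id>:<barcode>"`), column names gene symbols.
#' @param spots `data.frame` with columns `barcode`, `sample_id`,
#'   `in_tissue` (0/1), `array_row`, `array_col`, `layer`.
#' @param meta `data.frame` with columns `sample_id`, `patient_id`,
#'   `project_id`, `disease` (one of `"LP"`, `"AD"`, `"Pso"`, `"none"`),
#'   `condition` (`"lesional"` or `"non-lesional"`).
#' @return An object of class `spot_dataset`.
#' @export
spot_dataset <- function(counts, spots, meta) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "counts must carry spot keys as rownames and gene symbols as colnames")
  .assert(all(counts@x >= 0) && all(counts@x == round(counts@x)),
          "counts must be nonnegative integers")
  need <- c("barcode", "sample_id", "in_tissue", "array_row", "array_col", "layer")
  .assert(all(need %in% names(spots)), "spots table missing columns: %s",
          paste(setdiff(need, names(spots)), collapse = ", "))
  spots$key <- .spot_key(spots$sample_id, spots$barcode)
  .assert(!anyDuplicated(spots$key),
          "duplicate (sample_id, barcode) pairs in spot table")
  pos_key <- paste(spots$sample_id, spots$array_row, spots$array_col)
  .assert(!anyDuplicated(pos_key),
          "duplicate (sample_id, array_row, array_col) positions")
  parity_bad <- (spots$array_row + spots$array_col) %% 2L != 0L
  if (any(parity_bad)) {
    stop("Visium parity violated (array_row + array_col must be even) for: ",
         paste(utils::head(spots$key[parity_bad], 10), collapse = ", "),
         call. = FALSE)
  }
  .assert(setequal(rownames(counts), spots$key) &&
            nrow(counts) == nrow(spots),
          "counts rownames do not match spot keys")
  spots <- spots[match(rownames(counts), spots$key), , drop = FALSE]
  rownames(spots) <- NULL
  unknown <- setdiff(unique(spots$layer[spots$in_tissue == 1]), skin_layers())
  .assert(length(unknown) == 0, "unknown layer label(s): %s",
          paste(unknown, collapse = ", "))
  .assert(!any(spots$in_tissue == 1 & (is.na(spots$layer) | spots$layer == "")),
          "annotation missing for in-tissue spots")
  needm <- c("sample_id", "patient_id", "project_id", "disease", "condition")
  .assert(all(needm %in% names(meta)), "metadata missing columns: %s",
          paste(setdiff(needm, names(meta)), collapse = ", "))
  .assert(!anyDuplicated(meta$sample_id), "duplicate sample_id in metadata")
  .assert(setequal(unique(spots$sample_id), meta$sample_id),
          "metadata samples do not match spot table samples")
  .assert(all(meta$disease %in% c("LP", "AD", "Pso", "none")),
          "disease must be one of LP, AD, Pso, none")
  .assert(all(meta$condition %in% c("lesional", "non-lesional")),
          "condition must be 'lesional' or 'non-lesional'")
  structure(list(counts = counts, spots = spots,
                 meta = meta[order(meta$sample_id), , drop = FALSE]),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots x %d genes, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts), nrow(x$meta)))
  tab <- table(x$spots$sample_id)
  cat("  spots/sample:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$counts)

#' Subset a spot dataset by spot keys and/or genes
#'
#' @param ds A `spot_dataset`.
#' @param spots Character vector of spot keys to keep (default all).
#' @param genes Character vector of gene symbols to keep (default all).
#' @return A `spot_dataset` restricted to the requested spots/genes; samples
#'   with no remaining spots are dropped from the metadata.
#' @export
subset_dataset <- function(ds, spots = NULL, genes = NULL) {
  stopifnot(inherits(ds, "spot_dataset"))
  keys <- if (is.null(spots)) rownames(ds$counts) else spots
  gg <- if (is.null(genes)) colnames(ds$counts) else genes
  .assert(all(keys %in% rownames(ds$counts)), "unknown spot keys in subset")
  .assert(all(gg %in% colnames(ds$counts)), "unknown genes in subset")
  counts <- ds$counts[keys, gg, drop = FALSE]
  sp <- ds$spots[match(keys, ds$spots$key), , drop = FALSE]
  rownames(sp) <- NULL
  meta <- ds$meta[ds$meta$sample_id %in% unique(sp$sample_id), , drop = FALSE]
  structure(list(counts = counts, spots = sp, meta = meta),
            class = "spot_dataset")
}

# --- positions file -------------------------------------------------------

# Space Ranger v1 headerless dialect:
#   barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres
# A headered variant is auto-detected by sniffing the first row.
.read_positions <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- length(fields) >= 4 &&
    is.na(suppressWarnings(as.numeric(fields[2])))
  cn <- c("barcode", "in_tissue", "array_row", "array_col",
          "pxl_row_in_fullres", "pxl_col_in_fullres")
  pos <- utils::read.csv(path, header = has_header,
                         stringsAsFactors = FALSE)
  .assert(ncol(pos) >= 4, "positions file %s has fewer than 4 columns", path)
  names(pos)[seq_len(min(6, ncol(pos)))] <- cn[seq_len(min(6, ncol(pos)))]
  pos
}

.write_positions <- function(pos, path) {
  # always the headerless v1 dialect, deterministically ordered by barcode
  pos <- pos[order(pos$barcode), , drop = FALSE]
  lines <- sprintf("%s,%d,%d,%d,%d,%d", pos$barcode, pos$in_tissue,
                   pos$array_row, pos$array_col,
                   pos$pxl_row_in_fullres, pos$pxl_col_in_fullres)
  writeLines(lines, path)
}

# --- MTX triplet I/O ------------------------------------------------------

# Matrix::writeMM formats integers in scientific notation on occasion;
# write the triplet file explicitly so output is byte-stable and integral.
.write_mtx <- function(m, path) {
  # m: genes x barcodes sparse matrix (10x orientation)
  tm <- methods::as(m, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(tm@x))), con)
  if (length(tm@x)) {
    o <- order(tm@j, tm@i)
    writeLines(sprintf("%d %d %d", tm@i[o] + 1L, tm@j[o] + 1L,
                       as.integer(tm@x[o])), con)
  }
  invisible(path)
}

# --- load / save ----------------------------------------------------------

#' Load a Visium-dialect dataset from disk
#'
#' Expects the layout written by [save_dataset()] (and emitted by
#' [write_simulated_dataset()]): a `metadata.csv` and `annotation.csv` at the
#' top level plus one directory per sample containing `matrix.mtx`
#' (genes x barcodes), `barcodes.tsv`, `features.tsv` and
#' `tissue_positions_list.csv`.  Genes are harmonized across samples by
#' symbol (outer union, zero fill); duplicated symbols within a sample are
#' made unique by suffixing.
#'
#' @param dir Directory containing the file set.
#' @return A validated [spot_dataset()].
#' @export
load_dataset <- function(dir) {
  .assert(dir.exists(dir), "directory not found: %s", dir)
  need_file <- function(p) {
    .assert(file.exists(p), "missing file: %s", p)
    p
  }
  meta <- utils::read.csv(need_file(file.path(dir, "metadata.csv")),
                          stringsAsFactors = FALSE)
  ann <- utils::read.csv(need_file(file.path(dir, "annotation.csv")),
                         stringsAsFactors = FALSE)
  .assert(all(c("barcode", "sample_id", "layer") %in% names(ann)),
          "annotation.csv must have columns barcode, sample_id, layer")
  samples <- sort(meta$sample_id)
  per <- lapply(samples, function(sid) {
    sdir <- file.path(dir, sid)
    m <- Matrix::readMM(need_file(file.path(sdir, "matrix.mtx")))
    barcodes <- readLines(need_file(file.path(sdir, "barcodes.tsv")))
    feat <- utils::read.delim(need_file(file.path(sdir, "features.tsv")),
                              header = FALSE, stringsAsFactors = FALSE)
    genes <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
    genes <- make.unique(as.character(genes))
    .assert(nrow(m) == length(genes) && ncol(m) == length(barcodes),
            "matrix dimensions do not match features/barcodes in %s", sdir)
    pos <- .read_positions(need_file(file.path(sdir,
                                               "tissue_positions_list.csv")))
    pos <- pos[match(barcodes, pos$barcode), , drop = FALSE]
    .assert(!anyNA(pos$barcode), "barcodes missing from positions file in %s",
            sdir)
    counts <- Matrix::t(m)  # spots x genes
    dimnames(counts) <- list(.spot_key(sid, barcodes), genes)
    spots <- data.frame(barcode = barcodes, sample_id = sid,
                        in_tissue = as.integer(pos$in_tissue),
                        array_row = as.integer(pos$array_row),
                        array_col = as.integer(pos$array_col),
                        stringsAsFactors = FALSE)
    list(counts = counts, spots = spots)
  })
  all_genes <- sort(unique(unlist(lapply(per, function(p) colnames(p$counts)))))
  mats <- lapply(per, function(p) {
    m <- p$counts
    missing <- setdiff(all_genes, colnames(m))
    if (length(missing)) {
      pad <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(nrow(m), length(missing)),
                                  dimnames = list(rownames(m), missing))
      m <- cbind(m, pad)
    }
    m[, all_genes, drop = FALSE]
  })
  counts <- do.call(rbind, mats)
  spots <- do.call(rbind, lapply(per, `[[`, "spots"))
  akey <- .spot_key(ann$sample_id, ann$barcode)
  spots$layer <- ann$layer[match(.spot_key(spots$sample_id, spots$barcode),
                                 akey)]
  spot_dataset(counts, spots, meta)
}

#' Save a dataset in the Visium-dialect layout
#'
#' The inverse of [load_dataset()]; output is deterministic (spots and genes
#' sorted lexicographically), so two invocations on the same dataset are
#' byte-identical and `load_dataset(save_dataset(ds))` reproduces `ds`
#' cell-for-cell.
#'
#' @param ds A `spot_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "spot_dataset"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .assert(dir.exists(dir), "cannot create directory: %s", dir)
  genes <- sort(colnames(ds$counts))
  write.csv(ds$meta[order(ds$meta$sample_id), , drop = FALSE],
            file.path(dir, "metadata.csv"), row.names = FALSE, quote = FALSE)
  ann <- ds$spots[, c("barcode", "sample_id", "layer")]
  ann <- ann[order(ann$sample_id, ann$barcode), , drop = FALSE]
  write.csv(ann, file.path(dir, "annotation.csv"), row.names = FALSE,
            quote = FALSE)
  for (sid in sort(unique(ds$spots$sample_id))) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    sp <- ds$spots[ds$spots$sample_id == sid, , drop = FALSE]
    sp <- sp[order(sp$barcode), , drop = FALSE]
    m <- Matrix::t(ds$counts[sp$key, genes, drop = FALSE])  # genes x barcodes
    .write_mtx(m, file.path(sdir, "matrix.mtx"))
    writeLines(sp$barcode, file.path(sdir, "barcodes.tsv"))
    writeLines(paste(genes, genes, "Gene Expression", sep = "\t"),
               file.path(sdir, "features.tsv"))
    pos <- data.frame(barcode = sp$barcode, in_tissue = sp$in_tissue,
                      array_row = sp$array_row, array_col = sp$array_col,
                      pxl_row_in_fullres = sp$array_row * 100L,
                      pxl_col_in_fullres = sp$array_col * 100L)
    .write_positions(pos, file.path(sdir, "tissue_positions_list.csv"))
  }
  invisible(dir)
}

#' Write the density-cluster summary table
#'
#' One row per cluster with the fixed column order `cluster_id, sample_id,
#' radius, n_seed_spots, n_ring_spots, cytokine_count, responder_count,
#' weight`.
#'
#' @param clusters List of `density_cluster` objects (with readouts attached,
#'   see [cluster_readout()]); an empty list yields a header-only CSV.
#' @param path Output CSV path.
#' @return The cluster table as a `data.frame`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- cluster_table(clusters)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Summarize density clusters as a data frame
#'
#' @param clusters List of `density_cluster` objects.
#' @return `data.frame` with one row per cluster (zero rows if empty).
#' @export
cluster_table <- function(clusters) {
  cols <- c("cluster_id", "sample_id", "radius", "n_seed_spots",
            "n_ring_spots", "cytokine_count", "responder_count", "weight")
  if (length(clusters) == 0) {
    df <- as.data.frame(setNames(
      list(character(0), character(0), integer(0), integer(0), integer(0),
           numeric(0), numeric(0), numeric(0)), cols))
    return(df)
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, sample_id = cl$sample_id,
               radius = cl$radius, n_seed_spots = length(cl$seed_spots),
               n_ring_spots = length(cl$ring_spots),
               cytokine_count = if (is.null(cl$cytokine_count)) NA_real_ else cl$cytokine_count,
               responder_count = if (is.null(cl$responder_count)) NA_real_ else cl$responder_count,
               weight = if (is.null(cl$weight)) NA_real_ else cl$weight,
               stringsAsFactors = FALSE)
  }))
}
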