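# Spot/gene quality control, size-factor normalization and per-spot
# covariates (cdr).

#' QC parameter set
#'
#' Defaults follow the operational thresholds used for inflamed-skin
#' Visium sections: at least 30 detected genes per spot, UMI count within
#' \[50, 500000\], mitochondrial fraction at most 25% (a deliberately
#' conservative cut, since acute inflammation raises the mitochondrial
#' fraction), and genes observed in at least 20 spots.
#'
#' @param min_genes_per_spot Minimum detected (count > 0) genes per spot.
#' @param min_spots_per_gene Minimum spots a gene must be observed in.
#' @param min_umi,max_umi Per-spot total UMI bounds (inclusive).
#' @param max_mt_fraction Maximum mitochondrial UMI fraction (inclusive).
#' @param mt_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes_per_spot = 30L, min_spots_per_gene = 20L,
                      min_umi = 50, max_umi = 500000,
                      max_mt_fraction = 0.25, mt_prefix = "MT-") {
  .assert(min_umi < max_umi, "min_umi must be below max_umi")
  .assert(max_mt_fraction >= 0 && max_mt_fraction <= 1,
          "max_mt_fraction must lie in [0, 1]")
  structure(list(min_genes_per_spot = min_genes_per_spot,
                 min_spots_per_gene = min_spots_per_gene,
                 min_umi = min_umi, max_umi = max_umi,
                 max_mt_fraction = max_mt_fraction, mt_prefix = mt_prefix),
            class = "qc_params")
}

#' Apply spot and gene quality control
#'
#' Spot rules run first: a spot is removed if it detects fewer than
#' `min_genes_per_spot` genes, its total UMI count falls outside
#' \[`min_umi`, `max_umi`\], or its mitochondrial fraction exceeds
#' `max_mt_fraction` (all boundaries keep the spot).  Genes observed in
#' fewer than `min_spots_per_gene` of the remaining spots are then
#' removed.  Per-rule removal counts overlap (a spot may violate several
#' rules); the report carries both per-rule and unique totals.
#'
#' @param ds A `spot_dataset` with raw counts.
#' @param params A [qc_params()].
#' @return List with `dataset` (filtered `spot_dataset`) and `report`
#'   (class `qc_report`).
#' @export
apply_qc <- function(ds, params = qc_params()) {
  stopifnot(inherits(ds, "spot_dataset"), inherits(params, "qc_params"))
  m <- ds$counts
  detected <- Matrix::rowSums(m > 0)
  libsize <- Matrix::rowSums(m)
  mt_genes <- startsWith(colnames(m), params$mt_prefix)
  mt_frac <- if (any(mt_genes)) {
    Matrix::rowSums(m[, mt_genes, drop = FALSE]) / pmax(libsize, 1)
  } else rep(0, nrow(m))
  viol <- cbind(low_genes = detected < params$min_genes_per_spot,
                low_umi = libsize < params$min_umi,
                high_umi = libsize > params$max_umi,
                high_mt = mt_frac > params$max_mt_fraction)
  bad_spot <- rowSums(viol) > 0
  if (all(bad_spot)) {
    stop("QC removed every spot; per-rule counts: ",
         paste(sprintf("%s=%d", colnames(viol), colSums(viol)),
               collapse = ", "), call. = FALSE)
  }
  kept <- m[!bad_spot, , drop = FALSE]
  gene_spots <- Matrix::colSums(kept > 0)
  bad_gene <- gene_spots < params$min_spots_per_gene
  out <- subset_dataset(ds, spots = rownames(kept),
                        genes = colnames(kept)[!bad_gene])
  report <- structure(list(
    n_spots_in = nrow(m), n_spots_out = nrow(out$counts),
    n_genes_in = ncol(m), n_genes_out = ncol(out$counts),
    spots_removed = sum(bad_spot), genes_removed = sum(bad_gene),
    per_rule = as.list(colSums(viol)),
    removed_spot_ids = rownames(m)[bad_spot],
    params = unclass(params)), class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: spots %d -> %d (removed %d), genes %d -> %d (removed %d)\n",
              x$n_spots_in, x$n_spots_out, x$spots_removed,
              x$n_genes_in, x$n_genes_out, x$genes_removed))
  cat("  per-rule spot violations:",
      paste(sprintf("%s=%d", names(x$per_rule), unlist(x$per_rule)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Size factors and cellular detection rate
#'
#' Size factors are library sizes divided by their geometric mean, so the
#' geometric mean of the returned factors is 1 (pooled-deconvolution
#' factors are not reimplemented; any externally computed positive factor
#' vector can be supplied downstream instead).  The cellular detection
#' rate (cdr) is the fraction of genes detected per spot.
#'
#' @param ds A QC-passing `spot_dataset`.
#' @return List of class `norm_factors` with numeric vectors `size_factor`
#'   and `cdr`, named by spot key.
#' @export
compute_norm_factors <- function(ds) {
  stopifnot(inherits(ds, "spot_dataset"))
  libsize <- Matrix::rowSums(ds$counts)
  .assert(all(libsize > 0), "zero-library spot encountered (run QC first)")
  sf <- libsize / exp(mean(log(libsize)))
  cdr <- Matrix::rowSums(ds$counts > 0) / ncol(ds$counts)
  structure(list(size_factor = setNames(as.numeric(sf), rownames(ds$counts)),
                 cdr = setNames(as.numeric(cdr), rownames(ds$counts))),
            class = "norm_factors")
}

#' Size-factor normalization with log10 transform
#'
#' Returns `log10(count / size_factor + 1)` as a sparse matrix.  Note the
#' base-10 logarithm (not the field-standard natural/2-base log1p); zero
#' counts map to exactly 0.  Raw counts stay untouched in the dataset —
#' the DEG model and the cluster readouts consume raw counts.
#'
#' @param ds A `spot_dataset`.
#' @param factors A [compute_norm_factors()] result.
#' @return Sparse numeric matrix, spots x genes.
#' @export
normalize_log <- function(ds, factors) {
  stopifnot(inherits(ds, "spot_dataset"), inherits(factors, "norm_factors"))
  sf <- factors$size_factor[rownames(ds$counts)]
  .assert(!anyNA(sf), "size factors missing for some spots")
  m <- methods::as(ds$counts, "TsparseMatrix")
  x <- log10(m@x / sf[m@i + 1L] + 1)
  Matrix::sparseMatrix(i = m@i + 1L, j = m@j + 1L, x = x, dims = dim(m),
                       dimnames = dimnames(m))
}
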