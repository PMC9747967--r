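# Leukocyte / cytokine spot labeling, layer enrichment, and the
# per-disease cytokine distribution.

#' Flag leukocyte-positive spots
#'
#' A spot is leukocyte-positive if it carries at least one UMI of any
#' marker gene (default CD2, CD3D, CD3E, CD3G, CD247, PTPRC); a single
#' transcript counts as a positive association.
#'
#' @param ds A `spot_dataset` with raw counts.
#' @param markers Marker gene symbols.
#' @return Named logical vector over spot keys.
#' @export
label_leukocytes <- function(ds, markers = default_leukocyte_markers()) {
  stopifnot(inherits(ds, "spot_dataset"))
  present <- intersect(markers, colnames(ds$counts))
  if (length(present) == 0) {
    stop("no leukocyte marker gene present in the matrix; missing: ",
         paste(markers, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(markers, present)
  if (length(missing)) {
    warning("marker gene(s) absent, ignored: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  tot <- Matrix::rowSums(ds$counts[, present, drop = FALSE])
  setNames(tot >= 1, rownames(ds$counts))
}

#' Per-cytokine UMI counts and positivity flags
#'
#' A spot is positive for a cytokine if it carries at least one UMI of
#' that cytokine's transcript.  Spots positive for several cytokines are
#' retained in each cytokine's set (double-positive spots are not thinned
#' out).
#'
#' @param ds A `spot_dataset` with raw counts.
#' @param cytokines Cytokine gene symbols.
#' @return `data.frame` keyed by `key` with `<cytokine>_umi` and
#'   `<cytokine>_pos` columns.
#' @export
label_cytokines <- function(ds, cytokines = default_cytokines()) {
  stopifnot(inherits(ds, "spot_dataset"))
  absent <- setdiff(cytokines, colnames(ds$counts))
  .assert(length(absent) == 0, "cytokine gene(s) absent from matrix: %s",
          paste(absent, collapse = ", "))
  out <- data.frame(key = rownames(ds$counts), stringsAsFactors = FALSE)
  for (cy in cytokines) {
    umi <- as.integer(ds$counts[, cy])
    out[[paste0(cy, "_umi")]] <- umi
    out[[paste0(cy, "_pos")]] <- umi >= 1L
  }
  out
}

#' Combined spot label table
#'
#' Runs [label_leukocytes()] and [label_cytokines()] and attaches the
#' layer group of each spot; labels cover every spot of the (QC-passing)
#' dataset.
#'
#' @param ds A `spot_dataset`.
#' @param markers Leukocyte marker genes.
#' @param cytokines Cytokine genes.
#' @return Object of class `spot_labels`: a list with `table`
#'   (`data.frame`) and the `cytokines` used.
#' @export
label_spots <- function(ds, markers = default_leukocyte_markers(),
                        cytokines = default_cytokines()) {
  tab <- label_cytokines(ds, cytokines)
  tab$leukocyte_pos <- unname(label_leukocytes(ds, markers))
  tab$layer_group <- ds$spots$layer[match(tab$key, ds$spots$key)]
  structure(list(table = tab, cytokines = cytokines), class = "spot_labels")
}

#' @export
print.spot_labels <- function(x, ...) {
  cat(sprintf("spot_labels: %d spots, %d leukocyte+\n", nrow(x$table),
              sum(x$table$leukocyte_pos)))
  for (cy in x$cytokines) {
    cat(sprintf("  %s: %d positive spots, %d UMIs\n", cy,
                sum(x$table[[paste0(cy, "_pos")]]),
                sum(x$table[[paste0(cy, "_umi")]])))
  }
  invisible(x)
}

#' Test spatial enrichment of a cytokine between layer groups
#'
#' For each sample the raw cytokine UMIs are summed over the spots of the
#' two layer groups; the paired per-sample sums are compared with a
#' two-sided Wilcoxon signed-rank test (samples are the pairing unit,
#' zero differences dropped per the classical procedure).  The exact
#' distribution is used for at most 25 informative pairs; above that a
#' normal approximation with continuity correction (ties always fall back
#' to the approximation, with the usual warning suppressed).
#'
#' @param ds A `spot_dataset` with raw counts (unnormalized, per design).
#' @param labels A [label_spots()] result.
#' @param cytokine Cytokine gene symbol.
#' @param group_A,group_B Disjoint sets of layer names from
#'   [skin_layers()].
#' @return List of class `enrichment_result`: `cytokine`, `group_A`,
#'   `group_B`, `statistic`, `p_value`, `pairs` (per-sample sums).
#' @export
layer_enrichment_test <- function(ds, labels, cytokine, group_A, group_B) {
  stopifnot(inherits(ds, "spot_dataset"), inherits(labels, "spot_labels"))
  .assert(length(intersect(group_A, group_B)) == 0,
          "layer groups must be disjoint")
  .assert(all(c(group_A, group_B) %in% skin_layers()),
          "unknown layer name in group definition")
  .assert(length(unique(ds$spots$sample_id)) >= 2,
          "at least two samples required for the paired test")
  umi <- labels$table[[paste0(cytokine, "_umi")]]
  .assert(!is.null(umi), "labels do not cover cytokine %s", cytokine)
  layer <- labels$table$layer_group
  sample <- ds$spots$sample_id[match(labels$table$key, ds$spots$key)]
  sums <- function(grp) {
    v <- tapply(umi * (layer %in% grp), sample, sum)
    v[sort(names(v))]
  }
  a <- sums(group_A)
  b <- sums(group_B)
  d <- a - b
  n_inf <- sum(d != 0)
  res <- if (n_inf == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    list(statistic = NA_real_, p.value = 1)
  } else {
    suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                 exact = n_inf <= 25, correct = TRUE))
  }
  structure(list(cytokine = cytokine, group_A = group_A, group_B = group_B,
                 statistic = unname(res$statistic),
                 p_value = min(1, res$p.value),
                 pairs = data.frame(sample_id = names(a), sum_A = as.numeric(a),
                                    sum_B = as.numeric(b),
                                    stringsAsFactors = FALSE)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment of %s: {%s} vs {%s}, V=%s, p=%.3g (n=%d samples)\n",
              x$cytokine, paste(x$group_A, collapse = ","),
              paste(x$group_B, collapse = ","),
              format(x$statistic), x$p_value, nrow(x$pairs)))
  invisible(x)
}

#' Per-disease cytokine distribution
#'
#' For each disease, total UMIs of the cytokines are rescaled to sum to
#' 100 (percentages).  A disease with no cytokine UMIs at all yields a
#' row of `NaN` with a warning.
#'
#' @param ds A `spot_dataset`.
#' @param labels A [label_spots()] result.
#' @return Numeric matrix, diseases x cytokines, rows summing to 100.
#' @export
cytokine_distribution <- function(ds, labels) {
  stopifnot(inherits(ds, "spot_dataset"), inherits(labels, "spot_labels"))
  cys <- labels$cytokines
  disease <- ds$meta$disease[match(ds$spots$sample_id, ds$meta$sample_id)]
  disease <- disease[match(labels$table$key, ds$spots$key)]
  out <- t(vapply(sort(unique(disease)), function(dz) {
    tot <- vapply(cys, function(cy)
      sum(labels$table[[paste0(cy, "_umi")]][disease == dz]), 0)
    s <- sum(tot)
    if (s == 0) {
      warning("no cytokine UMIs for disease ", dz, call. = FALSE)
      rep(NaN, length(cys))
    } else 100 * tot / s
  }, numeric(length(cys))))
  colnames(out) <- cys
  out
}
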