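# Weighted Spearman correlation, pseudo-bulk and cluster-level
# correlations, the radius sweep with optimum selection, and the
# origin-constrained line fit.

#' Weighted Spearman correlation
#'
#' Zero-weight observations are dropped (so `w = c(1,1,1,0)` equals
#' removing the fourth point), both vectors are replaced by mid-ranks
#' (ties averaged), and a weighted Pearson correlation of the rank
#' vectors is computed.  With uniform weights this is exactly the
#' classical Spearman coefficient.  The two-sided p-value uses a
#' t-statistic with `n - 2` degrees of freedom applied to the weighted
#' coefficient; since the weighted null is not exactly t, a seeded
#' permutation p-value is available via `p_method = "permutation"`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param w Nonnegative weights (default uniform); must not all be zero.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for `p_method = "permutation"`.
#' @param perm_seed Seed for the permutation null.
#' @return List of class `correlation_result`: `method`, `r`, `p_value`,
#'   `n_units`, `ok` (FALSE with a `message` for degenerate input —
#'   fewer than 3 positive-weight units or zero rank variance).
#' @export
weighted_spearman <- function(x, y, w = rep(1, length(x)),
                              p_method = c("t", "permutation"),
                              n_perm = 10000L, perm_seed = 1L) {
  p_method <- match.arg(p_method)
  .assert(length(x) == length(y) && length(x) == length(w),
          "x, y, w must have equal length")
  .assert(all(w >= 0) && sum(w) > 0, "weights must be >= 0 and not all zero")
  keep <- w > 0 & is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  n <- length(x)
  fail <- function(msg) {
    structure(list(method = "weighted_spearman", r = NA_real_,
                   p_value = NA_real_, n_units = n, ok = FALSE,
                   message = msg), class = "correlation_result")
  }
  if (n < 3) return(fail("fewer than 3 positive-weight observations"))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (var(rx) == 0 || var(ry) == 0) {
    return(fail("zero rank variance; correlation undefined"))
  }
  wcor <- function(a, b, w) {
    w <- w / sum(w)
    am <- sum(w * a); bm <- sum(w * b)
    sab <- sum(w * (a - am) * (b - bm))
    saa <- sum(w * (a - am)^2); sbb <- sum(w * (b - bm)^2)
    sab / sqrt(saa * sbb)
  }
  r <- wcor(rx, ry, w)
  r <- max(-1, min(1, r))
  p <- if (p_method == "t") {
    if (abs(r) >= 1) {
      .Machine$double.xmin
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    set.seed(perm_seed)
    null <- replicate(n_perm, abs(wcor(rx, sample(ry), w)))
    (1 + sum(null >= abs(r))) / (n_perm + 1)
  }
  structure(list(method = "weighted_spearman", r = r, p_value = min(1, p),
                 n_units = n, ok = TRUE, message = NULL),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("%s: r = %.4f, p = %.3g (n = %d)\n", x$method, x$r,
                x$p_value, x$n_units))
  } else {
    cat(sprintf("%s: undefined (%s)\n", x$method, x$message))
  }
  invisible(x)
}

#' Pseudo-bulk correlation per tissue section
#'
#' Ignores spatial structure: per section, cytokine and responder UMIs
#' are summed over the epidermal spots; the section totals enter a
#' weighted Spearman with weights equal to the per-section cytokine
#' totals (sections with zero cytokine UMIs thus drop out).
#'
#' @param ds A QC-passing `spot_dataset`.
#' @param labels A [label_spots()] result.
#' @param cytokine Cytokine name.
#' @param signature Responder signature (object or gene vector).
#' @param universe_layers Layer set (default [epidermis_layers()]).
#' @param ... Passed to [weighted_spearman()].
#' @return A `correlation_result` with the per-section sums attached as
#'   `sections`.
#' @export
pseudo_bulk_correlation <- function(ds, labels, cytokine, signature,
                                    universe_layers = epidermis_layers(),
                                    ...) {
  stopifnot(inherits(ds, "spot_dataset"))
  genes <- if (inherits(signature, "responder_signature")) signature$genes else signature
  genes <- intersect(genes, colnames(ds$counts))
  tab <- labels$table
  keys <- tab$key[tab$layer_group %in% universe_layers]
  sample <- ds$spots$sample_id[match(keys, ds$spots$key)]
  cyt <- as.numeric(ds$counts[keys, cytokine])
  rsp <- if (length(genes)) {
    Matrix::rowSums(ds$counts[keys, genes, drop = FALSE])
  } else rep(0, length(keys))
  cyt_tot <- tapply(cyt, sample, sum)
  rsp_tot <- tapply(rsp, sample, sum)
  .assert(sum(cyt_tot > 0) >= 3,
          "fewer than 3 sections with cytokine UMIs; pseudo-bulk undefined")
  res <- weighted_spearman(as.numeric(cyt_tot), as.numeric(rsp_tot),
                           w = as.numeric(cyt_tot), ...)
  res$sections <- data.frame(sample_id = names(cyt_tot),
                             cytokine_count = as.numeric(cyt_tot),
                             responder_count = as.numeric(rsp_tot))
  res
}

#' Correlation across density clusters
#'
#' Weighted Spearman of per-cluster cytokine counts against responder
#' counts, weighted by the cytokine counts.
#'
#' @param clusters List of readout-annotated `density_cluster` objects
#'   (pooled across samples at a fixed radius).
#' @param ... Passed to [weighted_spearman()].
#' @return A `correlation_result` (with `ok = FALSE` if fewer than 3
#'   clusters).
#' @export
clustered_correlation <- function(clusters, ...) {
  if (length(clusters) < 3) {
    return(structure(list(method = "weighted_spearman", r = NA_real_,
                          p_value = NA_real_, n_units = length(clusters),
                          ok = FALSE, message = "fewer than 3 clusters"),
                     class = "correlation_result"))
  }
  x <- vapply(clusters, `[[`, 0, "cytokine_count")
  y <- vapply(clusters, `[[`, 0, "responder_count")
  w <- vapply(clusters, `[[`, 0, "weight")
  weighted_spearman(x, y, w, ...)
}

#' Sweep the cluster radius and select the radius of action
#'
#' For every radius the density clusters are rebuilt (adjacency and seed
#' components are radius-independent and computed once per sample), the
#' per-cluster cytokine/responder counts read out, and the clustered
#' weighted Spearman correlation computed on the pooled clusters.  The
#' optimal radius maximizes the correlation coefficient; ties break
#' toward the smaller radius (parsimony).  Radii with fewer than 3
#' clusters (or otherwise undefined correlations) are recorded and
#' skipped.  A secondary Pearson coefficient on the raw per-cluster sums
#' is reported alongside.
#'
#' @param ds A QC-passing `spot_dataset`.
#' @param labels A [label_spots()] result.
#' @param cytokine Cytokine name.
#' @param signature Responder signature (object or gene vector).
#' @param radii Integer radii to sweep (default `0:9`).
#' @param universe_layers,require_leukocyte,adjacency_mode Passed to
#'   [compute_clusters()].
#' @param ... Passed to [weighted_spearman()].
#' @return List of class `radius_sweep_result`: `table` (per-radius r, p,
#'   n_clusters, significance flag, Pearson r), `optimal_radius`,
#'   `optimal` (the winning `correlation_result`), and `clusters` at the
#'   optimal radius.
#' @export
radius_sweep <- function(ds, labels, cytokine, signature, radii = 0:9,
                         universe_layers = epidermis_layers(),
                         require_leukocyte = TRUE,
                         adjacency_mode = "index", ...) {
  rows <- list()
  best <- NULL
  best_clusters <- NULL
  for (r in radii) {
    clusters <- compute_clusters(ds, labels, cytokine, signature, r,
                                 universe_layers = universe_layers,
                                 require_leukocyte = require_leukocyte,
                                 adjacency_mode = adjacency_mode)
    res <- clustered_correlation(clusters, ...)
    pear <- if (res$ok) {
      x <- vapply(clusters, `[[`, 0, "cytokine_count")
      y <- vapply(clusters, `[[`, 0, "responder_count")
      if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_
    } else NA_real_
    rows[[as.character(r)]] <- data.frame(
      radius = r, r = res$r, p_value = res$p_value,
      n_clusters = length(clusters),
      significant = isTRUE(res$ok) && !is.na(res$p_value) &&
        res$p_value < 0.05,
      pearson_r = pear, ok = res$ok)
    if (res$ok && (is.null(best) || res$r > best$r)) {
      best <- res
      best$radius <- r
      best_clusters <- clusters
    }
  }
  .assert(!is.null(best), "correlation undefined at every swept radius")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, optimal_radius = best$radius, optimal = best,
                 cytokine = cytokine, clusters = best_clusters),
            class = "radius_sweep_result")
}

#' @export
print.radius_sweep_result <- function(x, ...) {
  cat(sprintf("radius_sweep for %s: optimal radius %d (r = %.3f, p = %.3g)\n",
              x$cytokine, x$optimal_radius, x$optimal$r, x$optimal$p_value))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Least-squares line through the origin
#'
#' Slope of the zero-intercept ordinary least squares fit,
#' `sum(x * y) / sum(x^2)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The slope (a single number).
#' @export
fit_origin_line <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 1,
          "x and y must be non-empty and of equal length")
  sx2 <- sum(x^2)
  .assert(sx2 > 0, "all x are zero; slope undefined")
  sum(x * y) / sx2
}
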