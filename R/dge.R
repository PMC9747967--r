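# Per-gene negative-binomial GLM differential expression.
#
# Raw counts are modeled with a log link and a log(size factor) offset;
# biological covariates (cdr, project, patient, annotation) enter as
# fixed effects; inference is a two-sided Wald test on the condition
# coefficient, BH-corrected across genes.  The dispersion is estimated
# per gene: method-of-moments initialization, then maximum likelihood,
# alternating with IRLS for the coefficients.  No quasi-likelihood or
# dispersion shrinkage is applied (deliberate simplification; the
# inference target — condition coefficient plus BH — is unchanged).

#' Build the DEG design matrix and offset
#'
#' One-hot encodes categorical covariates with reference-level drop
#' (first level), centers cdr, and uses `log(size_factor)` as the model
#' offset.  Collinear columns are dropped with a warning and recorded.
#'
#' @param ds A QC-passing `spot_dataset`.
#' @param factors A [compute_norm_factors()] result.
#' @param condition Named logical vector over spot keys: `TRUE` for the
#'   test group, `FALSE` for the reference, `NA` to exclude the spot.
#' @param covariates Subset of
#'   `c("cdr", "project", "patient", "annotation", "condition")`;
#'   `"condition"` must be included.
#' @return List of class `deg_design`: `X` (model matrix), `offset`,
#'   `keys` (modeled spots), `condition_col`, `dropped` (column names
#'   removed to restore full rank).
#' @export
build_design <- function(ds, factors, condition,
                         covariates = c("cdr", "project", "patient",
                                        "annotation", "condition")) {
  stopifnot(inherits(ds, "spot_dataset"), inherits(factors, "norm_factors"))
  .assert("condition" %in% covariates, "covariates must include 'condition'")
  .assert(all(covariates %in% c("cdr", "project", "patient", "annotation",
                                "condition")),
          "unknown covariate requested")
  keys <- names(condition)[!is.na(condition)]
  .assert(length(keys) > 0 && all(keys %in% rownames(ds$counts)),
          "condition must be a named vector over spot keys")
  cond <- condition[keys]
  .assert(length(unique(cond)) == 2, "condition is constant; cannot test")
  idx <- match(keys, ds$spots$key)
  midx <- match(ds$spots$sample_id[idx], ds$meta$sample_id)
  df <- data.frame(condition = as.numeric(cond))
  if ("cdr" %in% covariates) {
    cdr <- factors$cdr[keys]
    df$cdr <- cdr - mean(cdr)
  }
  if ("project" %in% covariates) df$project <- factor(ds$meta$project_id[midx])
  if ("patient" %in% covariates) df$patient <- factor(ds$meta$patient_id[midx])
  if ("annotation" %in% covariates) df$annotation <- factor(ds$spots$layer[idx])
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    .assert("condition" %in% colnames(X)[keep],
            "condition column is collinear with other covariates")
    warning("dropping collinear design column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  structure(list(X = X, offset = log(unname(factors$size_factor[keys])),
                 keys = keys, condition_col = "condition", dropped = dropped),
            class = "deg_design")
}

# Single-gene NB fit: alternating IRLS (beta | theta) and profile MLE
# (theta | beta).  Returns beta, se of the target column, theta and a
# convergence flag.
.fit_nb_one <- function(y, X, offset, target,
                        alpha_floor = 1e-8, alpha_ceil = 1e4,
                        max_outer = 8L, max_inner = 25L, tol = 1e-8) {
  n <- length(y)
  # Poisson initialization
  init <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = poisson(), offset = offset)),
    error = function(e) NULL)
  if (is.null(init) || !all(is.finite(init$coefficients))) {
    return(list(converged = FALSE))
  }
  beta <- init$coefficients
  eta <- drop(X %*% beta) + offset
  mu <- pmax(exp(eta), 1e-10)
  # method-of-moments dispersion: alpha = 1/theta in var = mu + alpha mu^2
  alpha <- sum((y - mu)^2 - mu) / sum(mu^2)
  alpha <- min(max(alpha, alpha_floor), alpha_ceil)
  ll_alpha <- function(la, mu) {
    sum(stats::dnbinom(y, size = 1 / exp(la), mu = mu, log = TRUE))
  }
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    theta <- 1 / alpha
    for (inner in seq_len(max_inner)) {
      w <- mu / (1 + mu / theta)
      z <- (eta - offset) + (y - mu) / mu
      fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$coefficients)) {
        return(list(converged = FALSE))
      }
      delta <- max(abs(fit$coefficients - beta))
      beta <- fit$coefficients
      eta <- drop(X %*% beta) + offset
      if (max(eta) > 50) return(list(converged = FALSE))  # divergence
      mu <- pmax(exp(eta), 1e-10)
      if (delta < tol) break
    }
    opt <- stats::optimize(ll_alpha, c(log(alpha_floor), log(alpha_ceil)),
                           mu = mu, maximum = TRUE)
    new_alpha <- exp(opt$maximum)
    moved <- abs(log(new_alpha) - log(alpha))
    alpha <- new_alpha
    if (delta < tol && moved < 1e-4) {
      converged <- TRUE
      break
    }
  }
  theta <- 1 / alpha
  w <- mu / (1 + mu / theta)
  info <- crossprod(X, X * w)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(list(converged = FALSE))
  j <- match(target, colnames(X))
  se <- sqrt(cov[j, j])
  list(beta = unname(beta[j]), se = se, theta = theta,
       fully_converged = converged)
}

#' Fit per-gene negative-binomial GLMs
#'
#' Fits `Y_sg ~ design` with a log link and `log(size factor)` offset per
#' gene, estimating a per-gene dispersion (method-of-moments
#' initialization, MLE refinement, floored at `1e-8`), and reports the
#' condition effect as `log2fc = beta_condition / ln 2` with a two-sided
#' Wald p-value.  All-zero genes are excluded; non-converged genes are
#' flagged and given `p_value = 1`.
#'
#' @param ds A `spot_dataset` (raw counts).
#' @param design A [build_design()] result.
#' @param genes Genes to fit (default: all).
#' @return `data.frame` of class `deg_table`: `gene`, `log2fc`,
#'   `p_value`, `adj_p_value` (BH), `mean_count`, `dispersion`,
#'   `converged`.
#' @export
fit_nb_glm <- function(ds, design, genes = colnames(ds$counts)) {
  stopifnot(inherits(ds, "spot_dataset"), inherits(design, "deg_design"))
  m <- ds$counts[design$keys, genes, drop = FALSE]
  nz <- Matrix::colSums(m) > 0
  if (!all(nz)) m <- m[, nz, drop = FALSE]
  out <- lapply(colnames(m), function(g) {
    y <- as.numeric(m[, g])
    fit <- .fit_nb_one(y, design$X, design$offset, design$condition_col)
    if (is.null(fit$beta) || !is.finite(fit$se) || fit$se <= 0) {
      data.frame(gene = g, log2fc = NA_real_, p_value = 1,
                 mean_count = mean(y), dispersion = NA_real_,
                 converged = FALSE, stringsAsFactors = FALSE)
    } else {
      z <- fit$beta / fit$se
      data.frame(gene = g, log2fc = fit$beta / log(2),
                 p_value = if (fit$fully_converged) 2 * pnorm(-abs(z)) else 1,
                 mean_count = mean(y), dispersion = 1 / fit$theta,
                 converged = fit$fully_converged, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, out)
  tab$adj_p_value <- bh_adjust(tab$p_value)
  tab <- tab[, c("gene", "log2fc", "p_value", "adj_p_value", "mean_count",
                 "dispersion", "converged")]
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Benjamini–Hochberg step-up adjustment
#'
#' Standard BH: sort p ascending, multiply by `m/rank`, enforce
#' monotonicity from the largest p downwards, cap at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m <= 1) return(pmin(p, 1))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

#' Call differentially expressed genes
#'
#' Genes with `|log2fc| >= fc_cut` and (adjusted or raw) `p <= p_cut`;
#' both cutoffs inclusive.
#'
#' @param deg A `deg_table`.
#' @param fc_cut Absolute log2FC threshold (default 1).
#' @param p_cut P-value threshold (default 0.05).
#' @param use_adjusted Use BH-adjusted p-values (default `TRUE`).
#' @return Sorted character vector of called genes.
#' @export
call_degs <- function(deg, fc_cut = 1, p_cut = 0.05, use_adjusted = TRUE) {
  p <- if (use_adjusted) deg$adj_p_value else deg$p_value
  keep <- !is.na(deg$log2fc) & abs(deg$log2fc) >= fc_cut & p <= p_cut
  sort(deg$gene[keep])
}

#' Condition vector: cytokine-positive vs cytokine-negative spots
#'
#' The spot universe is restricted to `universe_layers`; positives are
#' the cytokine-positive spots, negatives the cytokine-negative ones
#' (optionally only leukocyte-positive spots on either side).
#'
#' @param ds A `spot_dataset`.
#' @param labels A [label_spots()] result.
#' @param cytokine Cytokine name.
#' @param universe_layers Layer set (default [epidermis_layers()]).
#' @param leukocyte_only Restrict both groups to leukocyte-positive spots.
#' @return Named logical vector over the universe keys.
#' @export
contrast_cytokine <- function(ds, labels, cytokine,
                              universe_layers = epidermis_layers(),
                              leukocyte_only = FALSE) {
  tab <- labels$table
  uni <- tab$layer_group %in% universe_layers &
    (!leukocyte_only | tab$leukocyte_pos)
  cond <- rep(NA, nrow(tab))
  cond[uni] <- tab[[paste0(cytokine, "_pos")]][uni]
  setNames(cond, tab$key)[uni]
}

#' Condition vector: cytokine-positive vs non-cluster spots
#'
#' For the data-driven expansion of cytokine-gene associations:
#' positives are the cytokine-positive spots; negatives are the
#' epidermal spots belonging to no density cluster at the cytokine's
#' optimal radius.  Spots inside a cluster (seed or ring) that are
#' cytokine-negative are excluded from both groups.
#'
#' @param ds A `spot_dataset`.
#' @param labels A [label_spots()] result.
#' @param clusters List of `density_cluster` objects at the optimal
#'   radius.
#' @param cytokine Cytokine name.
#' @param universe_layers Layer set (default [epidermis_layers()]).
#' @return Named logical vector (with no `NA` entries; excluded spots are
#'   simply absent).
#' @export
contrast_noncluster <- function(ds, labels, clusters, cytokine,
                                universe_layers = epidermis_layers()) {
  tab <- labels$table
  uni_keys <- tab$key[tab$layer_group %in% universe_layers]
  member <- unique(unlist(lapply(clusters, function(cl)
    c(cl$seed_spots, cl$ring_spots))))
  pos_keys <- tab$key[tab[[paste0(cytokine, "_pos")]]]
  pos <- intersect(uni_keys, pos_keys)
  neg <- setdiff(uni_keys, union(member, pos_keys))
  .assert(length(neg) > 0, "no non-cluster negative spots remain")
  setNames(c(rep(TRUE, length(pos)), rep(FALSE, length(neg))),
           c(pos, neg))
}
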