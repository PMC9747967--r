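# Density-based clustering on the Visium hex array.
#
# Geometry lives in 0-based array-index space: adjacent spots in the same
# row differ by 2 columns, spots in adjacent rows by 1 column, and
# row + col is even everywhere.  A radius-r hex neighborhood around a
# center collects offsets (j, i) with j in [-r, r], i in
# [-2r+|j|, 2r-|j|], i + j even — the centered hexagonal number
# 3r^2 + 3r + 1 of spots including the center.

#' Hexagonal neighborhood of a spot in array-index space
#'
#' Returns the spots within hex ring distance `r` of `center` (inclusive of
#' the center): row offsets `j` in `[-r, r]` and column offsets `i` in
#' `[-2r+|j|, 2r-|j|]` with `i + j` even.  The neighborhood size is the
#' centered hexagonal number `3r^2 + 3r + 1`.
#'
#' @param center Integer vector `c(array_row, array_col)`; `row + col` must
#'   be even.
#' @param r Integer radius >= 0.
#' @return Two-column integer matrix (`array_row`, `array_col`) of member
#'   coordinates, center included.
#' @export
#' @examples
#' nrow(hex_neighborhood(c(10, 10), 2))  # 19
hex_neighborhood <- function(center, r) {
  .assert(length(center) == 2 && sum(center) %% 2 == 0,
          "center must be a length-2 coordinate with even row+col parity")
  .assert(length(r) == 1 && r >= 0 && r == round(r), "radius must be an integer >= 0")
  r <- as.integer(r)
  js <- seq.int(-r, r)
  out <- do.call(rbind, lapply(js, function(j) {
    lim <- 2L * r - abs(j)
    i <- seq.int(-lim, lim, by = 2L)  # endpoints share j's parity, so i+j even
    cbind(center[1] + j, center[2] + i)
  }))
  colnames(out) <- c("array_row", "array_col")
  out
}

#' Graph of adjacent cytokine-positive spots
#'
#' Connects cytokine transcript-positive spots of one sample whose
#' Euclidean distance in (array_row, array_col) index space is at most
#' `max_dist` (default 2.0, boundary inclusive).  In index space the
#' default links the 6 physical hex neighbors (offsets (0, ±2), (±1, ±1))
#' and additionally spots two rows apart in the same column (offset
#' (±2, 0)), which sit at index distance 2 but are not physical
#' neighbors; `mode = "hex6"` restricts to the 6 physical neighbors.
#'
#' @param spots `data.frame` with columns `key`, `array_row`, `array_col`
#'   (cytokine-positive spots of a single sample).
#' @param max_dist Maximum Euclidean index-space distance (default 2.0).
#' @param mode `"index"` (default, distance rule as published) or `"hex6"`
#'   (strict physical hex adjacency).
#' @return List with `nodes` (spot keys), `coords` (matrix), and `edges`
#'   (two-column matrix of node indices, i < j). Empty input gives an empty
#'   graph.
#' @export
build_adjacency <- function(spots, max_dist = 2.0, mode = c("index", "hex6")) {
  mode <- match.arg(mode)
  n <- nrow(spots)
  coords <- cbind(spots$array_row, spots$array_col)
  if (is.null(n) || n == 0) {
    return(list(nodes = character(0),
                coords = matrix(numeric(0), 0, 2), edges = matrix(0L, 0, 2)))
  }
  edges <- matrix(0L, 0, 2)
  if (n > 1) {
    d <- as.matrix(stats::dist(coords))
    keep <- which(upper.tri(d) & d <= max_dist + 1e-9, arr.ind = TRUE)
    if (mode == "hex6" && nrow(keep)) {
      dr <- abs(coords[keep[, 1], 1] - coords[keep[, 2], 1])
      dc <- abs(coords[keep[, 1], 2] - coords[keep[, 2], 2])
      phys <- (dr == 0 & dc == 2) | (dr == 1 & dc == 1)
      keep <- keep[phys, , drop = FALSE]
    }
    edges <- unname(keep)
  }
  list(nodes = spots$key, coords = coords, edges = edges)
}

#' Connected components of the cytokine adjacency graph
#'
#' Each component is a cluster seed set; isolated cytokine-positive spots
#' form singleton components.
#'
#' @param graph Result of [build_adjacency()].
#' @return List of character vectors of spot keys, ordered by their
#'   lexicographically smallest member.
#' @export
seed_clusters <- function(graph) {
  n <- length(graph$nodes)
  if (n == 0) return(list())
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$edges)) g <- igraph::add_edges(g, t(graph$edges))
  memb <- igraph::components(g)$membership
  comps <- split(graph$nodes, memb)
  comps <- lapply(comps, sort)
  comps <- unname(comps[order(vapply(comps, `[`, "", 1L))])
  comps
}

#' Expand seed components by a hex radius and merge overlaps
#'
#' Each seed component is expanded by the union of radius-`r` hex
#' neighborhoods of its seeds, intersected with the spot universe
#' (typically the QC-passing epidermal spots of the sample).  Clusters
#' sharing any member spot are merged transitively until a fixpoint;
#' the result partitions its member spots.  Cluster ids are
#' `"<sample_id>:<radius>:<smallest seed key>"`, so they are deterministic
#' and independent of component processing order.
#'
#' @param components List of seed key vectors (from [seed_clusters()]).
#' @param r Integer hex radius >= 0.
#' @param universe `data.frame` of candidate member spots with columns
#'   `key`, `array_row`, `array_col` (must contain the seed spots).
#' @param sample_id Sample identifier stamped on the clusters.
#' @return List of `density_cluster` objects with fields `cluster_id`,
#'   `sample_id`, `radius`, `seed_spots`, `ring_spots`.
#' @export
expand_and_merge <- function(components, r, universe, sample_id) {
  .assert(r >= 0 && r == round(r), "radius must be an integer >= 0")
  if (length(components) == 0) return(list())
  .assert(all(unlist(components) %in% universe$key),
          "seed spots missing from universe")
  coord_key <- paste(universe$array_row, universe$array_col)
  rowcol <- function(keys) {
    idx <- match(keys, universe$key)
    cbind(universe$array_row[idx], universe$array_col[idx])
  }
  members <- lapply(components, function(seeds) {
    cc <- rowcol(seeds)
    hood <- unique(do.call(rbind, lapply(seq_len(nrow(cc)), function(k) {
      hex_neighborhood(cc[k, ], r)
    })))
    hit <- match(paste(hood[, 1], hood[, 2]), coord_key)
    sort(universe$key[hit[!is.na(hit)]])
  })
  # union-find merge of clusters sharing any member spot
  parent <- seq_along(members)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  owner <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_along(members)) {
    for (key in members[[ci]]) {
      prev <- owner[[key]]
      if (is.null(prev)) {
        owner[[key]] <- ci
      } else {
        ra <- find(prev); rb <- find(ci)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_along(members), find, 0L)
  out <- lapply(sort(unique(roots)), function(root) {
    idx <- which(roots == root)
    seeds <- sort(unique(unlist(components[idx])))
    memb <- sort(unique(unlist(members[idx])))
    structure(list(cluster_id = paste(sample_id, r, seeds[1], sep = ":"),
                   sample_id = sample_id, radius = as.integer(r),
                   seed_spots = seeds,
                   ring_spots = setdiff(memb, seeds)),
              class = "density_cluster")
  })
  out[order(vapply(out, `[[`, "", "cluster_id"))]
}

#' @export
print.density_cluster <- function(x, ...) {
  cat(sprintf("density_cluster %s: r=%d, %d seed + %d ring spot(s)\n",
              x$cluster_id, x$radius, length(x$seed_spots),
              length(x$ring_spots)))
  invisible(x)
}

#' Read out cytokine and responder counts of a cluster
#'
#' `cytokine_count` sums the cytokine's raw UMIs over the seed spots;
#' `responder_count` sums raw UMIs of all responder-signature genes over
#' every member spot (seeds + ring); the correlation `weight` equals the
#' cytokine count.
#'
#' @param cluster A `density_cluster`.
#' @param ds The (QC-passing) `spot_dataset` with raw counts.
#' @param cytokine Cytokine gene symbol.
#' @param signature A [responder_signature()] or character vector of genes.
#' @return The cluster with `cytokine_count`, `responder_count` and
#'   `weight` fields attached.
#' @export
cluster_readout <- function(cluster, ds, cytokine, signature) {
  stopifnot(inherits(cluster, "density_cluster"), inherits(ds, "spot_dataset"))
  genes <- if (inherits(signature, "responder_signature")) signature$genes else signature
  .assert(cytokine %in% colnames(ds$counts),
          "cytokine gene %s absent from count matrix", cytokine)
  missing <- setdiff(genes, colnames(ds$counts))
  if (length(missing)) {
    warning("signature gene(s) absent from matrix, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
    genes <- setdiff(genes, missing)
  }
  members <- c(cluster$seed_spots, cluster$ring_spots)
  cluster$cytokine_count <- sum(ds$counts[cluster$seed_spots, cytokine])
  cluster$responder_count <- if (length(genes)) {
    sum(ds$counts[members, genes, drop = FALSE])
  } else 0
  cluster$weight <- cluster$cytokine_count
  cluster
}

#' Build readout-annotated clusters for one cytokine at one radius
#'
#' Convenience wrapper running [build_adjacency()], [seed_clusters()],
#' [expand_and_merge()] and [cluster_readout()] per sample and pooling the
#' clusters.  Seeds are the cytokine-positive spots (optionally restricted
#' to leukocyte-positive spots) within the universe; the universe defaults
#' to the epidermal spots of the dataset.
#'
#' @param ds QC-passing `spot_dataset` (raw counts).
#' @param labels A [spot_labels] object from [label_spots()].
#' @param cytokine Cytokine gene symbol.
#' @param signature Responder signature (object or gene vector).
#' @param r Hex radius.
#' @param universe_layers Layers forming the spot universe
#'   (default [epidermis_layers()]).
#' @param require_leukocyte Require seeds to be leukocyte-positive
#'   (default `TRUE`).
#' @param adjacency_mode Passed to [build_adjacency()].
#' @return List of readout-annotated `density_cluster` objects, pooled
#'   across samples.
#' @export
compute_clusters <- function(ds, labels, cytokine, signature, r,
                             universe_layers = epidermis_layers(),
                             require_leukocyte = TRUE,
                             adjacency_mode = "index") {
  stopifnot(inherits(ds, "spot_dataset"), inherits(labels, "spot_labels"))
  lab <- labels$table
  pos_col <- paste0(cytokine, "_pos")
  .assert(pos_col %in% names(lab), "labels do not cover cytokine %s", cytokine)
  uni_all <- ds$spots[ds$spots$layer %in% universe_layers, , drop = FALSE]
  seeds_ok <- lab$key[lab[[pos_col]] &
                        (!require_leukocyte | lab$leukocyte_pos)]
  out <- list()
  for (sid in sort(unique(uni_all$sample_id))) {
    uni <- uni_all[uni_all$sample_id == sid, , drop = FALSE]
    seed_spots <- uni[uni$key %in% seeds_ok, , drop = FALSE]
    if (nrow(seed_spots) == 0) next
    graph <- build_adjacency(seed_spots, mode = adjacency_mode)
    comps <- seed_clusters(graph)
    cls <- expand_and_merge(comps, r, uni, sid)
    cls <- lapply(cls, cluster_readout, ds = ds, cytokine = cytokine,
                  signature = signature)
    out <- c(out, cls)
  }
  out
}
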