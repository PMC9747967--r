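# Independent oracles, kept deliberately naive and separate from the
# package implementation paths they check.

# Explicit parity grid of spots as a two-column matrix (array_row,
# array_col), rows 0..(nr-1), cols with row parity.
oracle_grid <- function(nr, nc) {
  rows <- rep(seq_len(nr) - 1L, each = nc)
  cols <- rep(2L * (seq_len(nc) - 1L), times = nr) + rows %% 2L
  cbind(rows, cols)
}

# BFS ball of hex radius r on the 6-neighbor physical adjacency of an
# explicit grid; returns coordinate keys "row col".
oracle_bfs_ball <- function(grid, center, r) {
  key <- paste(grid[, 1], grid[, 2])
  depth <- rep(Inf, nrow(grid))
  start <- match(paste(center[1], center[2]), key)
  stopifnot(!is.na(start))
  depth[start] <- 0
  frontier <- start
  offs <- rbind(c(0, 2), c(0, -2), c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  d <- 0
  while (length(frontier) && d < r) {
    d <- d + 1
    nxt <- integer(0)
    for (i in frontier) {
      for (k in seq_len(nrow(offs))) {
        j <- match(paste(grid[i, 1] + offs[k, 1], grid[i, 2] + offs[k, 2]),
                   key)
        if (!is.na(j) && depth[j] > d) {
          depth[j] <- d
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- nxt
  }
  sort(key[depth <= r])
}

# All-pairs distance thresholding oracle for build_adjacency.
oracle_adjacency <- function(spots, max_dist = 2.0) {
  n <- nrow(spots)
  edges <- NULL
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- sqrt((spots$array_row[i] - spots$array_row[j])^2 +
                    (spots$array_col[i] - spots$array_col[j])^2)
        if (d <= max_dist + 1e-9) edges <- rbind(edges, c(i, j))
      }
    }
  }
  if (is.null(edges)) matrix(0L, 0, 2) else edges
}

# Closed-form hex distance in array-index space via axial coordinates.
oracle_hex_dist <- function(a, b) {
  q1 <- (a[2] - a[1]) / 2; r1 <- a[1]
  q2 <- (b[2] - b[1]) / 2; r2 <- b[1]
  (abs(q1 - q2) + abs(r1 - r2) + abs(q1 + r1 - q2 - r2)) / 2
}

# Brute-force expansion + union-find merge oracle: members are universe
# spots within closed-form hex distance r of any component seed; clusters
# sharing members merge transitively.  Returns a set of member-key sets.
oracle_expand_merge <- function(components, r, universe) {
  members <- lapply(components, function(seeds) {
    idx <- match(seeds, universe$key)
    keep <- vapply(seq_len(nrow(universe)), function(i) {
      any(vapply(idx, function(s) {
        oracle_hex_dist(c(universe$array_row[i], universe$array_col[i]),
                        c(universe$array_row[s], universe$array_col[s])) <= r
      }, TRUE))
    }, TRUE)
    sort(universe$key[keep])
  })
  parent <- seq_along(members)
  find <- function(i) while (TRUE) {
    if (parent[i] == i) return(i) else i <- parent[i]
  }
  for (a in seq_along(members)) {
    for (b in seq_len(a - 1)) {
      if (length(intersect(members[[a]], members[[b]]))) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_along(members), find, 0L)
  out <- lapply(unique(roots), function(rt)
    sort(unique(unlist(members[roots == rt]))))
  out[order(vapply(out, `[`, "", 1L))]
}
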