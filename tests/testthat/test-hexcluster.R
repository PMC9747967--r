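test_that("hex neighborhoods follow the centered hexagonal law and the BFS ball", {
  grid <- oracle_grid(30, 40)
  center <- c(14, 40 + 14 %% 2)
  for (r in 0:5) {
    hood <- hex_neighborhood(center, r)
    expect_equal(nrow(hood), 3 * r^2 + 3 * r + 1)
    expect_setequal(paste(hood[, 1], hood[, 2]),
                    oracle_bfs_ball(grid, center, r))
  }
  expect_error(hex_neighborhood(c(1, 2), 1), "parity")
  expect_error(hex_neighborhood(c(2, 2), -1), "radius")
})

test_that("radius-1 neighborhood at (10,10) enumerates the seven expected spots", {
  hood <- hex_neighborhood(c(10, 10), 1)
  expect_setequal(paste(hood[, 1], hood[, 2]),
                  c("10 10", "10 8", "10 12", "9 9", "9 11", "11 9", "11 11"))
})

test_that("adjacency follows the <= 2.0 index-distance rule, boundary inclusive", {
  spots <- data.frame(key = c("a", "b", "c", "d"),
                      array_row = c(10, 11, 10, 10),
                      array_col = c(10, 11, 12, 14))
  g <- build_adjacency(spots)
  ekeys <- apply(g$edges, 1, function(e) paste(sort(g$nodes[e]), collapse = "-"))
  expect_true("a-b" %in% ekeys)   # sqrt(2)
  expect_true("a-c" %in% ekeys)   # exactly 2.0
  expect_false("a-d" %in% ekeys)  # 4.0
  # strict hex mode drops the (+-2, 0) vertical link
  spots2 <- data.frame(key = c("a", "e"), array_row = c(10, 12),
                       array_col = c(10, 10))
  expect_equal(nrow(build_adjacency(spots2)$edges), 1)
  expect_equal(nrow(build_adjacency(spots2, mode = "hex6")$edges), 0)
  expect_equal(length(build_adjacency(spots[0, ])$nodes), 0)
})

test_that("adjacency equals the all-pairs oracle on random instances", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:60, 1)
    rows <- sample(0:30, n, replace = TRUE)
    cols <- 2L * sample(0:30, n, replace = TRUE) + rows %% 2L
    df <- unique(data.frame(array_row = rows, array_col = cols))
    df$key <- sprintf("s%03d", seq_len(nrow(df)))
    g <- build_adjacency(df)
    o <- oracle_adjacency(df)
    norm <- function(e) if (nrow(e)) paste(pmin(e[, 1], e[, 2]),
                                           pmax(e[, 1], e[, 2])) else character(0)
    expect_setequal(norm(g$edges), norm(o))
  }
})

test_that("seed components: chains join, distant spots stay singletons", {
  spots <- data.frame(key = c("a", "b", "c", "z"),
                      array_row = c(10, 10, 10, 30),
                      array_col = c(10, 12, 14, 30))
  comps <- seed_clusters(build_adjacency(spots))
  expect_length(comps, 2)
  expect_setequal(comps[[1]], c("a", "b", "c"))
  expect_equal(comps[[2]], "z")
  expect_equal(seed_clusters(build_adjacency(spots[0, ])), list())
})

test_that("expand_and_merge: r=0 identity, overlap merge, order independence", {
  uni <- as.data.frame(oracle_grid(10, 12))
  names(uni) <- c("array_row", "array_col")
  uni$key <- sprintf("u%03d", seq_len(nrow(uni)))
  seed_at <- function(row, col) uni$key[uni$array_row == row & uni$array_col == col]
  comps <- list(seed_at(4, 4), seed_at(4, 12))
  r0 <- expand_and_merge(comps, 0, uni, "S01")
  expect_length(r0, 2)
  expect_equal(lapply(r0, `[[`, "seed_spots"), comps)
  expect_equal(lengths(lapply(r0, `[[`, "ring_spots")), c(0L, 0L))
  # seeds 4 apart: radius-2 rings share the midpoint -> one merged cluster
  r2 <- expand_and_merge(comps, 2, uni, "S01")
  expect_length(r2, 1)
  expect_setequal(r2[[1]]$seed_spots, unlist(comps))
  r2b <- expand_and_merge(rev(comps), 2, uni, "S01")
  expect_equal(lapply(r2, `[[`, "ring_spots"), lapply(r2b, `[[`, "ring_spots"))
  expect_equal(r2[[1]]$cluster_id, r2b[[1]]$cluster_id)
})

test_that("expansion equals the brute-force union-find oracle on random instances", {
  set.seed(11)
  uni <- as.data.frame(oracle_grid(14, 16))
  names(uni) <- c("array_row", "array_col")
  uni$key <- sprintf("u%03d", seq_len(nrow(uni)))
  for (i in 1:15) {
    seeds <- sample(uni$key, sample(2:8, 1))
    sdf <- uni[match(seeds, uni$key), ]
    comps <- seed_clusters(build_adjacency(sdf))
    r <- sample(0:4, 1)
    got <- expand_and_merge(comps, r, uni, "S01")
    got_sets <- lapply(got, function(cl) sort(c(cl$seed_spots, cl$ring_spots)))
    got_sets <- got_sets[order(vapply(got_sets, `[`, "", 1L))]
    expect_equal(got_sets, oracle_expand_merge(comps, r, uni))
    # partition: no spot in two clusters
    expect_false(anyDuplicated(unlist(got_sets)) > 0)
  }
})

test_that("members at radius r stay members at radius r+1 (monotonicity)", {
  set.seed(3)
  uni <- as.data.frame(oracle_grid(12, 12))
  names(uni) <- c("array_row", "array_col")
  uni$key <- sprintf("u%03d", seq_len(nrow(uni)))
  seeds <- sample(uni$key, 5)
  comps <- seed_clusters(build_adjacency(uni[match(seeds, uni$key), ]))
  prev <- NULL
  for (r in 0:4) {
    mem <- sort(unique(unlist(lapply(expand_and_merge(comps, r, uni, "S01"),
                                     function(cl) c(cl$seed_spots, cl$ring_spots)))))
    if (!is.null(prev)) expect_true(all(prev %in% mem))
    prev <- mem
  }
})

test_that("cluster readout sums seeds for cytokine and all members for responders", {
  m <- matrix(0, 8, 3, dimnames = list(NULL, c("IL17A", "RSPA", "RSPB")))
  m[1, "IL17A"] <- 2
  m[2:8, "RSPA"] <- 5
  m[2:8, "RSPB"] <- c(5, 5, 5, 0, 0, 0, 0)
  ds <- make_flat_dataset(m)
  keys <- rownames(ds$counts)
  cl <- structure(list(cluster_id = "c1", sample_id = "S01", radius = 1L,
                       seed_spots = keys[1], ring_spots = keys[2:8]),
                  class = "density_cluster")
  out <- cluster_readout(cl, ds, "IL17A", c("RSPA", "RSPB"))
  expect_equal(out$cytokine_count, 2)
  expect_equal(out$responder_count, 35 + 15)
  expect_equal(out$weight, 2)
  expect_equal(cluster_readout(cl, ds, "IL17A", character(0))$responder_count, 0)
  expect_warning(out2 <- cluster_readout(cl, ds, "IL17A", c("RSPA", "GHOST")),
                 "GHOST")
  expect_equal(out2$responder_count, 35)
})
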