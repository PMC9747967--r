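test_that("weighted Spearman reduces to classical Spearman under uniform weights", {
  expect_equal(weighted_spearman(1:3, 1:3)$r, 1)
  expect_equal(weighted_spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  set.seed(5)
  for (i in 1:40) {
    n <- sample(5:120, 1)
    x <- sample(1:15, n, replace = TRUE)   # plenty of ties
    y <- x + rnorm(n, 0, sample(c(0.5, 2, 10), 1))
    got <- weighted_spearman(x, y)
    if (!got$ok) next
    expect_equal(got$r, cor(x, y, method = "spearman"), tolerance = 1e-10)
  }
})

test_that("zero weights drop observations; scaling weights changes nothing", {
  x <- c(1, 3, 5, 2); y <- c(2, 1, 7, 4)
  with0 <- weighted_spearman(x, y, c(1, 1, 1, 0))
  dropped <- weighted_spearman(x[1:3], y[1:3])
  expect_equal(with0$r, dropped$r)
  expect_equal(with0$n_units, 3)
  w <- c(1, 2, 3, 4)
  expect_equal(weighted_spearman(x, y, w)$r, weighted_spearman(x, y, 2 * w)$r)
})

test_that("r is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- rpois(30, 5) + 1; y <- rpois(30, 8) + 1; w <- runif(30, 0.5, 2)
  base <- weighted_spearman(x, y, w)$r
  expect_equal(weighted_spearman(exp(x / 3), y, w)$r, base)
  expect_equal(weighted_spearman(x, y^3, w)$r, base)
})

test_that("degenerate inputs yield an error result, not NaN", {
  res <- weighted_spearman(c(1, 1, 1), c(1, 2, 3))
  expect_false(res$ok)
  expect_match(res$message, "variance")
  res2 <- weighted_spearman(c(1, 2), c(1, 2))
  expect_false(res2$ok)
  expect_error(weighted_spearman(1:3, 1:3, c(0, 0, 0)), "weights")
})

test_that("permutation p-values broadly agree with the t approximation", {
  set.seed(13)
  x <- rnorm(25); y <- x + rnorm(25)
  pt_ <- weighted_spearman(x, y)$p_value
  pp <- weighted_spearman(x, y, p_method = "permutation", n_perm = 4000,
                          perm_seed = 2)$p_value
  expect_lt(abs(log10(max(pp, 1e-4)) - log10(max(pt_, 1e-4))), 1.5)
})

test_that("clustered correlation handles the documented examples", {
  mk <- function(x, y, w) structure(list(cluster_id = "c", sample_id = "S",
    radius = 0L, seed_spots = "a", ring_spots = character(0),
    cytokine_count = x, responder_count = y, weight = w),
    class = "density_cluster")
  cls <- Map(mk, c(1, 2, 3), c(10, 20, 30), c(1, 2, 3))
  expect_equal(clustered_correlation(cls)$r, 1)
  anti <- Map(mk, c(1, 2, 3), c(30, 20, 10), c(1, 1, 1))
  expect_equal(clustered_correlation(anti)$r, -1)
  expect_false(clustered_correlation(cls[1])$ok)
})

test_that("pseudo-bulk correlation is 1 for proportional section totals", {
  set.seed(21)
  sim <- simulate_dataset(tiny_sim_config(seed = 5))
  labels <- label_spots(sim$dataset)
  res <- pseudo_bulk_correlation(sim$dataset, labels, "IL17A",
                                 sim$truth$responder_genes$IL17A)
  expect_true(res$ok)
  expect_true(abs(res$r) <= 1)
  # proportional construction
  m <- matrix(0, 9, 2, dimnames = list(NULL, c("IFNG", "R1")))
  cyt <- rep(c(1, 2, 3), each = 3)
  m[, "IFNG"] <- cyt; m[, "R1"] <- 10 * cyt
  mats <- lapply(1:3, function(i) m[(3 * i - 2):(3 * i), , drop = FALSE])
  coords <- lapply(1:3, function(i) cbind(0:2, c(0, 1, 2) * 2 + (0:2) %% 2))
  ds <- make_two_sample_dataset(mats, coords,
                                rep(list(rep("basal epidermis", 3)), 3))
  lab <- suppressWarnings(label_spots(ds, markers = "IFNG",
                                      cytokines = "IFNG"))
  expect_equal(pseudo_bulk_correlation(ds, lab, "IFNG", "R1")$r, 1)
})

test_that("origin-constrained least squares matches the closed form", {
  expect_equal(fit_origin_line(c(1, 2), c(2, 4)), 2)
  expect_equal(fit_origin_line(c(1, 2), c(0, 0)), 0)
  expect_equal(fit_origin_line(c(1, 2), c(1, 5)), 2.2)
  expect_error(fit_origin_line(c(0, 0), c(1, 2)), "zero")
})

test_that("radius sweep returns a full table and an optimum in the swept set", {
  sim <- simulate_dataset(tiny_sim_config(seed = 11))
  labels <- label_spots(sim$dataset)
  sw <- radius_sweep(sim$dataset, labels, "IL17A",
                     sim$truth$responder_genes$IL17A, radii = 0:4)
  expect_s3_class(sw, "radius_sweep_result")
  expect_equal(nrow(sw$table), 5)
  expect_true(sw$optimal_radius %in% 0:4)
  ok <- sw$table[sw$table$ok, ]
  expect_equal(sw$optimal$r, max(ok$r))
  # ties break toward the smallest radius
  expect_equal(sw$optimal_radius, min(ok$radius[ok$r == max(ok$r)]))
})

test_that("clustered correlation is near zero without planted amplification", {
  rs <- c()
  for (s in 1:4) {
    sim <- simulate_dataset(sim_config(seed = 700 + s, amplification = 1,
                                       cytokine_spot_rate = 0.008))
    labels <- label_spots(sim$dataset)
    cl <- compute_clusters(sim$dataset, labels, "IL17A",
                           sim$truth$responder_genes$IL17A, 0L)
    cc <- clustered_correlation(cl)
    if (cc$ok) rs <- c(rs, cc$r)
  }
  expect_true(length(rs) >= 3)
  expect_lt(abs(mean(rs)), 0.3)
})

test_that("gene column order never affects the clustered statistic", {
  sim <- simulate_dataset(tiny_sim_config(seed = 3))
  labels <- label_spots(sim$dataset)
  sig <- sim$truth$responder_genes$IFNG
  base <- clustered_correlation(
    compute_clusters(sim$dataset, labels, "IFNG", sig, 2L))
  perm <- sim$dataset
  set.seed(1)
  perm$counts <- perm$counts[, sample(ncol(perm$counts))]
  labels2 <- label_spots(perm)
  shuffled <- clustered_correlation(
    compute_clusters(perm, labels2, "IFNG", sig, 2L))
  expect_equal(shuffled$r, base$r)
  expect_equal(shuffled$p_value, base$p_value)
})
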