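make_design_fixture <- function() {
  # two samples (patients), two layers, balanced condition
  set.seed(31)
  mats <- list(); coords <- list(); layers <- list()
  for (i in 1:2) {
    m <- matrix(rpois(20 * 6, 5), 20, 6,
                dimnames = list(NULL, sprintf("g%d", 1:6)))
    mats[[i]] <- m
    rows <- rep(0:3, each = 5)
    cols <- (0:19 %% 5) * 2 + rows %% 2
    coords[[i]] <- cbind(rows, cols)
    layers[[i]] <- rep(c("basal epidermis", "dermis 1"), each = 10)
  }
  ds <- make_two_sample_dataset(mats, coords, layers)
  ds$meta$project_id <- "pr1"
  list(ds = ds, factors = compute_norm_factors(ds))
}

test_that("design uses reference coding: 2 patients x 2 layers -> 5 columns", {
  fx <- make_design_fixture()
  cond <- setNames(rep(c(TRUE, FALSE), 20), rownames(fx$ds$counts))
  des <- build_design(fx$ds, fx$factors, cond,
                      covariates = c("cdr", "patient", "annotation",
                                     "condition"))
  expect_equal(ncol(des$X), 5)  # intercept + condition + cdr + patient + layer
  expect_length(des$dropped, 0)
  # all size factors 1 -> zero offset
  fx$factors$size_factor[] <- 1
  des1 <- build_design(fx$ds, fx$factors, cond,
                       covariates = c("cdr", "condition"))
  expect_equal(des1$offset, rep(0, 40))
})

test_that("a covariate confounded with condition is dropped with a warning", {
  fx <- make_design_fixture()
  cond <- setNames(fx$ds$spots$sample_id == "S02", fx$ds$spots$key)
  expect_warning(des <- build_design(fx$ds, fx$factors, cond,
                                     covariates = c("patient", "condition")),
                 "collinear")
  expect_true(any(grepl("patient", des$dropped)))
  expect_error(build_design(fx$ds, fx$factors,
                            setNames(rep(TRUE, 40), fx$ds$spots$key)),
               "constant")
})

test_that("BH adjustment matches the hand calculation and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(2:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
})

test_that("DEG calling is inclusive at both cutoffs and monotone", {
  deg <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.0, -1.2, 0.9, 2.0),
                    p_value = c(0.05, 0.01, 0.001, 0.2),
                    adj_p_value = c(0.05, 0.01, 0.001, 0.2))
  expect_setequal(call_degs(deg), c("a", "b"))
  expect_setequal(call_degs(deg, use_adjusted = FALSE), c("a", "b"))
  loose <- call_degs(deg, fc_cut = 0.5, p_cut = 0.3)
  expect_true(all(call_degs(deg) %in% loose))
})

test_that("NB fit recovers a planted 4-fold effect and the Poisson limit", {
  set.seed(47)
  n <- 600
  condv <- rep(c(TRUE, FALSE), each = 300)
  G <- 105   # few DE genes among many nulls, so size factors stay honest
  m <- matrix(rnbinom(n * G, mu = 5, size = 2), n, G,
              dimnames = list(NULL, sprintf("g%03d", 1:G)))
  for (g in 1:5) m[condv, g] <- rnbinom(300, mu = 20, size = 2)
  ds <- make_flat_dataset(m)
  cond <- setNames(condv, rownames(ds$counts))
  des <- build_design(ds, compute_norm_factors(ds), cond,
                      covariates = "condition")
  deg <- fit_nb_glm(ds, des, genes = sprintf("g%03d", 1:5))
  expect_true(all(abs(deg$log2fc - 2) < 0.5))
  expect_true(all(deg$p_value < 1e-4))
  expect_true(all(deg$adj_p_value >= deg$p_value))
  # Poisson-generated data: estimates match the Poisson GLM closely
  set.seed(48)
  mp <- matrix(rpois(300 * 10, 6), 300, 10,
               dimnames = list(NULL, sprintf("p%02d", 1:10)))
  dsp <- make_flat_dataset(mp)
  condp <- setNames(rep(c(TRUE, FALSE), 150), rownames(dsp$counts))
  desp <- build_design(dsp, compute_norm_factors(dsp), condp,
                       covariates = "condition")
  degp <- fit_nb_glm(dsp, desp)
  for (g in seq_len(10)) {
    ref <- glm(as.numeric(dsp$counts[, g]) ~ desp$X - 1 +
                 offset(desp$offset), family = poisson())
    expect_lt(abs(degp$log2fc[g] - unname(coef(ref)[2]) / log(2)), 1e-3)
  }
  # estimated dispersion hits the floor (near-Poisson)
  expect_true(all(degp$dispersion < 1e-2))
})

test_that("NB fit cross-checks against MASS::glm.nb on overdispersed genes", {
  skip_if_not_installed("MASS")
  set.seed(53)
  n <- 400
  condv <- rep(c(TRUE, FALSE), each = 200)
  m <- matrix(rnbinom(n * 6, mu = ifelse(condv, 12, 6), size = 1.5), n, 6,
              dimnames = list(NULL, sprintf("q%d", 1:6)))
  ds <- make_flat_dataset(m)
  cond <- setNames(condv, rownames(ds$counts))
  des <- build_design(ds, compute_norm_factors(ds), cond,
                      covariates = "condition")
  deg <- fit_nb_glm(ds, des)
  for (g in 1:6) {
    ref <- suppressWarnings(
      MASS::glm.nb(as.numeric(ds$counts[, g]) ~ des$X - 1 +
                     offset(des$offset)))
    expect_equal(deg$log2fc[g], unname(coef(ref)[2]) / log(2),
                 tolerance = 0.02)
  }
})

test_that("non-cluster contrast excludes cytokine-negative ring spots", {
  m <- matrix(0, 12, 3, dimnames = list(NULL, c("IL17A", "CD3D", "R1")))
  m[1, "IL17A"] <- 2
  m[, "CD3D"] <- 1
  ds <- make_flat_dataset(m)
  keys <- rownames(ds$counts)
  labels <- label_spots(ds, markers = "CD3D", cytokines = "IL17A")
  cl <- structure(list(cluster_id = "c", sample_id = "S01", radius = 1L,
                       seed_spots = keys[1], ring_spots = keys[2:4]),
                  class = "density_cluster")
  cond <- contrast_noncluster(ds, labels, list(cl), "IL17A")
  expect_true(cond[[keys[1]]])
  expect_false(any(keys[2:4] %in% names(cond)))   # ring, cytokine-negative
  expect_setequal(names(cond)[!cond], keys[5:12])
  # with no clusters, negatives are all cytokine-negative epidermal spots
  cond0 <- contrast_noncluster(ds, labels, list(), "IL17A")
  expect_setequal(names(cond0)[!cond0], keys[2:12])
})
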