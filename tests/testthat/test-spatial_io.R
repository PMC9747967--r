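test_that("save/load round-trips counts, coordinates, annotations and metadata", {
  sim <- simulate_dataset(tiny_sim_config(seed = 2, n_samples = 2L))
  ds <- sim$dataset
  dir <- withr::local_tempdir()
  save_dataset(ds, dir)
  back <- load_dataset(dir)
  keys <- sort(rownames(ds$counts))
  genes <- sort(colnames(ds$counts))
  expect_equal(as.matrix(back$counts[keys, genes]),
               as.matrix(ds$counts[keys, genes]))
  sp <- ds$spots[match(keys, ds$spots$key), ]
  bp <- back$spots[match(keys, back$spots$key), ]
  expect_equal(bp$array_row, sp$array_row)
  expect_equal(bp$array_col, sp$array_col)
  expect_equal(bp$layer, sp$layer)
  expect_equal(back$meta, ds$meta, ignore_attr = TRUE)
})

test_that("saving is deterministic: two writes are byte-identical", {
  sim <- simulate_dataset(tiny_sim_config(seed = 4, n_samples = 2L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  save_dataset(sim$dataset, d1)
  save_dataset(sim$dataset, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("a one-spot one-gene dataset writes the single MTX entry '1 1 5'", {
  m <- matrix(5, 1, 1, dimnames = list("S01:BC0001", "GENE1"))
  spots <- data.frame(barcode = "BC0001", sample_id = "S01", in_tissue = 1L,
                      array_row = 0L, array_col = 0L,
                      layer = "basal epidermis")
  meta <- data.frame(sample_id = "S01", patient_id = "P1",
                     project_id = "pr1", disease = "none",
                     condition = "lesional")
  ds <- spot_dataset(Matrix::Matrix(m, sparse = TRUE), spots, meta)
  dir <- withr::local_tempdir()
  save_dataset(ds, dir)
  mtx <- readLines(file.path(dir, "S01", "matrix.mtx"))
  expect_equal(mtx[[3]], "1 1 5")
  back <- load_dataset(dir)
  expect_equal(as.numeric(back$counts[1, 1]), 5)
})

test_that("parity violations and unknown layers are fatal with specifics", {
  spots <- data.frame(barcode = c("A", "B"), sample_id = "S01",
                      in_tissue = 1L, array_row = c(1L, 0L),
                      array_col = c(2L, 0L),
                      layer = "basal epidermis")
  m <- matrix(1, 2, 1, dimnames = list(c("S01:A", "S01:B"), "G"))
  meta <- data.frame(sample_id = "S01", patient_id = "P1",
                     project_id = "pr1", disease = "none",
                     condition = "lesional")
  expect_error(spot_dataset(m, spots, meta), "S01:A")
  spots$array_row <- c(2L, 0L)
  spots$layer <- c("basal epidermis", "stratum corneum")
  expect_error(spot_dataset(m, spots, meta), "stratum corneum")
})

test_that("missing files are fatal and name the file", {
  dir <- withr::local_tempdir()
  expect_error(load_dataset(file.path(dir, "nope")), "not found")
  sim <- simulate_dataset(tiny_sim_config(seed = 6, n_samples = 2L))
  save_dataset(sim$dataset, dir)
  unlink(file.path(dir, "S01", "barcodes.tsv"))
  expect_error(load_dataset(dir), "barcodes.tsv")
})

test_that("positions files with and without header are both read", {
  sim <- simulate_dataset(tiny_sim_config(seed = 7, n_samples = 2L))
  dir <- withr::local_tempdir()
  save_dataset(sim$dataset, dir)
  pos_path <- file.path(dir, "S01", "tissue_positions_list.csv")
  pos <- read.csv(pos_path, header = FALSE)
  names(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row_in_fullres", "pxl_col_in_fullres")
  write.csv(pos, pos_path, row.names = FALSE, quote = FALSE)  # headered dialect
  back <- load_dataset(dir)
  expect_equal(nrow(back$counts), nrow(sim$dataset$counts))
})

test_that("cluster tables have the fixed column order and pass sums through", {
  cols <- c("cluster_id", "sample_id", "radius", "n_seed_spots",
            "n_ring_spots", "cytokine_count", "responder_count", "weight")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cluster_table(list(), path)
  empty <- read.csv(path)
  expect_equal(names(empty), cols)
  expect_equal(nrow(empty), 0)
  cl <- structure(list(cluster_id = "S01:1:k", sample_id = "S01",
                       radius = 1L, seed_spots = "k",
                       ring_spots = c("a", "b"), cytokine_count = 2,
                       responder_count = 40, weight = 2),
                  class = "density_cluster")
  write_cluster_table(list(cl), path)
  tab <- read.csv(path)
  expect_equal(names(tab), cols)
  expect_equal(tab$cytokine_count, 2)
  expect_equal(tab$responder_count, 40)
  expect_equal(tab$n_ring_spots, 2)
})

test_that("empty datasets survive the round trip", {
  m <- matrix(0, 1, 2, dimnames = list("S01:B1", c("G1", "G2")))
  spots <- data.frame(barcode = "B1", sample_id = "S01", in_tissue = 1L,
                      array_row = 0L, array_col = 0L,
                      layer = "basal epidermis")
  meta <- data.frame(sample_id = "S01", patient_id = "P1",
                     project_id = "pr1", disease = "none",
                     condition = "lesional")
  ds <- spot_dataset(Matrix::Matrix(m, sparse = TRUE), spots, meta)
  dir <- withr::local_tempdir()
  save_dataset(ds, dir)
  back <- load_dataset(dir)
  expect_equal(sum(back$counts), 0)
  expect_equal(dim(back$counts), c(1L, 2L))
})
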