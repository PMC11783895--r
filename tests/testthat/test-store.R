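# HDF5 feature storage: round trips, index contracts, loaders, throughput.

test_that("homogeneous collections round-trip and reject mixed shapes", {
  st <- create_store(tempfile(fileext = ".h5"))
  ents <- lapply(1:10, function(i) array(sample(0:255, 27, TRUE),
                                         dim = c(3, 3, 3)))
  write_homogeneous(st, "vox", ents, rep("ALA", 10))
  expect_equal(n_entries(st, "vox"), 10L)
  for (i in c(1, 7, 10))
    expect_identical(read_entry(st, "vox", i),
                     array(as.numeric(ents[[i]]), c(3, 3, 3)))
  expect_error(read_entry(st, "vox", 11), "range")
  st2 <- create_store(tempfile(fileext = ".h5"))
  bad <- c(ents[1:2], list(array(0, c(2, 2, 2))))
  expect_error(write_homogeneous(st2, "vox", bad, rep("ALA", 3)), "shape")
})

test_that("heterogeneous collections obey the prefix-sum index contract", {
  st <- create_store(tempfile(fileext = ".h5"))
  lens <- c(17L, 20L, 22L)
  ents <- lapply(lens, function(n) matrix(sample(0:99, n * 3, TRUE), n, 3))
  write_heterogeneous(st, "coord", ents, c("PRO", "MET", "LEU"))
  m <- flexfrag:::.collection_meta(st, "coord")
  expect_equal(m$start, c(0L, 17L, 37L))
  expect_equal(m$end, c(17L, 37L, 59L))
  expect_equal(m$end[-3], m$start[-1])
  expect_equal(m$end[3], sum(lens))
  for (i in 1:3)
    expect_identical(unname(read_entry(st, "coord", i)),
                     matrix(as.numeric(ents[[i]]), lens[i], 3))
  st2 <- create_store(tempfile(fileext = ".h5"))
  expect_error(write_heterogeneous(st2, "c", list(matrix(0, 2, 3),
                                                  matrix(0, 2, 4)),
                                   c("A", "B")), "second dimension")
  # single entry: start 0, end = its length
  st3 <- create_store(tempfile(fileext = ".h5"))
  write_heterogeneous(st3, "c", list(matrix(1, 5, 3)), "GLY")
  m3 <- flexfrag:::.collection_meta(st3, "c")
  expect_equal(m3$start, 0L)
  expect_equal(m3$end, 5L)
})

test_that("labels round-trip through the id/code tables", {
  st <- create_store(tempfile(fileext = ".h5"))
  labs <- c("SER", "ALA", "SER", "GLY")
  write_homogeneous(st, "x", lapply(1:4, function(i) matrix(i, 2, 2)), labs)
  expect_equal(read_labels(st), labs)
})

test_that("loader epochs cover every entry once, invariant to workers", {
  st <- create_store(tempfile(fileext = ".h5"))
  write_homogeneous(st, "x", lapply(1:10, function(i) matrix(i, 2, 2)),
                    rep(c("A", "B"), 5))
  collect <- function(workers, seed) {
    it <- iterate_batches(st, "x", batch_size = 3L, workers = workers,
                          seed = seed)
    idx <- integer(0); sizes <- integer(0)
    while (!is.null(b <- it())) {
      idx <- c(idx, b$indices)
      sizes <- c(sizes, length(b$features))
    }
    list(idx = idx, sizes = sizes)
  }
  r1 <- collect(1L, 5)
  expect_equal(r1$sizes, c(3L, 3L, 3L, 1L))
  expect_setequal(r1$idx, 1:10)
  r4 <- collect(4L, 5)
  expect_identical(r4$idx, r1$idx)      # workers change throughput only
  r_other <- collect(1L, 6)
  expect_setequal(r_other$idx, 1:10)
  expect_false(identical(r_other$idx, r1$idx))
  expect_error(iterate_batches(st, "nope", 2L), "unknown")
})

test_that("throughput benchmark is definitionally consistent", {
  st <- create_store(tempfile(fileext = ".h5"))
  write_homogeneous(st, "vox", lapply(1:40, function(i) array(i, c(8, 8, 8))),
                    rep("ALA", 40))
  r <- benchmark_throughput(st, "vox", cores = 1L, batch_size = 16L,
                            repeats = 10L)
  expect_length(r$epoch_times, 10L)
  expect_equal(r$bits_per_s, r$samples_per_s * r$entry_bits)
  expect_equal(r$entry_bits, 8^3 * 32)
  # voxel entries carry exactly twice the values of hilbert images
  expect_equal(prod(c(32, 32, 32)), 2 * prod(c(128, 128)))
})

test_that("featurized collections keep label alignment with coordinates", {
  st <- generate_dataset(c("ALA", "GLY"), 3, seed = 11,
                         path = tempfile(fileext = ".h5"))
  featurize_store(st, "voxel")
  expect_equal(n_entries(st, "voxel"), 6L)
  v4 <- read_entry(st, "voxel", 4)
  direct <- unclass(voxelize(read_fragment(st, 4)))
  expect_equal(v4, direct, tolerance = 1e-6,  # 32-bit storage rounding
               ignore_attr = TRUE)
})
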