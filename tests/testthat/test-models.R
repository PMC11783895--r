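# Baseline classifiers and the fixed training protocol.

test_that("learning-rate schedule matches its closed form", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 0.001)
  expect_equal(lr_at_epoch(cfg, 29), 0.001)
  expect_equal(lr_at_epoch(cfg, 30), 0.0005)
  expect_equal(lr_at_epoch(cfg, 119), 0.000125)
  for (e in 0:119)
    expect_equal(lr_at_epoch(cfg, e), 0.001 * 0.5^(e %/% 30))
  expect_error(lr_at_epoch(cfg, -1), "nonnegative")
  expect_error(train_config(early_stop_acc = 101), "early_stop_acc")
})

test_that("models produce the requested class dimension and finite scores", {
  m20 <- build_model("voxnet_prelu", 20, width = 0.25, seed = 1)
  z <- matrix(0, 32^3, 1)
  s <- model_forward(m20, z)
  expect_equal(dim(s), c(20L, 1L))
  expect_true(all(is.finite(s)))
  m400 <- build_model("resnet18_1ch", 400, width = 0.1, seed = 2)
  s2 <- model_forward(m400, matrix(rnorm(128^2), ncol = 1))
  expect_equal(nrow(s2), 400L)
  expect_true(all(is.finite(s2)))
  mp <- build_model("pointnet_like", 20, input_shape = 24L, width = 0.5,
                    seed = 3)
  s3 <- model_forward(mp, matrix(rnorm(72 * 2), ncol = 2))
  expect_equal(dim(s3), c(20L, 2L))
  expect_error(build_model("alexnet", 20), "arg")
})

test_that("pointnet scores are invariant to point permutation", {
  mp <- build_model("pointnet_like", 5, input_shape = 10L, seed = 4)
  pts <- matrix(rnorm(30), 10, 3)
  perm <- pts[sample.int(10), ]
  s1 <- model_forward(mp, matrix(as.numeric(t(pts)), ncol = 1))
  s2 <- model_forward(mp, matrix(as.numeric(t(perm)), ncol = 1))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("training is deterministic and early-stops on separable data", {
  set.seed(5)
  # linearly separable toy: two blobs in a small voxel space
  n <- 40
  x1 <- matrix(rnorm(n * 12^3, 0, 0.3), ncol = n)
  x2 <- matrix(rnorm(n * 12^3, 1.5, 0.3), ncol = n)
  dat <- list(x = cbind(x1, x2), y = rep(1:2, each = n))
  run <- function() {
    m <- build_model("voxnet_prelu", 2, input_shape = 12L, width = 0.2,
                     seed = 6)
    train(m, dat, dat, train_config(epochs = 30, seed = 7))
  }
  m1 <- run()
  h1 <- attr(m1, "history")
  expect_lt(nrow(h1), 30)                       # early stop triggered
  expect_gt(tail(h1$test_acc, 1), 99.5)
  m2 <- run()
  expect_identical(attr(m2, "history"), h1)     # same seed, same run
  # shape mismatch rejected before the first epoch
  bad <- list(x = matrix(0, 10, 4), y = rep(1L, 4))
  m <- build_model("voxnet_prelu", 2, input_shape = 12L, width = 0.2)
  expect_error(train(m, bad, bad, train_config(epochs = 1)), "shape")
})

test_that("evaluate reports accuracy consistent with its confusion matrix", {
  set.seed(8)
  m <- build_model("pointnet_like", 3, input_shape = 5L, width = 0.3,
                   seed = 9)
  dat <- list(x = matrix(rnorm(15 * 30), ncol = 30), y = sample(3, 30, TRUE))
  ev <- evaluate(m, dat)
  expect_equal(dim(ev$confusion), c(3L, 3L))
  expect_equal(rowSums(ev$confusion), as.vector(table(factor(dat$y, 1:3))))
  expect_equal(ev$accuracy, 100 * sum(diag(ev$confusion)) / 30)
  expect_error(evaluate(m, list(x = matrix(0, 15, 0), y = integer(0))),
               "empty")
})

test_that("dual confusion lumping marginalizes and conserves counts", {
  codes <- as.vector(outer(standard_residues(), standard_residues(),
                           paste0))
  # identity matrix stays diagonal
  I400 <- diag(400)
  dimnames(I400) <- list(codes, codes)
  l1 <- lump_dual_confusion(I400, 1)
  expect_equal(l1, diag(20, 20) * 1, ignore_attr = TRUE)
  expect_equal(sum(l1), sum(I400))
  # crafted off-diagonal: true METGLY predicted GLNGLY, count 7
  M <- matrix(0, 400, 400, dimnames = list(codes, codes))
  M["METGLY", "GLNGLY"] <- 7
  p1 <- lump_dual_confusion(M, 1)
  expect_equal(p1["MET", "GLN"], 7)
  expect_equal(sum(p1), 7)
  p2 <- lump_dual_confusion(M, 2)
  expect_equal(p2["GLY", "GLY"], 7)
  expect_equal(sum(diag(p2)), 7)
  # totals agree between positions for random matrices
  set.seed(11)
  Mr <- matrix(rpois(160000, 0.05), 400, 400, dimnames = list(codes, codes))
  expect_equal(sum(lump_dual_confusion(Mr, 1)), sum(Mr))
  expect_equal(sum(lump_dual_confusion(Mr, 2)), sum(Mr))
  expect_error(lump_dual_confusion(Mr[1:20, 1:20], 1), "400")
})

test_that("a small voxel model separates synthetic residue classes", {
  dat <- fixture_voxel_xy(c("GLY", "TRP"), 30, seed = 21)
  tr <- list(x = dat$x[, c(1:20, 31:50)], y = dat$y[c(1:20, 31:50)])
  te <- list(x = dat$x[, c(21:30, 51:60)], y = dat$y[c(21:30, 51:60)])
  m <- build_model("voxnet_prelu", 2, width = 0.25, seed = 12)
  m <- train(m, tr, te, train_config(epochs = 6, seed = 13))
  expect_gt(tail(attr(m, "history")$test_acc, 1), 90)
})
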