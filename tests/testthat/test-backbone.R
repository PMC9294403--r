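test_that("backbone maps volume batches to nonnegative feature rows", {
  cfg <- backbone_config(channel_widths = rep(8L, 6), input_edge = 32)
  bb <- suppressMessages(build_backbone(cfg, seed = 1))
  set.seed(2)
  vols <- lapply(1:4, function(i) array(rnorm(32^3), dim = c(32, 32, 32)))
  f <- extract_features(bb, vols)
  expect_equal(dim(f), c(4, 8))
  expect_true(all(f >= 0))
  expect_true(all(is.finite(f)))
  # the real-data volume size works with the same pooling layout
  cfg28 <- backbone_config(channel_widths = rep(8L, 6), input_edge = 28)
  bb28 <- suppressMessages(build_backbone(cfg28, seed = 1))
  f28 <- extract_features(bb28, array(rnorm(28^3), dim = c(28, 28, 28)))
  expect_equal(dim(f28), c(1, 8))
  # zero volume: finite features, no NaN
  fz <- extract_features(bb, array(0, dim = c(32, 32, 32)))
  expect_true(all(is.finite(fz)))
})

test_that("evaluation-mode features are deterministic and batch-independent", {
  bb <- tiny_backbone(seed = 3)
  set.seed(4)
  vols <- lapply(1:6, function(i) array(rnorm(8^3), dim = c(8, 8, 8)))
  f1 <- extract_features(bb, vols)
  f2 <- extract_features(bb, vols)
  expect_identical(f1, f2)
  # same volume embedded alone or inside a batch: identical row
  alone <- extract_features(bb, vols[[3]])
  expect_equal(as.vector(alone), f1[3, ], tolerance = 1e-12)
  expect_error(extract_features(bb, array(0, c(9, 9, 9))), "edge")
})

test_that("pooling layouts that erase the volume are rejected", {
  expect_error(backbone_config(pool_blocks = 1:6, input_edge = 28),
               "below 1")
  expect_error(backbone_config(channel_widths = rep(8, 5)), "6")
})

test_that("linear head behaves like an affine softmax scorer", {
  f <- matrix(c(1, 2, 3, 4), 1, 4)
  w0 <- list(W = matrix(0, 3, 4), b = rep(0, 3))
  p <- fscc:::softmax_rows(linear_head(f, w0))
  expect_equal(as.vector(p), rep(1 / 3, 3))
  wfav <- list(W = rbind(rep(10, 4), rep(0, 4), rep(-10, 4)), b = rep(0, 3))
  expect_equal(which.max(linear_head(f, wfav)), 1L)
  s <- linear_head(f, wfav)
  expect_equal(fscc:::softmax_rows(s + 100), fscc:::softmax_rows(s))
  expect_error(linear_head(matrix(1, 1, 3), w0), "match")
})

test_that("compiled backward pass matches finite differences", {
  cfg <- tiny_backbone_config(edge = 8, width = 3, pools = c(1, 3))
  bb <- suppressMessages(build_backbone(cfg, seed = 5))
  set.seed(6)
  N <- 3
  x <- matrix(rnorm(8^3 * N), 8^3, N)
  pool <- 1:6 %in% cfg$pool_blocks
  wts <- matrix(rnorm(N * 3), N, 3)
  loss_of <- function(params) {
    f <- fscc:::cnn_forward_cpp(x, params, cfg$channel_widths, pool, 8, TRUE,
                                0.1, 1e-5, FALSE)$features
    sum(f * wts)
  }
  fw <- fscc:::cnn_forward_cpp(x, bb$params, cfg$channel_widths, pool, 8,
                               TRUE, 0.1, 1e-5, TRUE)
  gr <- fscc:::cnn_backward_cpp(wts, fw$cache, bb$params, cfg$channel_widths,
                                pool, 8, 1e-5)
  eps <- 1e-6
  set.seed(7)
  for (b in c(1, 2, 4, 6)) {
    for (field in c("W", "gamma", "beta")) {
      i <- sample(length(bb$params[[b]][[field]]), 1)
      pp <- bb$params; pp[[b]][[field]][i] <- pp[[b]][[field]][i] + eps
      pm <- bb$params; pm[[b]][[field]][i] <- pm[[b]][[field]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      ana <- gr[[b]][[field]][i]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = sprintf("grad block %d %s", b, field))
    }
  }
})

test_that("checkpoints round-trip through save/load", {
  bb <- tiny_backbone(seed = 8)
  path <- tempfile(fileext = ".rds")
  save_backbone(bb, path)
  back <- load_backbone(path)
  expect_equal(back$params, bb$params)
  expect_equal(back$config, bb$config)
  saveRDS(list(format = "other"), path)
  expect_error(load_backbone(path), "checkpoint")
})
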