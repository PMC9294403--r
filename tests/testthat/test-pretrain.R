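make_blob_volumes <- function(n_per_class, edge = 8, sep = 4, seed = 1) {
  # two classes of tiny volumes: bright centred blob vs corner blob
  set.seed(seed)
  sph <- generate_shape_density(list(type = "sphere", radius = 2.5), edge)
  shifted <- array(0, dim = c(edge, edge, edge))
  shifted[1:4, 1:4, 1:4] <- sph[3:6, 3:6, 3:6]
  vols <- list(); labels <- integer(0)
  for (cl in 0:1) {
    proto <- if (cl == 0) sph else shifted
    for (i in seq_len(n_per_class)) {
      vols[[length(vols) + 1]] <- proto * sep +
        array(rnorm(edge^3, sd = 0.3), dim = c(edge, edge, edge))
      labels <- c(labels, cl)
    }
  }
  list(volumes = vols, labels = labels)
}

test_that("a tiny pre-training run completes with finite logged losses", {
  d <- make_blob_volumes(8)
  bb <- fscc_pretrain(d$volumes, d$labels, tiny_backbone_config(),
                      pretrain_config(batch_size = 8, epochs = 1,
                                      learning_rate = 1e-3, seed = 1),
                      loss_config())
  expect_s3_class(bb, "fscc_backbone")
  expect_true(bb$trained)
  expect_named(bb$log, c("epoch", "batch", "ce", "scl", "total"))
  expect_true(all(is.finite(as.matrix(bb$log[, c("ce", "scl", "total")]))))
  expect_equal(bb$log$total, bb$log$ce + 0.05 * bb$log$scl)
})

test_that("pre-training separates a linearly separable two-class set", {
  d <- make_blob_volumes(10)
  bb <- fscc_pretrain(d$volumes, d$labels, tiny_backbone_config(),
                      pretrain_config(batch_size = 10, epochs = 30,
                                      learning_rate = 1e-3, seed = 2),
                      loss_config())
  pred <- predict(bb, d$volumes, type = "class")
  expect_equal(mean(pred == d$labels), 1.0)
})

test_that("pre-training is deterministic under a fixed seed", {
  d <- make_blob_volumes(6)
  run <- function() fscc_pretrain(
    d$volumes, d$labels, tiny_backbone_config(),
    pretrain_config(batch_size = 6, epochs = 2, learning_rate = 1e-3,
                    seed = 11), loss_config())
  b1 <- run(); b2 <- run()
  expect_identical(b1$log, b2$log)
  expect_identical(b1$params, b2$params)
})

test_that("degenerate base sets are rejected", {
  d <- make_blob_volumes(4)
  expect_error(fscc_pretrain(d$volumes[1:4], rep(0, 4),
                             tiny_backbone_config(),
                             pretrain_config(batch_size = 4, epochs = 1,
                                             seed = 1)),
               "2 base classes")
  expect_error(fscc_pretrain(d$volumes[c(1, 5)], c(0, 1),
                             tiny_backbone_config(),
                             pretrain_config(batch_size = 2, epochs = 1,
                                             seed = 1)),
               "2 samples")
})

test_that("the contrastive term tightens within-class feature similarity", {
  # direction of the contrastive-pre-training claim, as a majority vote
  # over seeds at small scale
  cfg <- tiny_backbone_config(edge = 8, width = 4)
  wins <- 0
  for (seed in 1:3) {
    d <- make_blob_volumes(8, seed = seed + 20)
    cos_within <- function(lambda) {
      bb <- fscc_pretrain(d$volumes, d$labels, cfg,
                          pretrain_config(batch_size = 8, epochs = 5,
                                          learning_rate = 1e-3, seed = seed),
                          loss_config(lambda_scl = lambda))
      f <- extract_features(bb, d$volumes)
      f <- f / pmax(sqrt(rowSums(f^2)), 1e-12)
      sims <- c()
      for (cl in 0:1) {
        rows <- f[d$labels == cl, ]
        cs <- tcrossprod(rows)
        sims <- c(sims, cs[upper.tri(cs)])
      }
      mean(sims)
    }
    if (cos_within(0.05) >= cos_within(0)) wins <- wins + 1
  }
  expect_gte(wins, 2)
})
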