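test_that("base statistics are the arithmetic mean and unbiased covariance", {
  X <- rbind(c(0, 0), c(2, 2))
  st <- compute_base_statistics(X, c(5, 5))
  expect_equal(st[["5"]]$mean, c(1, 1))
  expect_equal(st[["5"]]$cov, matrix(2, 2, 2))  # divisor n - 1
  expect_equal(st[["5"]]$n, 2)
  same <- compute_base_statistics(rbind(c(1, 2), c(1, 2), c(1, 2)), rep(0, 3))
  expect_equal(same[["0"]]$cov, matrix(0, 2, 2))
  expect_error(compute_base_statistics(rbind(c(1, 2)), 3), "fewer than 2")
})

test_that("base statistics match a plain-loop oracle on random instances", {
  set.seed(1)
  X <- matrix(rnorm(60 * 4), 60, 4)
  labels <- sample(0:4, 60, replace = TRUE)
  st <- compute_base_statistics(X, labels)
  oracle <- oracle_class_stats(X, labels)
  for (cl in names(oracle)) {
    expect_equal(max(abs(st[[cl]]$mean - oracle[[cl]]$mean)), 0,
                 tolerance = 1e-10)
    expect_equal(max(abs(st[[cl]]$cov - oracle[[cl]]$cov)), 0,
                 tolerance = 1e-10)
  }
})

test_that("Tukey transform matches its closed forms on each branch", {
  expect_equal(tukey_transform(c(0, 1.3, 7), 1), c(0, 1.3, 7))
  expect_equal(tukey_transform(c(4, 9), 0.5), c(2, 3))
  expect_equal(tukey_transform(c(1, exp(1)), 0), c(0, 1))
  expect_equal(tukey_transform(0, 0.5), 0)  # 0^0.5 = 0 is legal
  expect_equal(tukey_transform(0, 0), log(1e-6))  # epsilon floor
  expect_error(tukey_transform(c(-1, 2), 0.5), "nonnegative")
  m <- matrix(c(1, 4, 9, 16), 2, 2)
  expect_equal(tukey_transform(m, 0.5), sqrt(m))
})

test_that("nearest base-class selection agrees with a brute-force sort", {
  set.seed(2)
  st <- compute_base_statistics(matrix(rnorm(80 * 6), 80, 6),
                                rep(0:7, each = 10))
  v <- rnorm(6)
  sel <- select_nearest_base_classes(v, st, 3)
  d <- vapply(st, function(s) sqrt(sum((s$mean - v)^2)), 0)
  expect_equal(sel$classes, names(sort(d))[1:3])
  expect_equal(sel$distances, d)
  # exact hit: distance zero, class selected first
  hit <- select_nearest_base_classes(st[["4"]]$mean, st, 1)
  expect_equal(hit$classes, "4")
  expect_equal(unname(hit$distances["4"]), 0)
  expect_length(select_nearest_base_classes(v, st, 8)$classes, 8)
  expect_error(select_nearest_base_classes(v, st, 9), "k must be")
  # ties broken by ascending class id
  tied <- structure(list(`7` = list(mean = c(1, 0), cov = diag(2), n = 5),
                         `2` = list(mean = c(-1, 0), cov = diag(2), n = 5)),
                    class = "fscc_base_stats")
  expect_equal(select_nearest_base_classes(c(0, 0), tied, 1)$classes, "2")
})

test_that("calibration averages the selected statistics with the support", {
  st <- structure(list(
    a = list(mean = c(0, 0), cov = diag(2, 2), n = 10),
    b = list(mean = c(2, 2), cov = diag(4, 2), n = 10)),
    class = "fscc_base_stats")
  cal <- calibrate(c(1, 1), st, c("a", "b"), ridge_epsilon = 1e-6)
  expect_equal(cal$mu_prime, c(1, 1))  # (0,0) + (2,2) + (1,1) over 3
  expect_equal(diag(cal$sigma_prime), rep(3, 2), tolerance = 1e-5)
  expect_equal(cal$sigma_prime[1, 2], 0)
  # k = 1 fixed point: support equal to the base mean
  fix <- calibrate(c(0, 0), st, "a")
  expect_equal(fix$mu_prime, c(0, 0))
  expect_equal(fix$sigma_prime, diag(2, 2) + diag(2e-6, 2), tolerance = 1e-9)
  # set semantics: selection order irrelevant
  cal2 <- calibrate(c(1, 1), st, c("b", "a"), ridge_epsilon = 1e-6)
  expect_equal(cal2$mu_prime, cal$mu_prime)
  expect_equal(cal2$sigma_prime, cal$sigma_prime)
  expect_error(calibrate(c(1, 1), st, character(0)), "empty")
  expect_error(calibrate(c(1, 1), st, "z"), "not among")
})

test_that("calibration matches an independent plain-loop oracle", {
  set.seed(3)
  for (rep in 1:20) {
    d <- sample(2:8, 1)
    nb <- sample(3:8, 1)
    X <- matrix(rnorm(nb * 12 * d), nb * 12, d)
    labels <- rep(seq_len(nb) - 1, each = 12)
    st <- compute_base_statistics(X, labels)
    v <- rnorm(d)
    k <- sample(seq_len(nb), 1)
    sel <- select_nearest_base_classes(v, st, k)
    cal <- calibrate(v, st, sel$classes, ridge_epsilon = 1e-12)
    # oracle: loops over the selected classes
    mu <- v
    for (cl in sel$classes) mu <- mu + st[[cl]]$mean
    mu <- mu / (k + 1)
    S <- matrix(0, d, d)
    for (cl in sel$classes) S <- S + st[[cl]]$cov
    S <- S / k
    expect_equal(max(abs(cal$mu_prime - mu)), 0, tolerance = 1e-10)
    expect_equal(max(abs(cal$sigma_prime - S)), 0, tolerance = 1e-8)
  }
})

test_that("calibrated sampling reproduces the requested Gaussian", {
  st <- structure(list(
    a = list(mean = c(1, 2, 3), cov = diag(c(1, 2, 0.5)), n = 50),
    b = list(mean = c(2, 1, 4), cov = diag(c(2, 1, 1.5)), n = 50)),
    class = "fscc_base_stats")
  cal <- calibrate(c(1.5, 1.5, 3.5), st, c("a", "b"))
  expect_equal(nrow(sample_calibrated_features(cal, 0)), 0)
  s1 <- sample_calibrated_features(cal, 50, seed = 4)
  expect_identical(s1, sample_calibrated_features(cal, 50, seed = 4))
  big <- sample_calibrated_features(cal, 10000, seed = 5)
  se <- sqrt(diag(cal$sigma_prime) / 10000)
  expect_true(all(abs(colMeans(big) - cal$mu_prime) < 3 * se))
  expect_lt(sqrt(sum((cov(big) - cal$sigma_prime)^2)),
            0.05 * sqrt(sum(cal$sigma_prime^2)))
  # degenerate covariance: all samples at the mean
  degen <- cal
  degen$sigma_prime <- diag(1e-18, 3)
  d0 <- sample_calibrated_features(degen, 20, seed = 6)
  expect_equal(max(abs(sweep(d0, 2, cal$mu_prime))), 0, tolerance = 1e-8)
  # non-PSD covariance is reported with its smallest eigenvalue
  bad <- cal
  bad$sigma_prime <- diag(c(1, -0.5, 1))
  expect_error(sample_calibrated_features(bad, 5, seed = 1),
               "positive definite")
})

test_that("calibrated retraining augments the support as specified", {
  bench <- small_benchmark(seed = 9)
  bs <- compute_base_statistics(bench$base$features, bench$base$labels)
  sup_idx <- vapply(8:12, function(cl)
    which(bench$novel$labels == cl)[1], 0L)
  sup_x <- bench$novel$features[sup_idx, ]
  sup_y <- bench$novel$labels[sup_idx]
  cfg <- calibration_config(tukey_lambda = 1, n_sampled_per_support = 150,
                            seed = 2)
  clf <- train_calibrated_classifier(sup_x, sup_y, bs, cfg)
  expect_equal(clf$n_train, 5 * (1 + 150))  # 5-way-1-shot bookkeeping
  expect_equal(clf$classes, 8:12)
  # ablation limit: no sampling trains on the transformed support alone
  cfg0 <- calibration_config(tukey_lambda = 1, n_sampled_per_support = 0,
                             seed = 2)
  clf0 <- train_calibrated_classifier(sup_x, sup_y, bs, cfg0)
  expect_equal(clf0$n_train, 5)
  expect_error(train_calibrated_classifier(sup_x[, 1:4], sup_y, bs, cfg),
               "dimension")
  expect_error(train_calibrated_classifier(sup_x, rep(0, 5), bs, cfg),
               "overlap")
})

test_that("a 2-way-1-shot classifier separates well-separated classes", {
  bench <- generate_feature_benchmark(feature_benchmark_config(
    n_base_classes = 4, n_novel_classes = 2, dim = 8,
    class_mean_scale = 4, within_class_cov_scale = 0.3,
    novel_from_base_mixture = FALSE,
    samples_per_base_class = 100, samples_per_novel_class = 60, seed = 10))
  bs <- compute_base_statistics(bench$base$features, bench$base$labels)
  accs <- vapply(1:5, function(s) {
    task <- sample_episode(bench$novel$labels, 2, 1, q_queries = 20, seed = s)
    evaluate_fscc(bench$novel$features, bench$novel$labels, task, bs,
                  calibration_config(tukey_lambda = 1, seed = s))$accuracy
  }, 0)
  expect_gt(mean(accs), 0.9)
})
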