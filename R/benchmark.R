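#' Feature-space Gaussian benchmark configuration
#'
#' Configuration for a pure feature-space benchmark used to exercise
#' distribution calibration in isolation: base-class features are drawn from
#' per-class multivariate Gaussians whose means are shifted so the feature
#' support is nonnegative (the domain of the Tukey power transform), and
#' novel-class means can be constructed as averages of two base means — the
#' regime in which transferring base-class statistics is justified.
#'
#' @param n_base_classes number of base classes (default 8).
#' @param n_novel_classes number of novel classes (default 5).
#' @param dim feature dimensionality (>= 2, default 16).
#' @param samples_per_base_class draws per base class (default 200).
#' @param samples_per_novel_class draws per novel class available for
#'   episode sampling (default 100).
#' @param class_mean_scale standard deviation of the class-mean draw
#'   (default 1): controls the spread of class centres.
#' @param within_class_cov_scale within-class variance scale (default 1).
#'   Together with `class_mean_scale` this sets the task difficulty; the
#'   defaults put a 1-shot linear classifier in the moderate-accuracy regime
#'   rather than at ceiling.
#' @param novel_from_base_mixture if `TRUE` (default) each novel mean is the
#'   average of 2 randomly chosen distinct base means (sources recorded).
#' @param seed integer seed.
#' @return an object of class `fscc_benchmark_config`.
#' @export
feature_benchmark_config <- function(n_base_classes = 8, n_novel_classes = 5,
                                     dim = 16, samples_per_base_class = 200,
                                     samples_per_novel_class = 100,
                                     class_mean_scale = 1,
                                     within_class_cov_scale = 1,
                                     novel_from_base_mixture = TRUE,
                                     seed = 1) {
  if (dim < 2) .fscc_stop("dim must be >= 2")
  if (class_mean_scale <= 0 || within_class_cov_scale < 0)
    .fscc_stop("scales must be positive (within_class_cov_scale may be 0)")
  if (n_base_classes < 2) .fscc_stop("need >= 2 base classes")
  structure(list(n_base_classes = as.integer(n_base_classes),
                 n_novel_classes = as.integer(n_novel_classes),
                 dim = as.integer(dim),
                 samples_per_base_class = as.integer(samples_per_base_class),
                 samples_per_novel_class = as.integer(samples_per_novel_class),
                 class_mean_scale = class_mean_scale,
                 within_class_cov_scale = within_class_cov_scale,
                 novel_from_base_mixture = isTRUE(novel_from_base_mixture),
                 seed = as.integer(seed)),
            class = "fscc_benchmark_config")
}

#' Generate a feature-space Gaussian benchmark
#'
#' Base-class means are drawn i.i.d. Gaussian with scale
#' `class_mean_scale`, then all means are shifted by a common vector so that
#' every mean coordinate is at least four within-class standard deviations
#' above zero; drawn features are finally clipped at zero (a rare event
#' under that margin), keeping the feature support nonnegative as required
#' by the Tukey transform. Per-class covariances are isotropic with a mild
#' per-class scale factor between 0.8 and 1.2; a mixture novel class
#' inherits the average of its two source covariances.
#'
#' @param config an [feature_benchmark_config()] object.
#' @return list with components `base` (`features` matrix, `labels`
#'   `0..n_base-1`), `novel` (`features`, `labels` numbered after the base
#'   classes), and `truth` (`base_means`, `novel_means`, `base_covs`,
#'   `novel_covs`, `novel_sources`).
#' @export
generate_feature_benchmark <- function(config) {
  stopifnot(inherits(config, "fscc_benchmark_config"))
  set.seed(config$seed)
  d <- config$dim
  nb <- config$n_base_classes
  nn <- config$n_novel_classes
  base_means <- matrix(rnorm(nb * d, sd = config$class_mean_scale), nb, d)
  base_sd2 <- config$within_class_cov_scale * runif(nb, 0.8, 1.2)
  novel_sources <- NULL
  if (config$novel_from_base_mixture) {
    novel_sources <- t(vapply(seq_len(nn),
                              function(i) sort(sample(nb, 2)), integer(2)))
    novel_means <- (base_means[novel_sources[, 1], , drop = FALSE] +
                    base_means[novel_sources[, 2], , drop = FALSE]) / 2
    novel_sd2 <- (base_sd2[novel_sources[, 1]] + base_sd2[novel_sources[, 2]]) / 2
  } else {
    novel_means <- matrix(rnorm(nn * d, sd = config$class_mean_scale), nn, d)
    novel_sd2 <- config$within_class_cov_scale * runif(nn, 0.8, 1.2)
  }
  # shift so every mean coordinate clears zero by 4 within-class sd
  margin <- 4 * sqrt(max(c(base_sd2, novel_sd2, 0)))
  shift <- margin - min(base_means, novel_means)
  if (shift > 0) {
    base_means <- base_means + shift
    novel_means <- novel_means + shift
  }
  draw <- function(means, sd2, count) {
    n_cl <- nrow(means)
    feats <- matrix(0, n_cl * count, d)
    labs <- integer(n_cl * count)
    for (i in seq_len(n_cl)) {
      rows <- (i - 1) * count + seq_len(count)
      feats[rows, ] <- matrix(rnorm(count * d, sd = sqrt(sd2[i])), count, d,
                              byrow = TRUE) +
        matrix(means[i, ], count, d, byrow = TRUE)
      labs[rows] <- i - 1L
    }
    feats[feats < 0] <- 0
    list(features = feats, labels = labs)
  }
  base <- draw(base_means, base_sd2, config$samples_per_base_class)
  novel <- draw(novel_means, novel_sd2, config$samples_per_novel_class)
  novel$labels <- novel$labels + nb
  base_covs <- lapply(base_sd2, function(s) diag(s, d))
  novel_covs <- lapply(novel_sd2, function(s) diag(s, d))
  list(base = base, novel = novel,
       truth = list(base_means = base_means, novel_means = novel_means,
                    base_covs = base_covs, novel_covs = novel_covs,
                    novel_sources = novel_sources))
}

#' Write a feature benchmark to plain-text tables
#'
#' Writes `base_features.csv`, `novel_features.csv` (features plus a label
#' column) and `truth_means.csv` under `dir`.
#'
#' @param bench result of [generate_feature_benchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_feature_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(part, path) {
    df <- as.data.frame(part$features)
    df$label <- part$labels
    write.csv(df, path, row.names = FALSE)
  }
  wr(bench$base, file.path(dir, "base_features.csv"))
  wr(bench$novel, file.path(dir, "novel_features.csv"))
  tm <- as.data.frame(rbind(bench$truth$base_means, bench$truth$novel_means))
  tm$class <- c(seq_len(nrow(bench$truth$base_means)),
                nrow(bench$truth$base_means) +
                  seq_len(nrow(bench$truth$novel_means))) - 1L
  write.csv(tm, file.path(dir, "truth_means.csv"), row.names = FALSE)
  invisible(dir)
}
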