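#' Calibration configuration
#'
#' Tunables of the stage-2 distribution calibration. `tukey_lambda` is the
#' Tukey ladder-of-powers exponent applied elementwise to the (nonnegative)
#' features to make them more Gaussian; 0.5 is the recommended value. Note
#' this is distinct from the pre-training loss weight, which is also
#' conventionally called lambda. `k_neighbors` base classes nearest to each
#' transformed support feature donate their statistics; 2 is the value used
#' in the distribution-calibration literature. Each support example yields
#' `n_sampled_per_support` synthetic features for classifier retraining.
#'
#' @param tukey_lambda power-transform exponent (default 0.5).
#' @param k_neighbors number of base classes transferred (default 2).
#' @param n_sampled_per_support synthetic feature draws per support example
#'   (default 150; 0 disables calibration-based augmentation).
#' @param ridge_epsilon relative diagonal regularization of the calibrated
#'   covariance: the ridge added is `ridge_epsilon * mean(diag(sigma))`
#'   (default 1e-6).
#' @param classifier_ridge ridge penalty of the multinomial logistic
#'   classifier retrained on the augmented features (default 1.0).
#' @param seed integer seed for feature sampling.
#' @return an object of class `fscc_calibration_config`.
#' @export
calibration_config <- function(tukey_lambda = 0.5, k_neighbors = 2,
                               n_sampled_per_support = 150,
                               ridge_epsilon = 1e-6, classifier_ridge = 1.0,
                               seed = 1) {
  if (k_neighbors < 1) .fscc_stop("k_neighbors must be >= 1")
  if (n_sampled_per_support < 0)
    .fscc_stop("n_sampled_per_support must be >= 0")
  if (ridge_epsilon <= 0) .fscc_stop("ridge_epsilon must be positive")
  structure(list(tukey_lambda = tukey_lambda,
                 k_neighbors = as.integer(k_neighbors),
                 n_sampled_per_support = as.integer(n_sampled_per_support),
                 ridge_epsilon = ridge_epsilon,
                 classifier_ridge = classifier_ridge,
                 seed = as.integer(seed)),
            class = "fscc_calibration_config")
}

#' Per-class mean and covariance of base-class features
#'
#' The Gaussian description of each base class: arithmetic mean and
#' unbiased covariance (divisor `n - 1`) of its feature vectors.
#'
#' @param features `N x D` matrix of base-class features.
#' @param labels length-N base class ids.
#' @return an object of class `fscc_base_stats`: named list (one element
#'   per class id) of lists `mean`, `cov`, `n`.
#' @export
compute_base_statistics <- function(features, labels) {
  features <- rbind(features)
  classes <- sort(unique(labels))
  out <- lapply(classes, function(cl) {
    X <- features[labels == cl, , drop = FALSE]
    if (nrow(X) < 2)
      .fscc_stop("base class ", cl, " has fewer than 2 samples")
    list(mean = colMeans(X), cov = cov(X), n = nrow(X))
  })
  names(out) <- as.character(classes)
  structure(out, class = "fscc_base_stats")
}

#' @export
print.fscc_base_stats <- function(x, ...) {
  d <- length(x[[1]]$mean)
  cat(sprintf("Base-class feature statistics: %d classes, dimension %d\n",
              length(x), d))
  for (cl in names(x))
    cat(sprintf("  class %s: n = %d\n", cl, x[[cl]]$n))
  invisible(x)
}

#' Write / read base statistics as plain-text JSON
#'
#' @param stats an `fscc_base_stats`.
#' @param path destination `.json` path.
#' @return `path` (write) or the restored `fscc_base_stats` (read).
#' @export
write_base_statistics <- function(stats, path) {
  stopifnot(inherits(stats, "fscc_base_stats"))
  jsonlite::write_json(lapply(stats, function(s)
    list(mean = s$mean, cov = s$cov, n = s$n)), path, digits = NA,
    auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_base_statistics
#' @export
read_base_statistics <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(s)
    list(mean = as.numeric(s$mean), cov = as.matrix(s$cov),
         n = as.integer(s$n)))
  structure(out, class = "fscc_base_stats")
}

#' Tukey ladder-of-powers transform
#'
#' Elementwise `v^lambda` for `lambda != 0` and `log(v)` for `lambda = 0`,
#' applied to nonnegative feature vectors to reduce skew before the Gaussian
#' calibration. Zeros are legal for positive exponents (`0^0.5 = 0`); for
#' `lambda <= 0` zero entries are floored at `1e-6` first.
#'
#' @param v numeric vector or matrix with nonnegative entries.
#' @param tukey_lambda the exponent (default 0.5).
#' @return transformed values, same shape.
#' @examples
#' tukey_transform(c(4, 9), 0.5)  # 2 3
#' @export
tukey_transform <- function(v, tukey_lambda = 0.5) {
  if (any(v < 0)) .fscc_stop("Tukey transform requires nonnegative entries")
  if (tukey_lambda == 0) return(log(pmax(v, 1e-6)))
  if (tukey_lambda < 0) v <- pmax(v, 1e-6)
  v^tukey_lambda
}

#' Select the base classes nearest to a transformed support feature
#'
#' Euclidean distances between the transformed support vector and every
#' base-class mean; the `k` smallest are selected, ties broken by ascending
#' class id.
#'
#' @param v_tilde transformed support feature vector.
#' @param base_stats an `fscc_base_stats`.
#' @param k number of classes to select (<= number of base classes).
#' @return list with `classes` (k selected ids, nearest first) and
#'   `distances` (named vector over all base classes).
#' @export
select_nearest_base_classes <- function(v_tilde, base_stats, k) {
  stopifnot(inherits(base_stats, "fscc_base_stats"))
  if (k < 1 || k > length(base_stats))
    .fscc_stop("k must be in [1, number of base classes]")
  d <- vapply(base_stats, function(s) sqrt(sum((s$mean - v_tilde)^2)), 0)
  ids <- names(base_stats)
  num <- suppressWarnings(as.numeric(ids))
  ord <- if (anyNA(num)) order(d, ids) else order(d, num)  # ties: ascending id
  list(classes = names(base_stats)[ord[seq_len(k)]],
       distances = d)
}

#' Calibrate the feature distribution of one novel support example
#'
#' The calibrated mean is the average of the `k` selected base means and
#' the transformed support feature itself (`k + 1` terms); the calibrated
#' covariance is the average of the `k` selected base covariances, plus a
#' diagonal ridge before any sampling.
#'
#' @param v_tilde transformed support feature.
#' @param base_stats an `fscc_base_stats`.
#' @param selected character vector of selected base class ids.
#' @param ridge_epsilon relative diagonal ridge (see
#'   [calibration_config()]).
#' @return an object of class `fscc_calibrated`: list with `mu_prime`,
#'   `sigma_prime` (ridge already added), `support_feature`,
#'   `selected_classes`.
#' @export
calibrate <- function(v_tilde, base_stats, selected,
                      ridge_epsilon = 1e-6) {
  stopifnot(inherits(base_stats, "fscc_base_stats"))
  selected <- as.character(selected)
  if (length(selected) == 0) .fscc_stop("empty base-class selection")
  if (!all(selected %in% names(base_stats)))
    .fscc_stop("selected ids not among the base classes")
  k <- length(selected)
  mu <- Reduce(`+`, lapply(base_stats[selected], `[[`, "mean"))
  mu_prime <- (mu + v_tilde) / (k + 1)
  sigma <- Reduce(`+`, lapply(base_stats[selected], `[[`, "cov")) / k
  # relative ridge; falls back to an absolute one when the donated
  # covariances are entirely degenerate (e.g. dead feature channels)
  md <- mean(diag(sigma))
  ridge <- ridge_epsilon * if (md > 0) md else 1
  sigma_prime <- sigma + diag(ridge, nrow(sigma))
  structure(list(mu_prime = mu_prime, sigma_prime = sigma_prime,
                 support_feature = v_tilde, selected_classes = selected),
            class = "fscc_calibrated")
}

#' Sample synthetic features from a calibrated distribution
#'
#' Independent multivariate Gaussian draws with mean `mu_prime` and
#' covariance `sigma_prime` (already ridge-regularized), via a Cholesky
#' factor; deterministic under the seed.
#'
#' @param calibrated an `fscc_calibrated`.
#' @param count number of draws (0 gives an empty matrix).
#' @param seed integer seed.
#' @return `count x D` matrix.
#' @export
sample_calibrated_features <- function(calibrated, count, seed = NULL) {
  stopifnot(inherits(calibrated, "fscc_calibrated"))
  d <- length(calibrated$mu_prime)
  if (count == 0) return(matrix(0, 0, d))
  L <- tryCatch(chol(calibrated$sigma_prime), error = function(e) {
    ev <- min(eigen(calibrated$sigma_prime, symmetric = TRUE,
                    only.values = TRUE)$values)
    .fscc_stop("calibrated covariance is not positive definite after ",
               "regularization (smallest eigenvalue ", format(ev), ")")
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  z <- matrix(rnorm(count * d), count, d)
  z %*% L + matrix(calibrated$mu_prime, count, d, byrow = TRUE)
}

# Multinomial logistic regression with ridge penalty, fitted to convergence
# with BFGS on the penalized mean cross-entropy. Deterministic (zero init).
fit_multinomial_ridge <- function(X, y_idx, C, ridge = 1.0, maxit = 500) {
  X <- rbind(X)
  n <- nrow(X); d <- ncol(X)
  unpack <- function(theta) {
    list(W = matrix(theta[seq_len(C * d)], C, d),
         b = theta[C * d + seq_len(C)])
  }
  obj <- function(theta) {
    p <- unpack(theta)
    scores <- X %*% t(p$W) + matrix(p$b, n, C, byrow = TRUE)
    m <- apply(scores, 1, max)
    lse <- m + log(rowSums(exp(scores - m)))
    mean(lse - scores[cbind(seq_len(n), y_idx)]) +
      0.5 * ridge * sum(p$W^2) / n
  }
  grad <- function(theta) {
    p <- unpack(theta)
    scores <- X %*% t(p$W) + matrix(p$b, n, C, byrow = TRUE)
    pr <- softmax_rows(scores)
    pr[cbind(seq_len(n), y_idx)] <- pr[cbind(seq_len(n), y_idx)] - 1
    dW <- crossprod(pr, X) / n + ridge * p$W / n
    db <- colSums(pr) / n
    c(as.vector(dW), db)
  }
  fit <- optim(rep(0, C * d + C), obj, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  unpack(fit$par)
}

#' Retrain the classifier for novel classes with distribution calibration
#'
#' For every support example: Tukey-transform its feature vector, select the
#' `k` nearest base classes, calibrate a Gaussian (mean and covariance)
#' against them, and sample `n_sampled_per_support` synthetic features
#' labeled with the example's class. A multinomial logistic classifier with
#' ridge penalty is then trained on the union of all transformed support
#' features and all sampled features. With `n_sampled_per_support = 0` this
#' reduces to training on the transformed support alone (the no-calibration
#' ablation).
#'
#' @param support_features `(N*K) x D` matrix of raw (nonnegative) support
#'   features.
#' @param support_labels novel class ids, one per support row.
#' @param base_stats an `fscc_base_stats` computed from base classes only.
#' @param config an [calibration_config()].
#' @return an object of class `fscc_classifier` with a [predict] method
#'   operating on raw features (queries are transformed internally with the
#'   same exponent).
#' @export
train_calibrated_classifier <- function(support_features, support_labels,
                                        base_stats,
                                        config = calibration_config()) {
  stopifnot(inherits(base_stats, "fscc_base_stats"),
            inherits(config, "fscc_calibration_config"))
  support_features <- rbind(support_features)
  d <- length(base_stats[[1]]$mean)
  if (ncol(support_features) != d)
    .fscc_stop("support feature dimension ", ncol(support_features),
               " does not match base statistics dimension ", d)
  novel_classes <- sort(unique(support_labels))
  overlap <- intersect(as.character(novel_classes), names(base_stats))
  if (length(overlap) > 0)
    .fscc_stop("novel classes overlap the base classes: ",
               paste(overlap, collapse = " "))
  set.seed(config$seed)
  Xs <- tukey_transform(support_features, config$tukey_lambda)
  parts_x <- list(Xs)
  parts_y <- list(support_labels)
  calibrations <- vector("list", nrow(Xs))
  if (config$n_sampled_per_support > 0) {
    for (i in seq_len(nrow(Xs))) {
      v <- Xs[i, ]
      sel <- select_nearest_base_classes(v, base_stats, config$k_neighbors)
      cal <- calibrate(v, base_stats, sel$classes, config$ridge_epsilon)
      calibrations[[i]] <- cal
      samp <- sample_calibrated_features(cal, config$n_sampled_per_support)
      parts_x[[length(parts_x) + 1]] <- samp
      parts_y[[length(parts_y) + 1]] <- rep(support_labels[i], nrow(samp))
    }
  }
  X <- do.call(rbind, parts_x)
  y <- unlist(parts_y)
  y_idx <- match(y, novel_classes)
  w <- fit_multinomial_ridge(X, y_idx, length(novel_classes),
                             ridge = config$classifier_ridge)
  structure(list(W = w$W, b = w$b, classes = novel_classes,
                 tukey_lambda = config$tukey_lambda, config = config,
                 calibrations = calibrations,
                 n_train = nrow(X)),
            class = "fscc_classifier")
}

#' @export
print.fscc_classifier <- function(x, ...) {
  cat(sprintf("Calibrated novel-class classifier: %d classes, dimension %d\n",
              length(x$classes), ncol(x$W)))
  cat(sprintf("  trained on %d points (Tukey lambda %.3g, k = %d, %d sampled per support)\n",
              x$n_train, x$tukey_lambda, x$config$k_neighbors,
              x$config$n_sampled_per_support))
  invisible(x)
}

#' @export
coef.fscc_classifier <- function(object, ...) {
  cbind(`(Intercept)` = object$b, object$W)
}

#' Classify query features with a calibrated classifier
#'
#' @param object an `fscc_classifier`.
#' @param newdata `N x D` matrix of raw (nonnegative) query features; they
#'   are Tukey-transformed with the classifier's exponent before scoring.
#' @param type `"class"` (default) or `"prob"`.
#' @param transform apply the Tukey transform to `newdata` (default `TRUE`;
#'   set `FALSE` if the features are already transformed).
#' @param ... unused.
#' @return predicted class ids, or an `N x C` probability matrix.
#' @export
predict.fscc_classifier <- function(object, newdata, type = c("class", "prob"),
                                    transform = TRUE, ...) {
  type <- match.arg(type)
  X <- rbind(newdata)
  if (transform) X <- tukey_transform(X, object$tukey_lambda)
  scores <- X %*% t(object$W) + matrix(object$b, nrow(X), length(object$b),
                                       byrow = TRUE)
  if (type == "prob") {
    p <- softmax_rows(scores)
    colnames(p) <- object$classes
    return(p)
  }
  object$classes[max.col(scores, ties.method = "first")]
}
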