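#' Conv-6 backbone configuration
#'
#' The feature extractor is six ConvBlocks, each a 3x3x3 convolution
#' (padding 1), batch normalization, ReLU, and an optional 2x2x2 max-pool
#' (stride 2); the final activations are globally average-pooled into one
#' nonnegative feature vector per volume. Pooling cannot be applied in all
#' six blocks for 28- or 32-voxel inputs (the spatial size would vanish),
#' so the default pools after blocks 1-4.
#'
#' @param channel_widths integer vector of 6 channel counts (default 64
#'   each). The feature dimension equals the last width (global average
#'   pooling).
#' @param pool_blocks blocks (subset of 1..6) followed by max-pooling;
#'   default `1:4`.
#' @param input_edge voxels per edge of the input volumes (28 or 32 for the
#'   standard extraction sizes; any value >= 8 with a positive pooled size
#'   is accepted).
#' @param normalize_input normalize each volume to zero mean, unit variance
#'   before the network (default `TRUE`; standard for low-SNR tomography
#'   inputs).
#' @param bn_momentum,bn_eps batch-normalization running-statistics momentum
#'   and variance floor.
#' @return an object of class `fscc_backbone_config`.
#' @export
backbone_config <- function(channel_widths = rep(64L, 6), pool_blocks = 1:4,
                            input_edge = 32, normalize_input = TRUE,
                            bn_momentum = 0.1, bn_eps = 1e-5) {
  channel_widths <- as.integer(channel_widths)
  if (length(channel_widths) != 6 || any(channel_widths < 1))
    .fscc_stop("channel_widths must be 6 positive counts")
  if (!all(pool_blocks %in% 1:6)) .fscc_stop("pool_blocks must be in 1..6")
  e <- as.integer(input_edge)
  for (b in 1:6) if (b %in% pool_blocks) e <- e %/% 2L
  if (e < 1)
    .fscc_stop("pooling layout reduces the spatial size below 1 voxel ",
               "for input_edge = ", input_edge)
  if (channel_widths[6] < 2)
    .fscc_stop("feature dimension (last channel width) must be >= 2")
  structure(list(channel_widths = channel_widths,
                 pool_blocks = sort(unique(as.integer(pool_blocks))),
                 input_edge = as.integer(input_edge),
                 feature_dim = channel_widths[6],
                 normalize_input = isTRUE(normalize_input),
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "fscc_backbone_config")
}

init_backbone_params <- function(config) {
  lapply(1:6, function(b) {
    cin <- if (b == 1) 1L else config$channel_widths[b - 1]
    cout <- config$channel_widths[b]
    fan_in <- cin * 27
    list(W = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in),
         b = rep(0, cout), gamma = rep(1, cout), beta = rep(0, cout),
         rmean = rep(0, cout), rvar = rep(1, cout))
  })
}

#' Build an (untrained) Conv-6 feature extractor
#'
#' Initializes the backbone parameters (He initialization for the
#' convolution kernels) and reports the parameter count.
#'
#' @param config an [backbone_config()] object.
#' @param seed integer seed for the parameter initialization.
#' @return an object of class `fscc_backbone` (untrained; see
#'   [fscc_pretrain()] for stage-1 training).
#' @export
build_backbone <- function(config = backbone_config(), seed = 1) {
  stopifnot(inherits(config, "fscc_backbone_config"))
  set.seed(as.integer(seed))
  obj <- structure(list(config = config, params = init_backbone_params(config),
                        head = NULL, classes = NULL, log = NULL,
                        trained = FALSE, seed = as.integer(seed)),
                   class = "fscc_backbone")
  message(sprintf("Conv-6 backbone built: %s parameters (feature dim %d)",
                  format(n_backbone_params(obj), big.mark = ","),
                  config$feature_dim))
  obj
}

n_backbone_params <- function(backbone) {
  n <- sum(vapply(backbone$params, function(p)
    length(p$W) + length(p$b) + length(p$gamma) + length(p$beta), 0))
  if (!is.null(backbone$head)) n <- n + length(backbone$head$W) +
      length(backbone$head$b)
  n
}

#' @export
print.fscc_backbone <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Conv-6 3D feature extractor (%s)\n",
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  input %d^3, channels %s, pooling after blocks %s\n",
              cfg$input_edge, paste(cfg$channel_widths, collapse = "-"),
              paste(cfg$pool_blocks, collapse = ",")))
  cat(sprintf("  feature dim %d, %s parameters\n", cfg$feature_dim,
              format(n_backbone_params(x), big.mark = ",")))
  if (!is.null(x$classes))
    cat("  classifier head over classes:", paste(x$classes, collapse = " "), "\n")
  invisible(x)
}

# Stack volumes (list of arrays, 3D array, or V x N matrix) into the V x N
# matrix the compiled forward pass expects, applying input normalization.
stack_volumes <- function(volumes, config) {
  e <- config$input_edge
  if (is.matrix(volumes)) {
    if (nrow(volumes) != e^3) .fscc_stop("volume size does not match input_edge")
    m <- volumes
  } else {
    if (is.array(volumes) && length(dim(volumes)) == 3) volumes <- list(volumes)
    ok <- vapply(volumes, function(v) length(dim(v)) == 3 && all(dim(v) == e),
                 TRUE)
    if (!all(ok))
      .fscc_stop("all volumes must be cubic arrays of edge ", e)
    m <- vapply(volumes, as.vector, numeric(e^3))
    if (!is.matrix(m)) m <- matrix(m, ncol = 1)
  }
  if (config$normalize_input) {
    mu <- colMeans(m)
    s <- sqrt(colMeans(m^2) - mu^2)
    s[s == 0] <- Inf  # constant volumes map to zeros
    m <- sweep(sweep(m, 2, mu), 2, s, "/")
  }
  m
}

#' Extract feature vectors from subtomogram volumes
#'
#' Runs the frozen extractor in evaluation mode (batch-normalization uses
#' running statistics, so each volume's features are independent of the
#' batch composition and deterministic).
#'
#' @param backbone an `fscc_backbone`.
#' @param volumes list of cubic arrays, a single array, or a `V x N` matrix
#'   of flattened volumes.
#' @param eval_mode use frozen normalization statistics (default `TRUE`).
#'   `FALSE` uses batch statistics and is only meaningful inside training.
#' @param batch_size volumes processed per compiled call (memory knob).
#' @return `N x feature_dim` matrix of nonnegative features.
#' @export
extract_features <- function(backbone, volumes, eval_mode = TRUE,
                             batch_size = 64) {
  stopifnot(inherits(backbone, "fscc_backbone"))
  cfg <- backbone$config
  x <- stack_volumes(volumes, cfg)
  n <- ncol(x)
  out <- matrix(0, n, cfg$feature_dim)
  pool <- 1:6 %in% cfg$pool_blocks
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- cnn_forward_cpp(x[, idx, drop = FALSE], backbone$params,
                          cfg$channel_widths, pool, cfg$input_edge,
                          train = !eval_mode, bn_momentum = cfg$bn_momentum,
                          bn_eps = cfg$bn_eps, want_cache = FALSE)
    out[idx, ] <- fw$features
  }
  out
}

#' @describeIn extract_features `predict` method: returns features
#'   (`type = "features"`), or base-class scores/labels when the backbone
#'   carries its pre-training classifier head.
#' @param object,newdata,type,... S3 method arguments.
#' @export
predict.fscc_backbone <- function(object, newdata,
                                  type = c("features", "scores", "class"),
                                  ...) {
  type <- match.arg(type)
  f <- extract_features(object, newdata)
  if (type == "features") return(f)
  if (is.null(object$head))
    .fscc_stop("backbone has no classifier head; run fscc_pretrain() first")
  scores <- f %*% t(object$head$W) + matrix(object$head$b, nrow(f),
                                            length(object$head$b), byrow = TRUE)
  colnames(scores) <- object$classes
  if (type == "scores") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Affine classifier head
#'
#' Maps feature vectors to one score per class; the softmax is applied
#' downstream by the losses.
#'
#' @param features `N x D` feature matrix.
#' @param weights list with `W` (`C x D`) and `b` (length `C`).
#' @return `N x C` score matrix.
#' @export
linear_head <- function(features, weights) {
  features <- rbind(features)
  if (ncol(features) != ncol(weights$W))
    .fscc_stop("feature length ", ncol(features),
               " does not match head weights ", ncol(weights$W))
  features %*% t(weights$W) +
    matrix(weights$b, nrow(features), nrow(weights$W), byrow = TRUE)
}

#' Save / load a backbone checkpoint
#'
#' The checkpoint is a single portable archive holding the configuration,
#' parameters, classifier head, training log and a format version field.
#'
#' @param backbone an `fscc_backbone`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `fscc_backbone` (load).
#' @export
save_backbone <- function(backbone, path) {
  stopifnot(inherits(backbone, "fscc_backbone"))
  saveRDS(list(format = "fscc_backbone", version = 1L,
               backbone = unclass(backbone)), path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "fscc_backbone"))
    .fscc_stop("not an fscc backbone checkpoint: ", path)
  structure(x$backbone, class = "fscc_backbone")
}
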