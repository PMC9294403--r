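#' Pre-training configuration
#'
#' Optimization settings for stage-1 training on the base classes. The
#' printed defaults follow the published setup for abundant synthetic data
#' (Adam, learning rate 0.05, batch 128, 5 epochs); the 0.05 learning rate
#' is unusually high for Adam and small runs typically converge better near
#' `1e-3`. For small datasets the corresponding published setting is batch
#' 32 with 50 epochs.
#'
#' @param batch_size samples per class-balanced mini-batch (default 128).
#' @param epochs training epochs (default 5).
#' @param learning_rate Adam step size (default 0.05; see Details).
#' @param optimizer only `"adam"` is implemented.
#' @param seed integer seed covering initialization and batch sampling.
#' @return an object of class `fscc_pretrain_config`.
#' @export
pretrain_config <- function(batch_size = 128, epochs = 5,
                            learning_rate = 0.05, optimizer = "adam",
                            seed = 1) {
  if (batch_size < 2) .fscc_stop("batch_size must be >= 2")
  if (epochs < 1) .fscc_stop("epochs must be >= 1")
  if (learning_rate <= 0) .fscc_stop("learning_rate must be positive")
  if (!identical(optimizer, "adam")) .fscc_stop("only the adam optimizer is implemented")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "fscc_pretrain_config")
}

# Adam over a flat list of numeric arrays.
adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- vector("list", length(p))
      names(out) <- names(p)
      mm <- m; vv <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out[[i]] <- r$p; mm[[i]] <- r$m; vv[[i]] <- r$v
      }
      list(p = out, m = mm, v = vv)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      list(p = p - lr * (m / b1t) / (sqrt(v / b2t) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

#' Stage-1 pre-training of the feature extractor on base classes
#'
#' Trains the Conv-6 extractor and a linear classifier head on the base
#' dataset with the weighted objective `L = L_CE + lambda_scl * L_SCL`:
#' cross-entropy on the head's softmax plus the supervised contrastive loss
#' on (L2-normalized copies of) the extracted features. Mini-batches are
#' class-balanced so every anchor has contrastive positives. The run is
#' deterministic under the configuration seed (up to the platform's
#' floating-point reproducibility).
#'
#' @param volumes base-class volumes: list of cubic arrays or a `V x N`
#'   matrix of flattened volumes.
#' @param labels integer class labels (>= 2 classes, each with >= 2
#'   samples).
#' @param backbone an `fscc_backbone_config` (a fresh backbone is built) or
#'   an existing `fscc_backbone` to continue training.
#' @param config an [pretrain_config()].
#' @param loss an [loss_config()].
#' @return a trained `fscc_backbone` whose `log` element is a data frame
#'   with per-batch `epoch`, `batch`, `ce`, `scl`, `total`.
#' @export
fscc_pretrain <- function(volumes, labels,
                          backbone = backbone_config(),
                          config = pretrain_config(),
                          loss = loss_config()) {
  stopifnot(inherits(config, "fscc_pretrain_config"),
            inherits(loss, "fscc_loss_config"))
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    .fscc_stop("pre-training needs at least 2 base classes")
  if (any(table(labels) < 2))
    .fscc_stop("every base class needs at least 2 samples")
  set.seed(config$seed)
  if (inherits(backbone, "fscc_backbone_config")) {
    cfg <- backbone
    backbone <- suppressMessages(build_backbone(cfg, seed = config$seed))
  } else {
    stopifnot(inherits(backbone, "fscc_backbone"))
    cfg <- backbone$config
  }
  x <- stack_volumes(volumes, cfg)
  D <- cfg$feature_dim
  C <- length(classes)
  head <- list(W = matrix(rnorm(C * D, sd = 0.01), C, D), b = rep(0, C))
  pool <- 1:6 %in% cfg$pool_blocks
  all_params <- list(blocks = backbone$params, head = head)
  opt <- adam_init(list(blocks = strip_running(all_params$blocks),
                        head = head))
  log <- list()
  row <- 0
  for (epoch in seq_len(config$epochs)) {
    batches <- class_balanced_batches(labels, config$batch_size)
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      xb <- x[, idx, drop = FALSE]
      yb <- match(labels[idx], classes)  # 1-based head indices
      fw <- cnn_forward_cpp(xb, all_params$blocks, cfg$channel_widths, pool,
                            cfg$input_edge, train = TRUE,
                            bn_momentum = cfg$bn_momentum,
                            bn_eps = cfg$bn_eps, want_cache = TRUE)
      # forward pass updates the batch-norm running statistics
      for (b in 1:6) {
        all_params$blocks[[b]]$rmean <- fw$running[[b]]$rmean
        all_params$blocks[[b]]$rvar <- fw$running[[b]]$rvar
      }
      feats <- fw$features
      nB <- length(idx)
      scores <- linear_head(feats, all_params$head)
      probs <- softmax_rows(scores)
      ce <- cross_entropy_loss(probs, yb)
      scl_res <- withCallingHandlers(
        supervised_contrastive_loss(feats, yb, tau = loss$tau,
                                    normalize = loss$normalize_embeddings,
                                    grad = TRUE),
        warning = function(w) invokeRestart("muffleWarning"))
      total <- combined_loss(ce, scl_res$loss, loss$lambda_scl)
      # gradients: CE through the head, SCL directly on the features
      dscore <- probs
      dscore[cbind(seq_len(nB), yb)] <- dscore[cbind(seq_len(nB), yb)] - 1
      dscore <- dscore / nB
      dhead_W <- crossprod(dscore, feats)
      dhead_b <- colSums(dscore)
      dfeat <- dscore %*% all_params$head$W +
        loss$lambda_scl * scl_res$grad
      block_grads <- cnn_backward_cpp(dfeat, fw$cache, all_params$blocks,
                                      cfg$channel_widths, pool,
                                      cfg$input_edge, cfg$bn_eps)
      grads <- list(blocks = lapply(block_grads, function(g)
        list(W = g$W, b = as.vector(g$b), gamma = as.vector(g$gamma),
             beta = as.vector(g$beta))),
        head = list(W = dhead_W, b = dhead_b))
      trainable <- list(blocks = strip_running(all_params$blocks),
                        head = all_params$head)
      st <- adam_step(trainable, grads, opt, lr = config$learning_rate)
      opt <- st$state
      for (b in 1:6) {
        all_params$blocks[[b]]$W <- st$params$blocks[[b]]$W
        all_params$blocks[[b]]$b <- st$params$blocks[[b]]$b
        all_params$blocks[[b]]$gamma <- st$params$blocks[[b]]$gamma
        all_params$blocks[[b]]$beta <- st$params$blocks[[b]]$beta
      }
      all_params$head <- st$params$head
      row <- row + 1
      log[[row]] <- data.frame(epoch = epoch, batch = bi, ce = ce,
                               scl = scl_res$loss, total = total)
    }
  }
  backbone$params <- all_params$blocks
  backbone$head <- all_params$head
  backbone$classes <- classes
  backbone$log <- do.call(rbind, log)
  backbone$trained <- TRUE
  backbone$pretrain_config <- config
  backbone$loss_config <- loss
  backbone
}

strip_running <- function(blocks) {
  lapply(blocks, function(p) p[c("W", "b", "gamma", "beta")])
}

#' @export
summary.fscc_backbone <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    first <- object$log[1, ]
    last <- object$log[nrow(object$log), ]
    cat(sprintf("  training: %d batches, total loss %.4f -> %.4f\n",
                nrow(object$log), first$total, last$total))
  }
  invisible(object)
}
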