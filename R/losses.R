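#' Cross-entropy loss
#'
#' Mean over the mini-batch of the negative log-probability assigned to the
#' true class. Probabilities are clamped at `1e-12` so a zero probability at
#' the true label yields a large finite loss rather than infinity.
#'
#' @param probs `N x C` matrix of predicted class probabilities (rows must
#'   sum to 1 within `1e-6`).
#' @param labels integer labels, either 0-based (`0..C-1`) or 1-based
#'   (`1..C`); 0-based is assumed when any 0 is present.
#' @return scalar loss.
#' @examples
#' cross_entropy_loss(matrix(0.2, 3, 5), c(0, 1, 4))  # log(5)
#' @export
cross_entropy_loss <- function(probs, labels) {
  probs <- rbind(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    .fscc_stop("probability rows must sum to 1")
  idx <- label_index(labels, ncol(probs))
  p <- probs[cbind(seq_len(nrow(probs)), idx)]
  mean(-log(pmax(p, 1e-12)))
}

label_index <- function(labels, C) {
  labels <- as.integer(labels)
  idx <- if (any(labels == 0L)) labels + 1L else labels
  if (any(idx < 1L | idx > C)) .fscc_stop("labels out of range for ", C,
                                          " classes")
  idx
}

#' Supervised contrastive loss
#'
#' For each anchor `i`, positives are the other samples `j != i` sharing its
#' label; the loss is
#' `sum_i -1/(N_i - 1) * sum_{j in P(i)} log( exp(z_i.z_j / tau) /
#' sum_{k != i} exp(z_i.z_k / tau) )`,
#' where `N_i` counts the anchor's class in the batch. Anchors whose class
#' appears only once have no positives and contribute 0 (with a warning).
#' Embeddings are L2-normalized internally by default, which is what makes
#' the temperature `tau = 0.07` meaningful; raw dot products can be used by
#' turning `normalize` off. The denominator uses a max-subtracted
#' log-sum-exp for numerical stability.
#'
#' @param embeddings `M x D` matrix (M >= 2).
#' @param labels length-M class labels.
#' @param tau positive temperature controlling class separation
#'   (default 0.07).
#' @param normalize L2-normalize the embeddings inside the loss
#'   (default `TRUE`).
#' @param grad also return the gradient with respect to the (raw, input)
#'   embeddings.
#' @return scalar loss, or (with `grad = TRUE`) a list `loss`, `grad`.
#' @export
supervised_contrastive_loss <- function(embeddings, labels, tau = 0.07,
                                        normalize = TRUE, grad = FALSE) {
  z0 <- rbind(embeddings)
  M <- nrow(z0)
  if (M < 2) .fscc_stop("supervised contrastive loss needs at least 2 samples")
  if (tau <= 0) .fscc_stop("tau must be positive")
  labels <- as.vector(labels)
  counts <- table(labels)
  n_i <- as.vector(counts[as.character(labels)])
  if (all(n_i == 1)) {
    warning("all classes are singletons: contrastive loss is 0")
    if (grad) return(list(loss = 0, grad = matrix(0, M, ncol(z0))))
    return(0)
  }
  if (any(n_i == 1))
    warning("singleton-class samples contribute 0 to the contrastive loss")
  norms <- NULL
  z <- z0
  if (normalize) {
    norms <- pmax(sqrt(rowSums(z0^2)), 1e-12)
    z <- z0 / norms
  }
  S <- tcrossprod(z) / tau
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  off <- !diag(TRUE, M)
  # row-wise log-sum-exp over k != i, max-subtracted
  Soff <- S
  diag(Soff) <- -Inf
  mx <- apply(Soff, 1, max)
  lse <- mx + log(rowSums(exp(Soff - mx)))
  w <- ifelse(n_i > 1, 1 / (n_i - 1), 0)
  per_anchor <- -w * rowSums(same * (S - lse))
  loss <- sum(per_anchor)
  if (!grad) return(loss)
  # dL/dS[i,k] = P_i * p_ik - w_i * 1[k positive], for k != i
  P_i <- rowSums(same)  # number of positives per anchor (N_i - 1 or 0)
  p <- exp(Soff - lse)  # softmax over k != i; exp(-Inf)=0 on the diagonal
  G <- p * P_i * w - same * w
  G[!off] <- 0
  dz <- (G %*% z + crossprod(G, z)) / tau
  if (normalize) {
    # back through z = f / ||f||
    proj <- rowSums(dz * z)
    dz <- (dz - z * proj) / norms
  }
  list(loss = loss, grad = dz)
}

#' Combined pre-training loss
#'
#' The stage-1 objective: cross-entropy plus `lambda_scl` times the
#' supervised contrastive loss. `lambda_scl = 0` is the no-contrastive
#' ablation; the recommended weight is 0.05, which keeps the two terms at a
#' comparable order of magnitude.
#'
#' @param ce scalar cross-entropy loss.
#' @param scl scalar supervised contrastive loss.
#' @param lambda_scl nonnegative weight (default 0.05).
#' @return `ce + lambda_scl * scl`.
#' @export
combined_loss <- function(ce, scl, lambda_scl = 0.05) {
  if (!is.finite(ce) || !is.finite(scl)) .fscc_stop("losses must be finite")
  if (lambda_scl < 0) .fscc_stop("lambda_scl must be nonnegative")
  ce + lambda_scl * scl
}

#' Loss configuration for pre-training
#'
#' @param lambda_scl weight of the contrastive term (default 0.05).
#' @param tau contrastive temperature (default 0.07).
#' @param normalize_embeddings L2-normalize embeddings inside the
#'   contrastive loss (default `TRUE`).
#' @return an object of class `fscc_loss_config`.
#' @export
loss_config <- function(lambda_scl = 0.05, tau = 0.07,
                        normalize_embeddings = TRUE) {
  if (tau <= 0) .fscc_stop("tau must be positive")
  if (lambda_scl < 0) .fscc_stop("lambda_scl must be nonnegative")
  structure(list(lambda_scl = lambda_scl, tau = tau,
                 normalize_embeddings = isTRUE(normalize_embeddings)),
            class = "fscc_loss_config")
}

# softmax with max subtraction, rows of a score matrix
softmax_rows <- function(scores) {
  scores <- rbind(scores)
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}
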