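# Shared fixtures: everything is generated in code at test time.

# A small backbone configuration that keeps compiled passes fast.
tiny_backbone_config <- function(edge = 8, width = 4, pools = 1:3) {
  backbone_config(channel_widths = rep(as.integer(width), 6),
                  pool_blocks = pools, input_edge = edge,
                  normalize_input = FALSE)
}

tiny_backbone <- function(seed = 1, ...) {
  suppressMessages(build_backbone(tiny_backbone_config(...), seed = seed))
}

# Small feature benchmark; evaluated at tukey_lambda = 1 (its features are
# Gaussian by construction).
small_benchmark <- function(seed = 1, ...) {
  generate_feature_benchmark(feature_benchmark_config(seed = seed, ...))
}

# Independent plain-loop oracle for per-class mean / unbiased covariance.
oracle_class_stats <- function(X, labels) {
  out <- list()
  for (cl in sort(unique(labels))) {
    rows <- X[labels == cl, , drop = FALSE]
    n <- nrow(rows)
    mu <- rep(0, ncol(rows))
    for (i in seq_len(n)) mu <- mu + rows[i, ]
    mu <- mu / n
    S <- matrix(0, ncol(rows), ncol(rows))
    for (i in seq_len(n)) S <- S + tcrossprod(rows[i, ] - mu)
    out[[as.character(cl)]] <- list(mean = mu, cov = S / (n - 1), n = n)
  }
  out
}

# Independent term-by-term evaluation of the supervised contrastive loss.
oracle_scl <- function(emb, labels, tau = 0.07, normalize = TRUE) {
  M <- nrow(emb)
  if (normalize)
    emb <- emb / pmax(sqrt(rowSums(emb^2)), 1e-12)
  total <- 0
  for (i in seq_len(M)) {
    n_i <- sum(labels == labels[i])
    if (n_i < 2) next
    den <- 0
    for (k in seq_len(M)) if (k != i)
      den <- den + exp(sum(emb[i, ] * emb[k, ]) / tau)
    s <- 0
    for (j in seq_len(M)) if (j != i && labels[j] == labels[i])
      s <- s + log(exp(sum(emb[i, ] * emb[j, ]) / tau) / den)
    total <- total - s / (n_i - 1)
  }
  total
}
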