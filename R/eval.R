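#' Sample one N-way-K-shot episode
#'
#' Chooses `n_way` novel classes, then for each class draws `k_shot`
#' support and `q_queries` query samples uniformly without replacement, so
#' support and query are disjoint and cover exactly the same classes.
#'
#' @param labels class ids of the novel dataset, one per sample.
#' @param n_way number of classes in the episode.
#' @param k_shot labeled support samples per class.
#' @param q_queries query samples per class (default 15, the usual episodic
#'   evaluation convention).
#' @param seed integer seed.
#' @return an object of class `fscc_task`: list with `classes`,
#'   `support_idx`, `query_idx` (indices into `labels`), and the episode
#'   shape (`n_way`, `k_shot`, `q_queries`).
#' @export
sample_episode <- function(labels, n_way, k_shot, q_queries = 15, seed = NULL) {
  classes <- sort(unique(labels))
  if (n_way > length(classes))
    .fscc_stop("n_way exceeds the number of novel classes")
  if (!is.null(seed)) set.seed(as.integer(seed))
  chosen <- sort(sample(classes, n_way))
  sup <- integer(0); qry <- integer(0)
  for (cl in chosen) {
    pool <- which(labels == cl)
    if (length(pool) < k_shot + q_queries)
      .fscc_stop("class ", cl, " has only ", length(pool),
                 " samples; needs ", k_shot + q_queries)
    pick <- sample(pool, k_shot + q_queries)
    sup <- c(sup, pick[seq_len(k_shot)])
    qry <- c(qry, pick[k_shot + seq_len(q_queries)])
  }
  structure(list(classes = chosen, support_idx = sup, query_idx = qry,
                 n_way = as.integer(n_way), k_shot = as.integer(k_shot),
                 q_queries = as.integer(q_queries)),
            class = "fscc_task")
}

#' Accuracy and F1 from one-vs-rest confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FN + FP + TN)` and
#' `F1 = 2 TP / (2 TP + FN + FP)`. A degenerate F1 denominator (no true
#' positives and no errors involving the class) is defined as 0 with a
#' warning.
#'
#' @param counts a list or named vector with `TP`, `TN`, `FP`, `FN`.
#' @return scalar in `[0, 1]`.
#' @examples
#' accuracy(c(TP = 3, TN = 5, FP = 1, FN = 1))  # 0.8
#' f1_score(c(TP = 3, TN = 0, FP = 1, FN = 1))  # 0.75
#' @export
accuracy <- function(counts) {
  counts <- as.list(counts)
  tot <- counts$TP + counts$FN + counts$FP + counts$TN
  if (tot <= 0) .fscc_stop("confusion counts sum to zero")
  (counts$TP + counts$TN) / tot
}

#' @rdname accuracy
#' @export
f1_score <- function(counts) {
  counts <- as.list(counts)
  den <- 2 * counts$TP + counts$FN + counts$FP
  if (den <= 0) {
    warning("degenerate F1 denominator: defining F1 = 0")
    return(0)
  }
  2 * counts$TP / den
}

# One-vs-rest confusion counts per class from predicted/true label vectors.
confusion_counts <- function(predicted, truth, classes) {
  out <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tn <- sum(predicted != cl & truth != cl)
    c(TP = tp, TN = tn, FP = fp, FN = fn)
  })
  names(out) <- as.character(classes)
  out
}

#' Evaluate one few-shot episode with calibrated retraining
#'
#' Trains the calibrated classifier on the episode's support features and
#' classifies its queries in transformed space. The base statistics must
#' come from base classes only: any overlap with the episode's classes is
#' an error.
#'
#' @param features `N x D` matrix of novel-set features (extracted with a
#'   frozen backbone).
#' @param labels novel class ids aligned with `features`.
#' @param task an `fscc_task` indexing into `features`.
#' @param base_stats an `fscc_base_stats`.
#' @param config an [calibration_config()].
#' @return list with `accuracy`, per-class `confusion`, `predicted`,
#'   `truth`.
#' @export
evaluate_fscc <- function(features, labels, task, base_stats,
                          config = calibration_config()) {
  stopifnot(inherits(task, "fscc_task"))
  overlap <- intersect(as.character(task$classes), names(base_stats))
  if (length(overlap) > 0)
    .fscc_stop("base/novel class overlap: ", paste(overlap, collapse = " "))
  clf <- train_calibrated_classifier(features[task$support_idx, , drop = FALSE],
                                     labels[task$support_idx], base_stats,
                                     config)
  pred <- predict(clf, features[task$query_idx, , drop = FALSE])
  truth <- labels[task$query_idx]
  list(accuracy = mean(pred == truth),
       confusion = confusion_counts(pred, truth, task$classes),
       predicted = pred, truth = truth)
}

#' Evaluate one episode with the fine-tuning baseline
#'
#' The standard comparison condition: the frozen extractor's raw
#' (untransformed) support features train a ridge multinomial linear head
#' with no feature augmentation; queries are classified in raw feature
#' space. Equivalent to the calibration-off, contrastive-off ablation when
#' the backbone was trained without the contrastive term.
#'
#' @param features,labels,task as in [evaluate_fscc()].
#' @param ridge ridge penalty of the linear head (default 1.0).
#' @param extra_support optional list `features`, `labels` appended to the
#'   support set (for the resampled-support baseline variant that spends a
#'   larger label budget).
#' @return list with `accuracy`, per-class `confusion`, `predicted`,
#'   `truth`.
#' @export
evaluate_baseline_finetune <- function(features, labels, task, ridge = 1.0,
                                       extra_support = NULL) {
  stopifnot(inherits(task, "fscc_task"))
  X <- features[task$support_idx, , drop = FALSE]
  y <- labels[task$support_idx]
  if (!is.null(extra_support)) {
    X <- rbind(X, extra_support$features)
    y <- c(y, extra_support$labels)
  }
  classes <- sort(unique(y))
  w <- fit_multinomial_ridge(X, match(y, classes), length(classes),
                             ridge = ridge)
  Xq <- features[task$query_idx, , drop = FALSE]
  scores <- Xq %*% t(w$W) + matrix(w$b, nrow(Xq), length(w$b), byrow = TRUE)
  pred <- classes[max.col(scores, ties.method = "first")]
  truth <- labels[task$query_idx]
  list(accuracy = mean(pred == truth),
       confusion = confusion_counts(pred, truth, task$classes),
       predicted = pred, truth = truth)
}

#' Run an episodic few-shot evaluation
#'
#' Samples `n_tasks` N-way-K-shot episodes (per-task seeds are
#' `master_seed + task index`, reproducible yet independent) and aggregates
#' accuracy and per-class macro F1. The standard protocol evaluates 100
#' random tasks at N = 5 with K = 1 or 5.
#'
#' @param method `"fscc"` (calibrated retraining) or `"baseline"`
#'   (fine-tuning head).
#' @param features `N x D` matrix of novel-set features.
#' @param labels novel class ids aligned with `features`.
#' @param base_stats an `fscc_base_stats` (required for `"fscc"`).
#' @param n_way,k_shot,q_queries episode shape (defaults 5, 1, 15).
#' @param n_tasks number of episodes (default 100).
#' @param master_seed integer seed.
#' @param config an [calibration_config()].
#' @return an object of class `fscc_report`: list with
#'   `per_task_accuracy`, `mean_accuracy`, `sd_accuracy`, `ci95_half_width`
#'   (over tasks), `per_class_f1` (one-vs-rest from pooled confusion
#'   counts), `macro_f1`, `n_tasks`, and a `config` echo.
#' @export
run_evaluation <- function(method = c("fscc", "baseline"), features, labels,
                           base_stats = NULL, n_way = 5, k_shot = 1,
                           q_queries = 15, n_tasks = 100, master_seed = 1,
                           config = calibration_config()) {
  method <- match.arg(method)
  if (n_tasks < 1) .fscc_stop("n_tasks must be >= 1")
  if (method == "fscc" && is.null(base_stats))
    .fscc_stop("the fscc method needs base statistics")
  acc <- numeric(n_tasks)
  pooled <- NULL
  for (t in seq_len(n_tasks)) {
    task <- sample_episode(labels, n_way, k_shot, q_queries,
                           seed = master_seed + t)
    cfg_t <- config
    cfg_t$seed <- master_seed + t
    res <- if (method == "fscc") {
      evaluate_fscc(features, labels, task, base_stats, cfg_t)
    } else {
      evaluate_baseline_finetune(features, labels, task,
                                 ridge = config$classifier_ridge)
    }
    acc[t] <- res$accuracy
    for (cl in names(res$confusion)) {
      if (is.null(pooled)) pooled <- list()
      pooled[[cl]] <- if (is.null(pooled[[cl]])) res$confusion[[cl]] else
        pooled[[cl]] + res$confusion[[cl]]
    }
  }
  per_class_f1 <- vapply(pooled, function(cc)
    suppressWarnings(f1_score(cc)), 0)
  structure(list(method = method,
                 per_task_accuracy = acc,
                 mean_accuracy = mean(acc),
                 sd_accuracy = if (n_tasks > 1) sd(acc) else 0,
                 ci95_half_width = if (n_tasks > 1)
                   qt(0.975, n_tasks - 1) * sd(acc) / sqrt(n_tasks) else 0,
                 per_class_f1 = per_class_f1,
                 macro_f1 = mean(per_class_f1),
                 n_tasks = as.integer(n_tasks),
                 config = list(n_way = n_way, k_shot = k_shot,
                               q_queries = q_queries,
                               master_seed = master_seed,
                               method = method,
                               calibration = unclass(config))),
            class = "fscc_report")
}

#' @export
print.fscc_report <- function(x, ...) {
  cat(sprintf("%d-way-%d-shot evaluation, %d tasks, method: %s\n",
              x$config$n_way, x$config$k_shot, x$n_tasks, x$method))
  cat(sprintf("  mean accuracy %.2f%% (sd over tasks %.2f%%, 95%% half-width %.2f%%)\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy,
              100 * x$ci95_half_width))
  cat(sprintf("  macro F1 %.3f\n", x$macro_f1))
  invisible(x)
}

#' @export
summary.fscc_report <- function(object, ...) {
  print(object)
  cat("  per-class F1:\n")
  for (cl in names(object$per_class_f1))
    cat(sprintf("    class %s: %.3f\n", cl, object$per_class_f1[cl]))
  invisible(object)
}

#' @export
plot.fscc_report <- function(x, ...) {
  graphics::hist(100 * x$per_task_accuracy,
                 main = sprintf("%d-way-%d-shot per-task accuracy (%s)",
                                x$config$n_way, x$config$k_shot, x$method),
                 xlab = "accuracy (%)", col = "grey80", border = "white", ...)
  graphics::abline(v = 100 * x$mean_accuracy, lwd = 2)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes a machine-readable JSON report (fixed 6-digit precision, so
#' same-seed reruns are byte-identical) and a CSV of per-task accuracies
#' next to it.
#'
#' @param report an `fscc_report`.
#' @param path destination `.json` path; the per-task CSV replaces the
#'   extension with `_tasks.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fscc_report"))
  out <- list(method = report$method,
              n_tasks = report$n_tasks,
              mean_accuracy = round(report$mean_accuracy, 6),
              sd_accuracy = round(report$sd_accuracy, 6),
              ci95_half_width = round(report$ci95_half_width, 6),
              macro_f1 = round(report$macro_f1, 6),
              per_class_f1 = round(report$per_class_f1, 6),
              config = report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  csv <- sub("\\.json$", "_tasks.csv", path)
  write.csv(data.frame(task = seq_len(report$n_tasks),
                       accuracy = round(report$per_task_accuracy, 6)),
            csv, row.names = FALSE)
  invisible(path)
}
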