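test_that("episodes have the right shape, are disjoint and deterministic", {
  labels <- rep(8:12, each = 25)
  task <- sample_episode(labels, 5, 5, q_queries = 15, seed = 1)
  expect_length(task$support_idx, 25)
  expect_length(task$query_idx, 75)
  expect_length(intersect(task$support_idx, task$query_idx), 0)
  expect_setequal(unique(labels[task$support_idx]), task$classes)
  expect_setequal(unique(labels[task$query_idx]), task$classes)
  expect_identical(sample_episode(labels, 3, 1, 10, seed = 2),
                   sample_episode(labels, 3, 1, 10, seed = 2))
  err <- tryCatch(sample_episode(rep(0:1, each = 4), 2, 2, q_queries = 10),
                  error = identity)
  expect_match(conditionMessage(err), "class [01] has only")
  expect_error(sample_episode(labels, 9, 1), "n_way")
})

test_that("accuracy and F1 follow their confusion-count formulas", {
  expect_equal(accuracy(c(TP = 3, TN = 5, FP = 1, FN = 1)), 0.8)
  expect_equal(accuracy(c(TP = 10, TN = 40, FP = 0, FN = 0)), 1.0)
  expect_equal(f1_score(c(TP = 3, TN = 0, FP = 1, FN = 1)), 0.75)
  expect_equal(f1_score(c(TP = 7, TN = 3, FP = 0, FN = 0)), 1.0)
  expect_equal(suppressWarnings(f1_score(c(TP = 0, TN = 5, FP = 0, FN = 0))), 0)
  expect_warning(f1_score(c(TP = 0, TN = 5, FP = 0, FN = 0)), "degenerate")
  expect_equal(f1_score(c(TP = 0, TN = 5, FP = 2, FN = 1)), 0)
  expect_error(accuracy(c(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
  # random instance: formula matches a brute-force count
  set.seed(3)
  truth <- sample(1:4, 60, replace = TRUE)
  pred <- sample(1:4, 60, replace = TRUE)
  cc <- fscc:::confusion_counts(pred, truth, 1:4)
  for (cl in 1:4) {
    expect_equal(sum(unlist(cc[[cl]])), 60)
    expect_equal(accuracy(cc[[cl]]),
                 mean((pred == cl) == (truth == cl)))
  }
  # multiclass accuracy equals mean per-class recall at equal query counts
  truth_eq <- rep(1:4, each = 15)
  pred_eq <- sample(1:4, 60, replace = TRUE)
  cc_eq <- fscc:::confusion_counts(pred_eq, truth_eq, 1:4)
  recalls <- vapply(cc_eq, function(x) x["TP"] / (x["TP"] + x["FN"]), 0)
  expect_equal(mean(pred_eq == truth_eq), mean(recalls))
})

test_that("a task whose queries duplicate its support is classified perfectly", {
  bench <- generate_feature_benchmark(feature_benchmark_config(
    n_base_classes = 4, n_novel_classes = 3, dim = 8, class_mean_scale = 3,
    within_class_cov_scale = 0.3, samples_per_base_class = 50,
    samples_per_novel_class = 20, seed = 4))
  bs <- compute_base_statistics(bench$base$features, bench$base$labels)
  task <- sample_episode(bench$novel$labels, 3, 3, q_queries = 5, seed = 5)
  task$query_idx <- rep(task$support_idx, 2)[seq_along(task$query_idx)]
  for (res in list(
    evaluate_fscc(bench$novel$features, bench$novel$labels, task, bs,
                  calibration_config(tukey_lambda = 1, seed = 6)),
    evaluate_baseline_finetune(bench$novel$features, bench$novel$labels,
                               task))) {
    expect_equal(res$accuracy, 1.0)
  }
})

test_that("evaluation reports are internally consistent and reproducible", {
  bench <- small_benchmark(seed = 6, samples_per_base_class = 60,
                           samples_per_novel_class = 40)
  bs <- compute_base_statistics(bench$base$features, bench$base$labels)
  cfg <- calibration_config(tukey_lambda = 1, seed = 1)
  rep1 <- run_evaluation("fscc", bench$novel$features, bench$novel$labels,
                         bs, n_way = 5, k_shot = 1, q_queries = 10,
                         n_tasks = 8, master_seed = 3, config = cfg)
  expect_length(rep1$per_task_accuracy, 8)
  expect_equal(rep1$mean_accuracy, mean(rep1$per_task_accuracy))
  expect_equal(rep1$sd_accuracy, sd(rep1$per_task_accuracy))
  expect_equal(rep1$ci95_half_width,
               qt(0.975, 7) * sd(rep1$per_task_accuracy) / sqrt(8))
  expect_equal(rep1$macro_f1, mean(rep1$per_class_f1))
  rep2 <- run_evaluation("fscc", bench$novel$features, bench$novel$labels,
                         bs, n_way = 5, k_shot = 1, q_queries = 10,
                         n_tasks = 8, master_seed = 3, config = cfg)
  expect_identical(rep1$per_task_accuracy, rep2$per_task_accuracy)
  one <- run_evaluation("baseline", bench$novel$features, bench$novel$labels,
                        n_way = 5, k_shot = 1, q_queries = 10, n_tasks = 1,
                        master_seed = 3)
  expect_equal(one$sd_accuracy, 0)
  expect_equal(one$mean_accuracy, one$per_task_accuracy[1])
  expect_error(run_evaluation("fscc", bench$novel$features,
                              bench$novel$labels, NULL), "base statistics")
})

test_that("two master seeds agree within sampling noise on a fixed benchmark", {
  bench <- small_benchmark(seed = 7, samples_per_base_class = 60,
                           samples_per_novel_class = 60)
  bs <- compute_base_statistics(bench$base$features, bench$base$labels)
  cfg <- calibration_config(tukey_lambda = 1, seed = 1)
  ra <- run_evaluation("fscc", bench$novel$features, bench$novel$labels, bs,
                       n_way = 5, k_shot = 1, n_tasks = 25, master_seed = 101,
                       config = cfg)
  rb <- run_evaluation("fscc", bench$novel$features, bench$novel$labels, bs,
                       n_way = 5, k_shot = 1, n_tasks = 25, master_seed = 2002,
                       config = cfg)
  expect_false(identical(ra$per_task_accuracy, rb$per_task_accuracy))
  se <- sqrt(ra$sd_accuracy^2 / 25 + rb$sd_accuracy^2 / 25)
  expect_lt(abs(ra$mean_accuracy - rb$mean_accuracy), 3 * se)
})

test_that("an uninformative extractor scores at chance level", {
  set.seed(8)
  feats <- matrix(abs(rnorm(150 * 8)), 150, 8)  # random nonneg features
  labels <- rep(20:24, each = 30)
  base_feats <- matrix(abs(rnorm(200 * 8)), 200, 8)
  bs <- compute_base_statistics(base_feats, rep(0:3, each = 50))
  repc <- run_evaluation("fscc", feats, labels, bs, n_way = 5, k_shot = 1,
                         q_queries = 10, n_tasks = 40, master_seed = 5,
                         config = calibration_config(tukey_lambda = 1,
                                                     seed = 5))
  se <- max(repc$sd_accuracy / sqrt(40), sqrt(0.2 * 0.8 / (40 * 50)))
  expect_lt(abs(repc$mean_accuracy - 0.2), max(3 * se, 0.04))
})

test_that("reports serialize with fixed precision and a per-task CSV", {
  bench <- small_benchmark(seed = 9, samples_per_base_class = 40,
                           samples_per_novel_class = 30)
  rep1 <- run_evaluation("baseline", bench$novel$features,
                         bench$novel$labels, n_way = 3, k_shot = 1,
                         q_queries = 5, n_tasks = 4, master_seed = 2)
  path <- tempfile(fileext = ".json")
  write_report(rep1, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$mean_accuracy, round(rep1$mean_accuracy, 6))
  tasks <- read.csv(sub("\\.json$", "_tasks.csv", path))
  expect_equal(nrow(tasks), 4)
  expect_equal(tasks$accuracy, round(rep1$per_task_accuracy, 6))
})
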