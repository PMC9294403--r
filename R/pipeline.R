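#' Base-class statistics in the calibration's working space
#'
#' Distribution calibration compares Tukey-transformed support features
#' against base-class means, so the base statistics must be computed in the
#' same transformed space. This helper applies the transform to the base
#' features and then computes per-class mean and covariance. With
#' `tukey_lambda = 1` it reduces to [compute_base_statistics()] on the raw
#' features.
#'
#' @param features `N x D` matrix of raw (nonnegative) base-class features.
#' @param labels base class ids.
#' @param tukey_lambda the exponent shared with the support/query pathway
#'   (default 0.5).
#' @return an `fscc_base_stats`.
#' @export
base_statistics_from_features <- function(features, labels,
                                          tukey_lambda = 0.5) {
  compute_base_statistics(tukey_transform(rbind(features), tukey_lambda),
                          labels)
}

#' End-to-end few-shot evaluation from volumes
#'
#' Convenience wrapper for the full stage-2 pathway: extract features for
#' the base and novel volumes with a frozen pre-trained backbone, compute
#' base statistics in the calibration's transformed space, and run the
#' episodic evaluation.
#'
#' @param backbone a trained `fscc_backbone`.
#' @param base_volumes,base_labels the base dataset (statistics donor).
#' @param novel_volumes,novel_labels the novel dataset (episodes).
#' @param method `"fscc"` or `"baseline"`.
#' @param n_way,k_shot,q_queries,n_tasks,master_seed episodic protocol.
#' @param config an [calibration_config()].
#' @return an `fscc_report`.
#' @export
evaluate_from_volumes <- function(backbone, base_volumes, base_labels,
                                  novel_volumes, novel_labels,
                                  method = c("fscc", "baseline"),
                                  n_way = 5, k_shot = 1, q_queries = 15,
                                  n_tasks = 100, master_seed = 1,
                                  config = calibration_config()) {
  method <- match.arg(method)
  overlap <- intersect(unique(base_labels), unique(novel_labels))
  if (length(overlap) > 0)
    .fscc_stop("base and novel classes must be disjoint; overlap: ",
               paste(overlap, collapse = " "))
  novel_feats <- extract_features(backbone, novel_volumes)
  base_stats <- NULL
  if (method == "fscc") {
    base_feats <- extract_features(backbone, base_volumes)
    base_stats <- base_statistics_from_features(base_feats, base_labels,
                                                config$tukey_lambda)
  }
  run_evaluation(method, novel_feats, novel_labels, base_stats,
                 n_way = n_way, k_shot = k_shot, q_queries = q_queries,
                 n_tasks = n_tasks, master_seed = master_seed,
                 config = config)
}
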