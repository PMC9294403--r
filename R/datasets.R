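#' Random disjoint base/novel class partition
#'
#' Few-shot evaluation requires the novel classes to be disjoint from the
#' classes used for pre-training. This draws a uniformly random partition of
#' the class ids into a base set and a novel set.
#'
#' @param class_ids vector of distinct class ids.
#' @param n_novel number of novel classes (< number of classes).
#' @param seed integer seed.
#' @return an object of class `fscc_split`: list with `base_classes`,
#'   `novel_classes`, `seed`.
#' @examples
#' make_split(0:11, n_novel = 5, seed = 1)  # 7 base + 5 novel
#' @export
make_split <- function(class_ids, n_novel, seed = 1) {
  class_ids <- unique(class_ids)
  if (n_novel >= length(class_ids) || n_novel < 1)
    .fscc_stop("n_novel must be in [1, number of classes - 1]")
  set.seed(as.integer(seed))
  novel <- sort(sample(class_ids, n_novel))
  base <- sort(setdiff(class_ids, novel))
  stopifnot(length(intersect(base, novel)) == 0,
            length(base) > 0, length(novel) > 0)
  structure(list(base_classes = base, novel_classes = novel,
                 seed = as.integer(seed)),
            class = "fscc_split")
}

#' @export
print.fscc_split <- function(x, ...) {
  cat("Base/novel class split (seed", x$seed, ")\n")
  cat("  base: ", paste(x$base_classes, collapse = " "), "\n")
  cat("  novel:", paste(x$novel_classes, collapse = " "), "\n")
  invisible(x)
}

#' Class-balanced mini-batches
#'
#' Builds mini-batches that draw a uniform number of samples from each
#' class, so the supervised contrastive loss always finds positive pairs.
#' When `batch_size` is not a multiple of the class count, the remainder is
#' distributed to randomly chosen classes, keeping per-class counts within
#' one of each other. Samples are drawn without replacement within a batch
#' and independently across batches.
#'
#' @param labels vector of class labels (one per sample).
#' @param batch_size samples per batch.
#' @param seed integer seed.
#' @param n_batches number of batches; default
#'   `ceiling(length(labels) / batch_size)` (one epoch's worth).
#' @return list of integer index vectors into `labels`.
#' @export
class_balanced_batches <- function(labels, batch_size, seed = NULL,
                                   n_batches = NULL) {
  classes <- sort(unique(labels))
  C <- length(classes)
  if (batch_size < C) .fscc_stop("batch_size smaller than the class count")
  pools <- lapply(classes, function(cl) which(labels == cl))
  small <- classes[vapply(pools, length, 0L) < 2]
  if (length(small) > 0)
    warning("classes with fewer than 2 samples (no contrastive positives): ",
            paste(small, collapse = " "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(n_batches)) n_batches <- ceiling(length(labels) / batch_size)
  per <- batch_size %/% C
  rem <- batch_size %% C
  lapply(seq_len(n_batches), function(b) {
    quota <- rep(per, C)
    if (rem > 0) {
      extra <- sample(C, rem)
      quota[extra] <- quota[extra] + 1L
    }
    idx <- unlist(lapply(seq_len(C), function(i) {
      pool <- pools[[i]]
      if (quota[i] <= length(pool)) {
        pool[sample.int(length(pool), quota[i])]
      } else {
        # tiny class: top up with replacement
        c(pool, pool[sample.int(length(pool), quota[i] - length(pool),
                                replace = TRUE)])
      }
    }))
    sample(idx)  # shuffle within the batch
  })
}

#' Write a dataset of subtomograms as MRC files plus a CSV manifest
#'
#' The manifest has columns `subtomogram_path`, `class_id`, `split`
#' (`base` or `novel`); paths are relative to the manifest's directory.
#'
#' @param dataset an `fscc_dataset` from [build_synthetic_dataset()].
#' @param dir output directory (created if needed).
#' @param split optional `fscc_split`; when given, each record is tagged by
#'   its class's side of the split, otherwise all records are tagged `base`.
#' @param voxel_size voxel spacing written to the MRC headers.
#' @return path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(dataset, dir, split = NULL, voxel_size = 1) {
  stopifnot(inherits(dataset, "fscc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$volumes)
  paths <- sprintf("subtomo_%04d.mrc", seq_len(n) - 1)
  tag <- rep("base", n)
  if (!is.null(split)) {
    stopifnot(inherits(split, "fscc_split"))
    tag <- ifelse(dataset$labels %in% split$novel_classes, "novel", "base")
  }
  for (i in seq_len(n))
    write_subtomogram(dataset$volumes[[i]], file.path(dir, paths[i]),
                      voxel_size = voxel_size, overwrite = TRUE)
  manifest <- data.frame(subtomogram_path = paths,
                         class_id = dataset$labels, split = tag,
                         stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a manifest CSV and its subtomogram volumes
#'
#' @param manifest_path path to a manifest written by [write_dataset()] (or
#'   any CSV with columns `subtomogram_path`, `class_id`, `split`).
#' @param load_volumes read the MRC volumes too (default `TRUE`).
#' @return list with `manifest` (data frame), `class_counts`, and (when
#'   loaded) `volumes` and `labels` aligned with the manifest rows.
#' @export
read_manifest <- function(manifest_path, load_volumes = TRUE) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subtomogram_path", "class_id", "split")
  if (!all(need %in% names(man)))
    .fscc_stop("manifest must have columns: ", paste(need, collapse = ", "))
  bad <- unique(man$class_id[!man$split %in% c("base", "novel")])
  if (length(bad) > 0) .fscc_stop("invalid split tags in manifest")
  sides <- tapply(man$split, man$class_id, function(s) length(unique(s)))
  if (any(sides > 1))
    .fscc_stop("classes appearing on both sides of the split: ",
               paste(names(sides)[sides > 1], collapse = " "))
  out <- list(manifest = man,
              class_counts = table(man$class_id))
  if (load_volumes) {
    root <- dirname(manifest_path)
    subs <- lapply(file.path(root, man$subtomogram_path), read_subtomogram)
    out$volumes <- lapply(subs, `[[`, "volume")
    out$labels <- man$class_id
  }
  out
}

# Per-volume intensity normalization applied before the network: zero mean,
# unit variance (constant volumes map to all zeros).
normalize_volume <- function(v) {
  s <- sd(as.vector(v))
  if (s == 0) return(array(0, dim = dim(v)))
  (v - mean(v)) / s
}
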