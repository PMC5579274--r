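#' Balanced partition plan for an imbalanced training sample
#'
#' Splits a training (bootstrap) sample into an ensemble of near-balanced
#' partitions: with `N-` majority and `N+` minority instances,
#' `P = round(N-/N+)` (half-up) partitions are created; the minority
#' instances are copied into every partition while the majority instances
#' are randomly distributed without replacement so each partition holds
#' `floor(N-/P)` or `ceil(N-/P)` of them. For example, 168 majority and 32
#' minority instances give 5 partitions: two with 33 and three with 34
#' majority instances, all carrying the 32 minority instances.
#'
#' @param majority_idx,minority_idx integer indices of the two classes. If
#'   the "minority" set is larger, the roles are swapped with a warning.
#' @param rng_seed integer seed making the majority shuffle reproducible.
#' @return An object of class `partition_plan`: list with `partitions`
#'   (list of index vectors), `P`, `minority_idx`, `majority_idx`.
#' @export
plan_partitions <- function(majority_idx, minority_idx, rng_seed = NULL) {
  if (length(minority_idx) == 0)
    stop("no minority-class (event) instances in the sample")
  if (length(majority_idx) < length(minority_idx)) {
    warning("minority class is larger than majority class; swapping roles")
    tmp <- majority_idx; majority_idx <- minority_idx; minority_idx <- tmp
  }
  nneg <- length(majority_idx)
  npos <- length(minority_idx)
  P <- max(1L, as.integer(floor(nneg / npos + 0.5)))  # half-up rounding
  if (!is.null(rng_seed)) set.seed(rng_seed)
  shuffled <- sample(majority_idx)
  base <- nneg %/% P
  extra <- nneg %% P  # the last `extra` partitions take one more
  sizes <- c(rep(base, P - extra), rep(base + 1L, extra))
  splits <- split(shuffled, rep(seq_len(P), times = sizes))
  partitions <- lapply(splits, function(mj) c(mj, minority_idx))
  structure(list(partitions = unname(partitions), P = P,
                 minority_idx = minority_idx, majority_idx = majority_idx,
                 majority_sizes = sizes),
            class = "partition_plan")
}

#' Apply a minority under/oversampling weight to one partition
#'
#' Adjusts the minority representation within a partition to
#' `round(w * N+)` instances: sampling without replacement when `w < 1`,
#' duplication of every instance followed by sampling with replacement for
#' the remainder when `w > 1` (so every minority instance stays represented
#' at least once), identity at `w = 1`.
#'
#' @param partition index vector (one element of a [plan_partitions()] plan).
#' @param minority_idx the plan's minority indices.
#' @param w weight in \[0.5, 2\].
#' @param rng_seed integer seed.
#' @return resampled index vector (a multiset when `w > 1`).
#' @export
apply_class_weight <- function(partition, minority_idx, w, rng_seed = NULL) {
  stopifnot(w >= 0.5, w <= 2.0)
  if (w == 1) return(partition)
  minor <- partition[partition %in% minority_idx]
  major <- partition[!partition %in% minority_idx]
  target <- round(w * length(minor))
  if (target == 0) stop("weight ", w, " would remove every minority instance")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (w < 1) {
    keep <- sample(minor, target)
  } else {
    keep <- c(minor, sample(minor, target - length(minor), replace = TRUE))
  }
  c(major, keep)
}

#' The minority-weight tuning grid
#'
#' @return the 16 weights 0.5, 0.6, ..., 2.0 (step 0.1).
#' @export
weight_grid <- function() seq(0.5, 2.0, by = 0.1)

#' Serialize a partition plan to JSON for audit
#'
#' @param plan a [plan_partitions()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
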