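# Similarity and distance kernels used by the samplers: the Tanimoto
# coefficient on binary vectors, and the Value Difference Metric (VDM)
# driven by class-conditional per-bit value probabilities.

check_binary_vec <- function(v, arg) {
  if (anyNA(v) || !all(v == 0 | v == 1)) {
    stop("'", arg, "' must be a binary (0/1) vector")
  }
}

#' Tanimoto similarity of two binary vectors
#'
#' `|a AND b| / |a OR b|`, the standard chemical similarity on bit sets.
#' Two all-zero vectors are identical objects and return 1 by convention
#' (avoids 0/0 while preserving "identical implies maximal similarity").
#'
#' @param a,b binary vectors of equal length
#' @return similarity in `[0, 1]`; symmetric
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  check_binary_vec(a, "a"); check_binary_vec(b, "b")
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1 | b == 1)
  if (union == 0) return(1)
  inter / union
}

# Tanimoto similarity of each row of X against binary vector v.
# All-zero vs all-zero pairs get similarity 1 (same convention as tanimoto()).
tanimoto_to_vector <- function(X, v) {
  inter <- as.numeric(X %*% v)
  union <- rowSums(X) + sum(v) - inter
  ifelse(union == 0, 1, inter / union)
}

# Full pairwise Tanimoto similarity matrix for the rows of X.
tanimoto_matrix <- function(X) {
  inter <- tcrossprod(X)
  n <- rowSums(X)
  union <- outer(n, n, "+") - inter
  S <- ifelse(union == 0, 1, inter / union)
  S
}

#' Fit class-conditional value statistics for the Value Difference Metric
#'
#' For every bit j and value v in \{0,1\} estimates
#' `P(class = c | bit_j = v) = (n(c, v) + s) / (n(v) + 2 s)` for both
#' classes, where `s` is the Laplace smoothing constant.  Smoothing keeps
#' the conditionals defined when a value is unseen in one class.
#'
#' @param dataset an [fp_dataset()] containing both classes
#' @param smoothing nonnegative smoothing constant (default 1, Laplace)
#' @return an object of class `class_value_stats`: per-bit probability
#'   matrices `p1_given_v0`, `p1_given_v1` (active-class conditionals;
#'   inactive is the complement), value counts `n_v0`, `n_v1`, and the
#'   smoothing constant.
#' @export
fit_class_value_stats <- function(dataset, smoothing = 1) {
  stopifnot(inherits(dataset, "fp_dataset"), smoothing >= 0)
  cs <- class_split(dataset)  # errors on single-class input
  X <- dataset$X
  act <- dataset$y == 1L
  n_v1 <- colSums(X)
  n_v0 <- nrow(X) - n_v1
  n_act_v1 <- colSums(X[act, , drop = FALSE])
  n_act_v0 <- sum(act) - n_act_v1
  p1_v1 <- (n_act_v1 + smoothing) / (n_v1 + 2 * smoothing)
  p1_v0 <- (n_act_v0 + smoothing) / (n_v0 + 2 * smoothing)
  # unsmoothed fit with a bit value entirely absent: conditional undefined,
  # fall back to the class prior so distances stay finite
  prior <- mean(act)
  p1_v1[is.nan(p1_v1)] <- prior
  p1_v0[is.nan(p1_v0)] <- prior
  structure(list(p1_given_v0 = p1_v0, p1_given_v1 = p1_v1,
                 n_v0 = n_v0, n_v1 = n_v1, smoothing = smoothing,
                 bit_count = ncol(X)),
            class = "class_value_stats")
}

#' Value Difference Metric distance between two binary vectors
#'
#' Stanfill-Waltz form:
#' `sum_j sum_c |P(c | bit_j = a_j) - P(c | bit_j = b_j)|^q`.
#' Zero iff the two vectors carry identical values on every bit; symmetric.
#'
#' @param a,b binary vectors matching the fitted bit width
#' @param stats a [fit_class_value_stats()] result
#' @param exponent positive exponent `q` (default 2)
#' @return nonnegative distance
#' @export
vdm_distance <- function(a, b, stats, exponent = 2) {
  stopifnot(inherits(stats, "class_value_stats"), exponent > 0)
  if (length(a) != stats$bit_count || length(b) != stats$bit_count) {
    stop("vector width must match stats bit width (", stats$bit_count, ")")
  }
  check_binary_vec(a, "a"); check_binary_vec(b, "b")
  sum(vdm_bit_costs(stats, exponent)[a != b])
}

# Per-bit cost of disagreeing on bit j; for binary values the VDM sum
# collapses to a lookup: d_j = sum_c |P(c|1) - P(c|0)|^q, and
# dist(a, b) = sum over disagreeing bits of d_j.
vdm_bit_costs <- function(stats, exponent) {
  gap <- abs(stats$p1_given_v1 - stats$p1_given_v0)
  gap^exponent + gap^exponent  # active term + inactive term (equal gaps)
}

# VDM distance of each row of X against binary vector v.
vdm_to_vector <- function(X, v, stats, exponent = 2) {
  d <- vdm_bit_costs(stats, exponent)
  disagree <- sweep(X, 2L, v, "!=")
  as.numeric(disagree %*% d)
}

#' k nearest neighbors within a fingerprint pool
#'
#' Finds the `k` pool rows most similar to a query row under Tanimoto
#' similarity or least distant under the VDM.  The query row is excluded
#' from its own neighbor list; ties are broken by lower row index so
#' results are deterministic.
#'
#' @param query_index row index of the query within `pool`
#' @param pool an [fp_dataset()] or binary matrix of candidate rows
#' @param k number of neighbors, `k < nrow(pool)`
#' @param metric `"tanimoto"` or `"vdm"`
#' @param stats [fit_class_value_stats()] result; required for `"vdm"`
#' @param exponent VDM exponent (default 2)
#' @return integer vector of `k` pool row indices, best first
#' @export
k_nearest <- function(query_index, pool, k, metric = c("tanimoto", "vdm"),
                      stats = NULL, exponent = 2) {
  metric <- match.arg(metric)
  X <- if (inherits(pool, "fp_dataset")) pool$X else pool
  n <- nrow(X)
  stopifnot(query_index >= 1L, query_index <= n)
  if (k >= n) stop("k (", k, ") must be smaller than the pool size (", n, ")")
  q <- X[query_index, ]
  if (metric == "tanimoto") {
    score <- -tanimoto_to_vector(X, q)  # ascending order = most similar first
  } else {
    if (is.null(stats)) stop("metric 'vdm' requires 'stats'")
    score <- vdm_to_vector(X, q, stats, exponent)
  }
  score[query_index] <- Inf
  order(score, seq_len(n))[seq_len(k)]
}
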