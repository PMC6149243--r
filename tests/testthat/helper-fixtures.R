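# Shared fixtures and independent oracles.  Oracles are deliberately
# naive (explicit loops, brute-force enumeration) and never call the code
# paths they check.

make_dataset <- function(X, y, ids = NULL) {
  fp_dataset(as.matrix(X), y, ids)
}

# Random imbalanced binary dataset (uniform iid bits; no cluster structure).
random_dataset <- function(n_majority, n_minority, n_bits, seed,
                           density = 0.4) {
  set.seed(seed)
  n <- n_majority + n_minority
  X <- matrix(as.integer(runif(n * n_bits) < density), nrow = n)
  # guard against an all-zero-width pathological draw
  X[, 1] <- 1L
  fp_dataset(X, c(rep(0L, n_majority), rep(1L, n_minority)))
}

# --- oracles ---------------------------------------------------------------

tanimoto_oracle <- function(a, b) {
  inter <- 0; union <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    if (a[i] == 1 || b[i] == 1) union <- union + 1
  }
  if (union == 0) 1 else inter / union
}

# exhaustive sort-based k-nearest oracle
k_nearest_oracle <- function(query_index, X, k, score_fun, decreasing) {
  n <- nrow(X)
  scores <- vapply(seq_len(n), function(j) score_fun(X[query_index, ], X[j, ]),
                   0)
  idx <- setdiff(seq_len(n), query_index)
  s <- scores[idx]
  ord <- if (decreasing) order(-s, idx) else order(s, idx)
  idx[ord][seq_len(k)]
}

vdm_oracle <- function(a, b, stats, q) {
  total <- 0
  for (j in seq_along(a)) {
    pa1 <- if (a[j] == 1) stats$p1_given_v1[j] else stats$p1_given_v0[j]
    pb1 <- if (b[j] == 1) stats$p1_given_v1[j] else stats$p1_given_v0[j]
    total <- total + abs(pa1 - pb1)^q + abs((1 - pa1) - (1 - pb1))^q
  }
  total
}

# pairwise-comparison AUC oracle
auc_oracle <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# brute-force best k-medoids assignment cost over all medoid sets
kmedoids_bruteforce <- function(X, n_medoids) {
  n <- nrow(X)
  S <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) tanimoto_oracle(X[i, ], X[j, ])))
  sets <- utils::combn(n, n_medoids, simplify = FALSE)
  costs <- vapply(sets, function(s) {
    sum(apply(S[, s, drop = FALSE], 1, max))
  }, 0)
  list(best_cost = max(costs), costs = costs)
}
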