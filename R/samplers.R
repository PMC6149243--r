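# The nine sampling conditions: a no-sampling baseline plus eight
# strategies that equalize class counts exactly.  Every sampler takes the
# dataset and a seed, returns a `sampling_result` with a full audit trail,
# and treats "minority" as whichever class is rarer in the input (active or
# inactive -- nothing is hard-wired to the active class).
#
# All randomness flows through the caller-supplied seed; the caller's RNG
# state is left untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

new_sampling_result <- function(dataset, method, seed, params = list(),
                                removed_indices = integer(0),
                                duplicated_indices = integer(0),
                                synthetic_parents = NULL,
                                iterations = 0L, audit = list()) {
  if (is.null(synthetic_parents)) {
    synthetic_parents <- matrix(integer(0), ncol = 3L,
                                dimnames = list(NULL,
                                                c("seed_row", "neighbor1",
                                                  "neighbor2")))
  }
  structure(list(dataset = dataset, method = method, seed = as.integer(seed),
                 params = params,
                 removed_indices = as.integer(removed_indices),
                 duplicated_indices = as.integer(duplicated_indices),
                 synthetic_parents = synthetic_parents,
                 iterations = as.integer(iterations), audit = audit),
            class = "sampling_result")
}

#' @export
print.sampling_result <- function(x, ...) {
  d <- x$dataset
  cat(sprintf(paste0("<sampling_result> method '%s', seed %d: %d x %d ",
                     "(y=1: %d, y=0: %d)\n"),
              x$method, x$seed, nrow(d$X), d$bit_count,
              sum(d$y == 1L), sum(d$y == 0L)))
  cat(sprintf("  removed %d, duplicated %d, synthetic %d, iterations %d\n",
              length(x$removed_indices), length(x$duplicated_indices),
              nrow(x$synthetic_parents), x$iterations))
  invisible(x)
}

# Append rows (duplicates or synthetic) to a dataset with fresh unique ids.
append_rows <- function(dataset, newX, new_y, id_prefix) {
  n_new <- nrow(newX)
  new_ids <- paste0(id_prefix, seq_len(n_new))
  fp_dataset(rbind(dataset$X, newX), c(dataset$y, rep(new_y, n_new)),
             c(dataset$ids, new_ids), dataset$descriptor)
}

#' No-sampling baseline
#'
#' Returns the dataset untouched ("original dataset" condition); the only
#' condition exempt from the exact class-balance contract.
#'
#' @param dataset an [fp_dataset()]
#' @param seed integer seed (recorded but unused)
#' @return a `sampling_result` with empty audit lists
#' @export
sample_none <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "fp_dataset"))
  new_sampling_result(dataset, "none", seed)
}

#' Random under-sampling (RandUS)
#'
#' Removes uniformly chosen majority-class rows until both classes have the
#' minority count.  Minority rows are untouched.
#'
#' @inheritParams sample_none
#' @return a `sampling_result` whose dataset rows are a subset of the input
#' @export
random_undersample <- function(dataset, seed = 1L) {
  cs <- class_split(dataset)
  n_remove <- length(cs$majority_idx) - length(cs$minority_idx)
  removed <- with_seed(seed, sort(sample(cs$majority_idx, n_remove)))
  keep <- setdiff(seq_len(n_compounds(dataset)), removed)
  new_sampling_result(subset_rows(dataset, keep), "randus", seed,
                      removed_indices = removed)
}

#' Random over-sampling (RandOS)
#'
#' Appends duplicates of uniformly chosen (with replacement) minority rows
#' until both classes have the majority count; every original row is
#' retained.
#'
#' @inheritParams sample_none
#' @return a `sampling_result` whose dataset is a superset of the input
#' @export
random_oversample <- function(dataset, seed = 1L) {
  cs <- class_split(dataset)
  n_add <- length(cs$majority_idx) - length(cs$minority_idx)
  dup <- with_seed(seed,
                   sample(cs$minority_idx, n_add, replace = TRUE))
  out <- if (n_add > 0L) {
    append_rows(dataset, dataset$X[dup, , drop = FALSE], cs$minority_label,
                "dup_")
  } else dataset
  new_sampling_result(out, "randos", seed, duplicated_indices = dup)
}

#' MCF-guided augmented random under-sampling (AugRandomUS)
#'
#' Iteratively removes majority rows that are most similar (Tanimoto) to
#' the current most-common-feature fingerprint of the majority class (see
#' [build_mcf()]); the MCF is recomputed after every removal batch, so
#' redundancy near the class core is pruned first and the loss of variance
#' in the majority class is kept low.
#'
#' Per iteration, with `e` the current majority excess over the minority
#' count: the `L = max(1, ceiling(batch_fraction * e))` majority rows most
#' similar to the MCF form the candidate list, and
#' `max(1, ceiling(removal_fraction * L))` of them (capped at `e`) are
#' removed uniformly at random.  Iteration stops at exact balance.
#'
#' @inheritParams sample_none
#' @param batch_fraction fraction of the current excess forming the
#'   candidate list, in `(0, 1]`
#' @param removal_fraction fraction of the candidate list removed per
#'   iteration, in `(0, 1]`
#' @return a `sampling_result`; `audit$iterations` records, per iteration,
#'   the MCF set bits, the candidate batch (original row indices), the
#'   Tanimoto threshold that admitted the batch, and the removed rows.
#' @export
augmented_random_undersample <- function(dataset, seed = 1L,
                                         batch_fraction = 0.1,
                                         removal_fraction = 0.5) {
  stopifnot(batch_fraction > 0, batch_fraction <= 1,
            removal_fraction > 0, removal_fraction <= 1)
  cs <- class_split(dataset)
  n_min <- length(cs$minority_idx)
  alive <- rep(TRUE, n_compounds(dataset))
  removed <- integer(0)
  steps <- list()
  with_seed(seed, {
    repeat {
      maj_alive <- which(alive & dataset$y == cs$majority_label)
      excess <- length(maj_alive) - n_min
      if (excess <= 0L) break
      cur_rows <- which(alive)
      mcf <- build_mcf(dataset$X[maj_alive, , drop = FALSE],
                       dataset$X[cur_rows, , drop = FALSE])
      sims <- tanimoto_to_vector(dataset$X[maj_alive, , drop = FALSE],
                                 mcf$fingerprint)
      L <- max(1L, ceiling(batch_fraction * excess))
      batch <- maj_alive[order(-sims, seq_along(sims))[seq_len(L)]]
      r <- min(excess, max(1L, ceiling(removal_fraction * L)))
      out <- if (length(batch) == 1L) batch else sample(batch, r)
      alive[out] <- FALSE
      removed <- c(removed, out)
      steps[[length(steps) + 1L]] <-
        list(mcf_bits = which(mcf$fingerprint == 1L),
             batch = batch,
             batch_threshold = min(sims[match(batch, maj_alive)]),
             removed = out)
    }
  })
  new_sampling_result(subset_rows(dataset, which(alive)), "augrandus", seed,
                      params = list(batch_fraction = batch_fraction,
                                    removal_fraction = removal_fraction),
                      removed_indices = removed,
                      iterations = length(steps),
                      audit = list(iterations = steps))
}

#' MCF-guided augmented random over-sampling (AugRandOS)
#'
#' Mirror image of [augmented_random_undersample()] acting on the minority
#' class: the MCF is built with the current minority rows as reference
#' class; the candidate list holds the minority rows *least* similar to it
#' (rare, boundary-region structures), and a random part of the list is
#' duplicated each iteration until the minority reaches the majority count.
#' Duplicating the most dissimilar samples keeps the loss of variance low.
#'
#' @inheritParams augmented_random_undersample
#' @param duplication_fraction fraction of the candidate list duplicated
#'   per iteration, in `(0, 1]`
#' @return a `sampling_result`; dataset is a superset of the input.
#'   `duplicated_indices` refer to input rows (duplicates of duplicates are
#'   attributed to their original ancestor row).
#' @export
augmented_random_oversample <- function(dataset, seed = 1L,
                                        batch_fraction = 0.1,
                                        duplication_fraction = 0.5) {
  stopifnot(batch_fraction > 0, batch_fraction <= 1,
            duplication_fraction > 0, duplication_fraction <= 1)
  cs <- class_split(dataset)
  n_maj <- length(cs$majority_idx)
  n_input <- n_compounds(dataset)
  # ancestry of every current minority row in terms of input row indices
  min_rows <- cs$minority_idx     # current minority rows of X (growing)
  ancestor <- cs$minority_idx     # same length; original input row
  X <- dataset$X
  y_all <- dataset$y
  duplicated_idx <- integer(0)
  steps <- list()
  with_seed(seed, {
    repeat {
      deficit <- n_maj - length(min_rows)
      if (deficit <= 0L) break
      Xmin <- X[min_rows, , drop = FALSE]
      mcf <- build_mcf(Xmin, X)
      sims <- tanimoto_to_vector(Xmin, mcf$fingerprint)
      # candidate list capped at the current minority size (the deficit can
      # exceed it when the imbalance is strong)
      L <- min(length(min_rows), max(1L, ceiling(batch_fraction * deficit)))
      batch_pos <- order(sims, seq_along(sims))[seq_len(L)]  # least similar
      d <- min(deficit, max(1L, ceiling(duplication_fraction * L)))
      pick <- if (length(batch_pos) == 1L) rep(batch_pos, d) else {
        sample(batch_pos, d, replace = d > length(batch_pos))
      }
      newX <- Xmin[pick, , drop = FALSE]
      X <- rbind(X, newX)
      y_all <- c(y_all, rep(cs$minority_label, d))
      min_rows <- c(min_rows, nrow(X) - d + seq_len(d))
      ancestor <- c(ancestor, ancestor[pick])
      duplicated_idx <- c(duplicated_idx, ancestor[pick])
      steps[[length(steps) + 1L]] <-
        list(mcf_bits = which(mcf$fingerprint == 1L),
             batch_ancestors = ancestor[batch_pos],
             batch_threshold = max(sims[batch_pos]),
             duplicated = ancestor[pick])
    }
  })
  n_new <- nrow(X) - n_input
  ids <- c(dataset$ids, paste0("dup_", seq_len(n_new)))
  out <- fp_dataset(X, y_all, ids, dataset$descriptor)
  new_sampling_result(out, "augrandos", seed,
                      params = list(batch_fraction = batch_fraction,
                                    duplication_fraction = duplication_fraction),
                      duplicated_indices = duplicated_idx,
                      iterations = length(steps),
                      audit = list(iterations = steps))
}

# Assignment cost of a medoid configuration: sum over all majority rows of
# the Tanimoto similarity to the most similar medoid (ties: lowest medoid
# position).  S is the majority-majority similarity matrix.
kmedoids_cost <- function(S, medoid_pos) {
  sum(apply(S[, medoid_pos, drop = FALSE], 1L, max))
}

#' k-medoids under-sampling by random restarts (kMedoids1)
#'
#' Draws `restarts` independent uniform candidate sets of
#' `n_medoids = minority count` majority rows; for each draw every majority
#' row is assigned to its most similar medoid (Tanimoto) and the overall
#' sum of similarities is computed.  The draw with the highest sum becomes
#' the under-sampled majority class, so each retained row represents a
#' group of structurally related molecules.
#'
#' @inheritParams sample_none
#' @param restarts number of independent random medoid draws (default 100)
#' @param exhaustive if `TRUE`, enumerate every possible medoid set instead
#'   of sampling (tiny instances only); `restarts` is ignored.
#' @return a `sampling_result`; `audit$costs` holds the cost of every
#'   evaluated configuration and `audit$best_cost` the retained maximum.
#' @export
kmedoids_restart_undersample <- function(dataset, seed = 1L, restarts = 100L,
                                         exhaustive = FALSE) {
  cs <- class_split(dataset)
  n_med <- length(cs$minority_idx)
  maj <- cs$majority_idx
  if (length(maj) == n_med) {
    return(new_sampling_result(dataset, "kmedoids1", seed,
                               params = list(restarts = restarts)))
  }
  S <- tanimoto_matrix(dataset$X[maj, , drop = FALSE])
  draws <- if (exhaustive) {
    utils::combn(length(maj), n_med, simplify = FALSE)
  } else {
    with_seed(seed, replicate(restarts,
                              sample(length(maj), n_med), simplify = FALSE))
  }
  costs <- vapply(draws, function(d) kmedoids_cost(S, d), 0)
  best <- which.max(costs)  # ties: earliest draw
  medoids <- maj[sort(draws[[best]])]
  keep <- sort(c(cs$minority_idx, medoids))
  new_sampling_result(subset_rows(dataset, keep), "kmedoids1", seed,
                      params = list(restarts = restarts,
                                    exhaustive = exhaustive),
                      removed_indices = setdiff(maj, medoids),
                      iterations = length(draws),
                      audit = list(costs = costs, best_cost = costs[best]))
}

#' k-medoids under-sampling by random swaps (kMedoids2)
#'
#' Starts from `n_medoids = minority count` uniformly chosen majority rows.
#' Each medoid slot receives `swaps_per_medoid` iterations; in each, the
#' medoid is exchanged with a uniformly chosen non-medoid majority row, the
#' clusters are recomputed and the Tanimoto assignment cost evaluated.  The
#' final medoid set is the best configuration ever observed (best-so-far,
#' including the initial one), not the last.
#'
#' @inheritParams sample_none
#' @param swaps_per_medoid swap iterations allotted to each medoid slot
#'   (default 30)
#' @return a `sampling_result`; `audit$costs` records every evaluated
#'   configuration's cost, starting with the initial one.
#' @export
kmedoids_swap_undersample <- function(dataset, seed = 1L,
                                      swaps_per_medoid = 30L) {
  cs <- class_split(dataset)
  n_med <- length(cs$minority_idx)
  maj <- cs$majority_idx
  if (length(maj) == n_med) {
    return(new_sampling_result(dataset, "kmedoids2", seed,
                               params = list(swaps_per_medoid = swaps_per_medoid)))
  }
  S <- tanimoto_matrix(dataset$X[maj, , drop = FALSE])
  m <- length(maj)
  with_seed(seed, {
    current <- sample(m, n_med)
    costs <- kmedoids_cost(S, current)
    best <- current
    best_cost <- costs[1L]
    for (slot in seq_len(n_med)) {
      for (it in seq_len(swaps_per_medoid)) {
        candidates <- setdiff(seq_len(m), current)
        swap_in <- candidates[sample.int(length(candidates), 1L)]
        current[slot] <- swap_in
        cost <- kmedoids_cost(S, current)
        costs <- c(costs, cost)
        if (cost > best_cost) {
          best_cost <- cost
          best <- current
        }
      }
    }
    medoids <- maj[sort(best)]
    keep <- sort(c(cs$minority_idx, medoids))
    new_sampling_result(subset_rows(dataset, keep), "kmedoids2", seed,
                        params = list(swaps_per_medoid = swaps_per_medoid),
                        removed_indices = setdiff(maj, medoids),
                        iterations = n_med * swaps_per_medoid,
                        audit = list(costs = costs, best_cost = best_cost))
  })
}

#' Binary SMOTE over-sampling (SMOTE-TC / SMOTE-VDM)
#'
#' Creates synthetic minority rows until the classes balance.  Seed rows
#' cycle through a seeded shuffle of the minority class (re-shuffled each
#' pass, so oversampling above 100% spreads near-evenly).  For each
#' synthetic row, the seed row's `k` nearest minority neighbors are found
#' under Tanimoto similarity (`metric = "tanimoto"`, SMOTE-TC) or the Value
#' Difference Metric (`metric = "vdm"`, SMOTE-VDM; the class-conditional
#' statistics are fitted on the dataset handed to the sampler).  Two
#' distinct neighbors are drawn uniformly and each synthetic bit is the
#' 2-of-3 majority vote among seed row and the two neighbors.
#'
#' @inheritParams sample_none
#' @param k neighborhood size (default 5); requires minority count >= k+1
#' @param metric `"tanimoto"` or `"vdm"`
#' @param vdm_exponent exponent of the VDM (default 2)
#' @param vdm_smoothing Laplace smoothing of the VDM conditionals
#' @return a `sampling_result`; `synthetic_parents` records, per synthetic
#'   row, the input row indices of the seed row and both neighbors.
#' @export
smote <- function(dataset, seed = 1L, k = 5L,
                  metric = c("tanimoto", "vdm"), vdm_exponent = 2,
                  vdm_smoothing = 1) {
  metric <- match.arg(metric)
  cs <- class_split(dataset)
  min_idx <- cs$minority_idx
  n_min <- length(min_idx)
  n_add <- length(cs$majority_idx) - n_min
  if (n_min < k + 1L) {
    stop("SMOTE needs at least k+1 = ", k + 1L, " minority rows (have ",
         n_min, "); lower k")
  }
  stats <- if (metric == "vdm") {
    fit_class_value_stats(dataset, smoothing = vdm_smoothing)
  } else NULL
  # k nearest same-class neighbors of each minority row, precomputed on the
  # input minority class (synthetic rows never become parents)
  Xmin <- dataset$X[min_idx, , drop = FALSE]
  nn <- lapply(seq_len(n_min), function(i) {
    k_nearest(i, Xmin, k, metric = metric, stats = stats,
              exponent = vdm_exponent)
  })
  parents <- matrix(integer(0), ncol = 3L)
  newX <- NULL
  if (n_add > 0L) {
    with_seed(seed, {
      schedule <- integer(0)
      while (length(schedule) < n_add) schedule <- c(schedule, sample(n_min))
      schedule <- schedule[seq_len(n_add)]
      parents <- matrix(0L, nrow = n_add, ncol = 3L)
      newX <- matrix(0L, nrow = n_add, ncol = dataset$bit_count)
      for (s in seq_len(n_add)) {
        i <- schedule[s]
        nbrs <- nn[[i]][sample(k, 2L)]
        trio <- rbind(Xmin[i, ], Xmin[nbrs[1L], ], Xmin[nbrs[2L], ])
        newX[s, ] <- as.integer(colSums(trio) >= 2L)
        parents[s, ] <- c(min_idx[i], min_idx[nbrs])
      }
    })
  }
  colnames(parents) <- c("seed_row", "neighbor1", "neighbor2")
  out <- if (n_add > 0L) {
    append_rows(dataset, newX, cs$minority_label, "syn_")
  } else dataset
  method <- if (metric == "tanimoto") "smotetc" else "smotevdm"
  new_sampling_result(out, method, seed,
                      params = list(k = as.integer(k), metric = metric,
                                    vdm_exponent = vdm_exponent,
                                    vdm_smoothing = vdm_smoothing),
                      synthetic_parents = parents)
}

#' Method names understood by [resample()]
#' @return character vector of the nine sampling condition names
#' @export
sampler_methods <- function() {
  c("none", "randus", "augrandus", "randos", "augrandos",
    "kmedoids1", "kmedoids2", "smotetc", "smotevdm")
}

#' Apply a sampling condition by name
#'
#' Uniform dispatcher over the nine sampling conditions; extra arguments
#' are passed to the underlying sampler.
#'
#' @param dataset an [fp_dataset()]
#' @param method one of [sampler_methods()]
#' @param seed integer seed controlling all of the sampler's randomness
#' @param ... method-specific parameters (`k`, `batch_fraction`, ...)
#' @return a `sampling_result`
#' @export
resample <- function(dataset, method, seed = 1L, ...) {
  method <- match.arg(method, sampler_methods())
  switch(method,
         none = sample_none(dataset, seed),
         randus = random_undersample(dataset, seed),
         augrandus = augmented_random_undersample(dataset, seed, ...),
         randos = random_oversample(dataset, seed),
         augrandos = augmented_random_oversample(dataset, seed, ...),
         kmedoids1 = kmedoids_restart_undersample(dataset, seed, ...),
         kmedoids2 = kmedoids_swap_undersample(dataset, seed, ...),
         smotetc = smote(dataset, seed, metric = "tanimoto", ...),
         smotevdm = smote(dataset, seed, metric = "vdm", ...))
}

#' Serialize a sampling audit trail to JSON
#'
#' @param result a `sampling_result`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_audit <- function(result, path) {
  stopifnot(inherits(result, "sampling_result"))
  payload <- list(method = result$method, seed = result$seed,
                  params = result$params,
                  removed_indices = result$removed_indices,
                  duplicated_indices = result$duplicated_indices,
                  synthetic_parents = result$synthetic_parents,
                  iterations = result$iterations,
                  audit = result$audit)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
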