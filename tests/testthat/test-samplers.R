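# Unit and property tests for the nine sampling conditions.

expect_balanced <- function(res) {
  y <- res$dataset$y
  expect_identical(sum(y == 1L), sum(y == 0L))
}

rows_as_keys <- function(X) apply(X, 1, paste, collapse = "")

test_that("sample_none is the identity with empty audit lists", {
  d <- random_dataset(10, 4, 16, seed = 1)
  res <- sample_none(d, seed = 9)
  expect_identical(res$dataset$X, d$X)
  expect_identical(res$dataset$y, d$y)
  expect_length(res$removed_indices, 0)
  expect_length(res$duplicated_indices, 0)
  expect_identical(nrow(res$synthetic_parents), 0L)
  expect_identical(res$iterations, 0L)
})

test_that("random under-sampling removes the right count, deterministically", {
  d <- random_dataset(10, 4, 16, seed = 2)
  res <- random_undersample(d, seed = 5)
  expect_balanced(res)
  expect_length(res$removed_indices, 6)
  expect_true(all(d$y[res$removed_indices] == 0L))
  expect_identical(random_undersample(d, seed = 5)$removed_indices,
                   res$removed_indices)
  # already balanced input -> unchanged membership
  bal <- random_dataset(5, 5, 16, seed = 3)
  expect_identical(random_undersample(bal, seed = 1)$dataset$ids, bal$ids)
  # single-class input errors
  one <- fp_dataset(matrix(1L, 3, 4), c(1, 1, 1))
  expect_error(random_undersample(one), "both classes")
})

test_that("random over-sampling appends duplicates of minority rows", {
  d <- random_dataset(10, 4, 16, seed = 4)
  res <- random_oversample(d, seed = 5)
  expect_balanced(res)
  expect_identical(n_compounds(res$dataset), 20L)
  expect_length(res$duplicated_indices, 6)
  # every appended row is bit-identical to its recorded source row
  appended <- res$dataset$X[17:20 + 0, , drop = FALSE]
  new_rows <- res$dataset$X[(n_compounds(d) + 1):20, , drop = FALSE]
  for (i in seq_len(nrow(new_rows))) {
    expect_identical(new_rows[i, ], d$X[res$duplicated_indices[i], ])
  }
  expect_identical(random_oversample(d, seed = 5)$duplicated_indices,
                   res$duplicated_indices)
})

test_that("augmented under-sampling balances and its audit trail replays", {
  d <- random_dataset(10, 5, 24, seed = 6)
  res <- augmented_random_undersample(d, seed = 8, batch_fraction = 0.5,
                                      removal_fraction = 0.5)
  expect_balanced(res)
  expect_length(res$removed_indices, 5)
  expect_gt(res$iterations, 0)
  # replay: recompute each iteration's MCF from the audited survivor set and
  # confirm every removed row sat at or above the batch-admission threshold
  alive <- rep(TRUE, n_compounds(d))
  for (step in res$audit$iterations) {
    maj_alive <- which(alive & d$y == 0L)
    mcf <- build_mcf(d$X[maj_alive, , drop = FALSE],
                     d$X[alive, , drop = FALSE])
    expect_identical(which(mcf$fingerprint == 1L), step$mcf_bits)
    sims <- vapply(step$removed,
                   function(i) tanimoto_oracle(d$X[i, ], mcf$fingerprint), 0)
    expect_true(all(sims >= step$batch_threshold - 1e-12))
    expect_true(all(step$removed %in% step$batch))
    alive[step$removed] <- FALSE
  }
  expect_identical(sort(res$removed_indices), sort(which(!alive)))
})

test_that("batch_fraction = removal_fraction = 1 still terminates at balance", {
  d <- random_dataset(12, 3, 16, seed = 7)
  res <- augmented_random_undersample(d, seed = 1, batch_fraction = 1,
                                      removal_fraction = 1)
  expect_balanced(res)
})

test_that("augmented over-sampling duplicates audited least-similar rows", {
  d <- random_dataset(12, 3, 24, seed = 9)
  res <- augmented_random_oversample(d, seed = 2, batch_fraction = 0.5,
                                     duplication_fraction = 0.5)
  expect_balanced(res)
  expect_identical(n_compounds(res$dataset), 24L)
  # supersets: all original rows survive
  expect_identical(res$dataset$X[1:15, ], d$X)
  # every appended row duplicates a minority input row
  minority_keys <- rows_as_keys(d$X[d$y == 1L, , drop = FALSE])
  appended_keys <- rows_as_keys(res$dataset$X[16:24, , drop = FALSE])
  expect_true(all(appended_keys %in% minority_keys))
  expect_true(all(d$y[res$duplicated_indices] == 1L))
  # audit: every duplicated ancestor was in its iteration's dissimilar batch
  for (step in res$audit$iterations) {
    expect_true(all(step$duplicated %in% step$batch_ancestors))
  }
  # minority of identical rows: duplicates are that row, terminates
  X <- rbind(matrix(rbinom(8 * 10, 1, 0.5), 8), matrix(1L, 2, 10))
  X[, 1] <- 1L
  dd <- fp_dataset(X, c(rep(0, 8), 1, 1))
  r2 <- augmented_random_oversample(dd, seed = 3)
  expect_balanced(r2)
  expect_true(all(rows_as_keys(r2$dataset$X[11:16, , drop = FALSE]) ==
                    paste(rep(1, 10), collapse = "")))
})

test_that("kMedoids1 matches the exhaustive oracle on tiny instances", {
  for (seed in 1:4) {
    d <- random_dataset(6, 2, 12, seed = 100 + seed)
    maj_X <- d$X[d$y == 0L, , drop = FALSE]
    oracle <- kmedoids_bruteforce(maj_X, 2)
    res <- kmedoids_restart_undersample(d, seed = seed, exhaustive = TRUE)
    expect_balanced(res)
    expect_equal(res$audit$best_cost, oracle$best_cost)
    # retained majority rows are a subset of the input majority rows
    expect_true(all(res$dataset$ids %in% d$ids))
  }
})

test_that("kMedoids1 random restarts are cost-monotone and deterministic", {
  d <- random_dataset(20, 6, 24, seed = 12)
  res <- kmedoids_restart_undersample(d, seed = 4, restarts = 25)
  expect_balanced(res)
  expect_identical(res$iterations, 25L)
  expect_equal(res$audit$best_cost, max(res$audit$costs))
  res2 <- kmedoids_restart_undersample(d, seed = 4, restarts = 25)
  expect_identical(res$removed_indices, res2$removed_indices)
})

test_that("kMedoids2 improves on its start and is bounded by the optimum", {
  for (seed in 1:4) {
    d <- random_dataset(5, 2, 12, seed = 200 + seed)
    maj_X <- d$X[d$y == 0L, , drop = FALSE]
    oracle <- kmedoids_bruteforce(maj_X, 2)
    res <- kmedoids_swap_undersample(d, seed = seed, swaps_per_medoid = 30)
    expect_balanced(res)
    expect_gte(res$audit$best_cost, res$audit$costs[1])   # >= initial
    expect_lte(res$audit$best_cost, oracle$best_cost + 1e-12)
    expect_true(all(res$dataset$ids %in% d$ids))          # real instances
  }
})

test_that("SMOTE synthesizes 2-of-3 vote rows and balances exactly", {
  # hand example: seed [1,1,0], neighbors [1,0,0], [1,1,1] -> [1,1,0]
  trio <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1))
  expect_identical(as.integer(colSums(trio) >= 2), c(1L, 1L, 0L))

  d <- random_dataset(20, 8, 24, seed = 14)
  res <- smote(d, seed = 3, k = 5)
  expect_balanced(res)
  expect_identical(nrow(res$synthetic_parents), 12L)
  expect_identical(n_compounds(res$dataset), 40L)
  # exhaustive post-hoc parent vote check
  syn <- res$dataset$X[29:40, , drop = FALSE]
  for (i in seq_len(nrow(syn))) {
    par <- res$synthetic_parents[i, ]
    expect_true(all(d$y[par] == 1L))
    votes <- d$X[par[1], ] + d$X[par[2], ] + d$X[par[3], ]
    expect_identical(syn[i, ], as.integer(votes >= 2L))
    expect_identical(length(unique(par[2:3])), 2L)  # two distinct neighbors
  }
  # all three parents identical -> synthetic identical to them
  X <- rbind(matrix(rbinom(10 * 12, 1, 0.5), 10),
             matrix(rep(c(1L, 0L), each = 6), 7, 12, byrow = TRUE))
  X[, 1] <- 1L
  dd <- fp_dataset(X, c(rep(0, 10), rep(1, 7)))
  r2 <- smote(dd, seed = 1, k = 5)
  expect_true(all(rows_as_keys(r2$dataset$X[18:20, , drop = FALSE]) ==
                    rows_as_keys(X[11, , drop = FALSE])))
  expect_error(smote(random_dataset(10, 4, 8, seed = 1), k = 5), "lower k")
})

test_that("SMOTE-VDM uses VDM neighborhoods and audits parents", {
  d <- random_dataset(18, 7, 24, seed = 15)
  res <- smote(d, seed = 6, k = 4, metric = "vdm")
  expect_balanced(res)
  expect_identical(res$method, "smotevdm")
  stats <- fit_class_value_stats(d)
  min_idx <- which(d$y == 1L)
  for (i in seq_len(nrow(res$synthetic_parents))) {
    par <- res$synthetic_parents[i, ]
    seed_pos <- match(par[1], min_idx)
    nn <- k_nearest_oracle(seed_pos, d$X[min_idx, , drop = FALSE], 4,
                           function(a, b) vdm_oracle(a, b, stats, 2),
                           decreasing = FALSE)
    expect_true(all(match(par[2:3], min_idx) %in% nn))
  }
})

test_that("all nine conditions are deterministic under a fixed seed", {
  d <- random_dataset(16, 6, 32, seed = 16)
  for (m in sampler_methods()) {
    r1 <- resample(d, m, seed = 11)
    r2 <- resample(d, m, seed = 11)
    expect_identical(r1$dataset$X, r2$dataset$X, label = m)
    expect_identical(r1$dataset$ids, r2$dataset$ids, label = m)
    expect_identical(r1$removed_indices, r2$removed_indices, label = m)
    expect_identical(r1$duplicated_indices, r2$duplicated_indices, label = m)
    expect_identical(r1$synthetic_parents, r2$synthetic_parents, label = m)
  }
})

test_that("samplers never hard-wire the active class as minority", {
  # actives are the MAJORITY here; samplers must balance on the inactives
  set.seed(17)
  X <- matrix(rbinom(20 * 16, 1, 0.4), 20); X[, 1] <- 1L
  d <- fp_dataset(X, c(rep(1L, 14), rep(0L, 6)))
  for (m in setdiff(sampler_methods(), "none")) {
    res <- resample(d, m, seed = 2)
    y <- res$dataset$y
    expect_identical(sum(y == 1L), sum(y == 0L), label = m)
  }
  res <- random_undersample(d, seed = 1)
  expect_true(all(d$y[res$removed_indices] == 1L))
})

test_that("write_audit serializes a valid JSON audit trail", {
  d <- random_dataset(12, 5, 16, seed = 18)
  res <- smote(d, seed = 2, k = 4)
  path <- tempfile(fileext = ".json")
  write_audit(res, path)
  audit <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(audit$method, "smotetc")
  expect_identical(audit$seed, 2L)
  expect_identical(nrow(audit$synthetic_parents), nrow(res$synthetic_parents))
  unlink(path)
})
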