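test_that("confusion counts enumerate the 2x2 table", {
  cf <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(unclass(cf)[c("tp", "fn", "tn", "fp")],
                   list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_identical(perfect$fp + perfect$fn, 0L)
  allneg <- confusion(c(1, 0, 1), c(0, 0, 0))
  expect_identical(allneg$tp, 0L)
  expect_error(confusion(c(1, 0), c(1, 0, 0)), "length mismatch")
})

test_that("metrics match hand formulas and flag undefined ratios", {
  m <- metrics_from_confusion(structure(list(tp = 8L, fn = 2L, tn = 9L,
                                             fp = 1L), class = "confusion"))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f_measure, 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8))
  expect_length(m$flags, 0)

  p <- metrics_from_confusion(confusion(c(1, 0, 1), c(1, 0, 1)))
  expect_true(all(unlist(p[c("accuracy", "sensitivity", "specificity",
                             "f_measure")]) == 1))

  z <- metrics_from_confusion(confusion(c(1, 1, 0), c(0, 0, 0)))
  expect_identical(z$f_measure, 0)
  expect_true("precision" %in% z$flags || "f_measure" %in% z$flags)
})

test_that("metrics agree with a brute-force recount on 200 random instances", {
  set.seed(19)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    yt <- rbinom(n, 1, 0.5); yp <- rbinom(n, 1, 0.5)
    cf <- confusion(yt, yp)
    m <- metrics_from_confusion(cf)
    tp <- sum(yt & yp); tn <- sum(!yt & !yp)
    expect_equal(m$accuracy, (tp + tn) / n)
    if (sum(yt) > 0) expect_equal(m$sensitivity, tp / sum(yt))
    if (sum(!yt) > 0) expect_equal(m$specificity, tn / sum(!yt))
  }
})

test_that("roc_auc equals the pairwise oracle; constant scores give 0.5", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_identical(roc_auc(c(1, 0, 1, 0, 1), rep(0.3, 5)), 0.5)
  set.seed(20)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(roc_auc(y, s), auc_oracle(y, s))
  }
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("stratified folds preserve class proportions within one sample", {
  set.seed(21)
  y <- c(rep(0L, 83), rep(1L, 17))
  fold <- stratified_folds(y, 5, seed = 2)
  expect_identical(sort(unique(fold)), 1:5)
  for (f in 1:5) {
    expect_true(abs(sum(y[fold == f] == 1L) - 17 / 5) <= 1)
  }
  expect_identical(stratified_folds(y, 5, seed = 2), fold)
  expect_error(stratified_folds(y, 20, seed = 1), "minority")
})

test_that("cross-validation holds every row out exactly once, never leaks", {
  d <- random_dataset(40, 12, 24, seed = 22)
  folds <- stratified_folds(d$y, 4, seed = 3)
  block <- cross_validate(d, "smotetc", sampler_params = list(k = 3),
                          n_folds = 4, n_trees = 30, seed = 3, folds = folds)
  expect_identical(nrow(block$folds), 4L)
  # held-out union = dataset, each row once
  expect_identical(sort(unlist(lapply(1:4, function(f) which(folds == f)))),
                   1:52)
  # evaluated sample counts per fold match the held-out part sizes
  per_fold_n <- block$folds$tp + block$folds$fp + block$folds$tn +
    block$folds$fn
  expect_identical(as.integer(per_fold_n),
                   as.integer(table(folds)[as.character(1:4)]))
  # summary carries mean and sd for all five metrics
  expect_identical(block$summary$metric,
                   c("accuracy", "sensitivity", "specificity", "f_measure",
                     "auc"))
})

test_that("no-sampling CV on separable synthetic data scores >= 0.95", {
  gen <- generate(generator_spec(n_majority = 60, n_minority = 30,
                                 flip_noise = 0.02, overlap = 0),
                  seed = 5)
  block <- cross_validate(gen$dataset, "none", n_folds = 5, n_trees = 60,
                          seed = 5)
  acc <- block$summary$mean[block$summary$metric == "accuracy"]
  expect_gte(acc, 0.95)
})

test_that("external validation reports conserved counts and test-set ids", {
  pair <- generate_paperlike_pair(generator_spec(n_majority = 80,
                                                 n_minority = 20,
                                                 flip_noise = 0.15),
                                  test_fraction = 0.25, seed = 6)
  blk <- external_validate(pair$train, pair$test, "randus", n_trees = 50,
                           seed = 6)
  m <- blk$metrics
  expect_identical(m$fn + m$tp, sum(pair$test$y == 1L))  # conservation
  expect_identical(m$fp + m$tn, sum(pair$test$y == 0L))
  expect_true(all(blk$misclassified$id %in% pair$test$ids))
  expect_identical(sum(blk$misclassified$type == "FN"), m$fn)
  # resubstitution sanity: test = train, no sampling, separable data
  gen <- generate(generator_spec(n_majority = 40, n_minority = 20,
                                 flip_noise = 0.02, overlap = 0), seed = 7)
  re <- external_validate(gen$dataset, gen$dataset, "none", n_trees = 50,
                          seed = 7)
  expect_gte(re$metrics$accuracy, 0.98)
  expect_error(external_validate(pair$train,
                                 fp_dataset(matrix(1L, 2, 8), c(1, 0)),
                                 "none"),
               "bit widths differ")
})

test_that("run_comparison shares fold splits and reports the gap column", {
  d <- random_dataset(36, 12, 20, seed = 23)
  rep <- run_comparison(d, c("none", "randus", "smotetc"),
                        n_folds = 3, n_trees = 25, seed = 4)
  expect_identical(nrow(rep$summary), 3L)
  expect_equal(rep$summary$gap,
               abs(rep$summary$sensitivity - rep$summary$specificity))
  # shared split: per-fold evaluated counts identical across conditions
  sizes <- lapply(rep$cv, function(b) b$folds$tp + b$folds$fp + b$folds$tn +
                    b$folds$fn)
  expect_identical(sizes[[1]], sizes[[2]])
  expect_identical(sizes[[1]], sizes[[3]])
})

test_that("evaluation reports round-trip through JSON losslessly", {
  d <- random_dataset(30, 10, 16, seed = 24)
  rep <- run_comparison(d, c("none", "randus"), n_folds = 3, n_trees = 20,
                        seed = 8)
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$summary, rep$summary)
  expect_equal(back$cv$none$folds, rep$cv$none$folds)
  expect_equal(back$cv$randus$summary, rep$cv$randus$summary)
  expect_identical(back$config$n_trees, rep$config$n_trees)
  unlink(path)
})

test_that("leaky mode warns", {
  d <- random_dataset(24, 8, 16, seed = 25)
  expect_warning(cross_validate(d, "randos", n_folds = 2, n_trees = 10,
                                seed = 1, leaky = TRUE),
                 "leak")
})
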