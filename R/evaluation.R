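# Measurement harness: confusion-matrix metrics, rank-based ROC-AUC,
# stratified k-fold cross-validation with resampling applied inside the
# training folds, external-set validation, and multi-condition comparison.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred binary vectors of equal length; 1 = positive/active
#' @return list of class `confusion` with `tp`, `fp`, `tn`, `fn`
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  }
  check_binary_vec(y_true, "y_true"); check_binary_vec(y_pred, "y_pred")
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fn = sum(y_true == 1 & y_pred == 0)),
            class = "confusion")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (true positive rate, `tp / (tp + fn)`),
#' specificity (true negative rate, `tn / (tn + fp)`) and F-measure
#' (harmonic mean of precision and recall).  A metric whose denominator is
#' zero is reported as 0 and named in the `flags` attribute-carrying
#' element, so aggregate tables never silently drop folds.
#'
#' @param c a [confusion()] result
#' @return list with `accuracy`, `sensitivity`, `specificity`,
#'   `f_measure` and `flags` (character vector of metrics that were
#'   undefined and zero-filled)
#' @export
metrics_from_confusion <- function(c) {
  stopifnot(inherits(c, "confusion"))
  total <- c$tp + c$fp + c$tn + c$fn
  if (total == 0) stop("empty confusion: no evaluated samples")
  flags <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      0
    } else num / den
  }
  sens <- safe_div(c$tp, c$tp + c$fn, "sensitivity")
  spec <- safe_div(c$tn, c$tn + c$fp, "specificity")
  prec <- safe_div(c$tp, c$tp + c$fp, "precision")
  f <- if (prec + sens == 0) {
    flags <- c(flags, "f_measure")
    0
  } else 2 * prec * sens / (prec + sens)
  list(accuracy = (c$tp + c$tn) / total, sensitivity = sens,
       specificity = spec, f_measure = f, flags = unique(flags))
}

#' Area under the ROC curve
#'
#' Computed via the rank statistic (Mann-Whitney): the probability that a
#' random positive outranks a random negative, ties counting one half.
#' Constant scores therefore give exactly 0.5 (a random classifier sits on
#' the ROC diagonal).
#'
#' @param y_true binary truth vector containing both classes
#' @param scores real-valued classifier scores, higher = more positive
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  check_binary_vec(y_true, "y_true")
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc needs both classes in y_true")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Assigns each row to one of `n_folds` folds so the class ratio of every
#' fold matches the global ratio within one sample (each class is shuffled
#' and dealt round-robin).
#'
#' @param y binary label vector
#' @param n_folds number of folds
#' @param seed integer seed
#' @return integer fold id (1..n_folds) per row
#' @export
stratified_folds <- function(y, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (min(sum(y == 1), sum(y == 0)) < n_folds) {
    stop("n_folds (", n_folds, ") exceeds the minority class count")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and tags.
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(tags) * seq_along(utf8ToInt(tags)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 13) %% 2147483629)
}

fit_and_score <- function(train, test, n_trees, seed) {
  model <- train_rf(train, n_trees = n_trees, seed = seed)
  score <- predict(model, test, type = "prob")
  pred <- as.integer(score >= 0.5)
  cf <- confusion(test$y, pred)
  met <- metrics_from_confusion(cf)
  auc <- if (length(unique(test$y)) == 2L) roc_auc(test$y, score) else NA_real_
  list(confusion = cf, metrics = met, auc = auc, score = score, pred = pred)
}

#' Cross-validate one sampling condition
#'
#' Stratified k-fold cross-validation of a random forest under a sampling
#' condition.  Inside every fold the sampler is applied to the training
#' part only; the held-out part is never resampled, so duplicated or
#' synthetic rows can never leak into evaluation.  A leaky variant
#' (resampling the full dataset before splitting, as some studies do) is
#' available behind `leaky = TRUE` and warns loudly.
#'
#' @param dataset an [fp_dataset()]
#' @param method a [sampler_methods()] name
#' @param sampler_params named list of extra sampler arguments
#' @param n_folds folds (default 10)
#' @param n_trees forest size per fold (default 1000)
#' @param seed integer seed governing folds, samplers and forests
#' @param folds optional precomputed fold assignment (shared across
#'   conditions by [run_comparison()])
#' @param leaky if `TRUE`, resample before splitting (score-inflating;
#'   for reproduction studies only)
#' @return list of class `cv_block`: `method`, `folds` (per-fold metric
#'   data frame with columns fold/accuracy/sensitivity/specificity/
#'   f_measure/auc/flags), `summary` (mean and sd per metric), totals of
#'   the fold confusions, and the configuration used
#' @export
cross_validate <- function(dataset, method, sampler_params = list(),
                           n_folds = 10L, n_trees = 1000L, seed = 1L,
                           folds = NULL, leaky = FALSE) {
  stopifnot(inherits(dataset, "fp_dataset"))
  method <- match.arg(method, sampler_methods())
  if (leaky) {
    warning("leaky = TRUE: resampling before the fold split leaks ",
            "duplicated/synthetic rows into held-out folds and inflates ",
            "scores; use only for reproduction studies")
    res <- do.call(resample,
                   c(list(dataset, method, derive_seed(seed, method, "pre")),
                     sampler_params))
    dataset <- res$dataset
    folds <- NULL
  }
  if (is.null(folds)) folds <- stratified_folds(dataset$y, n_folds,
                                                derive_seed(seed, "folds"))
  n_folds <- max(folds)
  rows <- lapply(seq_len(n_folds), function(f) {
    train <- subset_rows(dataset, which(folds != f))
    test <- subset_rows(dataset, which(folds == f))
    if (!leaky) {
      res <- do.call(resample,
                     c(list(train, method, derive_seed(seed, method, f)),
                       sampler_params))
      train <- res$dataset
    }
    sc <- fit_and_score(train, test, n_trees,
                        derive_seed(seed, method, f, "rf"))
    data.frame(fold = f, accuracy = sc$metrics$accuracy,
               sensitivity = sc$metrics$sensitivity,
               specificity = sc$metrics$specificity,
               f_measure = sc$metrics$f_measure, auc = sc$auc,
               tp = sc$confusion$tp, fp = sc$confusion$fp,
               tn = sc$confusion$tn, fn = sc$confusion$fn,
               flags = paste(sc$metrics$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "f_measure",
                   "auc")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(tab[metric_cols], mean, 0, na.rm = TRUE),
    sd = vapply(tab[metric_cols], stats::sd, 0, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(method = method, mode = "cross_validation",
                 folds = tab, summary = summary,
                 config = list(n_folds = as.integer(n_folds),
                               n_trees = as.integer(n_trees),
                               seed = as.integer(seed),
                               sampler_params = sampler_params,
                               leaky = leaky)),
            class = "cv_block")
}

#' External-set validation of one sampling condition
#'
#' The sampler is applied to the training set only; the independent test
#' set is never touched.  Besides the five metrics, the per-compound
#' misclassification list (false negatives and false positives with their
#' ids) is reported.
#'
#' @param train,test [fp_dataset()]s with equal bit width
#' @inheritParams cross_validate
#' @return list of class `external_block` with `metrics` (single-row data
#'   frame), `misclassified` (data frame `id`, `type` in FN/FP), and the
#'   configuration
#' @export
external_validate <- function(train, test, method, sampler_params = list(),
                              n_trees = 1000L, seed = 1L) {
  stopifnot(inherits(train, "fp_dataset"), inherits(test, "fp_dataset"))
  if (train$bit_count != test$bit_count) {
    stop("train and test bit widths differ (", train$bit_count, " vs ",
         test$bit_count, ")")
  }
  method <- match.arg(method, sampler_methods())
  res <- do.call(resample,
                 c(list(train, method, derive_seed(seed, method, "ext")),
                   sampler_params))
  sc <- fit_and_score(res$dataset, test, n_trees,
                      derive_seed(seed, method, "ext", "rf"))
  if (is.na(sc$auc)) {
    warning("single-class test set: AUC undefined, reported as NA")
  }
  mis <- data.frame(
    id = c(test$ids[test$y == 1 & sc$pred == 0],
           test$ids[test$y == 0 & sc$pred == 1]),
    type = c(rep("FN", sc$confusion$fn), rep("FP", sc$confusion$fp)),
    stringsAsFactors = FALSE)
  metrics <- data.frame(accuracy = sc$metrics$accuracy,
                        sensitivity = sc$metrics$sensitivity,
                        specificity = sc$metrics$specificity,
                        f_measure = sc$metrics$f_measure, auc = sc$auc,
                        tp = sc$confusion$tp, fp = sc$confusion$fp,
                        tn = sc$confusion$tn, fn = sc$confusion$fn,
                        flags = paste(sc$metrics$flags, collapse = ";"),
                        stringsAsFactors = FALSE)
  structure(list(method = method, mode = "external", metrics = metrics,
                 misclassified = mis,
                 config = list(n_trees = as.integer(n_trees),
                               seed = as.integer(seed),
                               sampler_params = sampler_params)),
            class = "external_block")
}

#' Compare sampling conditions under a shared cross-validation split
#'
#' Runs [cross_validate()] (and [external_validate()] when a test set is
#' given) for every requested condition.  All conditions share one fold
#' assignment so differences are attributable to the samplers, not to the
#' split.  The summary table carries the sensitivity-specificity gap
#' `|sensitivity - specificity|` per condition, the quantity the samplers
#' are designed to shrink.
#'
#' @param train an [fp_dataset()]
#' @param conditions character vector of [sampler_methods()] names, or a
#'   named list `list(method = list(params...))`
#' @param test optional external [fp_dataset()]
#' @inheritParams cross_validate
#' @return list of class `evaluation_report`: `cv` (per-condition
#'   `cv_block`s), `external` (per-condition `external_block`s or NULL),
#'   `summary` data frame (condition x mean metrics + gap), `config`
#' @export
run_comparison <- function(train, conditions = sampler_methods(),
                           test = NULL, n_folds = 10L, n_trees = 1000L,
                           seed = 1L) {
  if (!is.list(conditions)) {
    conditions <- stats::setNames(replicate(length(conditions), list(),
                                            simplify = FALSE),
                                  conditions)
  }
  folds <- stratified_folds(train$y, n_folds, derive_seed(seed, "folds"))
  cv <- lapply(names(conditions), function(m) {
    cross_validate(train, m, conditions[[m]], n_folds = n_folds,
                   n_trees = n_trees, seed = seed, folds = folds)
  })
  names(cv) <- names(conditions)
  ext <- NULL
  if (!is.null(test)) {
    ext <- lapply(names(conditions), function(m) {
      external_validate(train, test, m, conditions[[m]],
                        n_trees = n_trees, seed = seed)
    })
    names(ext) <- names(conditions)
  }
  summary <- do.call(rbind, lapply(names(cv), function(m) {
    s <- cv[[m]]$summary
    means <- stats::setNames(s$mean, s$metric)
    data.frame(condition = m, accuracy = means[["accuracy"]],
               sensitivity = means[["sensitivity"]],
               specificity = means[["specificity"]],
               f_measure = means[["f_measure"]], auc = means[["auc"]],
               gap = abs(means[["sensitivity"]] - means[["specificity"]]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(cv = cv, external = ext, summary = summary,
                 config = list(n_folds = as.integer(n_folds),
                               n_trees = as.integer(n_trees),
                               seed = as.integer(seed),
                               conditions = conditions)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d condition(s), %d-fold CV, %d trees, seed %d\n",
              nrow(x$summary), x$config$n_folds, x$config$n_trees,
              x$config$seed))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' Full-precision JSON serialization; [read_report()] restores the report
#' losslessly.  Note: the sensitivity reported throughout this package is
#' the true positive rate `tp / (tp + fn)`.
#'
#' @param report an `evaluation_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  payload <- list(
    cv = lapply(report$cv, unclass),
    external = if (is.null(report$external)) NULL else
      lapply(report$external, unclass),
    summary = report$summary,
    config = report$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#' @param path JSON path
#' @return an `evaluation_report`
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_df <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
  cv <- lapply(raw$cv, function(b) {
    b$folds <- fix_df(b$folds)
    b$summary <- fix_df(b$summary)
    b$config$sampler_params <- as.list(b$config$sampler_params)
    structure(b, class = "cv_block")
  })
  ext <- NULL
  if (!is.null(raw$external) && length(raw$external)) {
    ext <- lapply(raw$external, function(b) {
      b$metrics <- fix_df(b$metrics)
      b$misclassified <- fix_df(b$misclassified)
      b$config$sampler_params <- as.list(b$config$sampler_params)
      structure(b, class = "external_block")
    })
  }
  conditions <- lapply(raw$config$conditions, as.list)
  structure(list(cv = cv, external = ext, summary = fix_df(raw$summary),
                 config = list(n_folds = raw$config$n_folds,
                               n_trees = raw$config$n_trees,
                               seed = raw$config$seed,
                               conditions = conditions)),
            class = "evaluation_report")
}
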