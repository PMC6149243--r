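#' Train a random-forest classifier on binary fingerprints
#'
#' A Breiman-style forest specialised to binary predictors (this package
#' bundles its own compiled implementation): per tree a bootstrap sample,
#' at each node `mtry` features drawn at random and the one with the most
#' homogeneous binary split (largest Gini decrease) used as the decision
#' node, trees grown to purity.  The forest scores new rows with the
#' fraction of tree votes for the active class.
#'
#' @param dataset an [fp_dataset()] containing both classes
#' @param n_trees number of trees (default 1000)
#' @param seed integer seed; fixed seed + data give identical forests
#' @param mtry features tried per node; default `floor(sqrt(bit_count))`
#' @return an object of class `fp_rf` usable with [predict.fp_rf()]
#' @export
train_rf <- function(dataset, n_trees = 1000L, seed = 1L, mtry = NULL) {
  stopifnot(inherits(dataset, "fp_dataset"), n_trees >= 1L)
  class_split(dataset)  # errors on single-class input
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(dataset$bit_count)))
  mtry <- min(as.integer(mtry), dataset$bit_count)
  forest <- with_seed(seed,
                      .rf_fit_cpp(dataset$X, dataset$y,
                                  as.integer(n_trees), mtry))
  structure(list(forest = forest, n_trees = as.integer(n_trees),
                 mtry = mtry, bit_count = dataset$bit_count,
                 seed = as.integer(seed)),
            class = "fp_rf")
}

#' Predict with a fingerprint random forest
#'
#' @param object an `fp_rf` model from [train_rf()]
#' @param newdata an [fp_dataset()] or binary matrix with matching width
#' @param type `"prob"` for the fraction of tree votes for the active
#'   class, `"class"` for the 0/1 label at threshold 0.5 (score >= 0.5
#'   predicts active)
#' @param ... unused
#' @return numeric score vector or integer label vector
#' @export
predict.fp_rf <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "fp_dataset")) newdata$X else newdata
  storage.mode(X) <- "integer"
  if (ncol(X) != object$bit_count) {
    stop("newdata has ", ncol(X), " bits; model expects ", object$bit_count)
  }
  score <- .rf_predict_cpp(object$forest, X)
  if (type == "prob") score else as.integer(score >= 0.5)
}

#' @export
print.fp_rf <- function(x, ...) {
  cat(sprintf("<fp_rf> %d trees, mtry %d, %d bits (seed %d)\n",
              x$n_trees, x$mtry, x$bit_count, x$seed))
  invisible(x)
}
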