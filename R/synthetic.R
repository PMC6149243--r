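# Synthetic imbalanced fingerprint generator: a Bernoulli-mixture model
# over bit space.  It emulates the structure of imbalanced toxicity
# datasets -- a strong class imbalance, a structurally heterogeneous
# minority (active) class spread over several subclusters, a more
# homogeneous majority class, and optional minority prototypes perturbed
# from majority prototypes so that borderline samples sit near the
# decision boundary.  No chemistry is generated: fingerprint space is the
# algorithms' true domain.  At the default flip noise of 0.2 the classes
# overlap: a forest still ranks well (high AUC) but its 0.5 threshold is
# biased toward the majority class, the pathology resampling repairs.

#' Specification for the synthetic fingerprint generator
#'
#' Defaults describe the regime the package's evaluation targets: 166 bits
#' (MACCS width), imbalance ratio 0.1 (within the 0.04-0.27 range typical
#' of curated toxicity datasets), three minority subclusters versus one
#' majority cluster, moderate prototype density, high per-bit flip noise,
#' and half of the minority prototypes perturbed from majority prototypes.
#'
#' @param n_bits fingerprint width (default 166)
#' @param n_majority,n_minority class sizes (defaults 300 / 30, ratio 0.1)
#' @param n_minority_clusters minority subclusters (default 3; actives in
#'   real datasets are structurally diverse)
#' @param n_majority_clusters majority clusters (default 1)
#' @param prototype_density expected fraction of set bits in a cluster
#'   prototype (default 0.3, comparable to MACCS fingerprints of drug-like
#'   molecules)
#' @param flip_noise per-bit Bernoulli flip probability around a prototype
#'   (default 0.2, the high-noise overlapping regime; lower it toward 0.05
#'   for cleanly separable classes)
#' @param overlap fraction of minority prototypes that are perturbed
#'   copies of majority prototypes rather than fresh draws (default 0.5;
#'   creates borderline actives near the decision boundary)
#' @return a validated list of class `generator_spec`
#' @export
generator_spec <- function(n_bits = 166L, n_majority = 300L,
                           n_minority = 30L, n_minority_clusters = 3L,
                           n_majority_clusters = 1L,
                           prototype_density = 0.3, flip_noise = 0.2,
                           overlap = 0.5) {
  spec <- list(n_bits = as.integer(n_bits),
               n_majority = as.integer(n_majority),
               n_minority = as.integer(n_minority),
               n_minority_clusters = as.integer(n_minority_clusters),
               n_majority_clusters = as.integer(n_majority_clusters),
               prototype_density = prototype_density,
               flip_noise = flip_noise, overlap = overlap)
  with(spec, {
    stopifnot(n_bits > 0L, n_majority > 0L, n_minority > 0L,
              n_minority_clusters > 0L, n_majority_clusters > 0L,
              prototype_density >= 0, prototype_density <= 1,
              flip_noise >= 0, flip_noise <= 1,
              overlap >= 0, overlap <= 1)
  })
  structure(spec, class = "generator_spec")
}

rbern_matrix <- function(n, p, prob) {
  matrix(as.integer(stats::runif(n * p) < prob), nrow = n, ncol = p)
}

#' Generate a synthetic imbalanced fingerprint dataset
#'
#' Draws cluster prototypes per class (minority prototypes optionally
#' perturbed from majority prototypes according to `spec$overlap`), then
#' emits each row as its cluster's prototype with independent per-bit
#' flips at `spec$flip_noise`.  Minority rows are labeled 1 (active).
#' The latent row-to-cluster map is returned for test assertions but is
#' never written into the dataset file format, so downstream code cannot
#' consume it.
#'
#' @param spec a [generator_spec()]
#' @param seed integer seed; fixed seed + spec reproduce the dataset
#' @return list with `dataset` (an [fp_dataset()]) and `clusters`
#'   (data frame `row`, `class`, `cluster`)
#' @export
generate <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(seed, {
    proto_maj <- rbern_matrix(spec$n_majority_clusters, spec$n_bits,
                              spec$prototype_density)
    n_overlap <- round(spec$overlap * spec$n_minority_clusters)
    proto_min <- matrix(0L, spec$n_minority_clusters, spec$n_bits)
    for (c in seq_len(spec$n_minority_clusters)) {
      if (c <= n_overlap) {
        base <- proto_maj[sample(spec$n_majority_clusters, 1L), ]
        flips <- stats::runif(spec$n_bits) < spec$flip_noise
        proto_min[c, ] <- ifelse(flips, 1L - base, base)
      } else {
        proto_min[c, ] <- as.integer(stats::runif(spec$n_bits) <
                                       spec$prototype_density)
      }
    }
    emit <- function(n, protos) {
      cl <- sample(nrow(protos), n, replace = TRUE)
      flips <- rbern_matrix(n, spec$n_bits, spec$flip_noise)
      X <- abs(protos[cl, , drop = FALSE] - flips)  # XOR
      list(X = X, cluster = cl)
    }
    maj <- emit(spec$n_majority, proto_maj)
    mnr <- emit(spec$n_minority, proto_min)
    X <- rbind(maj$X, mnr$X)
    y <- c(rep(0L, spec$n_majority), rep(1L, spec$n_minority))
    n <- nrow(X)
    dataset <- fp_dataset(X, y, sprintf("cmp%05d", seq_len(n)), "generic")
    clusters <- data.frame(
      row = seq_len(n),
      class = y,
      cluster = c(maj$cluster, mnr$cluster))
    list(dataset = dataset, clusters = clusters)
  })
}

#' Generate a matched train/test pair
#'
#' Generates one dataset from `spec` and splits it by a stratified random
#' split, so the test block preserves the class ratio within rounding --
#' mirroring the matched train/independent-test ratios of curated toxicity
#' benchmarks.
#'
#' @param spec a [generator_spec()]
#' @param test_fraction fraction of rows held out, in (0, 1)
#' @param seed integer seed
#' @return list with `train` and `test` [fp_dataset()]s
#' @export
generate_paperlike_pair <- function(spec = generator_spec(),
                                    test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  gen <- generate(spec, seed)
  d <- gen$dataset
  with_seed(derive_seed(seed, "split"), {
    test_idx <- unlist(lapply(c(0L, 1L), function(cls) {
      idx <- which(d$y == cls)
      n_test <- round(test_fraction * length(idx))
      sample(idx, n_test)
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n_compounds(d)), test_idx)
  if (length(test_idx) == 0L || length(train_idx) == 0L ||
      length(unique(d$y[test_idx])) < 2L ||
      length(unique(d$y[train_idx])) < 2L) {
    stop("split leaves a class empty; adjust test_fraction or class sizes")
  }
  list(train = subset_rows(d, train_idx), test = subset_rows(d, test_idx))
}
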