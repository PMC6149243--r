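#' Build a most-common-feature (MCF) fingerprint profile
#'
#' The MCF fingerprint is a synthetic reference fingerprint summarizing the
#' most common features of a class.  Construction:
#' \enumerate{
#'   \item The threshold `avg_frequency` is the overall average per-bit
#'     frequency of ones in the reference class (the class being profiled:
#'     the majority class when guiding under-sampling, the minority class
#'     when guiding over-sampling).
#'   \item For each bit the relative frequency of ones in the complete
#'     dataset (`frequency_rows`) is computed; bits strictly above the
#'     threshold are recorded as candidates, sorted by descending frequency
#'     (ties: lower bit index first).
#'   \item The number of set bits `n_features` is the reference class's
#'     mean set-bit count per row, rounded half up.
#'   \item The fingerprint sets the top `n_features` candidate bits.
#' }
#' If fewer candidates than `n_features` clear the threshold, the remaining
#' bits are taken by descending dataset frequency regardless of the
#' threshold and the profile is flagged (`fallback = TRUE`).
#'
#' @param reference_rows binary matrix of the class being profiled
#' @param frequency_rows binary matrix of the complete dataset from which
#'   per-bit frequencies are taken
#' @return an object of class `mcf_profile`: `fingerprint` (binary vector),
#'   `n_features`, `candidate_bits` (data frame `bit`, `frequency`; 1-based
#'   bit indices), `avg_frequency`, `fallback`.
#' @export
build_mcf <- function(reference_rows, frequency_rows) {
  if (!is.matrix(reference_rows) || nrow(reference_rows) == 0L ||
      ncol(reference_rows) == 0L) {
    stop("reference_rows must be a nonempty binary matrix")
  }
  if (!is.matrix(frequency_rows) || nrow(frequency_rows) == 0L) {
    stop("frequency_rows must be a nonempty binary matrix")
  }
  if (ncol(frequency_rows) != ncol(reference_rows)) {
    stop("reference and frequency matrices must have the same bit width")
  }
  if (anyNA(reference_rows) || anyNA(frequency_rows)) {
    stop("fingerprint matrices must not contain NA")
  }
  ref_bit_freq <- colMeans(reference_rows)
  avg_frequency <- mean(ref_bit_freq)
  n_features <- floor(mean(rowSums(reference_rows)) + 0.5)  # round half up
  if (n_features == 0L) stop("reference class has no features to profile")

  freq <- colMeans(frequency_rows)
  ord <- order(-freq, seq_along(freq))  # descending frequency, ties: low bit
  cand <- ord[freq[ord] > avg_frequency]

  fallback <- length(cand) < n_features
  chosen <- if (fallback) ord[seq_len(n_features)] else cand[seq_len(n_features)]
  fingerprint <- integer(length(freq))
  fingerprint[chosen] <- 1L
  structure(list(fingerprint = fingerprint,
                 n_features = as.integer(n_features),
                 candidate_bits = data.frame(bit = cand,
                                             frequency = freq[cand]),
                 avg_frequency = avg_frequency,
                 fallback = fallback),
            class = "mcf_profile")
}

#' @export
print.mcf_profile <- function(x, ...) {
  cat(sprintf("<mcf_profile> %d set bits of %d (threshold %.4f, %d candidates%s)\n",
              x$n_features, length(x$fingerprint), x$avg_frequency,
              nrow(x$candidate_bits),
              if (x$fallback) ", scarcity fallback fired" else ""))
  invisible(x)
}
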