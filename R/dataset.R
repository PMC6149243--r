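#' Construct a fingerprint dataset
#'
#' The universal data container of the package: a dense binary fingerprint
#' matrix with one row per compound, a binary activity label per row and a
#' unique compound identifier per row.
#'
#' @param X integer or numeric matrix with entries in \{0, 1\}; rows are
#'   compounds, columns are fingerprint bits.
#' @param y binary label vector, length `nrow(X)`; 1 = active, 0 = inactive.
#' @param ids character vector of unique, nonempty compound identifiers,
#'   length `nrow(X)`. Defaults to `"cmp<i>"`.
#' @param descriptor descriptor name, `"maccs"` (166 bits), `"morgan"`
#'   (power-of-two width, conventionally 2048) or `"generic"` for synthetic
#'   or externally computed matrices of any width.
#'
#' @return An object of class `fp_dataset`: a list with elements `ids`,
#'   `X` (integer matrix), `y` (integer vector), `descriptor` and
#'   `bit_count`.
#' @export
#' @examples
#' X <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), nrow = 2, byrow = TRUE)
#' fp_dataset(X, y = c(1, 0))
fp_dataset <- function(X, y, ids = NULL,
                       descriptor = c("generic", "maccs", "morgan")) {
  descriptor <- match.arg(descriptor)
  if (!is.matrix(X)) stop("X must be a matrix")
  storage.mode(X) <- "integer"
  if (anyNA(X) || !all(X == 0L | X == 1L)) {
    stop("all fingerprint entries must be 0 or 1")
  }
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (is.null(ids)) ids <- paste0("cmp", seq_len(nrow(X)))
  ids <- as.character(ids)
  if (length(ids) != nrow(X)) stop("length(ids) must equal nrow(X)")
  if (any(!nzchar(ids))) stop("compound ids must be nonempty")
  if (anyDuplicated(ids)) {
    stop("duplicate compound ids: ", paste(unique(ids[duplicated(ids)]),
                                           collapse = ", "))
  }
  if (descriptor == "maccs" && ncol(X) != 166L) {
    stop("maccs datasets must have exactly 166 bits, got ", ncol(X))
  }
  if (descriptor == "morgan" && bitwAnd(ncol(X), ncol(X) - 1L) != 0L) {
    stop("morgan bit width must be a power of two, got ", ncol(X))
  }
  dimnames(X) <- NULL
  structure(list(ids = ids, X = X, y = y, descriptor = descriptor,
                 bit_count = ncol(X)),
            class = "fp_dataset")
}

#' @export
print.fp_dataset <- function(x, ...) {
  cat(sprintf("<fp_dataset> %d compounds x %d bits (%s)\n",
              nrow(x$X), x$bit_count, x$descriptor))
  cat(sprintf("  actives (y=1): %d   inactives (y=0): %d\n",
              sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' Number of compounds in a dataset
#' @param dataset an `fp_dataset`
#' @return integer row count
#' @export
n_compounds <- function(dataset) nrow(dataset$X)

# Subset rows of a dataset, keeping ids/labels aligned.
subset_rows <- function(dataset, idx) {
  fp_dataset(dataset$X[idx, , drop = FALSE], dataset$y[idx],
             dataset$ids[idx], dataset$descriptor)
}

# Identify the minority (rarer) and majority classes.  Ties count as
# balanced; the minority label then defaults to 1 (actives).
class_split <- function(dataset) {
  n1 <- sum(dataset$y == 1L)
  n0 <- sum(dataset$y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("dataset must contain both classes (counts: y=1 ", n1,
         ", y=0 ", n0, ")")
  }
  minority_label <- if (n1 <= n0) 1L else 0L
  list(minority_label = minority_label,
       majority_label = 1L - minority_label,
       minority_idx = which(dataset$y == minority_label),
       majority_idx = which(dataset$y != minority_label),
       balanced = n1 == n0)
}

#' Write a fingerprint dataset to the package's plain-text format
#'
#' The format is a self-describing text file: comment-prefixed header lines
#' (`#fpds 1`, `#descriptor <name>`, `#bits <n>`), a column header line, then
#' one tab-separated row per compound: id, label, bit string.
#'
#' @param dataset an `fp_dataset`
#' @param path output file path
#' @return `path`, invisibly
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "fp_dataset"))
  bits <- apply(dataset$X, 1L, paste, collapse = "")
  lines <- c("#fpds 1",
             paste("#descriptor", dataset$descriptor),
             paste("#bits", dataset$bit_count),
             "id\tlabel\tbits",
             paste(dataset$ids, dataset$y, bits, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fingerprint dataset written by [write_dataset()]
#'
#' @param path input file path
#' @return an `fp_dataset`; `read_dataset(write_dataset(d, f))` reproduces
#'   `d` exactly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(header) < 3L || !identical(header[[1L]], "#fpds 1")) {
    stop("malformed header in ", path, ": expected '#fpds 1' signature")
  }
  get_field <- function(key) {
    hit <- grep(paste0("^#", key, " "), header, value = TRUE)
    if (length(hit) != 1L) stop("malformed header: missing #", key)
    sub(paste0("^#", key, " "), "", hit)
  }
  descriptor <- get_field("descriptor")
  bit_count <- as.integer(get_field("bits"))
  if (is.na(bit_count) || bit_count < 1L) stop("malformed header: bad #bits")
  if (length(body) < 2L) stop("no data rows in ", path)
  body <- body[-1L]  # column header line
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop("malformed row ", bad[[1L]], " in ", path)
  ids <- vapply(parts, `[[`, "", 1L)
  y <- as.integer(vapply(parts, `[[`, "", 2L))
  bits <- vapply(parts, `[[`, "", 3L)
  widths <- nchar(bits)
  bad <- which(widths != bit_count)
  if (length(bad)) {
    stop("row ", bad[[1L]], " (id ", ids[bad[[1L]]], ") has ",
         widths[bad[[1L]]], " bits but header says ", bit_count)
  }
  X <- matrix(as.integer(unlist(strsplit(bits, "", fixed = TRUE))),
              nrow = length(bits), ncol = bit_count, byrow = TRUE)
  fp_dataset(X, y, ids, descriptor)
}
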