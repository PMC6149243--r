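# Reading compound tables and computing fingerprints.  Fingerprint
# computation and SMILES validation are delegated to RDKit through the
# bundled Python helper (inst/python/fingerprint_tool.py); everything else
# is plain text handling.

python_helper <- function() {
  path <- system.file("python", "fingerprint_tool.py", package = "fpresample")
  if (!nzchar(path)) stop("bundled fingerprint_tool.py not found")
  path
}

run_helper <- function(args, input_lines) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("python interpreter not found on PATH; ",
                        "fingerprint computation requires Python + RDKit")
  inp <- tempfile(fileext = ".tsv")
  on.exit(unlink(inp), add = TRUE)
  writeLines(input_lines, inp)
  out <- suppressWarnings(
    system2(py, c(shQuote(python_helper()), args, shQuote(inp)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("fingerprint helper failed: ", paste(out, collapse = "\n"))
  }
  out
}

#' Read a labeled compound table
#'
#' Reads compounds (id, SMILES, binary activity label) from a delimited
#' text table, a `.smi` file with a sidecar label table, or an SDF with a
#' named label property.  SMILES strings are validated with RDKit; rows
#' whose SMILES cannot be parsed are skipped with a warning and counted.
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"csv"` (comma or tab
#'   autodetected), `"smi"` (`SMILES<whitespace>id` lines; requires
#'   `labels`), or `"sdf"`.
#' @param id_field,smiles_field,label_field column / SDF property names.
#' @param labels for `"smi"` input: a named vector or two-column
#'   data frame mapping id to binary label.
#' @return list with `records` (data frame: `id`, `smiles`, `label`) and
#'   `n_skipped` (rows dropped for unparseable SMILES).
#' @export
read_compound_table <- function(path, format = c("auto", "csv", "smi", "sdf"),
                                id_field = "id", smiles_field = "smiles",
                                label_field = "label", labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", sdf = "sdf", "csv")
  }
  recs <- switch(format,
    csv = read_delim_table(path, id_field, smiles_field, label_field),
    smi = read_smi_table(path, labels),
    sdf = read_sdf_table(path, id_field, label_field))
  if (nrow(recs) == 0L) stop("no parseable records in ", path)
  recs$label <- coerce_binary_label(recs$label, recs$id)
  if (anyDuplicated(recs$id)) {
    stop("duplicate compound ids: ",
         paste(unique(recs$id[duplicated(recs$id)]), collapse = ", "))
  }
  # RDKit-validate the SMILES; drop and count the unparseable ones
  out <- run_helper("validate", paste(recs$id, recs$smiles, sep = "\t"))
  ok <- strsplit(out, "\t", fixed = TRUE)
  stopifnot(length(ok) == nrow(recs))
  parseable <- vapply(ok, `[[`, "", 2L) == "1"
  n_skipped <- sum(!parseable)
  if (n_skipped > 0L) {
    warning("skipped ", n_skipped, " record(s) with unparseable SMILES: ",
            paste(recs$id[!parseable], collapse = ", "))
    recs <- recs[parseable, , drop = FALSE]
  }
  if (nrow(recs) == 0L) stop("no parseable records in ", path)
  rownames(recs) <- NULL
  list(records = recs, n_skipped = n_skipped)
}

read_delim_table <- function(path, id_field, smiles_field, label_field) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("no parseable records in ", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  for (f in c(id_field, smiles_field, label_field)) {
    if (!f %in% names(tab)) stop("column '", f, "' not found in ", path)
  }
  data.frame(id = as.character(tab[[id_field]]),
             smiles = as.character(tab[[smiles_field]]),
             label = tab[[label_field]], stringsAsFactors = FALSE)
}

read_smi_table <- function(path, labels) {
  if (is.null(labels)) stop(".smi input requires a 'labels' id->label table")
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels[[2L]], as.character(labels[[1L]]))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(parts) < 2L)) {
    stop("malformed .smi line ", which(lengths(parts) < 2L)[[1L]],
         ": expected 'SMILES id'")
  }
  ids <- vapply(parts, `[[`, "", 2L)
  missing <- setdiff(ids, names(labels))
  if (length(missing)) {
    stop("no label for compound(s): ", paste(missing, collapse = ", "))
  }
  data.frame(id = ids, smiles = vapply(parts, `[[`, "", 1L),
             label = unname(labels[ids]), stringsAsFactors = FALSE)
}

read_sdf_table <- function(path, id_field, label_field) {
  out <- run_helper(c("sdf2table", "--id-field", shQuote(id_field),
                      "--label-field", shQuote(label_field)),
                    readLines(path))
  if (length(out) == 0L) stop("no parseable records in ", path)
  parts <- strsplit(out, "\t", fixed = TRUE)
  data.frame(id = vapply(parts, `[[`, "", 1L),
             smiles = vapply(parts, `[[`, "", 2L),
             label = vapply(parts, `[[`, "", 3L), stringsAsFactors = FALSE)
}

coerce_binary_label <- function(label, ids) {
  raw <- trimws(as.character(label))
  mapped <- ifelse(raw %in% c("1", "1.0", "TRUE", "true", "active"), 1L,
            ifelse(raw %in% c("0", "0.0", "FALSE", "false", "inactive"), 0L,
                   NA_integer_))
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))[[1L]]
    stop("label '", raw[bad], "' of compound '", ids[bad],
         "' is not coercible to binary (0/1)")
  }
  mapped
}

#' Compute binary fingerprints for compound records
#'
#' Computes MACCS structural keys or Morgan (circular) fingerprints with
#' RDKit.  RDKit emits 167 MACCS positions with index 0 unused; that
#' padding position is dropped so the working width is exactly the 166
#' canonical keys.  Unparseable SMILES are a hard error here (use
#' [read_compound_table()] for tolerant ingestion).
#'
#' @param records data frame with columns `id`, `smiles`, `label` (as
#'   returned in `read_compound_table()$records`).
#' @param descriptor `"maccs"` or `"morgan"`.
#' @param morgan_radius circular fingerprint radius (default 2).
#' @param morgan_bits folded Morgan width; positive power of two
#'   (default 2048).
#' @return an [fp_dataset()] with one fingerprint row per record, in input
#'   order.  Deterministic: identical records give bit-identical rows.
#' @export
compute_fingerprints <- function(records, descriptor = c("maccs", "morgan"),
                                 morgan_radius = 2L, morgan_bits = 2048L) {
  descriptor <- match.arg(descriptor)
  stopifnot(is.data.frame(records),
            all(c("id", "smiles", "label") %in% names(records)),
            nrow(records) > 0L)
  morgan_radius <- as.integer(morgan_radius)
  morgan_bits <- as.integer(morgan_bits)
  if (morgan_radius < 1L) stop("morgan_radius must be >= 1")
  if (morgan_bits < 1L || bitwAnd(morgan_bits, morgan_bits - 1L) != 0L) {
    stop("morgan_bits must be a positive power of two")
  }
  args <- c("fps", "--descriptor", descriptor,
            "--radius", morgan_radius, "--bits", morgan_bits)
  out <- run_helper(args, paste(records$id, records$smiles, sep = "\t"))
  parts <- strsplit(out, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  stopifnot(identical(ids, as.character(records$id)))
  bits <- vapply(parts, `[[`, "", 2L)
  width <- if (descriptor == "maccs") 166L else morgan_bits
  X <- matrix(as.integer(unlist(strsplit(bits, "", fixed = TRUE))),
              nrow = length(bits), ncol = width, byrow = TRUE)
  fp_dataset(X, coerce_binary_label(records$label, records$id),
             as.character(records$id), descriptor)
}
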