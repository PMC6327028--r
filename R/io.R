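#' Write a transient absorption matrix to CSV
#'
#' The CSV dialect is: header `wavelength_nm` followed by the delay values in
#' ps; one row per wavelength; masked rows written as `NA` cells.  A sidecar
#' YAML file `<path>.meta.yaml` stores concentration, dose, seed and mode.
#'
#' @param mat A [ta_matrix()].
#' @param path Output CSV path.
#' @param meta Write the sidecar metadata file?
#' @return `path`, invisibly.
#' @export
write_ta_matrix <- function(mat, path, meta = TRUE) {
  stopifnot(inherits(mat, "ta_matrix"))
  df <- data.frame(wavelength_nm = mat$wavelengths, mat$absorbance,
                   check.names = FALSE)
  names(df)[-1] <- format(mat$delays, trim = TRUE, digits = 15)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  if (meta) {
    yaml::write_yaml(list(concentration = mat$concentration, dose = mat$dose,
                          seed = if (is.null(mat$seed)) "none" else mat$seed,
                          mode = mat$mode),
                     paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

.io_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tasolv_io_error", "error")))
}

#' Read a transient absorption matrix from CSV
#'
#' Inverse of [write_ta_matrix()].  Rows that are entirely `NA` become masked
#' wavelengths; the metadata sidecar is loaded when present.  Violations of
#' the dialect raise classed errors: `tasolv_ragged_rows`,
#' `tasolv_nonmonotone_grid`, `tasolv_bad_header`.
#'
#' @param path CSV path.
#' @return A [ta_matrix()].
#' @export
read_ta_matrix <- function(path) {
  if (!file.exists(path))
    .io_error(paste0("file not found: ", path), "tasolv_missing_file")
  lines <- readLines(path)
  nfield <- lengths(strsplit(lines, ",", fixed = TRUE))
  if (length(unique(nfield)) != 1)
    .io_error("ragged rows in TA matrix file", "tasolv_ragged_rows")
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm")
    .io_error("first column header must be `wavelength_nm`",
              "tasolv_bad_header")
  delays <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(delays))
    .io_error("delay headers must be numeric ps values", "tasolv_bad_header")
  wl <- df[[1]]
  if (any(diff(wl) <= 0))
    .io_error("wavelength grid must be strictly ascending",
              "tasolv_nonmonotone_grid")
  if (any(diff(delays) <= 0))
    .io_error("delay grid must be strictly ascending",
              "tasolv_nonmonotone_grid")
  A <- as.matrix(df[-1])
  dimnames(A) <- NULL
  mask <- apply(A, 1, function(r) all(is.na(r)))
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  seed <- meta$seed
  if (is.null(seed) || identical(seed, "none")) seed <- NULL
  ta_matrix(wl, delays, A, mask,
            concentration = meta$concentration %||% 0,
            dose = meta$dose %||% 25.3, seed = seed,
            mode = meta$mode %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a flat key-value report
#'
#' Machine-readable summary format used by [run_pipeline()]: one `key = value`
#' pair per line, keys sorted, numbers formatted with 10 significant digits so
#' reruns with the same seed are byte-identical.
#'
#' @param x Named list of scalars.
#' @param path Output path.
#' @return `path` (write) or named list (read), invisibly for write.
#' @export
write_report <- function(x, path) {
  keys <- sort(names(x))
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
  }
  writeLines(paste0(keys, " = ", vapply(x[keys], fmt, character(1))), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([^=]+) = (.*)$", lines))
  out <- lapply(kv, function(m) {
    v <- suppressWarnings(as.numeric(m[3]))
    if (is.na(v)) m[3] else v
  })
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}
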