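#' Read a signal from CSV
#'
#' Accepts two dialects, with or without a header row: a single amplitude
#' column, or `time_s,amplitude`. One-column files need `fs`; two-column
#' files must be uniformly sampled (the rate is inferred from the time
#' column unless `fs` overrides it). Parse problems are reported with the
#' offending line number.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; required for one-column files, optional
#'   override for two-column files.
#' @param name Label for the returned signal.
#' @return An [ecg_signal()].
#' @export
read_signal_csv <- function(path, fs = NULL, name = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("parse error: %s is empty", path))
  fields <- strsplit(lines, ",", fixed = TRUE)
  first <- suppressWarnings(as.numeric(trimws(fields[[1L]])))
  has_header <- anyNA(first)
  start <- if (has_header) 2L else 1L
  if (start > length(fields))
    stop(sprintf("parse error: %s has a header but no data rows", path))
  nc <- length(fields[[start]])
  if (!nc %in% c(1L, 2L))
    stop(sprintf("parse error at line %d: expected 1 or 2 columns, found %d", start, nc))
  m <- matrix(NA_real_, nrow = length(fields) - start + 1L, ncol = nc)
  for (i in start:length(fields)) {
    f <- trimws(fields[[i]])
    if (length(f) != nc)
      stop(sprintf("parse error at line %d: expected %d fields, found %d", i, nc, length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("parse error at line %d: non-numeric value '%s'",
                   i, f[which(is.na(v))[1L]]))
    m[i - start + 1L, ] <- v
  }
  if (nc == 1L) {
    if (is.null(fs))
      stop("'fs' is required for a one-column (amplitude-only) file")
    return(ecg_signal(m[, 1L], fs = fs, name = name))
  }
  tcol <- m[, 1L]
  if (nrow(m) < 3L)
    stop("a signal needs at least 3 samples")
  dt <- diff(tcol)
  if (any(dt <= 0) || max(abs(dt - dt[1L])) > 1e-6 * abs(dt[1L]))
    stop("non-uniform time steps: uniform sampling is required")
  ecg_signal(m[, 2L], fs = if (is.null(fs)) 1 / dt[1L] else fs, name = name)
}

#' Write a signal to CSV
#'
#' Writes a `time_s,amplitude` file at full double precision, so a
#' write/read round trip reproduces the samples exactly.
#'
#' @param signal An [ecg_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  t <- (seq_along(signal$samples) - 1) / signal$fs
  writeLines(c("time_s,amplitude",
               sprintf("%.17g,%.17g", t, signal$samples)), path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Blank lines and `#` comments are ignored; values are returned as strings
#' for the caller (typically the command-line interface, where flags
#' override file entries) to coerce.
#'
#' @param path Config file path.
#' @return Named character vector.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop(sprintf("config parse error: '%s' is not key=value", lines[bad][1L]))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(vals, keys)
}
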