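#' Construct a reduced 1-D scattering curve
#'
#' A `sas_curve` holds one reduced small-angle scattering measurement:
#' the scattering vector `q` (1/Angstrom), the intensity `I(q)`, its
#' 1-sigma uncertainty `dI(q)`, and optionally the 1-sigma width `dq(q)`
#' of the instrument's Gaussian q-resolution kernel.  Rows with `q <= 0`
#' or non-positive uncertainty are dropped (and logged); the surviving
#' curve must have at least 5 points with strictly increasing `q`.
#'
#' @param sample_id character scalar naming the measurement.
#' @param q scattering vector, 1/Angstrom, strictly increasing after cleanup.
#' @param intensity scattered intensity (arbitrary or absolute units).
#' @param d_intensity 1-sigma intensity uncertainty, same units, `> 0`.
#' @param d_q optional 1-sigma q-resolution width, 1/Angstrom, `>= 0`.
#' @param composition optional named numeric vector of solute
#'   concentrations (mg/ml), e.g. `c(P188 = 50, phenol = 10, benzyl_alcohol = 5)`.
#' @return An object of class `sas_curve`.
#' @export
sas_curve <- function(sample_id, q, intensity, d_intensity, d_q = NULL,
                      composition = NULL) {
  if (!is.character(sample_id) || length(sample_id) != 1L)
    malformed_error("sample_id must be a single character string")
  n <- length(q)
  if (length(intensity) != n || length(d_intensity) != n ||
      (!is.null(d_q) && length(d_q) != n))
    malformed_error(sprintf("curve '%s': q, I, dI%s must have equal length",
                            sample_id, if (is.null(d_q)) "" else ", dq"))
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  d_intensity <- as.numeric(d_intensity)
  if (!is.null(d_q)) d_q <- as.numeric(d_q)

  keep <- is.finite(q) & is.finite(intensity) & is.finite(d_intensity) &
    q > 0 & d_intensity > 0
  if (!is.null(d_q)) keep <- keep & is.finite(d_q) & d_q >= 0
  n_drop <- sum(!keep)
  if (n_drop > 0)
    log_event(sprintf("[%s] dropped %d/%d rows (q <= 0, dI <= 0 or non-finite)",
                      sample_id, n_drop, n))
  q <- q[keep]; intensity <- intensity[keep]; d_intensity <- d_intensity[keep]
  if (!is.null(d_q)) d_q <- d_q[keep]

  if (length(q) < 5L)
    malformed_error(sprintf("curve '%s': fewer than 5 usable rows (%d)",
                            sample_id, length(q)))
  if (any(diff(q) <= 0))
    malformed_error(sprintf("curve '%s': q must be strictly increasing", sample_id))
  if (!is.null(composition)) {
    composition <- unlist(composition)
    if (is.null(names(composition)) || any(names(composition) == ""))
      malformed_error(sprintf("curve '%s': composition must be named", sample_id))
  }
  structure(
    list(sample_id = sample_id, q = q, intensity = intensity,
         d_intensity = d_intensity, d_q = d_q, composition = composition,
         n_dropped = n_drop),
    class = "sas_curve")
}

#' Read a reduced SAS curve from an ASCII file
#'
#' Accepts the de-facto reduced-SAXS text convention: whitespace- or
#' comma-separated numeric columns `q I dI [dq]`, with `#` comment lines.
#' Three-column files yield a curve without resolution information.
#'
#' @param path file to read.
#' @param dialect `"auto"` detects 3 vs 4 columns from the data;
#'   `"three_column"` / `"four_column"` force the layout.
#' @param sample_id sample identifier; defaults to the file name.
#' @param composition optional named concentrations attached to the curve.
#' @return A [sas_curve].
#' @export
read_sas_curve <- function(path, dialect = c("auto", "three_column", "four_column"),
                           sample_id = NULL, composition = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) io_error(sprintf("cannot read curve file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    malformed_error(sprintf("file '%s' contains no data rows", path))
  fields <- strsplit(lines, "[,[:space:]]+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !(ncol %in% c(3L, 4L)))
    malformed_error(sprintf("file '%s': expected 3 or 4 numeric columns", path))
  want <- switch(dialect, auto = ncol, three_column = 3L, four_column = 4L)
  if (ncol != want)
    malformed_error(sprintf("file '%s': has %d columns, dialect requires %d",
                            path, ncol, want))
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                  ncol = ncol, byrow = TRUE))
  if (anyNA(vals))
    malformed_error(sprintf("file '%s': non-numeric entries in data rows", path))
  if (nrow(vals) < 5L)
    malformed_error(sprintf("file '%s': fewer than 5 usable rows", path))
  sas_curve(sample_id %||% basename(path),
            q = vals[, 1L], intensity = vals[, 2L], d_intensity = vals[, 3L],
            d_q = if (ncol == 4L) vals[, 4L] else NULL,
            composition = composition)
}

#' Write a SAS curve to an ASCII file
#'
#' Emits the same `q I dI [dq]` text format [read_sas_curve] reads, with
#' the sample id and composition preserved in `#` header comments.
#'
#' @param curve a [sas_curve].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sas_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sas_curve"))
  hdr <- sprintf("# sample_id: %s", curve$sample_id)
  if (!is.null(curve$composition))
    hdr <- c(hdr, sprintf("# composition: %s",
                          paste(names(curve$composition), curve$composition,
                                sep = "=", collapse = " ")))
  cols <- list(curve$q, curve$intensity, curve$d_intensity)
  hdr <- c(hdr, if (is.null(curve$d_q)) "# columns: q I dI" else "# columns: q I dI dq")
  if (!is.null(curve$d_q)) cols <- c(cols, list(curve$d_q))
  rows <- do.call(paste, c(lapply(cols, function(x) sprintf("%.15g", x))))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write curve file '%s'", path))
  invisible(path)
}

#' @export
print.sas_curve <- function(x, ...) {
  cat(sprintf("<sas_curve '%s': %d points, q in [%.4g, %.4g] 1/Ang%s>\n",
              x$sample_id, length(x$q), min(x$q), max(x$q),
              if (is.null(x$d_q)) "" else ", with dq"))
  if (!is.null(x$composition))
    cat("  composition (mg/ml):",
        paste(names(x$composition), signif(x$composition, 4), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.sas_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity, d_intensity = x$d_intensity)
  if (!is.null(x$d_q)) d$d_q <- x$d_q
  d
}
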