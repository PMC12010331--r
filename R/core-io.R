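# Readers/writers for the package's plain-text matrix layout and the small
# spectral arithmetic used for difference spectra.
#
# CSV layout: first cell is the literal "delay_ps" (or "delay_s", in which
# case delays are converted to ps on read); the rest of row 1 holds the
# wavelengths in nm; each subsequent row is a delay followed by the dA values
# in mOD. UTF-8, "." decimal, comma separated. Optional "# key: value"
# comment lines before the header carry pump_nm and label metadata.

#' Read a spectro-temporal matrix
#'
#' Reads the package's CSV matrix layout into a [spectral_time_matrix()].
#' Axes are sorted ascending on read (rows/columns permuted as needed);
#' duplicated axis values are an error rather than silently averaged.
#'
#' @param path file path.
#' @param format only `"csv"` is supported.
#' @return A [spectral_time_matrix()].
#' @export
read_matrix <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    tag_stop("format 'hdf5' is not supported by this build; use 'csv'",
             "tag_format_error")
  tag_assert(file.exists(path), sprintf("file not found: %s", path),
             "tag_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  meta <- list(pump_nm = NULL, label = "")
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", cl))[[1]]
    if (length(m) == 3) {
      if (m[2] == "pump_nm") meta$pump_nm <- as.numeric(m[3])
      if (m[2] == "label") meta$label <- m[3]
    }
  }
  lines <- lines[!is_comment]
  tag_assert(length(lines) >= 2, "file has no data rows", "tag_format_error")
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  unit <- trimws(header[1])
  tag_assert(unit %in% c("delay_ps", "delay_s"),
             sprintf("line 1: first cell must be 'delay_ps' (got '%s')", unit),
             "tag_format_error")
  wl <- suppressWarnings(as.numeric(header[-1]))
  tag_assert(length(wl) >= 1 && !anyNA(wl),
             "line 1: non-numeric wavelength header", "tag_format_error")
  ncol_expect <- length(wl) + 1
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != ncol_expect))
    tag_stop(sprintf("line %d: expected %d fields, found %d",
                     which(nfield != ncol_expect)[1] + 1, ncol_expect,
                     nfield[nfield != ncol_expect][1]),
             "tag_format_error")
  num <- suppressWarnings(vapply(body, as.numeric, numeric(ncol_expect)))
  if (anyNA(num))
    tag_stop(sprintf("line %d: non-numeric value",
                     which(colSums(is.na(num)) > 0)[1] + 1),
             "tag_format_error")
  delays <- num[1, ]
  values <- t(num[-1, , drop = FALSE])
  if (unit == "delay_s") delays <- delays * 1e12
  # sort both axes ascending; duplicates are unresolvable
  ow <- order(wl); od <- order(delays)
  wl <- wl[ow]; delays <- delays[od]
  values <- values[od, ow, drop = FALSE]
  tag_assert(all(diff(wl) > 0), "duplicated wavelength values",
             "tag_duplicate_axis_error")
  tag_assert(all(diff(delays) > 0), "duplicated delay values",
             "tag_duplicate_axis_error")
  spectral_time_matrix(wl, delays, values,
                       pump_nm = meta$pump_nm, label = meta$label)
}

#' Write a spectro-temporal matrix
#'
#' Writes the CSV layout read by [read_matrix()]. The round trip preserves
#' axes and values to better than 1e-9 mOD (full double precision is
#' written).
#'
#' @param matrix a [spectral_time_matrix()].
#' @param path output file path.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    tag_stop("format 'hdf5' is not supported by this build; use 'csv'",
             "tag_format_error")
  stopifnot(inherits(matrix, "spectral_time_matrix"))
  num <- function(x) formatC(x, digits = 17, format = "g")
  lines <- character(0)
  if (!is.null(matrix$pump_nm))
    lines <- c(lines, sprintf("# pump_nm: %s", num(matrix$pump_nm)))
  if (nzchar(matrix$label))
    lines <- c(lines, sprintf("# label: %s", matrix$label))
  lines <- c(lines,
             paste(c("delay_ps", num(matrix$wavelengths)), collapse = ","))
  rows <- vapply(seq_along(matrix$delays), function(i) {
    paste(c(num(matrix$delays[i]), num(matrix$values[i, ])), collapse = ",")
  }, character(1))
  ok <- tryCatch({
    writeLines(c(lines, rows), path, useBytes = TRUE); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  tag_assert(ok, sprintf("cannot write to %s", path), "tag_io_error")
  invisible(path)
}

#' Restrict a matrix to a wavelength range
#'
#' Keeps the wavelengths in `[lo_nm, hi_nm]` inclusive; the delay axis is
#' unchanged. Used e.g. to analyse the probe range below and above 500 nm
#' separately.
#'
#' @param matrix a [spectral_time_matrix()].
#' @param lo_nm,hi_nm inclusive bounds, nm, `lo_nm < hi_nm`.
#' @return A [spectral_time_matrix()].
#' @export
slice_spectral <- function(matrix, lo_nm, hi_nm) {
  stopifnot(inherits(matrix, "spectral_time_matrix"))
  tag_assert(lo_nm < hi_nm, "require lo_nm < hi_nm")
  keep <- matrix$wavelengths >= lo_nm & matrix$wavelengths <= hi_nm
  if (!any(keep))
    tag_stop(sprintf("no wavelengths in [%g, %g] nm", lo_nm, hi_nm),
             "tag_empty_slice_error")
  spectral_time_matrix(matrix$wavelengths[keep], matrix$delays,
                       matrix$values[, keep, drop = FALSE],
                       pump_nm = matrix$pump_nm, label = matrix$label)
}

#' Difference spectrum
#'
#' Elementwise difference `a - ref` of two spectra on identical wavelength
#' axes (within 1e-6 nm), e.g. a temperature difference spectrum
#' A(T) - A(T_ref). No implicit interpolation is performed: mismatched axes
#' are an error.
#'
#' @param a,ref [spectrum()] objects on the same axis.
#' @return A [spectrum()].
#' @export
difference_spectrum <- function(a, ref) {
  stopifnot(inherits(a, "spectrum"), inherits(ref, "spectrum"))
  tag_assert(axes_equal(a$wavelengths, ref$wavelengths),
             "wavelength axes differ; interpolate explicitly first",
             "tag_axis_mismatch_error")
  spectrum(a$wavelengths, a$values - ref$values,
           label = trimws(paste(a$label, "-", ref$label)))
}

#' Time-averaged transient spectrum
#'
#' Arithmetic mean over all delays `t_lo <= t <= t_hi` (inclusive), giving
#' one spectrum, e.g. the persistent product spectrum averaged over a late
#' delay window.
#'
#' @param matrix a [spectral_time_matrix()].
#' @param t_lo,t_hi window bounds, ps.
#' @return A [spectrum()].
#' @export
time_average_window <- function(matrix, t_lo, t_hi) {
  stopifnot(inherits(matrix, "spectral_time_matrix"))
  rows <- matrix$delays >= t_lo & matrix$delays <= t_hi
  if (!any(rows))
    tag_stop(sprintf("no delays in [%g, %g] ps", t_lo, t_hi),
             "tag_empty_window_error")
  spectrum(matrix$wavelengths,
           colMeans(matrix$values[rows, , drop = FALSE]),
           label = sprintf("mean %g-%g ps", t_lo, t_hi))
}
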