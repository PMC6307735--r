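#' Spectrum containers
#'
#' `spectrum1d` holds a 1D NMR spectrum: a ppm axis stored high-to-low (NMR
#' convention) with matching intensities, the observed nucleus and the
#' spectrometer frequency. `spectrum2d` holds a 2D 1H-13C intensity grid with
#' both ppm axes high-to-low (rows = 1H, columns = 13C).
#'
#' @param ppm Numeric ppm axis (will be sorted high-to-low).
#' @param intensity Numeric intensities matching `ppm`.
#' @param nucleus `"1H"` or `"31P"`.
#' @param freq_mhz Spectrometer frequency for the observed nucleus (MHz).
#' @param meta Optional named list of acquisition metadata.
#' @return `spectrum1d` / `spectrum2d` objects.
#' @export
spectrum1d <- function(ppm, intensity, nucleus = "1H", freq_mhz = 400.13,
                       meta = list()) {
  stopifnot(length(ppm) == length(intensity), length(ppm) > 1)
  o <- order(ppm, decreasing = TRUE)
  structure(list(ppm = ppm[o], intensity = intensity[o], nucleus = nucleus,
                 freq_mhz = freq_mhz, meta = meta),
            class = "spectrum1d")
}

#' @rdname spectrum1d
#' @param h_ppm,c_ppm 1H and 13C ppm axes (sorted high-to-low).
#' @export
spectrum2d <- function(h_ppm, c_ppm, intensity, meta = list()) {
  stopifnot(is.matrix(intensity), nrow(intensity) == length(h_ppm),
            ncol(intensity) == length(c_ppm))
  oh <- order(h_ppm, decreasing = TRUE)
  oc <- order(c_ppm, decreasing = TRUE)
  structure(list(h_ppm = h_ppm[oh], c_ppm = c_ppm[oc],
                 intensity = intensity[oh, oc, drop = FALSE], meta = meta),
            class = "spectrum2d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s @ %.2f MHz, %d points, %.3f..%.3f ppm\n",
              x$nucleus, x$freq_mhz, length(x$ppm),
              max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("<spectrum2d> 1H x 13C grid %d x %d (%.2f..%.2f x %.1f..%.1f ppm)\n",
              length(x$h_ppm), length(x$c_ppm),
              max(x$h_ppm), min(x$h_ppm), max(x$c_ppm), min(x$c_ppm)))
  invisible(x)
}

#' Read / write spectra as plain text
#'
#' 1D spectra are two-column ASCII (ppm, intensity); 2D spectra are a dense
#' matrix with the 13C ppm axis as header row and the 1H ppm axis as first
#' column.
#'
#' @param spec A `spectrum1d` or `spectrum2d`.
#' @param file Output path.
#' @return Reading returns the spectrum object; writing returns `file`
#'   invisibly.
#' @export
write_spectrum1d <- function(spec, file) {
  stopifnot(inherits(spec, "spectrum1d"))
  utils::write.table(data.frame(ppm = spec$ppm, intensity = spec$intensity),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_spectrum1d
#' @inheritParams spectrum1d
#' @export
read_spectrum1d <- function(file, nucleus = "1H", freq_mhz = 400.13) {
  d <- utils::read.table(file, header = TRUE)
  spectrum1d(d$ppm, d$intensity, nucleus = nucleus, freq_mhz = freq_mhz)
}

#' @rdname write_spectrum1d
#' @export
write_spectrum2d <- function(spec, file) {
  stopifnot(inherits(spec, "spectrum2d"))
  m <- cbind(h_ppm = spec$h_ppm, spec$intensity)
  colnames(m) <- c("h_ppm", format(spec$c_ppm, trim = TRUE))
  utils::write.table(m, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_spectrum1d
#' @export
read_spectrum2d <- function(file) {
  d <- as.matrix(utils::read.table(file, header = TRUE, check.names = FALSE))
  spectrum2d(d[, 1], as.numeric(colnames(d)[-1]), d[, -1, drop = FALSE])
}

#' Minimal JCAMP-DX export for 1D spectra
#'
#' Writes an XYDATA (X++(Y..Y)) JCAMP-DX 4.24 record; intended for
#' interoperability with external NMR viewers.
#'
#' @inheritParams write_spectrum1d
#' @param title Record title.
#' @export
write_jcamp <- function(spec, file, title = "hrmasflux synthetic spectrum") {
  stopifnot(inherits(spec, "spectrum1d"))
  n <- length(spec$ppm)
  hz <- spec$ppm * spec$freq_mhz
  lines <- c(
    "##TITLE=" %+% title,
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##.OBSERVE NUCLEUS=^" %+% spec$nucleus,
    sprintf("##.OBSERVE FREQUENCY=%.5f", spec$freq_mhz),
    "##XUNITS=HZ", "##YUNITS=ARBITRARY UNITS",
    sprintf("##FIRSTX=%.6f", hz[1]), sprintf("##LASTX=%.6f", hz[n]),
    sprintf("##NPOINTS=%d", n), "##XYDATA=(X++(Y..Y))")
  step <- (hz[n] - hz[1]) / (n - 1)
  rows <- split(spec$intensity, ceiling(seq_len(n) / 6))
  starts <- hz[1] + step * (cumsum(c(0, vapply(rows, length, 1L)))[seq_along(rows)])
  body <- vapply(seq_along(rows), function(i) {
    paste(c(sprintf("%.4f", starts[i]), sprintf("%.6g", rows[[i]])), collapse = " ")
  }, character(1))
  writeLines(c(lines, body, "##END="), file)
  invisible(file)
}

`%+%` <- function(a, b) paste0(a, b)

# Lorentzian line with unit area (ppm units)
.lorentz <- function(x, x0, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / ((x - x0)^2 + hw^2)
}

# Gaussian line with unit area (ppm units)
.gauss <- function(x, x0, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  stats::dnorm(x, mean = x0, sd = s)
}

# analytic integral of a unit-area Lorentzian over [lo, hi]
.lorentz_integral <- function(lo, hi, x0, fwhm) {
  hw <- fwhm / 2
  (atan((hi - x0) / hw) - atan((lo - x0) / hw)) / pi
}
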