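#' Construct an emission spectrum
#'
#' A `spectrum` holds one fluorescence emission scan: a strictly ascending
#' wavelength grid (nm) with non-negative intensities (arbitrary units), plus
#' acquisition metadata. Spectra of hydroxycoumarin-labelled receptors are
#' typically recorded between 340 and 600 nm with excitation at 320 nm, which
#' selectively excites the neutral form of the fluorophore.
#'
#' @param wavelengths numeric, nm, strictly ascending, length >= 10.
#' @param intensities numeric, same length, finite and >= 0.
#' @param excitation_nm excitation wavelength in nm (default 320).
#' @param condition condition label, e.g. `"apo"` or `"ghrelin"`.
#' @param probe probe position label, e.g. `"5.58"` (Ballesteros-Weinstein).
#' @param replicate integer replicate id.
#' @return an object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths, intensities, excitation_nm = 320,
                     condition = "unknown", probe = NA_character_,
                     replicate = 1L) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    abort("wavelengths and intensities must have equal length")
  if (length(wavelengths) < 10L)
    abort("a spectrum needs at least 10 points, got %d", length(wavelengths))
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    abort("wavelengths must be finite")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    abort("intensities must be finite")
  if (any(intensities < 0))
    abort("intensities must be >= 0")
  if (any(diff(wavelengths) <= 0))
    abort("wavelengths must be strictly ascending (duplicates not allowed)")
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         excitation_nm = excitation_nm, condition = as.character(condition),
         probe = as.character(probe), replicate = as.integer(replicate)),
    class = "spectrum")
}

#' Read an emission spectrum from a two-column text table
#'
#' Accepts comma- or whitespace/tab-delimited files with an optional header
#' line. Rows are sorted by wavelength; duplicated wavelengths are rejected.
#'
#' @param path file path.
#' @inheritParams spectrum
#' @return a [spectrum].
#' @export
read_spectrum <- function(path, condition = "unknown", probe = NA_character_,
                          replicate = 1L, excitation_nm = 320) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort("not a spectrum table: %s", path)
  sep <- if (any(grepl(",", utils::head(lines, 3)))) "," else ""
  tokens1 <- strsplit(trimws(lines[[1L]]),
                      if (sep == ",") "," else "[ \t]+")[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(tokens1)))
  df <- tryCatch(
    utils::read.table(text = lines, sep = sep, header = header,
                      stringsAsFactors = FALSE),
    error = function(e) abort("could not parse %s: %s", path, conditionMessage(e)))
  if (ncol(df) < 2L) abort("expected two columns (wavelength, intensity) in %s", path)
  wl <- df[[1L]]; it <- df[[2L]]
  if (!is.numeric(wl) || !is.numeric(it))
    abort("non-numeric rows in %s", path)
  if (anyDuplicated(wl)) abort("duplicated wavelengths in %s", path)
  ord <- order(wl)
  spectrum(wl[ord], it[ord], excitation_nm = excitation_nm,
           condition = condition, probe = probe, replicate = replicate)
}

#' Write a spectrum as a two-column CSV
#'
#' @param s a [spectrum].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  utils::write.csv(
    data.frame(wavelength = s$wavelengths, intensity = s$intensities),
    path, row.names = FALSE)
  invisible(path)
}

#' Normalise a spectrum to unit peak intensity
#'
#' Scales intensities so the maximum equals 1; wavelengths are unchanged.
#' Band-area fractions (and hence the hydration parameter H) are invariant
#' under this scaling, which is why H is comparable across spectra recorded
#' at different absolute intensities.
#'
#' @param s a [spectrum].
#' @return a normalised [spectrum].
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  m <- max(s$intensities)
  if (m <= 0) abort("cannot normalize an all-zero spectrum")
  s$intensities <- s$intensities / m
  s
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.0f-%.0f nm, exc %.0f nm | %s / probe %s / rep %d\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$excitation_nm, x$condition, x$probe, x$replicate))
  invisible(x)
}
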