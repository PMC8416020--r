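#' Define one emission band component
#'
#' Bands are peak-height parameterised: the peak function evaluates to
#' `amplitude` at `center`. Two shapes are available, both standard for
#' coumarin emission deconvolution:
#' \describe{
#'   \item{gaussian}{`A * exp(-(lambda - c)^2 / (2 w^2))`, `w` in nm.}
#'   \item{lognormal}{`A * exp(-log(lambda / c)^2 / (2 s^2))` with
#'     `s = width / center`, an asymmetric band whose maximum is still `A`
#'     at `c`; `width` keeps nm units via the relative-width mapping.}
#' }
#'
#' @param species one of `"neutral"`, `"anionic"`, `"tautomer"`: the three
#'   emitting forms of the 7-hydroxycoumarin fluorophore. Water in the probe
#'   microenvironment shifts population from neutral towards anion/tautomer
#'   emission, which is what the hydration parameter H summarises.
#' @param center band centre, nm > 0.
#' @param width band width, nm > 0.
#' @param amplitude peak height, >= 0.
#' @param shape `"gaussian"` or `"lognormal"`.
#' @return an object of class `"band_component"`.
#' @export
band_component <- function(species, center, width, amplitude = 1,
                           shape = c("gaussian", "lognormal")) {
  shape <- match.arg(shape)
  species <- match.arg(species, c("neutral", "anionic", "tautomer"))
  check_scalar(center, "center", lower = 1e-9)
  check_scalar(width, "width")
  if (width <= 0) abort("band width must be > 0")
  check_scalar(amplitude, "amplitude", lower = 0)
  structure(list(species = species, center = center, width = width,
                 amplitude = amplitude, shape = shape),
            class = "band_component")
}

#' Default three-band starting model
#'
#' Starting values only, never asserted as truth: centres 380 (neutral),
#' 450 (anionic), 510 nm (tautomer) with 30 nm widths span the recorded
#' 340-600 nm window with ordered centres.
#'
#' @param shape band shape passed to [band_component()].
#' @param amplitudes numeric(3) starting peak heights.
#' @return list of three [band_component()]s.
#' @export
default_bands <- function(shape = "gaussian", amplitudes = c(0.5, 0.5, 0.5)) {
  list(band_component("neutral", 380, 30, amplitudes[[1L]], shape),
       band_component("anionic", 450, 30, amplitudes[[2L]], shape),
       band_component("tautomer", 510, 30, amplitudes[[3L]], shape))
}

# internal: evaluate a single band on a wavelength grid
eval_band <- function(b, wl) {
  switch(b$shape,
    gaussian = b$amplitude * exp(-((wl - b$center)^2) / (2 * b$width^2)),
    lognormal = {
      s <- b$width / b$center
      b$amplitude * exp(-(log(wl / b$center)^2) / (2 * s^2))
    })
}

# internal: analytic band area (integral over wavelength)
band_area <- function(b) {
  switch(b$shape,
    gaussian = b$amplitude * b$width * sqrt(2 * pi),
    lognormal = {
      s <- b$width / b$center
      b$amplitude * b$center * s * sqrt(2 * pi) * exp(s^2 / 2)
    })
}

#' Evaluate a sum-of-bands model
#'
#' Elementwise sum of each band's peak function plus a constant baseline.
#'
#' @param components list of [band_component()]s; species must be unique.
#' @param baseline constant offset (default 0).
#' @param wavelengths ascending nm grid, non-empty.
#' @return numeric intensities.
#' @export
evaluate_band_model <- function(components, baseline = 0, wavelengths) {
  if (length(wavelengths) == 0L) abort("empty wavelength grid")
  if (!all(vapply(components, inherits, logical(1), "band_component")))
    abort("components must be band_component objects")
  sp <- vapply(components, `[[`, character(1), "species")
  if (anyDuplicated(sp)) abort("duplicate species labels in band model")
  out <- rep(baseline, length(wavelengths))
  for (b in components) out <- out + eval_band(b, wavelengths)
  out
}
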