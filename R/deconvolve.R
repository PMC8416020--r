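#' Default box constraints for the three-band fit
#'
#' Centres are confined to adjacent, non-overlapping windows
#' (neutral 340-425, anionic 425-485, tautomer 485-600 nm) so the ordering
#' neutral < anionic < tautomer is enforced and species labels cannot swap
#' during optimisation. Widths span 5-80 nm, amplitudes 0-1.5 (normalised
#' spectra peak at 1).
#'
#' @return list with `lower` and `upper` named numeric vectors over the
#'   parameter order `(center, width, amplitude)` per species.
#' @export
default_band_bounds <- function() {
  nm <- c("center.neutral", "width.neutral", "amplitude.neutral",
          "center.anionic", "width.anionic", "amplitude.anionic",
          "center.tautomer", "width.tautomer", "amplitude.tautomer")
  lower <- c(340, 5, 0, 425, 5, 0, 485, 5, 0)
  upper <- c(425, 80, 1.5, 485, 80, 1.5, 600, 80, 1.5)
  names(lower) <- names(upper) <- nm
  list(lower = lower, upper = upper)
}

# internal: components -> parameter vector and back
bands_to_par <- function(components) {
  unlist(lapply(components, function(b) c(b$center, b$width, b$amplitude)))
}
par_to_bands <- function(par, template) {
  lapply(seq_along(template), function(i) {
    b <- template[[i]]
    p <- par[(3L * (i - 1L) + 1L):(3L * i)]
    band_component(b$species, p[[1L]], max(p[[2L]], 1e-9), max(p[[3L]], 0), b$shape)
  })
}

#' Deconvolute a spectrum into neutral, anionic and tautomer bands
#'
#' Fits the sum-of-bands model to a (normalised) emission spectrum by bounded
#' nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nls.lm()]),
#' with multi-start jittering of the initial parameters for robustness.
#' Band areas are integrated analytically and expressed as fractions of the
#' total band area; the hydration parameter H is the summed fractional area
#' of the anionic and tautomer bands, so H lies in \[0, 1\] and increases
#' with local hydration of the probe site.
#'
#' @param s a [spectrum].
#' @param init list of exactly three [band_component()]s (one per species);
#'   default [default_bands()].
#' @param bounds list with `lower`/`upper` parameter vectors; default
#'   [default_band_bounds()]. Centre windows must keep the species ordered.
#' @param baseline `"none"` (offset fixed at 0, the default for normalised
#'   spectra) or `"constant"` (fitted offset >= 0).
#' @param normalize normalise the spectrum to unit peak before fitting
#'   (default `TRUE`); area fractions are invariant to overall scaling.
#' @param n_starts number of multi-start attempts (first uses `init` as
#'   given, the rest jitter it inside the bounds). Default 10.
#' @param seed seed for the jitter draws (restores the caller's RNG state).
#' @param h_mode `"fractional"` (H = anionic + tautomer area fractions,
#'   in \[0,1\]; default) or `"raw"` (H = summed raw areas, intensity-scale
#'   dependent).
#' @return an object of class `"deconvolution"` with elements `components`,
#'   `baseline`, `r_squared`, `areas`, `fractional_areas`, `H`, `residuals`,
#'   `fitted`, `spectrum`.
#' @export
fit_band_model <- function(s, init = NULL, bounds = default_band_bounds(),
                           baseline = c("none", "constant"),
                           normalize = TRUE, n_starts = 10L, seed = 1L,
                           h_mode = c("fractional", "raw")) {
  stopifnot(inherits(s, "spectrum"))
  baseline <- match.arg(baseline)
  h_mode <- match.arg(h_mode)
  if (max(s$intensities) <= 0) abort("cannot fit an all-zero spectrum")
  if (normalize) s <- normalize_spectrum(s)
  if (is.null(init)) init <- default_bands()
  sp <- vapply(init, `[[`, character(1), "species")
  if (!setequal(sp, c("neutral", "anionic", "tautomer")) || length(init) != 3L)
    abort("init must contain exactly the species neutral, anionic, tautomer")
  init <- init[order(match(sp, c("neutral", "anionic", "tautomer")))]

  wl <- s$wavelengths
  y <- s$intensities
  fit_base <- length(bounds$lower)  # 9 band parameters
  lower <- bounds$lower
  upper <- bounds$upper
  if (baseline == "constant") {
    lower <- c(lower, baseline0 = 0)
    upper <- c(upper, baseline0 = max(y))
  }

  resid_fun <- function(par) {
    comps <- par_to_bands(par[seq_len(fit_base)], init)
    b0 <- if (baseline == "constant") par[[fit_base + 1L]] else 0
    y - evaluate_band_model(comps, b0, wl)
  }

  par0 <- pmin(pmax(bands_to_par(init), lower[seq_len(fit_base)]),
               upper[seq_len(fit_base)])
  if (baseline == "constant") par0 <- c(par0, 0)

  starts <- with_seed(seed, {
    lapply(seq_len(max(1L, n_starts)), function(k) {
      if (k == 1L) return(par0)
      p <- par0
      jit_c <- stats::runif(3, -10, 10)
      jit_w <- stats::runif(3, 0.6, 1.5)
      jit_a <- stats::runif(3, 0.5, 1.5)
      idx <- seq(1, fit_base, by = 3)
      p[idx] <- p[idx] + jit_c
      p[idx + 1L] <- p[idx + 1L] * jit_w
      p[idx + 2L] <- p[idx + 2L] * jit_a
      pmin(pmax(p, lower), upper)
    })
  })

  best <- NULL
  best_ss <- Inf
  last_err <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) e)
    if (inherits(fit, "error")) { last_err <- fit; next }
    ss <- sum(fit$fvec^2)
    if (is.finite(ss) && ss < best_ss) { best_ss <- ss; best <- fit }
  }
  if (is.null(best))
    abort("band fit failed for all %d starts (last error: %s)", length(starts),
          if (is.null(last_err)) "none" else conditionMessage(last_err))

  comps <- par_to_bands(best$par[seq_len(fit_base)], init)
  b0 <- if (baseline == "constant") best$par[[fit_base + 1L]] else 0
  fitted <- evaluate_band_model(comps, b0, wl)
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_

  areas <- vapply(comps, band_area, numeric(1))
  names(areas) <- vapply(comps, `[[`, character(1), "species")
  total <- sum(areas)
  if (total <= 0) abort("degenerate fit: all band areas are zero")
  frac <- areas / total

  out <- structure(
    list(components = comps, baseline = b0, r_squared = r2,
         areas = areas, fractional_areas = frac,
         H = NA_real_, h_mode = h_mode,
         residuals = res, fitted = fitted, spectrum = s,
         ss_res = sum(res^2), convergence = best$info),
    class = "deconvolution")
  out$H <- hydration_parameter(out)
  out
}

#' Hydration parameter H from a deconvolution
#'
#' H is the summed contribution of the anionic and tautomer emission species.
#' In the default fractional-area convention H = f(anionic) + f(tautomer)
#' with f the band-area fractions, so H is dimensionless in \[0, 1\]; higher
#' H means a more hydrated probe microenvironment.
#'
#' @param d a `"deconvolution"` result from [fit_band_model()].
#' @return numeric H.
#' @export
hydration_parameter <- function(d) {
  stopifnot(inherits(d, "deconvolution"))
  need <- c("anionic", "tautomer")
  src <- if (identical(d$h_mode, "raw")) d$areas else d$fractional_areas
  if (!all(need %in% names(src)))
    abort("deconvolution result is missing species: %s",
          paste(setdiff(need, names(src)), collapse = ", "))
  if (!identical(d$h_mode, "raw")) {
    if (abs(sum(d$fractional_areas) - 1) > 1e-9)
      abort("fractional areas must sum to 1")
  }
  unname(sum(src[need]))
}

#' @export
print.deconvolution <- function(x, ...) {
  cat(sprintf("<deconvolution> R^2 = %.6f, H = %.4f (%s areas)\n",
              x$r_squared, x$H, x$h_mode))
  tab <- data.frame(
    species = vapply(x$components, `[[`, character(1), "species"),
    center = vapply(x$components, `[[`, numeric(1), "center"),
    width = vapply(x$components, `[[`, numeric(1), "width"),
    amplitude = vapply(x$components, `[[`, numeric(1), "amplitude"),
    fraction = as.numeric(x$fractional_areas))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tabulate fitted bands
#'
#' @param d a `"deconvolution"`.
#' @return data.frame of species, center, width, amplitude, area, fraction.
#' @export
band_table <- function(d) {
  stopifnot(inherits(d, "deconvolution"))
  data.frame(
    species = vapply(d$components, `[[`, character(1), "species"),
    center = vapply(d$components, `[[`, numeric(1), "center"),
    width = vapply(d$components, `[[`, numeric(1), "width"),
    amplitude = vapply(d$components, `[[`, numeric(1), "amplitude"),
    area = as.numeric(d$areas),
    fraction = as.numeric(d$fractional_areas))
}
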