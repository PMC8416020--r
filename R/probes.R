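#' Per-probe hydration profile
#'
#' For a probe residue (identified by its residue index, optionally tagged
#' with a Ballesteros-Weinstein label such as `"5.58"`), counts in every
#' frame the selected water atoms lying within `cutoff` of any side-chain
#' heavy atom of the residue (falling back to the C-alpha when the residue
#' has no side chain). The contact fraction is the fraction of frames with
#' at least one such water; `mean_count` is the average number per frame.
#' The 3.5 Angstrom default corresponds to the first hydration shell.
#'
#' @param e a [trajectory_ensemble()].
#' @param probe_resid residue index of the probe.
#' @param sel water selection (default [select_water()]).
#' @param cutoff contact distance, Angstrom > 0 (default 3.5).
#' @param bw_label optional Ballesteros-Weinstein label for reporting.
#' @return an object of class `"probe_hydration"`: `probe` (resid, bw_label),
#'   `cutoff`, `contact_fraction`, `mean_count`, `per_frame_counts`,
#'   `selection`, `state_label`.
#' @export
probe_hydration <- function(e, probe_resid, sel = NULL, cutoff = 3.5,
                            bw_label = NA_character_) {
  stopifnot(inherits(e, "trajectory_ensemble"))
  if (is.null(sel)) sel <- select_water(e)
  check_scalar(cutoff, "cutoff")
  if (cutoff <= 0) abort("cutoff must be > 0")
  res_idx <- which(e$atoms$resid == probe_resid &
                     !e$atoms$resname %in% c("HOH", "TIP3", "SOL", "WAT"))
  if (length(res_idx) == 0L) abort("unknown probe residue: %d", probe_resid)
  backbone <- c("N", "CA", "C", "O", "OXT")
  side <- res_idx[!e$atoms$name[res_idx] %in% backbone &
                    e$atoms$element[res_idx] != "H"]
  if (length(side) == 0L) side <- res_idx[e$atoms$name[res_idx] == "CA"]
  if (length(side) == 0L) abort("probe residue %d has no side-chain heavy atoms nor CA", probe_resid)

  nf <- n_frames(e)
  counts <- numeric(nf)
  cut2 <- cutoff^2
  if (length(sel) > 0L) {
    for (f in seq_len(nf)) {
      fc <- frame_coords(e, f)
      W <- fc[sel, , drop = FALSE]
      P <- fc[side, , drop = FALSE]
      d2 <- outer(rowSums(W^2), rowSums(P^2), "+") - 2 * W %*% t(P)
      counts[f] <- sum(apply(d2, 1L, min) <= cut2)
    }
  }
  structure(
    list(probe = list(resid = as.integer(probe_resid), bw_label = bw_label),
         cutoff = cutoff,
         contact_fraction = mean(counts >= 1),
         mean_count = mean(counts),
         per_frame_counts = counts,
         selection = attr(sel, "descriptor") %||% "",
         state_label = e$state_label),
    class = "probe_hydration")
}

#' @export
print.probe_hydration <- function(x, ...) {
  cat(sprintf("<probe_hydration> residue %d (%s), cutoff %.2f A: contact fraction %.3f, mean count %.3f [%s]\n",
              x$probe$resid, x$probe$bw_label, x$cutoff,
              x$contact_fraction, x$mean_count, x$state_label))
  invisible(x)
}

#' Classify the hydration change of a probe between two states
#'
#' Compares the water-contact fraction of the same probe in two trajectory
#' states (conventionally inactive vs active). The delta is
#' `active - inactive`; the call is `"increase"` if delta >= threshold,
#' `"decrease"` if delta <= -threshold, `"none"` otherwise. The default
#' threshold of 0.1 encodes a direction call, not an effect-size estimate.
#'
#' @param inactive,active [probe_hydration()] profiles computed with the
#'   same cutoff and water selection.
#' @param delta_threshold decision threshold on the contact-fraction change
#'   (default 0.1).
#' @return one-row data.frame: `probe`, `resid`, `fraction_inactive`,
#'   `fraction_active`, `delta`, `call`.
#' @export
classify_hydration_change <- function(inactive, active, delta_threshold = 0.1) {
  stopifnot(inherits(inactive, "probe_hydration"),
            inherits(active, "probe_hydration"))
  if (abs(inactive$cutoff - active$cutoff) > 1e-12)
    abort("profiles were computed with different cutoffs (%.3f vs %.3f)",
          inactive$cutoff, active$cutoff)
  if (!identical(inactive$selection, active$selection))
    abort("profiles were computed with different atom selections")
  check_scalar(delta_threshold, "delta_threshold", lower = 0)
  delta <- active$contact_fraction - inactive$contact_fraction
  call <- if (delta >= delta_threshold) "increase"
          else if (delta <= -delta_threshold) "decrease"
          else "none"
  lab <- inactive$probe$bw_label
  data.frame(
    probe = if (is.na(lab)) as.character(inactive$probe$resid) else lab,
    resid = inactive$probe$resid,
    fraction_inactive = inactive$contact_fraction,
    fraction_active = active$contact_fraction,
    delta = delta, call = call,
    stringsAsFactors = FALSE)
}

#' State comparison over several probes
#'
#' @param inactive_profiles,active_profiles lists of [probe_hydration()]
#'   profiles, matched by position.
#' @param delta_threshold see [classify_hydration_change()].
#' @return data.frame with one row per probe.
#' @export
compare_states <- function(inactive_profiles, active_profiles,
                           delta_threshold = 0.1) {
  if (length(inactive_profiles) != length(active_profiles))
    abort("profile lists must have equal length")
  do.call(rbind, Map(classify_hydration_change, inactive_profiles,
                     active_profiles,
                     MoreArgs = list(delta_threshold = delta_threshold)))
}
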