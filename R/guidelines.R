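#' Electrode-design guideline checks: geometry (guidelines 1-3)
#'
#' Checks a probe geometry against the three placement rules for a
#' three-electrode differential recording setup:
#' \itemize{
#'   \item G1: every pairwise distance among signal/reference/ground sites
#'     must exceed the maximum neuron size (default 20 um), so that close
#'     electrodes do not cancel the action potential.
#'   \item G2: every signal-reference distance must lie within the local
#'     LFP spread (default 20-200 um) so the reference still shares the
#'     LFP environment without sitting on top of the signal site.
#'   \item G3: a ground site should sit at the midpoint of each
#'     signal-reference pair (default tolerance: 10% of the pair
#'     distance), equalizing the two tissue paths and thereby the
#'     differential pickup of common-mode interference.
#' }
#' For multi-site roles the worst pair is reported.
#'
#' @param sites List of [electrode_site()] objects; at least one site of
#'   each role is required.
#' @param min_pitch_m G1 threshold in meters (default 20e-6).
#' @param sr_range_m G2 range in meters (default `c(20e-6, 200e-6)`).
#' @param midpoint_tol G3 tolerance as a fraction of the signal-reference
#'   distance (default 0.1).
#' @return Data.frame of class `"guideline_report"` with rows for
#'   guidelines 1-3: `guideline`, `name`, `status`, `measured`,
#'   `threshold`, `unit`.
#' @export
check_geometry <- function(sites, min_pitch_m = 20e-6,
                           sr_range_m = c(20e-6, 200e-6),
                           midpoint_tol = 0.1) {
  roles <- vapply(sites, function(s) s$role, character(1))
  for (need in c("signal", "reference", "ground")) {
    if (!any(roles == need)) {
      stop(sprintf("geometry has no %s site", need), call. = FALSE)
    }
  }
  pos <- t(vapply(sites, function(s) s$position, numeric(3)))
  dists <- as.matrix(stats::dist(pos))
  min_pair <- min(dists[upper.tri(dists)])

  sig_i <- which(roles == "signal")
  ref_i <- which(roles == "reference")
  gnd_i <- which(roles == "ground")
  sr <- expand.grid(s = sig_i, r = ref_i)
  sr_d <- mapply(function(s, r) dists[s, r], sr$s, sr$r)

  # per signal-reference pair: nearest ground's offset from the midpoint,
  # relative to the pair distance; worst pair reported
  mid_ratio <- mapply(function(s, r) {
    mid <- (pos[s, ] + pos[r, ]) / 2
    d_g <- min(vapply(gnd_i, function(g) sqrt(sum((pos[g, ] - mid)^2)),
                      numeric(1)))
    d_g / dists[s, r]
  }, sr$s, sr$r)

  rows <- rbind(
    guideline_row(1L, "inter-electrode pitch",
                  status = min_pair > min_pitch_m,
                  measured = min_pair * 1e6,
                  threshold = sprintf("> %g", min_pitch_m * 1e6), "um"),
    guideline_row(2L, "signal-reference distance",
                  status = all(sr_d >= sr_range_m[1] & sr_d <= sr_range_m[2]),
                  measured = max(sr_d) * 1e6,
                  threshold = sprintf("[%g, %g]", sr_range_m[1] * 1e6,
                                      sr_range_m[2] * 1e6), "um"),
    guideline_row(3L, "ground at signal-reference midpoint",
                  status = max(mid_ratio) <= midpoint_tol,
                  measured = max(mid_ratio),
                  threshold = sprintf("<= %g", midpoint_tol),
                  "fraction of S-R distance")
  )
  structure(rows, class = c("guideline_report", "data.frame"))
}

guideline_row <- function(id, name, status, measured, threshold, unit,
                          warn = FALSE) {
  data.frame(guideline = id, name = name,
             status = if (isTRUE(status)) "pass" else if (warn) "warn" else "fail",
             measured = measured, threshold = threshold, unit = unit,
             stringsAsFactors = FALSE)
}

#' Electrode-design guideline checks: impedance plan (guidelines 4-6)
#'
#' \itemize{
#'   \item G4: the ground electrode path impedance must be small (default
#'     bound 10 kOhm, a skull-screw/silver-wire ground); a value within
#'     10x the bound is reported as `"warn"` rather than `"fail"`.
#'   \item G5: the neural-signal attenuation from electrode to amplifier
#'     input ([attenuation_ratio()]) must stay below a bound (default 5%).
#'   \item G6: the reference path impedance must match `Z_S / N` within
#'     the scheme tolerance (rigorous matching), or the extreme-matching
#'     predicate must pass.
#' }
#'
#' @param setup A [recording_setup()].
#' @param scheme A [matching_scheme()].
#' @param zg_bound_ohm G4 bound in ohms (default 1e4).
#' @param attenuation_bound_pct G5 bound in percent (default 5).
#' @param extreme_factor Headroom factor for the extreme-matching
#'   predicate (default 100).
#' @return Data.frame of class `"guideline_report"` with rows 4-6.
#' @export
check_impedance_plan <- function(setup, scheme, zg_bound_ohm = 1e4,
                                 attenuation_bound_pct = 5,
                                 extreme_factor = 100) {
  stopifnot(inherits(setup, "recording_setup"),
            inherits(scheme, "matching_scheme"))
  zg <- impedance_magnitude(setup$z_g)
  att <- attenuation_ratio(setup)

  z_target <- rigorous_match_reference(setup$z_s, scheme$n)
  mismatch <- Mod(setup$z_r$value - z_target$value) / Mod(z_target$value)
  extreme_ok <- check_extreme_matching(setup, factor = extreme_factor)$pass
  g6_ok <- mismatch <= scheme$tolerance || extreme_ok

  rows <- rbind(
    guideline_row(4L, "ground path impedance",
                  status = zg <= zg_bound_ohm, measured = zg / 1e3,
                  threshold = sprintf("<= %g", zg_bound_ohm / 1e3), "kOhm",
                  warn = zg <= 10 * zg_bound_ohm),
    guideline_row(5L, "neural-signal attenuation",
                  status = att <= attenuation_bound_pct, measured = att,
                  threshold = sprintf("<= %g", attenuation_bound_pct), "%"),
    guideline_row(6L, "signal/reference impedance matching",
                  status = g6_ok, measured = mismatch,
                  threshold = sprintf("<= %g (or extreme matching)",
                                      scheme$tolerance),
                  "relative mismatch vs Z_S/N")
  )
  structure(rows, class = c("guideline_report", "data.frame"))
}

#' Combined guideline report (guidelines 1-6)
#'
#' @inheritParams check_geometry
#' @inheritParams check_impedance_plan
#' @param ... Passed through to [check_geometry()] and
#'   [check_impedance_plan()] by name.
#' @return Data.frame of class `"guideline_report"` with one row per
#'   guideline 1-6.
#' @export
check_guidelines <- function(sites, setup, scheme, ...) {
  args <- list(...)
  geo_args <- args[names(args) %in%
                     c("min_pitch_m", "sr_range_m", "midpoint_tol")]
  imp_args <- args[names(args) %in%
                     c("zg_bound_ohm", "attenuation_bound_pct",
                       "extreme_factor")]
  rows <- rbind(do.call(check_geometry, c(list(sites), geo_args)),
                do.call(check_impedance_plan,
                        c(list(setup, scheme), imp_args)))
  structure(rows, class = c("guideline_report", "data.frame"))
}

#' @export
print.guideline_report <- function(x, ...) {
  cat("Electrode design guideline report\n")
  df <- as.data.frame(x)
  df$measured <- signif(df$measured, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
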