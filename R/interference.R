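#' Impedance-matching scheme
#'
#' Two schemes suppress the common-mode-to-differential conversion at the
#' amplifier input of an N-channel recording system with one shared
#' reference input: *rigorous* matching sets `Z_R = Z_S / N` to mirror the
#' shared common-mode input impedance `Z_OP_N_CM = Z_OP_P_CM / N`;
#' *extreme* matching instead makes both electrode impedances negligible
#' against the common-mode input impedances.
#'
#' @param kind `"rigorous"` or `"extreme"`.
#' @param n Number of recording channels (>= 1).
#' @param tolerance Relative mismatch allowed by the scheme (>= 0).
#' @return Object of class `"matching_scheme"`.
#' @export
matching_scheme <- function(kind = c("rigorous", "extreme"), n = 1L,
                            tolerance = 0.05) {
  kind <- match.arg(kind)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (tolerance < 0) stop("`tolerance` must be >= 0", call. = FALSE)
  structure(list(kind = kind, n = as.integer(n), tolerance = tolerance),
            class = "matching_scheme")
}

cm_dividers <- function(setup) {
  list(
    p = setup$z_op_p_cm$value / (setup$z_op_p_cm$value + setup$z_s$value),
    n = setup$z_op_n_cm$value / (setup$z_op_n_cm$value + setup$z_r$value)
  )
}

#' Common-mode interference at the two amplifier inputs
#'
#' The common-mode electrode voltage reaches each input through its own
#' divider: `Z_OP_P_CM / (Z_OP_P_CM + Z_S)` on the positive side and
#' `Z_OP_N_CM / (Z_OP_N_CM + Z_R)` on the negative side.
#'
#' @param v_cm Common-mode interference phasor at the electrodes (volts).
#' @param setup A [recording_setup()].
#' @return List with `v_cmi_op_p` and `v_cmi_op_n`.
#' @export
cmi_at_inputs <- function(v_cm, setup) {
  stopifnot(inherits(setup, "recording_setup"))
  d <- cm_dividers(setup)
  list(v_cmi_op_p = v_cm * d$p, v_cmi_op_n = v_cm * d$n)
}

#' Divider imbalance of the two common-mode paths
#'
#' The complex difference of the two common-mode dividers; zero under exact
#' rigorous matching and the quantity that converts common-mode into
#' differential-mode interference (the potential divider effect).
#'
#' @param setup A [recording_setup()].
#' @return Complex imbalance.
#' @export
cm_divider_imbalance <- function(setup) {
  d <- cm_dividers(setup)
  d$p - d$n
}

#' Differential interference produced from a common-mode voltage
#'
#' `v_cm * (divider_P - divider_N)`: exactly zero when `Z_R = Z_S / N` and
#' `Z_OP_N_CM = Z_OP_P_CM / N` (rigorous matching), and negligible when
#' both electrode impedances are tiny against the common-mode input
#' impedances (extreme matching).
#'
#' @param v_cm Common-mode phasor (volts).
#' @param setup A [recording_setup()].
#' @return Complex differential-mode phasor (volts).
#' @export
cmi_differential <- function(v_cm, setup) {
  v_cm * cm_divider_imbalance(setup)
}

#' Shared common-mode input impedance of an N-channel amplifier
#'
#' The negative input is shared by N channels, so its common-mode input
#' impedance is the per-channel impedance divided by N.
#'
#' @param z_p_cm Per-channel (positive input) common-mode impedance.
#' @param n Channel count (>= 1).
#' @return An `impedance` at the same frequency.
#' @export
shared_cm_impedance <- function(z_p_cm, n) {
  stopifnot(is_impedance(z_p_cm), n >= 1)
  impedance(z_p_cm$value / n, z_p_cm$frequency)
}

#' Reference path impedance under rigorous matching
#'
#' `Z_R = Z_S / N`: with a signal electrode of 6.95e5 Ohm and 32 channels
#' this gives 2.17e4 Ohm.
#'
#' @param z_s Signal electrode path impedance.
#' @param n Channel count (>= 1).
#' @return An `impedance` at the same frequency.
#' @export
rigorous_match_reference <- function(z_s, n) {
  stopifnot(is_impedance(z_s), n >= 1)
  impedance(z_s$value / n, z_s$frequency)
}

#' Check the extreme-matching predicate
#'
#' Passes iff `max(|Z_S|, |Z_R|) <= |Z_OP_N_CM| / factor`. Because extreme
#' matching passes the common-mode voltage to the inputs almost without
#' attenuation, the report includes the residual conversion fraction and,
#' when `v_cm` and an input-range bound are supplied, a saturation warning
#' if the common-mode voltage reaching the positive input exceeds the
#' analog front-end's input range.
#'
#' @param setup A [recording_setup()].
#' @param factor Required headroom ratio (default 100).
#' @param v_cm Optional common-mode phasor for the saturation check.
#' @param input_range_v Optional front-end input-range bound (volts).
#' @return List with `pass`, `margin` (how many times the requirement is
#'   exceeded; `Inf` for zero electrode impedance), `residual_fraction`
#'   (|divider imbalance|), and `saturation_warning`.
#' @export
check_extreme_matching <- function(setup, factor = 100, v_cm = NULL,
                                   input_range_v = NULL) {
  stopifnot(inherits(setup, "recording_setup"), factor > 0)
  z_max <- max(impedance_magnitude(setup$z_s), impedance_magnitude(setup$z_r))
  bound <- impedance_magnitude(setup$z_op_n_cm) / factor
  margin <- if (z_max == 0) Inf else bound / z_max
  saturation <- FALSE
  if (!is.null(v_cm) && !is.null(input_range_v)) {
    v_p <- cmi_at_inputs(v_cm, setup)$v_cmi_op_p
    saturation <- Mod(v_p) > input_range_v
  }
  list(pass = z_max <= bound, margin = margin,
       residual_fraction = Mod(cm_divider_imbalance(setup)),
       saturation_warning = saturation)
}

#' Differential-mode interference at the amplifier input
#'
#' Two additive contributions: true differential pickup at the electrodes
#' scaled by the differential-mode transfer factor, and common-mode-to-
#' differential conversion through the divider imbalance:
#' \deqn{V_{DMI} = V_{DM} \frac{Z_{OP\_P\_DM}+Z_{OP\_N\_DM}}
#'   {Z_{OP\_P\_DM}+Z_{OP\_N\_DM}+Z_S+Z_R} +
#'   V_{CM}\left[\frac{Z_{OP\_P\_CM}}{Z_{OP\_P\_CM}+Z_S} -
#'   \frac{Z_{OP\_N\_CM}}{Z_{OP\_N\_CM}+Z_R}\right]}
#'
#' @param v_cm Common-mode interference phasor at the electrodes.
#' @param v_dm Differential-mode interference phasor at the electrodes.
#' @param setup A [recording_setup()].
#' @return An object of class `"interference_report"`: list with
#'   `term_dm_pickup`, `term_cm_conversion`, `v_dmi_op_diff` (their sum),
#'   `v_cmi_op_p`, `v_cmi_op_n`, `v_cmi_op_diff`, and the inputs.
#' @export
dmi_differential <- function(v_cm, v_dm, setup) {
  stopifnot(inherits(setup, "recording_setup"))
  term1 <- v_dm * dm_transfer_factor(setup)
  term2 <- v_cm * cm_divider_imbalance(setup)
  inputs <- cmi_at_inputs(v_cm, setup)
  structure(list(
    term_dm_pickup = term1,
    term_cm_conversion = term2,
    v_dmi_op_diff = term1 + term2,
    v_cmi_op_p = inputs$v_cmi_op_p,
    v_cmi_op_n = inputs$v_cmi_op_n,
    v_cmi_op_diff = cmi_differential(v_cm, setup),
    v_cm = v_cm, v_dm = v_dm,
    mismatch_fraction = Mod(cm_divider_imbalance(setup))
  ), class = "interference_report")
}

#' @export
print.interference_report <- function(x, ...) {
  cat("<interference_report> (magnitudes, uV)\n")
  uv <- function(v) sprintf("%.4g", Mod(v) * 1e6)
  cat(sprintf("  CMI at +input : %s\n", uv(x$v_cmi_op_p)))
  cat(sprintf("  CMI at -input : %s\n", uv(x$v_cmi_op_n)))
  cat(sprintf("  CMI diff      : %s\n", uv(x$v_cmi_op_diff)))
  cat(sprintf("  DMI total     : %s  (DM pickup %s + CM->DM %s)\n",
              uv(x$v_dmi_op_diff), uv(x$term_dm_pickup),
              uv(x$term_cm_conversion)))
  invisible(x)
}

#' Full interference chain: mains source to amplifier input
#'
#' Evaluates, at the interference frequency: the body voltage (shielded if
#' the network carries a shield), the hardware displacement current, the
#' ground-node current (taken equal to the hardware displacement current
#' when the ground path impedance is low), the electrode-referred EMI
#' voltages and their CM/DM decomposition, and finally the amplifier-
#' referred common-mode and differential-mode interference phasors.
#'
#' @param net A [coupling_network()].
#' @param env An [emi_environment()].
#' @param setup A [recording_setup()] at the interference frequency.
#' @return An `"interference_report"` (see [dmi_differential()]) with
#'   additional fields `v_body`, `i_d_h`.
#' @export
interference_pipeline <- function(net, env, setup) {
  stopifnot(inherits(net, "coupling_network"))
  v_body <- body_emi(net)
  i_d_h <- hardware_displacement_current(v_body, net)
  ev <- electrode_emi_voltages(i_d_h, env)
  cmdm <- cm_dm_decompose(ev$v_emi_me_s, ev$v_emi_me_r)
  rep <- dmi_differential(cmdm$cm, cmdm$dm, setup)
  rep$v_body <- v_body
  rep$i_d_h <- i_d_h
  rep
}

#' Serialize an interference report
#'
#' @param report An `"interference_report"`.
#' @return Data.frame with per-term magnitudes (uV) and phases (deg).
#' @export
interference_report_table <- function(report) {
  stopifnot(inherits(report, "interference_report"))
  terms <- c("v_cmi_op_p", "v_cmi_op_n", "v_cmi_op_diff",
             "term_dm_pickup", "term_cm_conversion", "v_dmi_op_diff")
  vals <- vapply(terms, function(t) report[[t]], complex(1))
  data.frame(term = terms, magnitude_uv = Mod(vals) * 1e6,
             phase_deg = Arg(vals) * 180 / pi, row.names = NULL)
}

#' Literature reference levels for interference scenarios
#'
#' Named constants commonly used to frame recording scenarios: typical
#' common-mode interference magnitudes for cortex/head/chest ground
#' placement, the usual amplifier CMRR requirement, and the smallest
#' detectable neural signal. These are scenario-building constants, not
#' model outputs.
#'
#' @return Data.frame with `name`, `value`, `unit`, `meaning`.
#' @export
emi_reference_levels <- function() {
  data.frame(
    name = c("cmi_ground_in_cortex", "cmi_ground_on_head",
             "cmi_ground_on_chest", "cmrr_requirement",
             "detectable_signal"),
    value = c(1e-3, 1e-2, 1e-1, 70, 5e-6),
    unit = c("V", "V", "V", "dB", "V_rms"),
    meaning = c(
      "typical CMI magnitude with the ground electrode in the cortex",
      "typical CMI magnitude with the ground electrode elsewhere on the head",
      "typical CMI magnitude with the ground electrode on the chest",
      "amplifier common-mode rejection usually required",
      "smallest neural signal considered detectable"),
    stringsAsFactors = FALSE
  )
}
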