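#' Power-line EMI coupling network
#'
#' Lumped-element description of how a mains-frequency interference source
#' reaches the body and the recording hardware: the source `v_ie` (phasor,
#' at `frequency`) with internal impedance `z_ie` couples to the body
#' (impedance `z_b`, earth capacitance `c_be`) directly through `c_ib`, or,
#' when a shield is present, through the shield network `c_is`/`z_se`/
#' `c_sb`. The hardware couples to earth through `c_he`, and `z_ig_star` is
#' the lumped equivalent impedance from the interference injection point on
#' the body to the recording-system IC ground.
#'
#' @param v_ie Source amplitude (volts, may be complex phasor).
#' @param frequency Source frequency in Hz (> 0 for any evaluation).
#' @param z_ie Source internal impedance (ohms, complex allowed).
#' @param z_b Body impedance (ohms); 200--1000 is the typical dry/wet
#'   contact band, values outside it warn.
#' @param c_be,c_ib,c_he Coupling capacitances in farads (> 0).
#' @param z_ig_star Equivalent impedance body-to-IC-ground (ohms).
#' @param shield Optional `list(c_is = , c_sb = , z_se = )` describing an
#'   electromagnetic shield between source and body.
#' @return Object of class `"coupling_network"`.
#' @export
coupling_network <- function(v_ie, frequency, z_ie, z_b, c_be, c_ib, c_he,
                             z_ig_star, shield = NULL) {
  stopifnot(frequency > 0)
  caps <- c(c_be = c_be, c_ib = c_ib, c_he = c_he)
  if (any(caps <= 0)) stop("capacitances must be > 0", call. = FALSE)
  if (Mod(z_b) < 200 || Mod(z_b) > 1000) {
    warning("|z_b| outside the typical 200-1000 Ohm body-impedance band")
  }
  if (!is.null(shield)) {
    stopifnot(all(c("c_is", "c_sb", "z_se") %in% names(shield)))
    if (shield$c_is <= 0 || shield$c_sb <= 0) {
      stop("shield capacitances must be > 0", call. = FALSE)
    }
  }
  structure(list(v_ie = as.complex(v_ie), frequency = frequency,
                 z_ie = as.complex(z_ie), z_b = as.complex(z_b),
                 c_be = c_be, c_ib = c_ib, c_he = c_he,
                 z_ig_star = as.complex(z_ig_star), shield = shield),
            class = "coupling_network")
}

cap_reactance <- function(capacitance, omega) 1 / (1i * omega * capacitance)

par2 <- function(a, b) a * b / (a + b)

# Body network seen from the source side: (Z_B + 1/jwC_BE) in parallel
# with (Z_IG* + 1/jwC_HE).
body_branch_impedance <- function(net) {
  w <- 2 * pi * net$frequency
  par2(net$z_b + cap_reactance(net$c_be, w),
       net$z_ig_star + cap_reactance(net$c_he, w))
}

#' Interference voltage on the body without shielding
#'
#' Voltage divider of the source across the body/hardware branch versus the
#' source impedance plus direct coupling capacitor:
#' \deqn{V_{EMI\_B} = V_{IE} \frac{P}{P + Z_{IE} + 1/(j\omega C_{IB})}},
#' with \eqn{P = (Z_B + 1/j\omega C_{BE}) \parallel (Z_{IG^*} + 1/j\omega C_{HE})}.
#'
#' @param net A [coupling_network()].
#' @return Complex phasor voltage on the body.
#' @export
body_emi_unshielded <- function(net) {
  stopifnot(inherits(net, "coupling_network"))
  w <- 2 * pi * net$frequency
  if (w <= 0) stop("zero frequency: capacitive branches undefined", call. = FALSE)
  p <- body_branch_impedance(net)
  net$v_ie * p / (p + net$z_ie + cap_reactance(net$c_ib, w))
}

#' Interference voltage on the body with electromagnetic shielding
#'
#' With a shield interposed, the direct coupling capacitance is negligible
#' and the source reaches the body through `c_is`, the shield-to-earth
#' impedance `z_se`, and the shield-to-body capacitance `c_sb`:
#' \deqn{\hat V_{EMI\_B} \approx V_{IE}
#'   \frac{P Z_{SE} / (P + Z_{SE} + 1/(j\omega C_{SB}))}
#'        {Z_{SE} + Z_{IE} + 1/(j\omega C_{IS})}}
#' A well-grounded shield (`z_se` small) collapses the body voltage; a
#' shield placed too close to the body (large `c_sb`) raises it.
#'
#' @param net A [coupling_network()] with a `shield` entry.
#' @return Complex phasor voltage on the body.
#' @export
body_emi_shielded <- function(net) {
  stopifnot(inherits(net, "coupling_network"))
  if (is.null(net$shield)) stop("network has no shield description", call. = FALSE)
  w <- 2 * pi * net$frequency
  if (w <= 0) stop("zero frequency: capacitive branches undefined", call. = FALSE)
  p <- body_branch_impedance(net)
  sh <- net$shield
  num <- p * sh$z_se / (p + sh$z_se + cap_reactance(sh$c_sb, w))
  net$v_ie * num / (sh$z_se + net$z_ie + cap_reactance(sh$c_is, w))
}

#' Body interference voltage, shielded if a shield is configured
#' @param net A [coupling_network()].
#' @return Complex phasor voltage.
#' @export
body_emi <- function(net) {
  if (is.null(net$shield)) body_emi_unshielded(net) else body_emi_shielded(net)
}

#' Displacement current through the body-to-earth branch
#'
#' Reported for the current budget; the body branch current is
#' `v_body / (Z_B + 1/(j w C_BE))`.
#'
#' @param v_body Body interference phasor (volts).
#' @param net A [coupling_network()].
#' @return Complex phasor current in amperes.
#' @export
body_displacement_current <- function(v_body, net) {
  w <- 2 * pi * net$frequency
  v_body / (net$z_b + cap_reactance(net$c_be, w))
}

#' Displacement current through the recording hardware
#'
#' \deqn{I_{D\_H} = V_{EMI\_B} / (1/(j\omega C_{HE}) + Z_{IG^*})}
#'
#' @param v_body Body interference phasor (volts).
#' @param net A [coupling_network()].
#' @return Complex phasor current in amperes.
#' @export
hardware_displacement_current <- function(v_body, net) {
  w <- 2 * pi * net$frequency
  if (w <= 0) stop("zero frequency: capacitive branch undefined", call. = FALSE)
  v_body / (cap_reactance(net$c_he, w) + net$z_ig_star)
}

#' Electrode-side EMI environment
#'
#' Path impedance of the ground electrode and inter-electrode tissue
#' impedances from the signal and reference sites to the ground site,
#' together with the fractions `f_sg`, `f_rg` of the ground-node current
#' that flow through those tissue branches. The split is not derivable from
#' the lumped model, so it is an explicit input; [admittance_split()]
#' derives fractions inversely proportional to the branch impedance
#' magnitudes.
#'
#' @param z_g,z_sg,z_rg `impedance` objects at the interference frequency.
#' @param f_sg,f_rg Non-negative split fractions with `f_sg + f_rg <= 1`.
#' @return Object of class `"emi_environment"`.
#' @export
emi_environment <- function(z_g, z_sg, z_rg, f_sg, f_rg) {
  stopifnot(is_impedance(z_g), is_impedance(z_sg), is_impedance(z_rg))
  common_frequency(list(z_g, z_sg, z_rg))
  if (f_sg < 0 || f_rg < 0 || f_sg + f_rg > 1) {
    stop("split fractions must satisfy f_sg, f_rg >= 0 and f_sg + f_rg <= 1",
         call. = FALSE)
  }
  structure(list(z_g = z_g, z_sg = z_sg, z_rg = z_rg,
                 f_sg = f_sg, f_rg = f_rg),
            class = "emi_environment")
}

#' Admittance-proportional current split
#'
#' Distributes a total branch budget over the signal-to-ground and
#' reference-to-ground tissue paths inversely proportional to their
#' impedance magnitudes (lower impedance draws more current).
#'
#' @param z_sg,z_rg `impedance` objects.
#' @param budget Total fraction assigned to the two branches (default 0.5).
#' @return List with `f_sg` and `f_rg`.
#' @export
admittance_split <- function(z_sg, z_rg, budget = 0.5) {
  stopifnot(budget >= 0, budget <= 1)
  y <- c(1 / impedance_magnitude(z_sg), 1 / impedance_magnitude(z_rg))
  f <- budget * y / sum(y)
  list(f_sg = f[[1L]], f_rg = f[[2L]])
}

#' Electrode-referred EMI voltages
#'
#' With the full ground-node current `i_gg_star` flowing through the ground
#' electrode path and fractions of it through the tissue branches:
#' \deqn{V_{EMI\_ME\_S} = I_{D\_GG^*} Z_G + I_{D\_SG} Z_{SG}}
#' \deqn{V_{EMI\_ME\_R} = I_{D\_GG^*} Z_G + I_{D\_RG} Z_{RG}}
#' Both voltages are referred to the recording-system IC ground.
#'
#' @param i_gg_star Ground-node current phasor (amperes).
#' @param env An [emi_environment()].
#' @return List with `v_emi_me_s` and `v_emi_me_r` (complex volts) and the
#'   branch currents `i_d_sg`, `i_d_rg`, `i_residual`.
#' @export
electrode_emi_voltages <- function(i_gg_star, env) {
  stopifnot(inherits(env, "emi_environment"))
  i_sg <- env$f_sg * i_gg_star
  i_rg <- env$f_rg * i_gg_star
  list(
    v_emi_me_s = i_gg_star * env$z_g$value + i_sg * env$z_sg$value,
    v_emi_me_r = i_gg_star * env$z_g$value + i_rg * env$z_rg$value,
    i_d_sg = i_sg, i_d_rg = i_rg,
    i_residual = (1 - env$f_sg - env$f_rg) * i_gg_star
  )
}

#' Common-mode / differential-mode decomposition
#'
#' `CM = (v_s + v_r)/2`, `DM = v_s - v_r`; the inverse map is
#' `v_s = CM + DM/2`, `v_r = CM - DM/2`.
#'
#' @param v_s,v_r Phasor voltages at the signal and reference electrodes.
#' @return List with `cm` and `dm`.
#' @export
cm_dm_decompose <- function(v_s, v_r) {
  list(cm = (v_s + v_r) / 2, dm = v_s - v_r)
}

#' Node-by-node report of the coupling chain
#'
#' @param net A [coupling_network()].
#' @param env An [emi_environment()].
#' @return Data.frame with one row per node/current (magnitude and phase).
#' @export
coupling_report <- function(net, env) {
  v_body <- body_emi(net)
  i_d_h <- hardware_displacement_current(v_body, net)
  i_d_b <- body_displacement_current(v_body, net)
  ev <- electrode_emi_voltages(i_d_h, env)
  cmdm <- cm_dm_decompose(ev$v_emi_me_s, ev$v_emi_me_r)
  vals <- c(v_emi_b = v_body, i_d_b = i_d_b, i_d_h = i_d_h,
            i_d_sg = ev$i_d_sg, i_d_rg = ev$i_d_rg,
            v_emi_me_s = ev$v_emi_me_s, v_emi_me_r = ev$v_emi_me_r,
            v_emi_me_cm = cmdm$cm, v_emi_me_dm = cmdm$dm)
  data.frame(node = names(vals), magnitude = Mod(vals),
             phase_deg = Arg(vals) * 180 / pi, row.names = NULL)
}
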