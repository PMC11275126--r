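#' Single-frequency complex impedance
#'
#' A two-terminal impedance represented as a complex phasor value at one
#' stated frequency. All circuit arithmetic in the package (series/parallel
#' combination, voltage dividers, branch-current solves) operates on these
#' objects and refuses to combine impedances defined at different
#' frequencies, which would be physically meaningless.
#'
#' @param value Complex (or real) impedance in ohms.
#' @param frequency Frequency in Hz at which `value` holds. Must be >= 0;
#'   a frequency of exactly 0 is permitted so that DC limits of
#'   parameterized elements can be represented.
#' @return An object of class `"impedance"` with fields `value` (complex)
#'   and `frequency` (double).
#' @examples
#' z <- impedance(1e3 - 2e3i, 1000)
#' impedance_magnitude(z)
#' @export
impedance <- function(value, frequency) {
  if (!is.numeric(frequency) || length(frequency) != 1L || is.na(frequency) ||
      frequency < 0) {
    stop("`frequency` must be a single non-negative number (Hz)", call. = FALSE)
  }
  value <- as.complex(value)
  if (length(value) != 1L || is.na(value)) {
    stop("`value` must be a single complex impedance in ohms", call. = FALSE)
  }
  structure(list(value = value, frequency = as.numeric(frequency)),
            class = "impedance")
}

#' @rdname impedance
#' @export
is_impedance <- function(x) inherits(x, "impedance")

#' Construct an impedance from polar components
#'
#' @param magnitude Magnitude in ohms (>= 0).
#' @param phase_deg Phase angle in degrees.
#' @param frequency Frequency in Hz.
#' @return An `impedance` object.
#' @export
impedance_polar <- function(magnitude, phase_deg, frequency) {
  stopifnot(magnitude >= 0)
  ph <- phase_deg * pi / 180
  impedance(magnitude * complex(real = cos(ph), imaginary = sin(ph)), frequency)
}

#' @rdname impedance
#' @export
impedance_magnitude <- function(x) {
  stopifnot(is_impedance(x))
  Mod(x$value)
}

#' @rdname impedance
#' @export
impedance_phase_deg <- function(x) {
  stopifnot(is_impedance(x))
  Arg(x$value) * 180 / pi
}

#' @export
print.impedance <- function(x, ...) {
  cat(sprintf("<impedance> |Z| = %s, phase = %.2f deg @ %g Hz\n",
              format_ohms(impedance_magnitude(x)), impedance_phase_deg(x),
              x$frequency))
  invisible(x)
}

format_ohms <- function(ohms) {
  if (ohms >= 1e6) sprintf("%.3g MOhm", ohms / 1e6)
  else if (ohms >= 1e3) sprintf("%.3g kOhm", ohms / 1e3)
  else sprintf("%.3g Ohm", ohms)
}

# All impedances being combined must share one frequency; returns it.
common_frequency <- function(zs, rel_tol = 1e-9) {
  stopifnot(length(zs) >= 1L)
  freqs <- vapply(zs, function(z) {
    stopifnot(is_impedance(z))
    z$frequency
  }, numeric(1))
  f0 <- freqs[[1L]]
  scale <- max(abs(f0), 1)
  if (any(abs(freqs - f0) > rel_tol * scale)) {
    stop("impedances are defined at different frequencies and cannot be combined",
         call. = FALSE)
  }
  f0
}

#' Impedance of an ideal capacitor
#'
#' Returns \eqn{Z = 1 / (j 2 \pi f C)}, magnitude \eqn{1/(2\pi f C)}.
#' This is the parameterization used for amplifier input impedances (a
#' 21 pF input capacitance corresponds to 7.6 MOhm at 1 kHz) and for the
#' parasitic coupling capacitors of the interference network.
#'
#' @param capacitance Capacitance in farads (> 0).
#' @param frequency Frequency in Hz (> 0).
#' @return An `impedance` object.
#' @examples
#' impedance_magnitude(capacitor_impedance(21e-12, 1000)) # ~7.6e6
#' @export
capacitor_impedance <- function(capacitance, frequency) {
  if (!is.numeric(capacitance) || capacitance <= 0) {
    stop("`capacitance` must be > 0 (farads)", call. = FALSE)
  }
  if (!is.numeric(frequency) || frequency <= 0) {
    stop("`frequency` must be > 0 (Hz)", call. = FALSE)
  }
  impedance(1 / (1i * 2 * pi * frequency * capacitance), frequency)
}

#' Randles parameterization of an electrode-electrolyte interface
#'
#' The textbook Randles cell: solution/spreading resistance `r_s` in series
#' with the parallel combination of charge-transfer resistance `r_ct` and
#' double-layer capacitance `c_dl` (no Warburg element).
#'
#' @param r_s Solution/spreading resistance in ohms (> 0).
#' @param r_ct Charge-transfer resistance in ohms (> 0).
#' @param c_dl Double-layer capacitance in farads (> 0).
#' @return An object of class `"randles_params"`.
#' @export
randles_params <- function(r_s, r_ct, c_dl) {
  if (any(c(r_s, r_ct, c_dl) <= 0)) {
    stop("Randles parameters must all be strictly positive", call. = FALSE)
  }
  structure(list(r_s = r_s, r_ct = r_ct, c_dl = c_dl),
            class = "randles_params")
}

#' Evaluate a Randles cell at a frequency
#'
#' \eqn{Z(f) = R_s + R_{ct} / (1 + j 2 \pi f R_{ct} C_{dl})}. At DC this is
#' \eqn{R_s + R_{ct}}; at high frequency it tends to \eqn{R_s}.
#'
#' @param params A [randles_params()] object.
#' @param frequency Frequency in Hz (>= 0).
#' @return An `impedance` object.
#' @export
randles_impedance <- function(params, frequency) {
  stopifnot(inherits(params, "randles_params"))
  if (!is.numeric(frequency) || frequency < 0) {
    stop("`frequency` must be >= 0 (Hz)", call. = FALSE)
  }
  w <- 2 * pi * frequency
  z <- params$r_s + params$r_ct / (1 + 1i * w * params$r_ct * params$c_dl)
  impedance(z, frequency)
}

#' Combine impedances in parallel or in series
#'
#' Both functions accept impedance objects either as `...` or as a single
#' list. All operands must be defined at the same frequency. A zero
#' impedance in a parallel combination short-circuits the result to 0.
#'
#' @param ... `impedance` objects, or one list of them.
#' @return An `impedance` object at the shared frequency.
#' @examples
#' z <- impedance_polar(6.95e5, -85, 1000)
#' impedance_magnitude(impedance_parallel(rep(list(z), 14))) # |Z|/14
#' @export
impedance_parallel <- function(...) {
  zs <- gather_impedances(...)
  f0 <- common_frequency(zs)
  vals <- vapply(zs, function(z) z$value, complex(1))
  if (any(Mod(vals) == 0)) return(impedance(0 + 0i, f0))
  impedance(1 / sum(1 / vals), f0)
}

#' @rdname impedance_parallel
#' @export
impedance_series <- function(...) {
  zs <- gather_impedances(...)
  f0 <- common_frequency(zs)
  impedance(sum(vapply(zs, function(z) z$value, complex(1))), f0)
}

gather_impedances <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !is_impedance(args[[1L]])) {
    args <- args[[1L]]
  }
  if (length(args) == 0L) stop("no impedances supplied", call. = FALSE)
  args
}

#' Evaluate a parameterized element over a frequency grid
#'
#' @param element A `randles_params` object, a capacitance given as
#'   `list(capacitance = C)`, or a function `f(frequency)` returning an
#'   `impedance`.
#' @param frequencies Numeric vector of frequencies in Hz.
#' @return A data.frame with columns `frequency`, `real`, `imag`,
#'   `magnitude`, `phase_deg`.
#' @export
impedance_sweep <- function(element, frequencies) {
  fn <- if (inherits(element, "randles_params")) {
    function(f) randles_impedance(element, f)
  } else if (is.list(element) && !is.null(element$capacitance)) {
    function(f) capacitor_impedance(element$capacitance, f)
  } else if (is.function(element)) {
    element
  } else {
    stop("unsupported element type for sweep", call. = FALSE)
  }
  rows <- lapply(frequencies, function(f) {
    z <- fn(f)
    data.frame(frequency = f, real = Re(z$value), imag = Im(z$value),
               magnitude = impedance_magnitude(z),
               phase_deg = impedance_phase_deg(z))
  })
  do.call(rbind, rows)
}

#' Read an electrode impedance plan from YAML or JSON
#'
#' Each named entry is either `{z_mag, z_phase_deg, freq}` (direct polar
#' value), `{capacitance, freq}`, or `{randles: {R_s, R_ct, C_dl}, freq}`
#' (evaluated at `freq`). Values may carry unit suffixes (see
#' [parse_quantity()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of `impedance` objects.
#' @export
read_impedance_plan <- function(path) {
  plan <- read_config_file(path)
  lapply(plan, impedance_from_entry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
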