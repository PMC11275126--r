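#' Extracellular current dipole in a homogeneous volume conductor
#'
#' A firing neuron's extracellular current loop is idealized as a current
#' source (+E) and sink (-E) separated by `2 * z_vec`, embedded in a
#' homogeneous, isotropic resistive medium of resistivity `rho_tis`.
#' Cortical grey matter resistivity is typically 1.65--3.9 Ohm*m; values
#' outside that band but inside 0.1--100 Ohm*m are accepted with a warning,
#' anything further out is rejected.
#'
#' @param i_ext Extracellular current amplitude in amperes.
#' @param z_vec Numeric length-3 vector (meters): half-separation from the
#'   dipole origin to the current source (+E); the sink (-E) sits at
#'   `-z_vec`.
#' @param rho_tis Tissue resistivity in Ohm*m (default 3).
#' @param label `"AP"` or `"LFP"`; controls which electrodes the source is
#'   assumed to reach (see [neural_signal_at_electrodes()]).
#' @param origin Numeric length-3 vector (meters): position of the dipole
#'   origin in the global frame (default the global origin).
#' @return Object of class `"dipole_source"`.
#' @export
dipole_source <- function(i_ext, z_vec, rho_tis = 3,
                          label = c("AP", "LFP"), origin = c(0, 0, 0)) {
  label <- match.arg(label)
  z_vec <- as.numeric(z_vec)
  origin <- as.numeric(origin)
  stopifnot(length(z_vec) == 3L, length(origin) == 3L, is.numeric(i_ext))
  if (sqrt(sum(z_vec^2)) <= 0) {
    stop("|z_vec| must be > 0: a dipole needs a finite pole separation",
         call. = FALSE)
  }
  if (rho_tis < 0.1 || rho_tis > 100) {
    stop("`rho_tis` outside the accepted range 0.1-100 Ohm*m", call. = FALSE)
  }
  if (rho_tis < 1.65 || rho_tis > 3.9) {
    warning("`rho_tis` outside the typical cortical band 1.65-3.9 Ohm*m")
  }
  structure(list(i_ext = i_ext, z_vec = z_vec, rho_tis = rho_tis,
                 label = label, origin = origin),
            class = "dipole_source")
}

#' Electrode site on a probe
#'
#' @param site_id Character or integer identifier.
#' @param position Numeric length-3 position in meters.
#' @param role One of `"signal"`, `"reference"`, `"ground"`.
#' @return Object of class `"electrode_site"`.
#' @export
electrode_site <- function(site_id, position, role) {
  role <- match.arg(role, c("signal", "reference", "ground"))
  position <- as.numeric(position)
  stopifnot(length(position) == 3L)
  structure(list(site_id = as.character(site_id), position = position,
                 role = role),
            class = "electrode_site")
}

# Evaluation closer than this to either pole is a configuration bug,
# not a field point; error instead of clamping.
POLE_GUARD_M <- 1e-7

pole_distances <- function(r, d) {
  rl <- as.numeric(r) - d$origin
  c(plus = sqrt(sum((rl - d$z_vec)^2)), minus = sqrt(sum((rl + d$z_vec)^2)))
}

check_not_at_pole <- function(r, d) {
  if (any(pole_distances(r, d) < POLE_GUARD_M)) {
    stop("field point within 0.1 um of a dipole pole (singularity)",
         call. = FALSE)
  }
}

#' Extracellular current density of a dipole
#'
#' Superposition of the two monopole terms:
#' \deqn{j(r) = \frac{I_{EXT}}{4\pi}\left[\frac{r-z}{|r-z|^3} -
#'   \frac{r+z}{|r+z|^3}\right]}
#'
#' @param r Numeric length-3 field point (meters, global frame).
#' @param d A [dipole_source()].
#' @return Numeric length-3 current density in A/m^2.
#' @export
current_density <- function(r, d) {
  stopifnot(inherits(d, "dipole_source"))
  check_not_at_pole(r, d)
  rl <- as.numeric(r) - d$origin
  rp <- rl - d$z_vec
  rm <- rl + d$z_vec
  (d$i_ext / (4 * pi)) *
    (rp / sum(rp^2)^1.5 - rm / sum(rm^2)^1.5)
}

#' Extracellular potential of a dipole
#'
#' \deqn{V(r) = \frac{I_{EXT}\,\rho_{TIS}}{4\pi}\left[\frac{1}{|r-z|} -
#'   \frac{1}{|r+z|}\right]}
#' The potential vanishes on the bisector plane of the dipole and is
#' antisymmetric under exchange of source and sink.
#'
#' @inheritParams current_density
#' @return Potential in volts.
#' @export
dipole_potential <- function(r, d) {
  stopifnot(inherits(d, "dipole_source"))
  check_not_at_pole(r, d)
  dist <- pole_distances(r, d)
  (d$i_ext * d$rho_tis / (4 * pi)) * (1 / dist[["plus"]] - 1 / dist[["minus"]])
}

#' Potentials at electrode sites and the differential-mode neural signal
#'
#' Superposes all sources at every site, then forms the differential-mode
#' neural signal `V(signal) - V(reference)`. When the reference (and
#' ground) electrode area is much larger than a neuron, action-potential
#' sources are assumed to be picked up only by the small signal electrode;
#' `ap_signal_only = TRUE` (the default) implements that assumption by
#' dropping AP-source contributions at reference and ground sites.
#'
#' @param sites List of [electrode_site()] objects; exactly one `"signal"`
#'   and one `"reference"` site are required for the differential output.
#' @param sources List of [dipole_source()] objects (possibly mixing AP and
#'   LFP labels); may be empty.
#' @param ap_signal_only Logical; see above.
#' @return List with `potentials` (named numeric, volts, one per site) and
#'   `v_ns_me_dm` (volts).
#' @export
neural_signal_at_electrodes <- function(sites, sources,
                                        ap_signal_only = TRUE) {
  stopifnot(is.list(sites), is.list(sources))
  roles <- vapply(sites, function(s) s$role, character(1))
  if (sum(roles == "signal") != 1L || sum(roles == "reference") != 1L) {
    stop("exactly one signal site and one reference site are required",
         call. = FALSE)
  }
  pots <- vapply(sites, function(site) {
    v <- 0
    for (src in sources) {
      if (ap_signal_only && src$label == "AP" && site$role != "signal") next
      v <- v + dipole_potential(site$position, src)
    }
    v
  }, numeric(1))
  names(pots) <- vapply(sites, function(s) s$site_id, character(1))
  v_sig <- pots[[which(roles == "signal")]]
  v_ref <- pots[[which(roles == "reference")]]
  list(potentials = pots, v_ns_me_dm = v_sig - v_ref)
}

#' Read probe geometry from YAML or JSON
#'
#' Expected structure: a top-level `sites` list whose entries carry `id`,
#' `role`, and coordinates `x`, `y`, `z` in micrometers (converted to
#' meters on load).
#'
#' @param path Path to the geometry file.
#' @return List of [electrode_site()] objects.
#' @export
read_probe_geometry <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$sites)) stop("geometry file has no `sites` entry", call. = FALSE)
  lapply(cfg$sites, site_from_entry)
}

#' Potential map of a set of sources over query points
#'
#' @param sources List of [dipole_source()] objects.
#' @param points Data.frame with columns `x`, `y`, `z` in meters.
#' @return The input data.frame with an added column `v` (volts), suitable
#'   for CSV export.
#' @export
potential_map <- function(sources, points) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  points$v <- vapply(seq_len(nrow(points)), function(i) {
    r <- c(points$x[i], points$y[i], points$z[i])
    sum(vapply(sources, function(s) dipole_potential(r, s), numeric(1)))
  }, numeric(1))
  points
}
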