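# Configuration loading shared by the file-based interfaces and the CLI.

read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop(sprintf("unsupported config format: .%s (use YAML or JSON)", ext),
         call. = FALSE)
  }
}

#' Parse a physical quantity with a unit suffix
#'
#' Accepts strings like `"695 kohm"`, `"21 pF"`, `"50 um"`, `"100 uV"`,
#' `"1.5 MOhm"` (case-insensitive unit, optional space) or bare numbers
#' (already in SI units), and returns the value in SI units (Ohm, F, m, V,
#' Hz, s, A).
#'
#' @param x A number or a string with a unit suffix.
#' @return Numeric value in SI units.
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*([a-zA-Z]*)\\s*$", x))[[1L]]
  if (length(m) == 0L) stop(sprintf("cannot parse quantity: '%s'", x),
                            call. = FALSE)
  value <- as.numeric(m[2L])
  unit <- m[3L]
  if (unit == "") return(value)
  prefixes <- c(p = 1e-12, n = 1e-9, u = 1e-6, m = 1e-3, k = 1e3, K = 1e3,
                M = 1e6, G = 1e9)
  bases <- c("ohm", "f", "v", "hz", "s", "a", "m")
  unit_l <- unit
  mult <- 1
  # longest base first so 'mohm' is not read as metre + leftovers
  base_match <- NULL
  for (b in c("ohm", "hz", "f", "v", "s", "a", "m")) {
    if (tolower(unit_l) == b) { base_match <- b; break }
    if (nchar(unit_l) > nchar(b) &&
        tolower(substr(unit_l, nchar(unit_l) - nchar(b) + 1L,
                       nchar(unit_l))) == b) {
      pre <- substr(unit_l, 1L, nchar(unit_l) - nchar(b))
      if (pre %in% names(prefixes) ||
          (tolower(pre) %in% names(prefixes) && b != "m")) {
        # 'M' must stay case-sensitive (mega vs milli)
        mult <- if (pre %in% names(prefixes)) prefixes[[pre]]
        else prefixes[[tolower(pre)]]
        base_match <- b
        break
      }
    }
  }
  if (is.null(base_match)) {
    stop(sprintf("unknown unit: '%s'", unit), call. = FALSE)
  }
  value * mult
}

impedance_from_entry <- function(entry, default_freq = NULL) {
  freq <- parse_quantity(entry$freq %||% default_freq)
  if (!is.null(entry$randles)) {
    p <- randles_params(parse_quantity(entry$randles$R_s),
                        parse_quantity(entry$randles$R_ct),
                        parse_quantity(entry$randles$C_dl))
    randles_impedance(p, freq)
  } else if (!is.null(entry$capacitance)) {
    capacitor_impedance(parse_quantity(entry$capacitance), freq)
  } else {
    impedance_polar(parse_quantity(entry$z_mag),
                    parse_quantity(entry$z_phase_deg %||% 0), freq)
  }
}

# YAML 1.1 parses a bare `y` key as boolean TRUE; map it back so probe
# sites can use plain x/y/z coordinate keys.
site_from_entry <- function(s) {
  nm <- names(s)
  nm[nm == "TRUE"] <- "y"
  names(s) <- nm
  electrode_site(s$id, c(s$x, s$y, s$z) * 1e-6, s$role)
}

#' Read a full simulation scenario from YAML or JSON
#'
#' Sections: `coupling_network` (source and parasitics; optional `shield`),
#' `recording_setup` (electrode and amplifier impedance entries, each
#' `{z_mag, z_phase_deg}` / `{capacitance}` / `{randles: ...}`),
#' `emi_environment` (`z_g`, `z_sg`, `z_rg`, `f_sg`, `f_rg`),
#' `probe_geometry` (inline `sites` or a `file` reference, um coordinates),
#' and `simulation` (`duration_s`, `fs_hz`, `seed`). Quantities may carry
#' unit suffixes (see [parse_quantity()]).
#'
#' @param path Path to the scenario file.
#' @return Object of class `"scenario_config"`: the built `net`, `setup`,
#'   `env`, `sites`, `simulation` list, and `hash` (configuration digest).
#' @export
read_scenario_config <- function(path) {
  cfg <- read_config_file(path)
  for (need in c("coupling_network", "recording_setup", "emi_environment")) {
    if (is.null(cfg[[need]])) {
      stop(sprintf("scenario is missing the `%s` section", need),
           call. = FALSE)
    }
  }
  cn <- cfg$coupling_network
  freq <- parse_quantity(cn$frequency %||% 50)
  shield <- NULL
  if (!is.null(cn$shield)) {
    shield <- list(c_is = parse_quantity(cn$shield$c_is),
                   c_sb = parse_quantity(cn$shield$c_sb),
                   z_se = parse_quantity(cn$shield$z_se))
  }
  net <- coupling_network(
    v_ie = parse_quantity(cn$v_ie), frequency = freq,
    z_ie = parse_quantity(cn$z_ie), z_b = parse_quantity(cn$z_b),
    c_be = parse_quantity(cn$c_be), c_ib = parse_quantity(cn$c_ib),
    c_he = parse_quantity(cn$c_he),
    z_ig_star = parse_quantity(cn$z_ig_star), shield = shield
  )
  rs <- cfg$recording_setup
  zi <- function(name) impedance_from_entry(rs[[name]], default_freq = freq)
  setup <- recording_setup(
    z_s = zi("z_s"), z_r = zi("z_r"), z_g = zi("z_g"),
    z_op_p_dm = zi("z_op_p_dm"), z_op_n_dm = zi("z_op_n_dm"),
    z_op_p_cm = zi("z_op_p_cm"), z_op_n_cm = zi("z_op_n_cm"),
    n_channels = rs$n_channels %||% 1L
  )
  ee <- cfg$emi_environment
  env <- emi_environment(
    z_g = impedance_from_entry(ee$z_g, default_freq = freq),
    z_sg = impedance_from_entry(ee$z_sg, default_freq = freq),
    z_rg = impedance_from_entry(ee$z_rg, default_freq = freq),
    f_sg = ee$f_sg, f_rg = ee$f_rg
  )
  sites <- NULL
  if (!is.null(cfg$probe_geometry)) {
    if (!is.null(cfg$probe_geometry$file)) {
      geom_path <- cfg$probe_geometry$file
      if (!file.exists(geom_path)) {
        geom_path <- file.path(dirname(path), geom_path)
      }
      sites <- read_probe_geometry(geom_path)
    } else {
      sites <- lapply(cfg$probe_geometry$sites, site_from_entry)
    }
  }
  sim <- cfg$simulation %||% list()
  simulation <- list(
    duration_s = parse_quantity(sim$duration_s %||% 10),
    fs_hz = parse_quantity(sim$fs_hz %||% 32000),
    seed = as.integer(sim$seed %||% 1L)
  )
  structure(list(net = net, setup = setup, env = env, sites = sites,
                 simulation = simulation, hash = rlang::hash(cfg),
                 source_path = path),
            class = "scenario_config")
}

#' Run a scenario: interference report plus synthetic recording
#'
#' The programmatic core behind the `simulate` CLI subcommand.
#'
#' @param scenario A `"scenario_config"`.
#' @param seed Optional seed override.
#' @return List with `report` (interference report), `recording`
#'   (a `"neural_recording"`), `hash`, `seed`.
#' @export
run_scenario <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  seed <- seed %||% scenario$simulation$seed
  rep <- interference_pipeline(scenario$net, scenario$env, scenario$setup)
  amp <- Mod(rep$v_cmi_op_diff + rep$v_dmi_op_diff)
  rec <- synthesize_recording(
    duration = scenario$simulation$duration_s,
    fs = scenario$simulation$fs_hz, seed = seed,
    interference_amplitude = amp,
    interference_freq_hz = scenario$net$frequency,
    spike_band_hz = min(10000, scenario$simulation$fs_hz / 2)
  )
  list(report = rep, recording = rec, hash = scenario$hash, seed = seed)
}

#' Read a recording exported by [write_recording_csv()]
#'
#' @param path CSV path (the JSON sidecar must sit alongside).
#' @return List with `samples` (matrix), `fs`, and the sidecar metadata.
#' @export
read_recording_csv <- function(path) {
  sidecar_path <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing JSON sidecar next to the recording CSV", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  samples <- as.matrix(df[, grepl("^ch", names(df)), drop = FALSE])
  if (nrow(samples) == 0) stop("recording is empty", call. = FALSE)
  list(samples = samples, fs = meta$fs_hz, meta = meta)
}
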