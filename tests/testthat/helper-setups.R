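# Shared fixture builders for the test suite.

# random passive (resistive-capacitive) impedance at frequency f
random_rc_impedance <- function(f, min_mag = 1e3, max_mag = 1e7) {
  impedance_polar(stats::runif(1, min_mag, max_mag),
                  stats::runif(1, -90, 0), f)
}

# recording setup with all seven impedances drawn at one frequency
random_setup <- function(f = 1000, n_channels = 1L) {
  recording_setup(
    z_s = random_rc_impedance(f), z_r = random_rc_impedance(f),
    z_g = random_rc_impedance(f, 1e2, 1e4),
    z_op_p_dm = random_rc_impedance(f, 1e6, 1e8),
    z_op_n_dm = random_rc_impedance(f, 1e6, 1e8),
    z_op_p_cm = random_rc_impedance(f, 1e6, 1e8),
    z_op_n_cm = random_rc_impedance(f, 1e6, 1e8),
    n_channels = n_channels
  )
}

# setup with balanced branch sums: z_r + z_op_n_dm == z_s + z_op_p_dm
balanced_setup <- function(f = 1000) {
  z_s <- random_rc_impedance(f)
  z_r <- random_rc_impedance(f)
  z_p <- random_rc_impedance(f, 1e6, 1e8)
  z_n <- impedance(z_s$value + z_p$value - z_r$value, f)
  recording_setup(
    z_s = z_s, z_r = z_r, z_g = random_rc_impedance(f, 1e2, 1e4),
    z_op_p_dm = z_p, z_op_n_dm = z_n,
    z_op_p_cm = random_rc_impedance(f, 1e6, 1e8),
    z_op_n_cm = random_rc_impedance(f, 1e6, 1e8)
  )
}

# setup with real (magnitude-aligned) impedances, as used for printed
# attenuation arithmetic
real_setup <- function(z_s, z_r, z_op, z_op_n = z_op, f = 1000,
                       n_channels = 1L) {
  recording_setup(
    z_s = impedance(z_s, f), z_r = impedance(z_r, f),
    z_g = impedance(1e3, f),
    z_op_p_dm = impedance(z_op, f), z_op_n_dm = impedance(z_op_n, f),
    z_op_p_cm = impedance(z_op, f), z_op_n_cm = impedance(z_op_n, f),
    n_channels = n_channels
  )
}

# exact rigorous matching: z_r = z_s/n, z_op_n_cm = z_op_p_cm/n
rigorous_setup <- function(n, f = 1000) {
  z_s <- random_rc_impedance(f)
  z_p_cm <- random_rc_impedance(f, 1e6, 1e8)
  recording_setup(
    z_s = z_s, z_r = rigorous_match_reference(z_s, n),
    z_g = random_rc_impedance(f, 1e2, 1e4),
    z_op_p_dm = random_rc_impedance(f, 1e6, 1e8),
    z_op_n_dm = random_rc_impedance(f, 1e6, 1e8),
    z_op_p_cm = z_p_cm, z_op_n_cm = shared_cm_impedance(z_p_cm, n),
    n_channels = n
  )
}

# three-electrode geometry, coordinates in micrometers
three_sites <- function(sig = c(0, 0, 0), ref = c(100, 0, 0),
                        gnd = c(50, 0, 0)) {
  list(electrode_site("S1", sig * 1e-6, "signal"),
       electrode_site("R1", ref * 1e-6, "reference"),
       electrode_site("G1", gnd * 1e-6, "ground"))
}

spec_coupling_network <- function() {
  coupling_network(v_ie = 230, frequency = 50, z_ie = 1e6, z_b = 500,
                   c_be = 100e-12, c_ib = 1e-12, c_he = 10e-12,
                   z_ig_star = 1e4)
}
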