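test_that("compliant geometry passes guidelines 1-3", {
  rep <- check_geometry(three_sites())
  expect_s3_class(rep, "guideline_report")
  expect_equal(rep$guideline, 1:3)
  expect_true(all(rep$status == "pass"))
  expect_output(print(rep), "guideline")
})

test_that("geometry violations are flagged per guideline", {
  # G1: 10 um pitch between signal and ground
  g1 <- check_geometry(three_sites(sig = c(0, 0, 0), ref = c(100, 0, 0),
                                   gnd = c(10, 0, 0)))
  expect_equal(g1$status[g1$guideline == 1], "fail")

  # G2: 300 um signal-reference distance exceeds the LFP spread
  g2 <- check_geometry(three_sites(sig = c(0, 0, 0), ref = c(300, 0, 0),
                                   gnd = c(150, 0, 0)))
  expect_equal(g2$status[g2$guideline == 2], "fail")

  # G3: ground far off the midpoint
  g3 <- check_geometry(three_sites(sig = c(0, 0, 0), ref = c(100, 0, 0),
                                   gnd = c(95, 0, 0)))
  expect_equal(g3$status[g3$guideline == 3], "fail")
  expect_equal(g3$measured[g3$guideline == 3], 0.45, tolerance = 1e-12)

  # a ground 10% of the pair distance from the midpoint is still compliant
  ok <- check_geometry(three_sites(gnd = c(60, 0, 0)))
  expect_equal(ok$status[ok$guideline == 3], "pass")

  expect_error(check_geometry(list(electrode_site("a", c(0, 0, 0), "signal"))),
               "no reference site")
})

test_that("multi-site geometry reports the worst pair", {
  sites <- c(three_sites(),
             list(electrode_site("S2", c(30, 0, 0) * 1e-6, "signal")))
  rep <- check_geometry(sites)
  # S2 sits 20 um from the ground at x = 50 um: boundary, not > 20 um
  expect_equal(rep$status[rep$guideline == 1], "fail")
  expect_equal(rep$measured[rep$guideline == 1], 20, tolerance = 1e-9)
})

test_that("impedance plan passes guidelines 4-6 under rigorous matching", {
  f <- 1000
  z_s <- impedance_polar(6.95e5, -85, f)
  setup <- recording_setup(
    z_s = z_s, z_r = rigorous_match_reference(z_s, 32),
    z_g = impedance(5e3, f),
    z_op_p_dm = impedance(14.9e6 + 0i, f),
    z_op_n_dm = impedance(14.9e6 + 0i, f),
    z_op_p_cm = impedance(3.2e8 + 0i, f),
    z_op_n_cm = impedance(1e7 + 0i, f),
    n_channels = 32L
  )
  rep <- check_impedance_plan(setup, matching_scheme("rigorous", n = 32L))
  expect_equal(rep$guideline, 4:6)
  expect_true(all(rep$status == "pass"))
})

test_that("impedance plan violations fail with informative measurements", {
  f <- 1000
  bad <- recording_setup(
    z_s = impedance(2.5e6, f), z_r = impedance(2.5e6, f),
    z_g = impedance(1e6, f),
    z_op_p_dm = impedance(6.6e6, f), z_op_n_dm = impedance(6.6e6, f),
    z_op_p_cm = impedance(6.6e6, f), z_op_n_cm = impedance(6.6e6, f)
  )
  rep <- check_impedance_plan(bad, matching_scheme("rigorous", n = 1L))
  # G4: 1 MOhm ground is beyond even the warn band
  expect_equal(rep$status[rep$guideline == 4], "fail")
  # G5: tens of percent attenuation
  expect_equal(rep$status[rep$guideline == 5], "fail")
  expect_gt(rep$measured[rep$guideline == 5], 5)
  # G6 passes here: Z_R equals Z_S / 1 exactly
  expect_equal(rep$status[rep$guideline == 6], "pass")

  # a ground within 10x the bound warns instead of failing
  warnish <- recording_setup(
    z_s = impedance(5e3, f), z_r = impedance(5e3, f),
    z_g = impedance(5e4, f),
    z_op_p_dm = impedance(1e9, f), z_op_n_dm = impedance(1e9, f),
    z_op_p_cm = impedance(1e9, f), z_op_n_cm = impedance(1e9, f)
  )
  rep_w <- check_impedance_plan(warnish, matching_scheme("rigorous", n = 1L))
  expect_equal(rep_w$status[rep_w$guideline == 4], "warn")
})

test_that("G6 accepts extreme matching when the mismatch is large", {
  f <- 1000
  setup <- recording_setup(
    z_s = impedance(5e3, f), z_r = impedance(4e3, f),  # 20% mismatch
    z_g = impedance(1e3, f),
    z_op_p_dm = impedance(1e9, f), z_op_n_dm = impedance(1e9, f),
    z_op_p_cm = impedance(1e9, f), z_op_n_cm = impedance(1e9, f)
  )
  rep <- check_impedance_plan(setup, matching_scheme("extreme", n = 1L,
                                                     tolerance = 0.05))
  expect_equal(rep$status[rep$guideline == 6], "pass")
  # same mismatch without the impedance headroom fails
  low <- recording_setup(
    z_s = impedance(5e3, f), z_r = impedance(4e3, f),
    z_g = impedance(1e3, f),
    z_op_p_dm = impedance(1e5, f), z_op_n_dm = impedance(1e5, f),
    z_op_p_cm = impedance(1e5, f), z_op_n_cm = impedance(1e5, f)
  )
  rep_low <- check_impedance_plan(low, matching_scheme("extreme", n = 1L,
                                                       tolerance = 0.05))
  expect_equal(rep_low$status[rep_low$guideline == 6], "fail")
})

test_that("combined report stacks all six guidelines", {
  f <- 1000
  z_s <- impedance(5e3, f)
  setup <- recording_setup(
    z_s = z_s, z_r = z_s, z_g = impedance(1e3, f),
    z_op_p_dm = impedance(14.9e6, f), z_op_n_dm = impedance(14.9e6, f),
    z_op_p_cm = impedance(1e9, f), z_op_n_cm = impedance(1e9, f)
  )
  rep <- check_guidelines(three_sites(), setup,
                          matching_scheme("rigorous", n = 1L),
                          midpoint_tol = 0.1, zg_bound_ohm = 1e4)
  expect_equal(rep$guideline, 1:6)
  expect_true(all(rep$status == "pass"))
})

test_that("bundled example configurations behave as designed", {
  good_geo <- read_probe_geometry(system.file("extdata", "probe_good.yaml",
                                              package = "neuroemi"))
  bad_geo <- read_probe_geometry(system.file("extdata", "probe_bad.yaml",
                                             package = "neuroemi"))
  expect_true(all(check_geometry(good_geo)$status == "pass"))
  expect_true(any(check_geometry(bad_geo)$status == "fail"))
})
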