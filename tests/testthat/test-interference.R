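test_that("rigorous matching reproduces the printed reference impedance", {
  z_s <- impedance_polar(6.95e5, -85, 1000)
  z_r <- rigorous_match_reference(z_s, 32)
  expect_equal(impedance_magnitude(z_r), 6.95e5 / 32)
  expect_equal(signif(impedance_magnitude(z_r), 3), 2.17e4)
  expect_equal(impedance_phase_deg(z_r), -85, tolerance = 1e-9)
  z_n <- shared_cm_impedance(impedance(3.2e8 + 0i, 1000), 32)
  expect_equal(z_n$value, 1e7 + 0i)
})

test_that("exact rigorous matching nulls CM-to-DM conversion", {
  set.seed(23)
  for (n in c(1L, 4L, 16L, 32L)) {
    for (k in 1:20) {
      setup <- rigorous_setup(n)
      v_cm <- 1e-3 + 5e-4i
      conv <- cmi_differential(v_cm, setup)
      # relative to the common-mode voltage that reaches the inputs
      expect_lt(Mod(conv), 1e-12 * Mod(v_cm))
      expect_lt(dmi_differential(v_cm, 0, setup)$mismatch_fraction, 1e-12)
    }
  }
})

test_that("breaking rigorous matching reintroduces conversion", {
  set.seed(29)
  setup <- rigorous_setup(32L)
  broken <- recording_setup(
    z_s = setup$z_s,
    z_r = impedance(setup$z_r$value * 1.2, setup$z_r$frequency),
    z_g = setup$z_g,
    z_op_p_dm = setup$z_op_p_dm, z_op_n_dm = setup$z_op_n_dm,
    z_op_p_cm = setup$z_op_p_cm, z_op_n_cm = setup$z_op_n_cm,
    n_channels = 32L
  )
  expect_gt(Mod(cmi_differential(1e-3 + 0i, broken)), 0)
})

test_that("CM dividers pass the inline oracle and bound the inputs", {
  setup <- real_setup(5e3, 2e3, 1e7, z_op_n = 5e6)
  v_cm <- 2e-3 + 0i
  inp <- cmi_at_inputs(v_cm, setup)
  expect_equal(inp$v_cmi_op_p, v_cm * 1e7 / (1e7 + 5e3), tolerance = 1e-15)
  expect_equal(inp$v_cmi_op_n, v_cm * 5e6 / (5e6 + 2e3), tolerance = 1e-15)
  expect_lt(Mod(inp$v_cmi_op_p), Mod(v_cm))
  # product-of-difference vs difference-of-products: allow cancellation
  expect_equal(cmi_differential(v_cm, setup),
               inp$v_cmi_op_p - inp$v_cmi_op_n, tolerance = 1e-9)
})

test_that("extreme matching predicate applies the headroom factor", {
  f <- 1000
  mk <- function(z_e) recording_setup(
    z_s = impedance(z_e, f), z_r = impedance(z_e, f),
    z_g = impedance(1e3, f),
    z_op_p_dm = impedance(1e9, f), z_op_n_dm = impedance(1e9, f),
    z_op_p_cm = impedance(1e9, f), z_op_n_cm = impedance(1e9, f)
  )
  pass <- check_extreme_matching(mk(1e6), factor = 100)
  expect_true(pass$pass)
  expect_gte(pass$margin, 10)
  fail <- check_extreme_matching(mk(2e7), factor = 100)
  expect_false(fail$pass)
  expect_lt(fail$margin, 1)
  # boundary: |Z| exactly |Z_cm|/factor passes
  expect_true(check_extreme_matching(mk(1e7), factor = 100)$pass)

  # saturation: nearly the full CM voltage reaches the input
  sat <- check_extreme_matching(mk(1e6), v_cm = 0.5 + 0i,
                                input_range_v = 0.01)
  expect_true(sat$saturation_warning)
  ok <- check_extreme_matching(mk(1e6), v_cm = 1e-3 + 0i,
                               input_range_v = 0.01)
  expect_false(ok$saturation_warning)
})

test_that("DMI is the sum of DM pickup and CM conversion", {
  set.seed(31)
  for (k in 1:20) {
    setup <- random_setup()
    v_cm <- complex(real = rnorm(1, sd = 1e-3), imaginary = rnorm(1, sd = 1e-3))
    v_dm <- complex(real = rnorm(1, sd = 1e-4), imaginary = rnorm(1, sd = 1e-4))
    rep <- dmi_differential(v_cm, v_dm, setup)
    expect_equal(rep$v_dmi_op_diff,
                 rep$term_dm_pickup + rep$term_cm_conversion,
                 tolerance = 1e-15)
    expect_equal(rep$term_dm_pickup, v_dm * dm_transfer_factor(setup),
                 tolerance = 1e-15)
    expect_equal(rep$term_cm_conversion, cmi_differential(v_cm, setup),
                 tolerance = 1e-15)
    expect_equal(rep$v_cmi_op_diff, rep$v_cmi_op_p - rep$v_cmi_op_n,
                 tolerance = 1e-9)
  }
})

test_that("interference pipeline composes the chain consistently", {
  f <- 50
  net <- spec_coupling_network()
  env <- emi_environment(impedance(1e3, f), impedance(2e5, f),
                         impedance(5e4, f), f_sg = 0.3, f_rg = 0.2)
  setup <- real_setup(5e3, 5e3, 1e7, f = f)
  rep <- interference_pipeline(net, env, setup)
  expect_s3_class(rep, "interference_report")

  v_body <- body_emi(net)
  i_d_h <- hardware_displacement_current(v_body, net)
  ev <- electrode_emi_voltages(i_d_h, env)
  cmdm <- cm_dm_decompose(ev$v_emi_me_s, ev$v_emi_me_r)
  manual <- dmi_differential(cmdm$cm, cmdm$dm, setup)
  expect_equal(rep$v_dmi_op_diff, manual$v_dmi_op_diff, tolerance = 1e-15)
  expect_equal(rep$v_body, v_body)
  expect_equal(rep$i_d_h, i_d_h)

  tab <- interference_report_table(rep)
  expect_s3_class(tab, "data.frame")
  expect_equal(tab$magnitude_uv[tab$term == "v_dmi_op_diff"],
               Mod(rep$v_dmi_op_diff) * 1e6)
  expect_output(print(rep), "DMI total")
})

test_that("reference levels table carries the expected scenario constants", {
  lev <- emi_reference_levels()
  get <- function(nm) lev$value[lev$name == nm]
  expect_equal(get("cmi_ground_in_cortex"), 1e-3)
  expect_equal(get("cmi_ground_on_chest"), 1e-1)
  expect_equal(get("cmrr_requirement"), 70)
  expect_equal(get("detectable_signal"), 5e-6)
})

test_that("matching scheme constructor validates its inputs", {
  s <- matching_scheme("rigorous", n = 32L, tolerance = 0.05)
  expect_equal(s$n, 32L)
  expect_error(matching_scheme("rigorous", n = 0), "n")
  expect_error(matching_scheme("extreme", tolerance = -1), "tolerance")
})
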