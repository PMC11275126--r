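# Smaller rates/durations than the defaults keep the suite fast; the
# sampling rate must still cover the requested spike band.
fast_rec <- function(...) {
  synthesize_recording(fs = 4000, spike_band_hz = 1000, ...)
}

test_that("stage fixture reproduces the reported PSD reduction factors", {
  stages <- default_stage_table()
  expect_length(stages, 5L)
  psd <- vapply(stages, function(s) s$psd_50hz_in_vivo, numeric(1))
  expect_true(all(diff(psd) < 0))
  # reduction relative to the all-skull baseline (stage 1)
  expect_equal(round(psd[1] / psd[2]), 3)
  expect_equal(round(psd[1] / psd[3]), 10)
  expect_equal(round(psd[1] / psd[4]), 39)
  expect_equal(psd[1] / psd[5], 1096, tolerance = 1e-3)
})

test_that("stage interference amplitude decreases strictly across stages", {
  amps <- vapply(default_stage_table(),
                 function(s) stage_interference(s)$amplitude, numeric(1))
  expect_true(all(diff(amps) < 0))
  # mV-scale at stage 1, tens of uV by stage 5
  expect_gt(amps[1], 1e-3)
  expect_lt(amps[5], 1e-4)
})

test_that("stage setups expose the matched impedances at both frequencies", {
  s3 <- default_stage_table()[[3]]
  setup_1k <- stage_recording_setup(s3, frequency = 1000)
  expect_equal(impedance_magnitude(setup_1k$z_s), 6.95e5)
  expect_equal(impedance_magnitude(setup_1k$z_r), 2.17e4)
  # capacitive electrodes scale by 20x at 50 Hz
  setup_50 <- stage_recording_setup(s3, frequency = 50)
  expect_equal(impedance_magnitude(setup_50$z_s), 6.95e5 * 20)
  # shared negative common-mode input: per-channel / 32
  expect_equal(impedance_magnitude(setup_50$z_op_n_cm),
               impedance_magnitude(setup_50$z_op_p_cm) / 32)
  # stage 1 has no cortical grounds: ground path is the skull resistance
  s1 <- default_stage_table()[[1]]
  expect_equal(stage_recording_setup(s1, 50)$z_g$value, 5e3 + 0i)
  expect_error(stage_config(1, 0, 0, z_ref_parallel = c(f50 = 1),
                            z_gnd_parallel = NULL, z_sg_eff = 1e4,
                            z_rg_eff = 1e4, f_sg = 0.3, f_rg = 0.2),
               "f50 and f1k")
})

test_that("spike template is biphasic with unit peak-to-peak", {
  tmpl <- neuroemi:::spike_template(32000)
  expect_equal(length(tmpl), round(1.2e-3 * 32000))
  expect_equal(max(tmpl) - min(tmpl), 1)
  expect_gt(max(tmpl), 0)
  expect_lt(min(tmpl), 0)
})

test_that("recordings are seed-deterministic and components sum exactly", {
  a <- fast_rec(duration = 2, seed = 7, interference_amplitude = 1e-3)
  b <- fast_rec(duration = 2, seed = 7, interference_amplitude = 1e-3)
  c <- fast_rec(duration = 2, seed = 8, interference_amplitude = 1e-3)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
  expect_equal(a$samples,
               a$components$spikes + a$components$lfp +
                 a$components$interference)
  # the interference component is exactly the requested sinusoid
  n <- nrow(a$samples)
  tt <- (seq_len(n) - 1) / a$fs
  expect_equal(a$components$interference[, 1], 1e-3 * sin(2 * pi * 50 * tt))
  # zero amplitude injects nothing
  quiet <- fast_rec(duration = 1, seed = 7, interference_amplitude = 0)
  expect_true(all(quiet$components$interference == 0))
})

test_that("sampling-rate and duration guards reject unusable requests", {
  expect_error(synthesize_recording(duration = 0), "duration")
  expect_error(synthesize_recording(fs = 1000), "2 kS/s")
  expect_error(synthesize_recording(fs = 4000, spike_band_hz = 10000),
               "spike-band")
  expect_error(synthesize_recording(fs = 4000, spike_band_hz = 1000,
                                    lfp_cutoff_hz = 2000),
               "LFP cutoff")
})

test_that("noiseless recordings return the drawn spike amplitudes", {
  rec <- fast_rec(duration = 5, seed = 3, spike_pp_v = 500e-6,
                  spike_pp_sd_v = 0, spike_rate_hz = 2,
                  lfp_sd_v = 0, interference_amplitude = 0)
  expect_true(all(rec$components$lfp == 0))
  st <- spike_pp_stats(rec, highpass_hz = NULL)
  expect_equal(st$n_spikes, length(rec$ground_truth$spikes[[1]]$neuron1$times))
  expect_gt(st$n_spikes, 0)
  expect_equal(st$mean_pp_uv, 500, tolerance = 1e-3)
  expect_lt(st$sd_pp_uv, 5)
})

test_that("Welch PSD recovers sinusoid power and noise variance", {
  fs <- 4000
  tt <- (0:(4 * fs - 1)) / fs
  a <- 1e-3
  x <- a * sin(2 * pi * 50 * tt)
  psd <- welch_psd(x, fs = fs)
  expect_s3_class(psd, "psd_estimate")
  expect_equal(psd$segment_length, fs)
  # the line integrates to A^2 / 2
  expect_equal(psd_band_power(psd, 45, 55), a^2 / 2, tolerance = 1e-6)
  # peak bin sits at 50 Hz
  expect_equal(psd$frequency[which.max(psd$density)], 50)
  # white noise: integrated density ~ variance
  set.seed(99)
  wn <- rnorm(8 * fs, sd = 1e-4)
  psd_wn <- welch_psd(wn, fs = fs)
  expect_equal(psd_band_power(psd_wn, 0, fs / 2), var(wn), tolerance = 0.1)
  expect_error(psd_at_line(psd, 50.5, tol_hz = 0.2), "tolerance")
  expect_error(welch_psd(x[1:4], fs = fs), "segment")
})

test_that("injected 50 Hz amplitude is recoverable from the PSD", {
  a <- 1e-3
  rec <- fast_rec(duration = 8, seed = 21, interference_amplitude = a)
  psd <- welch_psd(rec)
  recovered <- sqrt(2 * psd_band_power(psd, 45, 55))
  expect_equal(recovered, a, tolerance = 0.05)
})

test_that("staged experiment lowers the 50 Hz line, not the spikes", {
  stages <- default_stage_table()[c(1, 3, 5)]
  tab <- run_stage_experiment(stages, seed = 2, duration = 4, fs = 4000,
                              spike_band_hz = 1000)
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$psd_50hz) < 0))
  expect_true(all(diff(tab$interference_amp_v) < 0))
  # spike amplitudes unaffected by the interference level: all stage means
  # within a few ground-truth jitter sd of the nominal amplitudes
  expect_true(all(abs(tab$neuron1_pp_mean_uv - 947.55) < 3 * 62.94))
  expect_true(all(abs(tab$neuron2_pp_mean_uv - 312.32) < 3 * 49.68))
})

test_that("CSV export round-trips samples and metadata", {
  rec <- fast_rec(duration = 0.5, seed = 4, interference_amplitude = 2e-4,
                  n_channels = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(dim(back$samples), dim(rec$samples))
  expect_equal(unname(back$samples), unname(rec$samples), tolerance = 1e-10)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$meta$interference_amplitude_v, 2e-4)
  expect_error(read_recording_csv(withr::local_tempfile(fileext = ".csv")),
               "sidecar")
})
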