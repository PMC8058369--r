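test_that("mean firing rate matches brute-force counting", {
  fx <- tiny_fixture(0.01)
  rec <- spike_record(id = c(1L, 1L, 1L, 1L, 1L), time_ms = c(10, 200, 400, 600, 999),
                      placement = fx$placement)
  expect_equal(mean_firing_rate(rec, 1L, c(0, 1000)), 5)
  expect_equal(mean_firing_rate(rec, c(1L, 2L), c(0, 1000)), 2.5)
  expect_equal(mean_firing_rate(rec, 2L, c(0, 1000)), 0)
  expect_error(mean_firing_rate(rec, integer(), c(0, 1000)), "empty")
  expect_error(mean_firing_rate(rec, 1L, c(5, 5)), "non-empty")

  res <- run_background(fx, 300, rate = 20, seed = 2)
  ids <- fx$placement$id[fx$placement$cell_type == "GrC"]
  win <- c(50, 250)
  brute <- sum(res$spikes$id %in% ids & res$spikes$time_ms >= 50 &
                 res$spikes$time_ms < 250)
  expect_equal(mean_firing_rate(res$spikes, ids, win),
               brute / (length(ids) * 0.2))
})

test_that("binned rates are invariant to record chunking", {
  fx <- tiny_fixture(0.01)
  mf <- fx$placement$id[fx$placement$cell_type == "MF"]
  stim <- list(stimulus_spec(mf, rate = 15))
  whole <- simulate_network(fx$network, stim, 400, seed = 7)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  simulate_network(fx$network, stim, 400, seed = 7, out_file = f1,
                   flush_interval = 50)
  simulate_network(fx$network, stim, 400, seed = 7, out_file = f2,
                   flush_interval = 400)
  b0 <- bin_population_rates(whole$spikes, "GrC", bin = 100, window = c(0, 400))
  b1 <- bin_population_rates(read_spikes(f1), "GrC", bin = 100, window = c(0, 400))
  b2 <- bin_population_rates(read_spikes(f2), "GrC", bin = 100, window = c(0, 400))
  expect_equal(b1, b0)
  expect_equal(b2, b0)
})

test_that("cosine fits recover known parameters", {
  t <- seq(50, 1950, by = 100)
  # noiseless cosine: machine-precision recovery
  y <- 50 + 20 * cos(2 * pi * (t - 300) / 2000)
  fit <- cosine_fit(t, y, period = 2000)
  expect_equal(fit$offset, 50, tolerance = 1e-10)
  expect_equal(fit$amplitude, 20, tolerance = 1e-10)
  expect_equal(fit$phase, 300, tolerance = 1e-8)
  expect_equal(fit$min, 30, tolerance = 1e-10)
  expect_equal(fit$max, 70, tolerance = 1e-10)
  expect_equal(glance(fit)$rmse, 0, tolerance = 1e-10)
  expect_equal(tidy(fit)$estimate[1], 50, tolerance = 1e-10)

  # constant input: amplitude zero, phase undefined
  fit0 <- cosine_fit(t, rep(42, 20), period = 2000)
  expect_equal(fit0$offset, 42)
  expect_equal(fit0$amplitude, 0)
  expect_true(is.na(fit0$phase))

  expect_error(cosine_fit(1:2, 1:2, 2000), "at least 3")

  # Monte-Carlo recovery under Gaussian noise: bias below 0.5 Hz
  set.seed(5)
  fits <- t(vapply(1:100, function(i) {
    fit <- cosine_fit(t, 50 + 20 * cos(2 * pi * t / 2000) + rnorm(20, 0, 2),
                      period = 2000)
    c(fit$offset, fit$amplitude)
  }, numeric(2)))
  expect_lt(abs(mean(fits[, 1]) - 50), 0.5)
  expect_lt(abs(mean(fits[, 2]) - 20), 0.5)

  # phase difference is a signed circular difference
  fa <- cosine_fit(t, 10 + 5 * cos(2 * pi * t / 2000), 2000)
  fb <- cosine_fit(t, 10 - 5 * cos(2 * pi * t / 2000), 2000)
  expect_equal(abs(phase_difference(fa, fb)), pi, tolerance = 1e-6)
})

test_that("burst protocol computes period rates and obeys its contracts", {
  fx <- tiny_fixture(0.02)
  spec <- burst_protocol_spec(repetitions = 2)
  br <- run_burst_protocol(fx, spec, seed = 1)
  rates <- br$rates
  expect_setequal(unique(rates$cell_type),
                  setdiff(cell_type_order(), c("MF", "IO")))
  expect_true(all(rates$mean_hz >= 0) && all(rates$sd_hz >= 0))

  wide <- tidyr::pivot_wider(rates[, 1:3], names_from = "period",
                             values_from = "mean_hz")
  # excitatory drive sanity: granule and Purkinje rates rise during the burst
  expect_gt(wide$burst[wide$cell_type == "GrC"], wide$pre[wide$cell_type == "GrC"])
  expect_gt(wide$burst[wide$cell_type == "PC"], wide$pre[wide$cell_type == "PC"])

  # with all mossy-fiber input silenced, only cells with endogenous drive fire
  silent <- run_burst_protocol(
    fx, burst_protocol_spec(background_rate = 0, burst_rate = 0,
                            repetitions = 1), seed = 1)
  wide0 <- tidyr::pivot_wider(silent$rates[, 1:3], names_from = "period",
                              values_from = "mean_hz")
  expect_lt(wide0$pre[wide0$cell_type == "GrC"], 1)   # I_e = 0: silent
  for (tp in c("GoC", "SC", "BC", "PC", "DCN")) {     # I_e > 0: tonic
    expect_gt(wide0$pre[wide0$cell_type == tp], 1)
  }

  expect_error(run_burst_protocol(fx, burst_protocol_spec(burst_radius = 0)),
               "no mossy fibers")
})

test_that("OKR controls behave: no plasticity or no LTD means no learning", {
  fx <- tiny_fixture(0.02)
  spec_off <- okr_protocol_spec(n_trials = 4, plasticity = NULL)
  off <- run_okr_protocol(fx, spec_off, seed = 2)
  expect_true(all(is.na(off$w_mean)))
  pc <- off$fits[off$fits$cell_type == "PC", ]
  # without plasticity, trial curves are statistically stationary
  expect_lt(abs(pc$min[4] - pc$min[1]), 3 * stats::sd(pc$min) + 1e-9)

  spec_noltd <- okr_protocol_spec(
    n_trials = 4, plasticity = plasticity_params(ltd_rate = 0, ltp_gated = TRUE))
  noltd <- run_okr_protocol(fx, spec_noltd, seed = 2)
  expect_equal(noltd$w_mean, rep(1, 4), tolerance = 1e-9)
  pc2 <- noltd$fits[noltd$fits$cell_type == "PC", ]
  expect_equal(pc2$min, pc$min, tolerance = 1e-9)  # identical dynamics

  # phase contract at the miniature scale: PC opposes the drive, DCN follows
  drive_peak <- okr_drive_phase(spec_off)
  pc_phase <- off$fits$phase[off$fits$cell_type == "PC"][1]
  dcn_phase <- off$fits$phase[off$fits$cell_type == "DCN"][1]
  circ <- function(a, b, T = 2000) {
    d <- abs(a - b) %% T
    min(d, T - d) / T * 2 * pi
  }
  expect_gt(circ(pc_phase, drive_peak), pi / 2)
  expect_lt(circ(dcn_phase, drive_peak), pi / 2)
})
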