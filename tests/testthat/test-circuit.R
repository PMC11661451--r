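test_that("impedance limits: capacitor shorts at high frequency, dominates at low", {
  p <- circuit_params(1e4, 1e6, 1e-9)
  z_hi <- impedance_spectrum(p, 1e9)
  expect_equal(Re(z_hi), 1.01e6, tolerance = 1e-9)
  expect_lt(abs(Im(z_hi)) / Re(z_hi), 1e-3)
  z_lo <- impedance_spectrum(p, 1e-4)
  expect_equal(Arg(z_lo) * 180 / pi, -90, tolerance = 0.01)
  expect_error(impedance_spectrum(p, 0), "DC")
  # |Z| monotone decreasing with frequency for this topology
  f <- 10^seq(0, 5, length.out = 40)
  expect_true(all(diff(Mod(impedance_spectrum(p, f))) < 0))
})

test_that("impedance at 1 kHz matches an independent complex-arithmetic evaluation", {
  # frozen: Z = 1.01e6 - i/(2 pi 1e3 1e-9)
  z <- impedance_spectrum(circuit_params(1e4, 1e6, 1e-9), 1000)
  expect_equal(Mod(z), 1022462.8579613953, tolerance = 1e-12)
  expect_equal(Arg(z) * 180 / pi, -8.954983879125054, tolerance = 1e-10)
})

test_that("time constant is (R_s + R_P) C_P and grows with capacitance", {
  expect_equal(time_constant(circuit_params(5e5, 5e5, 6e-9)), 6e-3)
  taus <- vapply(c(1e-9, 2e-9, 8e-9), function(cp) {
    time_constant(circuit_params(1e4, 1e6, cp))
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
  # tau equals the 1 - 1/e crossing of the step response
  p <- circuit_params(1e4, 1e6, 1e-9)
  prot <- stimulus_protocol(v_bias = 0,
                            pulses = data.frame(amplitude = -0.1,
                                                onset = 0.001,
                                                duration = 0.05),
                            total_duration = 0.06, sampling_rate = 2e5)
  tr <- transferred_voltage(p, prot)
  target <- -0.1 * (1 - exp(-1))
  i_cross <- which(tr$v <= target)[1]
  t_cross <- stats::approx(tr$v[(i_cross - 1):i_cross],
                           tr$time_s[(i_cross - 1):i_cross],
                           xout = target)$y
  expect_equal(t_cross - 0.001, time_constant(p), tolerance = 1e-3)
})

test_that("transferred voltage: bias-only limit, 63.2% point, and pulse superposition", {
  p <- circuit_params(1e4, 1e6, 1e-9)
  quiet <- stimulus_protocol(v_bias = -0.45, total_duration = 0.1,
                             sampling_rate = 1e3)
  expect_true(all(transferred_voltage(p, quiet)$v == -0.45))
  tau <- time_constant(p)
  prot <- stimulus_protocol(v_bias = -0.45,
                            pulses = data.frame(amplitude = -0.1,
                                                onset = 0.01,
                                                duration = 0.05),
                            total_duration = 0.1, sampling_rate = 1e6)
  tr <- transferred_voltage(p, prot)
  v_at_tau <- tr$v[which.min(abs(tr$time_s - (0.01 + tau)))]
  expect_equal(v_at_tau - (-0.45), -0.1 * (1 - exp(-1)), tolerance = 1e-3)
  # superposition of non-overlapping pulses
  p1 <- data.frame(amplitude = -0.05, onset = 0.01, duration = 0.02)
  p2 <- data.frame(amplitude = 0.08, onset = 0.05, duration = 0.02)
  mk <- function(pl) stimulus_protocol(0, pl, 0.1, 1e4)
  both <- transferred_voltage(p, mk(rbind(p1, p2)))$v
  sum_ind <- transferred_voltage(p, mk(p1))$v +
    transferred_voltage(p, mk(p2))$v
  expect_equal(both, sum_ind, tolerance = 1e-12)
})

test_that("analytic step response matches a general-purpose ODE integration", {
  p <- circuit_params(1e4, 1e6, 1e-9)
  tau <- time_constant(p)
  prot <- stimulus_protocol(v_bias = -0.45,
                            pulses = data.frame(amplitude = c(-0.1, 0.06),
                                                onset = c(0.005, 0.06),
                                                duration = c(0.04, 0.02)),
                            total_duration = 0.1, sampling_rate = 2e4)
  analytic <- transferred_voltage(p, prot)
  v_app <- stimulus_voltage(prot)
  # stiff integration segment by segment between input discontinuities
  edges <- sort(unique(c(0, prot$pulses$onset,
                         prot$pulses$onset + prot$pulses$duration,
                         prot$total_duration)))
  t_all <- analytic$time_s
  v_ode <- numeric(length(t_all))
  state <- -0.45
  for (k in seq_len(length(edges) - 1)) {
    sel <- t_all >= edges[k] & t_all < edges[k + 1]
    v_in <- v_app$v[which(sel)[1]]
    tt <- unique(c(edges[k], t_all[sel], edges[k + 1]))
    sol <- deSolve::lsoda(c(v = state), tt,
                          function(t, y, parms) list((v_in - y) / tau),
                          rtol = 1e-12, atol = 1e-12)
    v_ode[sel] <- stats::approx(sol[, "time"], sol[, "v"],
                              xout = t_all[sel])$y
    state <- unname(sol[nrow(sol), "v"])
  }
  expect_lt(max(abs(analytic$v - v_ode)) / 0.1, 1e-6)
})

test_that("EIS fitting round-trips noiseless spectra to better than 0.1%", {
  p <- circuit_params(1e4, 1.2e9, 2.8e-11)
  sp <- synth_eis(p, noise_frac = 0, n_freq = 40)
  fit <- fit_eis(sp$frequencies, sp$z, r_s = 1e4)
  expect_true(attr(fit, "converged"))
  expect_false(attr(fit, "misfit"))
  expect_lt(rel_err(fit$r_s + fit$r_p, p$r_s + p$r_p), 1e-3)
  expect_lt(rel_err(fit$c_p, p$c_p), 1e-3)
  expect_error(fit_eis(c(1, 2, 3, 4), impedance_spectrum(p, c(1, 2, 3, 4))),
               ">= 5")
  expect_error(fit_eis(c(10, 20, 30, 40, 50),
                       impedance_spectrum(p, c(10, 20, 30, 40, 50))),
               "decades")
})

test_that("EIS fitting recovers parameters within 5% median under 1% noise", {
  p <- circuit_params(1e4, 1.2e9, 2.8e-11)
  errs <- vapply(1:20, function(seed) {
    sp <- synth_eis(p, noise_frac = 0.01, n_freq = 30, seed = seed)
    fit <- suppressWarnings(fit_eis(sp$frequencies, sp$z, r_s = 1e4))
    max(rel_err(fit$r_s + fit$r_p, p$r_s + p$r_p),
        rel_err(fit$c_p, p$c_p))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("a spectrum from a different topology is flagged as a misfit", {
  # a parallel RC (impedance collapsing at high frequency) cannot be
  # reproduced by the series topology, whose |Z| is bounded below by
  # the total resistance
  f <- 10^seq(0, 5, length.out = 25)
  z_par <- 1e6 / (1 + 2i * pi * f * 1e6 * 1e-9)
  expect_warning(fit <- fit_eis(f, z_par), "poorly described")
  expect_true(attr(fit, "misfit"))
})

test_that("default circuits give slower dynamics for larger antennas", {
  taus <- vapply(c(700, 1400, 1800), function(cap) {
    time_constant(default_circuit(antenna_geometry(cap)))
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
  expect_equal(taus[1], 6.0e-3, tolerance = 1e-6)
  expect_equal(taus[2], 34.7e-3, tolerance = 1e-6)
  expect_equal(taus[3], 233.9e-3, tolerance = 1e-6)
})

test_that("EIS spectra survive text round trips", {
  p <- circuit_params(1e4, 1e6, 1e-9)
  f <- 10^seq(0, 5, length.out = 12)
  z <- impedance_spectrum(p, f)
  path <- tempfile(fileext = ".tsv")
  write_eis(f, z, path)
  back <- read_eis(path)
  expect_equal(back$frequencies, f, tolerance = 1e-10)
  expect_equal(back$z, z, tolerance = 1e-10)
})
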