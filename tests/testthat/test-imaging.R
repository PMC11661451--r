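test_that("registration recovers programmed rigid shifts", {
  base <- smooth_test_image(48)
  # already aligned: zero shifts, frames untouched
  fr <- array(0, dim = c(3, 48, 48))
  for (i in 1:3) fr[i, , ] <- base
  seq0 <- image_sequence(fr, 200, 1)
  reg0 <- register_translation(seq0)
  expect_true(all(abs(reg0$shifts) < 1e-6))
  expect_equal(reg0$sequence$frames, seq0$frames, tolerance = 1e-9)
  # integer shift (3, -2): recovered exactly
  shifted <- base[c(46:48, 1:45), c(3:48, 1:2)]  # image moved by (+3, -2)
  fr2 <- array(0, dim = c(2, 48, 48))
  fr2[1, , ] <- base; fr2[2, , ] <- shifted
  reg2 <- register_translation(image_sequence(fr2, 200, 1))
  expect_equal(unname(reg2$shifts[2, ]), c(-3, 2), tolerance = 1e-6)
  expect_equal(reg2$sequence$frames[2, , ], base, tolerance = 1e-6)
  # subpixel shift 0.3 px: recovered within 0.1 px
  fr3 <- array(0, dim = c(2, 48, 48))
  fr3[1, , ] <- base
  fr3[2, , ] <- escat:::fourier_shift(base, 0.3, 0)
  reg3 <- register_translation(image_sequence(pmax(fr3, 0), 200, 1))
  expect_equal(unname(reg3$shifts[2, 1]), -0.3, tolerance = 0.1)
  # featureless frames are an error
  flat <- array(5, dim = c(2, 8, 8))
  expect_error(register_translation(image_sequence(flat, 200, 1)),
               "featureless")
})

test_that("Z scoring normalizes the baseline and flags zero-variance pixels", {
  set.seed(21)
  fr <- array(rpois(50 * 10 * 10, 400), dim = c(50, 10, 10))
  fr[, 4, 7] <- 123  # constant pixel
  z <- pixel_zscores(image_sequence(fr, 200, 1), baseline = 1:30)
  inv <- attr(z, "invalid")
  expect_true(inv[4, 7])
  expect_equal(sum(inv), 1)
  expect_true(all(is.na(z[, 4, 7])))
  zb <- z[1:30, , ]
  mu <- apply(zb, c(2, 3), mean)
  sdv <- apply(zb, c(2, 3), sd)
  expect_lt(max(abs(mu[!inv])), 1e-12)
  expect_equal(unname(sdv[!inv]), rep(1, sum(!inv)), tolerance = 1e-12)
})

test_that("the hand-worked 5-frame toy pixel gives z = 9 at the stimulus", {
  fr <- array(400, dim = c(6, 5, 5))
  fr[1:5, 3, 3] <- c(10, 12, 11, 10, 12)  # baseline: mean 11, sd 1
  fr[6, 3, 3] <- 20
  z <- suppressWarnings(pixel_zscores(image_sequence(fr, 200, 1),
                                      baseline = 1:5))
  expect_equal(z[6, 3, 3], 9)
})

test_that("antenna extraction averages only super-threshold pixels and reports empty masks", {
  # deterministic background texture so no pixel crosses the threshold
  # by chance; one pixel is given a genuine response
  tgrid <- 1:60
  fr <- array(0, dim = c(60, 21, 21))
  for (r in 1:21) for (cl in 1:21) {
    fr[, r, cl] <- 400 + 5 * sin(tgrid * (1 + (r * 21 + cl) %% 7) / 3)
  }
  fr[41:60, 11, 11] <- fr[41:60, 11, 11] + 500  # one responsive pixel
  z <- pixel_zscores(image_sequence(fr, 200, 1), baseline = 1:40)
  tr <- extract_antenna_trace(z, roi_spec(c(11, 11), 5),
                              stim_window = 41:60)
  expect_false(tr$no_responsive)
  expect_equal(tr$n_pixels, 1L)
  expect_equal(tr$z, unname(z[, 11, 11]))
  # no pixel beyond threshold
  tr0 <- extract_antenna_trace(z, roi_spec(c(5, 16), 3),
                               stim_window = 41:60)
  expect_true(tr0$no_responsive)
  expect_equal(tr0$n_pixels, 0L)
  expect_error(extract_antenna_trace(z, roi_spec(c(2, 2), 5)), "bounds")
})

test_that("a programmed Gaussian spot yields a concentric mask and the programmed amplitude", {
  layout <- array_layout(n_rows = 1, n_cols = 1)
  prot <- test_protocol()
  r <- render_sequence(layout, test_transfer(), test_circuit(), prot,
                       noise_model(), seed = 42)
  z <- pixel_zscores(r$sequence, baseline = 1:200)
  roi <- layout_rois(r$truth)[[1]]
  tr <- extract_antenna_trace(z, roi)
  expect_false(tr$no_responsive)
  # mask concentric with the spot
  expect_equal(mean(tr$pixel_mask$row), r$truth$centers$row[1],
               tolerance = 0.2)
  expect_equal(mean(tr$pixel_mask$col), r$truth$centers$col[1],
               tolerance = 0.2)
  # plateau amplitude at the largest pulse within 10% of the programmed
  # pixel-mean amplitude
  pred <- predict_electro_optics(r$truth)
  p <- prot$pulses[4, ]
  plateau <- mean(tr$z[tr$time >= p$onset + 0.5 & tr$time < p$onset + 1])
  expect_equal(plateau, pred$snr[1] * pred$noise_z[1], tolerance = 0.1)
})

test_that("characterization reproduces the definitional sensitivity, SNR and LOD examples", {
  mk_trace <- function(plateau, noise_sd, times, onset = 1, dur = 1) {
    zz <- numeric(length(times))
    base <- times < onset
    raw <- sin(1:sum(base))           # deterministic pseudo-noise
    zz[base] <- (raw - mean(raw)) / sd(raw) * noise_sd
    zz[times >= onset & times < onset + dur] <- plateau
    structure(list(time = times, z = zz, n_pixels = 5L,
                   no_responsive = FALSE), class = "zscore_trace")
  }
  times <- seq(0, 2.5, by = 1 / 200)
  prot1 <- stimulus_protocol(
    v_bias = -0.3,
    pulses = data.frame(amplitude = -0.1, onset = 1, duration = 1),
    total_duration = 2.5, sampling_rate = 200)
  # sensitivity 0.2 Z/mV and noise 0.5 -> LOD = 2.5 mV
  traces <- list("-50" = mk_trace(0.2 * 50, 0.5, times),
                 "-75" = mk_trace(0.2 * 75, 0.5, times),
                 "-100" = mk_trace(0.2 * 100, 0.5, times))
  s <- characterize(traces, prot1, noise_window = c(0, 1))
  expect_equal(s$sensitivity, 0.2, tolerance = 1e-9)
  expect_equal(s$noise, 0.5, tolerance = 1e-9)
  expect_equal(s$lod, 2.5, tolerance = 1e-9)
  expect_equal(s$lod, s$noise / s$sensitivity)  # definitional identity
  # plateau of 48 x noise at -100 mV -> SNR = 48
  traces48 <- list("-50" = mk_trace(24 * 0.5 / 2, 0.5, times),
                   "-75" = mk_trace(36 * 0.5 / 1.5, 0.5, times),
                   "-100" = mk_trace(48 * 0.5, 0.5, times))
  s48 <- characterize(traces48, prot1, noise_window = c(0, 1))
  expect_equal(s48$snr, 48, tolerance = 1e-9)
  # exact linear response Z = 0.3 |V|: slope recovered to machine precision
  amps <- seq(10, 100, by = 10)
  traces_lin <- setNames(lapply(amps, function(a) {
    mk_trace(0.3 * a, 0.1, times)
  }), -amps)
  s_lin <- characterize(traces_lin, prot1, noise_window = c(0, 1))
  expect_equal(s_lin$sensitivity, 0.3, tolerance = 1e-12)
  # non-positive sensitivity flags the LOD undefined
  traces_bad <- list("-50" = mk_trace(-1, 0.5, times),
                     "-75" = mk_trace(-2, 0.5, times),
                     "-100" = mk_trace(-3, 0.5, times))
  expect_warning(s_bad <- characterize(traces_bad, prot1,
                                       noise_window = c(0, 1)),
                 "undefined")
  expect_false(s_bad$lod_defined)
  expect_true(is.na(s_bad$lod))
})

test_that("time-constant fitting recovers exponential rises", {
  fps <- 2000
  times <- seq(0, 0.5, by = 1 / fps)
  tau <- 0.0347
  z <- ifelse(times >= 0.1, 12 * (1 - exp(-(times - 0.1) / tau)), 0)
  tr <- list(time = times, z = z)
  fit <- fit_time_constant(tr, onset = 0.1)
  expect_equal(as.numeric(fit), 34.7, tolerance = 0.01)
  # instantaneous step: tau bounded by one frame period
  z_step <- ifelse(times > 0.1, 8, 0)
  fit_step <- fit_time_constant(list(time = times, z = z_step),
                                onset = 0.1)
  expect_lte(as.numeric(fit_step), 1000 / fps)
  expect_error(fit_time_constant(list(time = times[1:3], z = z[1:3]),
                                 onset = 0.4), ">= 5")
})

test_that("time-constant fitting stays within 10% median under 10% amplitude noise", {
  fps <- 2000
  times <- seq(0, 0.5, by = 1 / fps)
  tau <- 0.0347
  clean <- ifelse(times >= 0.1, 10 * (1 - exp(-(times - 0.1) / tau)), 0)
  errs <- vapply(1:50, function(seed) {
    set.seed(seed)
    z <- clean + rnorm(length(times), sd = 1)
    rel_err(as.numeric(fit_time_constant(list(time = times, z = z),
                                         onset = 0.1)), 34.7)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("box-chart summaries follow the Tukey convention", {
  b <- summarize_boxchart(1:8)
  expect_equal(b$median, 4.5)
  expect_equal(b$q1, 2.75)   # linear (type 7) interpolation
  expect_equal(b$q3, 6.25)
  expect_equal(b$whisker_lo, 1)
  expect_equal(b$whisker_hi, 8)
  expect_length(b$outliers, 0)
  same <- summarize_boxchart(rep(3, 6))
  expect_equal(same$q3 - same$q1, 0)
  expect_length(same$outliers, 0)
  ext <- summarize_boxchart(c(1:8, 100))
  expect_equal(ext$outliers, 100)
  expect_error(summarize_boxchart(c(1, 2, 3)), ">= 4")
})
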