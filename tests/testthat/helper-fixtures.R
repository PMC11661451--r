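# Shared fixture builders for the test suite. Everything is generated
# in code; no binary fixtures.

# Numerical principal-value Kramers-Kronig transform of a single
# Tauc-Lorentz term's eps2, used as an independent oracle for the
# closed-form eps1.
kk_eps1_tl <- function(E, A, E0, C, Eg, upper = 200) {
  eps2 <- function(x) {
    ifelse(x > Eg,
           A * E0 * C * (x - Eg)^2 / (((x^2 - E0^2)^2 + C^2 * x^2) * x),
           0)
  }
  f <- function(x) 2 / pi * x * eps2(x) / (x + E)
  if (E <= Eg) {
    return(stats::integrate(function(x) f(x) / (x - E), Eg, upper,
                            rel.tol = 1e-9)$value)
  }
  fe <- f(E)
  smooth <- function(x) (f(x) - fe) / (x - E)
  v <- stats::integrate(smooth, Eg, upper, rel.tol = 1e-8,
                        subdivisions = 500)$value
  v + fe * log((upper - E) / (E - Eg))
}

# Smooth test image with broadband structure (for registration tests).
smooth_test_image <- function(n = 48, seed = 11) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  y <- matrix(0, n, n)
  for (k in 1:6) {
    cy <- runif(1, n / 4, 3 * n / 4); cx <- runif(1, n / 4, 3 * n / 4)
    s <- runif(1, 2, 5); a <- runif(1, 500, 2000)
    y <- y + a * exp(-(outer((1:n - cy)^2, (1:n - cx)^2, "+")) / (2 * s^2))
  }
  y + 100
}

# Default twin pieces shared by pipeline tests.
test_transfer <- function() sigmoid_transfer(1, 2, -0.45, 0.1)
test_circuit <- function() circuit_params(1e4, 5e6, 6.925e-9)  # tau ~34.7 ms

# Multi-amplitude pulse protocol: 1 s baseline then pulses of the given
# amplitudes (V), each 1 s long with 0.5 s recovery.
test_protocol <- function(amplitudes = c(-0.025, -0.05, -0.075, -0.1),
                          sampling_rate = 200) {
  n <- length(amplitudes)
  stimulus_protocol(
    v_bias = -0.45,
    pulses = data.frame(amplitude = amplitudes,
                        onset = 1 + (seq_len(n) - 1) * 1.5,
                        duration = 1),
    total_duration = 1 + n * 1.5,
    sampling_rate = sampling_rate)
}

# Render a stack and run the full analysis; returns per-antenna
# recovered and predicted figures of merit.
run_recovery <- function(layout, seed, noise = noise_model(),
                         register = FALSE, roi_radius = 2) {
  prot <- test_protocol()
  r <- render_sequence(layout, test_transfer(), test_circuit(), prot,
                       noise, seed = seed)
  seqc <- r$sequence
  if (register) seqc <- register_translation(seqc)$sequence
  z <- pixel_zscores(seqc, baseline = seq_len(1 * prot$sampling_rate))
  rois <- layout_rois(r$truth, radius = roi_radius)
  rec <- lapply(rois, function(roi) {
    tr <- extract_antenna_trace(z, roi)
    if (tr$no_responsive) return(NULL)
    characterize(tr, prot, noise_window = c(0, 1))
  })
  pred <- predict_electro_optics(r$truth, roi_radius = roi_radius)
  list(recovered = rec, predicted = pred, truth = r$truth)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
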