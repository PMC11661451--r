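# The electro-optic digital twin: a sigmoid transfer sigma(V) fitted to
# static scattering-vs-bias points, composed with the analytic circuit
# response, predicts the optical trace for an arbitrary stimulus.

#' Sigmoid scattering transfer
#'
#' sigma(V) = sigma_min + (sigma_max - sigma_min) /
#' (1 + exp((V - v_mid) / v_slope_width)): decreasing in V, so more
#' negative bias gives a brighter antenna.
#'
#' @param sigma_min,sigma_max Asymptotic cross sections in nm^2
#'   (sigma_max > sigma_min > 0).
#' @param v_mid Transition midpoint in V.
#' @param v_slope_width Transition width in V (> 0).
#' @return An object of class `sigmoid_transfer`.
#' @export
sigmoid_transfer <- function(sigma_min, sigma_max, v_mid, v_slope_width) {
  if (!(sigma_max > sigma_min && sigma_min > 0)) {
    stop("need sigma_max > sigma_min > 0", call. = FALSE)
  }
  if (v_slope_width <= 0) stop("v_slope_width must be > 0", call. = FALSE)
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 v_mid = v_mid, v_slope_width = v_slope_width),
            class = "sigmoid_transfer")
}

#' Evaluate a sigmoid transfer
#' @param transfer A `sigmoid_transfer`.
#' @param v Voltage(s) in V.
#' @return Cross section(s) in nm^2.
#' @export
transfer_sigma <- function(transfer, v) {
  stopifnot(inherits(transfer, "sigmoid_transfer"))
  transfer$sigma_min + (transfer$sigma_max - transfer$sigma_min) /
    (1 + exp((v - transfer$v_mid) / transfer$v_slope_width))
}

#' Analytic slope of a sigmoid transfer
#' @inheritParams transfer_sigma
#' @return d sigma / dV in nm^2/V (negative).
#' @export
transfer_slope <- function(transfer, v) {
  s <- 1 / (1 + exp((v - transfer$v_mid) / transfer$v_slope_width))
  -(transfer$sigma_max - transfer$sigma_min) / transfer$v_slope_width *
    s * (1 - s)
}

#' Fit a sigmoid transfer to scattering-vs-bias samples
#'
#' Levenberg-Marquardt least squares. A fit whose span
#' sigma_max - sigma_min is below `degenerate_frac` of the mean sample
#' value is flagged degenerate (attribute `degenerate`), as is
#' non-convergence (attribute `converged`).
#'
#' @param bias Bias voltages in V (>= 5 values spanning the transition).
#' @param sigma Scattering cross sections in nm^2.
#' @param degenerate_frac Span threshold, relative (default 1e-3).
#' @return A `sigmoid_transfer` with attributes `residual_norm`,
#'   `converged`, `degenerate`.
#' @export
fit_sigmoid_transfer <- function(bias, sigma, degenerate_frac = 1e-3) {
  if (length(bias) < 5) stop("need >= 5 samples", call. = FALSE)
  stopifnot(length(bias) == length(sigma))
  span0 <- max(diff(range(sigma)), 1e-6 * mean(sigma), .Machine$double.eps)
  p0 <- c(lo = min(sigma), span = span0,
          mid = stats::median(bias), lw = max(diff(range(bias)) / 8, 1e-3))
  resid <- function(p) {
    p["lo"] + p["span"] / (1 + exp((bias - p["mid"]) / abs(p["lw"]))) - sigma
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("sigmoid fit did not converge", call. = FALSE)
  }
  p <- fit$par
  lo <- max(p["lo"], .Machine$double.eps)
  # keep a representable span so a degenerate fit is still constructable
  span <- max(p["span"], 1e-9 * max(lo, 1))
  degenerate <- span < degenerate_frac * max(mean(abs(sigma)),
                                             .Machine$double.eps)
  if (degenerate) {
    warning("degenerate sigmoid fit: samples carry no transition (",
            "sigma_max ~ sigma_min)", call. = FALSE)
  }
  out <- sigmoid_transfer(sigma_min = lo, sigma_max = lo + span,
                          v_mid = unname(p["mid"]),
                          v_slope_width = abs(unname(p["lw"])))
  attr(out, "residual_norm") <- sqrt(sum(fit$fvec^2))
  attr(out, "converged") <- converged
  attr(out, "degenerate") <- degenerate
  out
}

#' Dynamic optical response to a stimulus protocol
#'
#' The instantaneous transferred voltage across the polymer (analytic RC
#' response) is pushed through the static sigmoid transfer:
#' sigma(t) = transfer(v_transferred(t)).
#'
#' @param protocol A `stimulus_protocol`.
#' @param circuit A `circuit_params`.
#' @param transfer A `sigmoid_transfer`.
#' @return Data frame with columns `time_s`, `sigma_nm2` (class
#'   `optical_trace`), with the transferred voltage kept in column `v`.
#' @export
dynamic_optical_response <- function(protocol, circuit, transfer) {
  vt <- transferred_voltage(circuit, protocol)
  sig <- transfer_sigma(transfer, vt$v)
  structure(data.frame(time_s = vt$time_s, sigma_nm2 = sig, v = vt$v),
            class = c("optical_trace", "data.frame"),
            sampling_rate = protocol$sampling_rate)
}

#' Write an optical trace as delimited text
#' @param trace An `optical_trace`.
#' @param path File path.
#' @export
write_optical_trace <- function(trace, path) {
  utils::write.table(trace[, c("time_s", "sigma_nm2")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
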