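# Equivalent circuit of the antenna-electrolyte interface: a solution
# resistance R_s in series with the polymer's own resistance R_P and
# volumetric capacitance C_P. The transferred voltage (the part of an
# applied stimulus that actually appears across the electrochromic
# element) is read across C_P, giving first-order dynamics with
# tau = (R_s + R_P) C_P.

#' Series RC circuit parameters
#'
#' @param r_s Solution (series) resistance in Ohm.
#' @param r_p Polymer series resistance in Ohm.
#' @param c_p Polymer volumetric capacitance in F.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(r_s, r_p, c_p) {
  if (any(c(r_s, r_p, c_p) <= 0)) {
    stop("all circuit parameters must be > 0", call. = FALSE)
  }
  structure(list(r_s = r_s, r_p = r_p, c_p = c_p), class = "circuit_params")
}

# Measured single-antenna time constants (ms) at optimal bias for the
# three fabricated cap diameters (um); log-log interpolated for other
# sizes.
tau_table <- data.frame(cap_um = c(0.7, 1.4, 1.8),
                        tau_ms = c(6.0, 34.7, 233.9))

#' Default circuit for an antenna geometry
#'
#' The capacitance is the polymer volumetric capacitance (39 F/cm^3)
#' times the antenna volume; the series resistance then follows from the
#' measured time constant for that cap diameter (log-log interpolated
#' between 6.0, 34.7 and 233.9 ms at 0.7, 1.4 and 1.8 um). Defaults are
#' order-of-magnitude representative, not a fit to any single device.
#'
#' @param geometry An `antenna_geometry`.
#' @param r_s Solution resistance in Ohm (default 1e4).
#' @param volumetric_capacitance F/cm^3 (default 39).
#' @return A `circuit_params`.
#' @export
default_circuit <- function(geometry = antenna_geometry(), r_s = 1e4,
                            volumetric_capacitance = 39) {
  stopifnot(inherits(geometry, "antenna_geometry"))
  v_nm3 <- 2 / 3 * pi * (geometry$cap_diameter / 2)^3 +
    pi * (geometry$stem_diameter / 2)^2 * geometry$stem_height
  c_p <- volumetric_capacitance * v_nm3 * 1e-21
  cap_um <- geometry$cap_diameter / 1000
  tau_s <- exp(stats::approx(log(tau_table$cap_um), log(tau_table$tau_ms),
                             xout = log(cap_um), rule = 2)$y) / 1000
  r_p <- tau_s / c_p - r_s
  if (r_p <= 0) stop("r_s too large for the interpolated time constant",
                     call. = FALSE)
  circuit_params(r_s = r_s, r_p = r_p, c_p = c_p)
}

#' Circuit time constant
#'
#' tau = (R_s + R_P) C_P.
#'
#' @param params A `circuit_params`.
#' @return Time constant in seconds.
#' @export
time_constant <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  (params$r_s + params$r_p) * params$c_p
}

#' Impedance spectrum of the series RC circuit
#'
#' Z(omega) = R_s + R_P + 1 / (i omega C_P).
#'
#' @param params A `circuit_params`.
#' @param frequencies Frequencies in Hz (> 0; zero diverges).
#' @return Complex impedance vector in Ohm.
#' @export
impedance_spectrum <- function(params, frequencies) {
  stopifnot(inherits(params, "circuit_params"))
  if (any(frequencies <= 0)) {
    stop("frequencies must be > 0 (capacitive impedance diverges at DC)",
         call. = FALSE)
  }
  omega <- 2 * pi * frequencies
  params$r_s + params$r_p + 1 / complex(real = 0, imaginary = omega * params$c_p)
}

#' Stimulus protocol: bias plus rectangular voltage pulses
#'
#' @param v_bias Holding bias in V.
#' @param pulses Data frame with columns `amplitude` (V), `onset` (s),
#'   `duration` (s). May have zero rows.
#' @param total_duration Total record length in s.
#' @param sampling_rate Samples per second.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(v_bias = 0, pulses = NULL,
                              total_duration = 1, sampling_rate = 200) {
  if (is.null(pulses)) {
    pulses <- data.frame(amplitude = numeric(), onset = numeric(),
                         duration = numeric())
  }
  pulses <- as.data.frame(pulses)
  stopifnot(all(c("amplitude", "onset", "duration") %in% names(pulses)))
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (nrow(pulses) &&
      (any(pulses$onset < 0) ||
       any(pulses$onset + pulses$duration > total_duration))) {
    stop("pulses must lie within [0, total_duration]", call. = FALSE)
  }
  structure(list(v_bias = v_bias, pulses = pulses,
                 total_duration = total_duration,
                 sampling_rate = sampling_rate),
            class = "stimulus_protocol")
}

#' Time grid of a protocol
#' @param protocol A `stimulus_protocol`.
#' @return Uniform time grid in s.
#' @export
protocol_times <- function(protocol) {
  n <- round(protocol$total_duration * protocol$sampling_rate)
  (seq_len(n) - 1) / protocol$sampling_rate
}

#' Applied stimulation voltage trace
#'
#' @param protocol A `stimulus_protocol`.
#' @return Data frame with columns `time_s`, `v` (class `voltage_trace`).
#' @export
stimulus_voltage <- function(protocol) {
  t <- protocol_times(protocol)
  v <- rep(protocol$v_bias, length(t))
  p <- protocol$pulses
  for (i in seq_len(nrow(p))) {
    on <- t >= p$onset[i] & t < p$onset[i] + p$duration[i]
    v[on] <- v[on] + p$amplitude[i]
  }
  structure(data.frame(time_s = t, v = v),
            class = c("voltage_trace", "data.frame"),
            sampling_rate = protocol$sampling_rate)
}

#' Voltage transferred across the polymer capacitance
#'
#' Analytic piecewise-exponential response of the series RC circuit to
#' the protocol's rectangular pulses, superposed on the holding bias
#' (the circuit is linear, so pulses superpose). Each pulse of amplitude
#' A contributes A (1 - exp(-(t - onset)/tau)) while on, decaying with
#' the same tau after its offset.
#'
#' @param params A `circuit_params`.
#' @param protocol A `stimulus_protocol`.
#' @return Data frame with `time_s`, `v` (class `voltage_trace`).
#' @export
transferred_voltage <- function(params, protocol) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(protocol, "stimulus_protocol"))
  t <- protocol_times(protocol)
  tau <- time_constant(params)
  v <- rep(protocol$v_bias, length(t))
  p <- protocol$pulses
  for (i in seq_len(nrow(p))) {
    a <- p$amplitude[i]; on <- p$onset[i]; off <- p$onset[i] + p$duration[i]
    rising <- t >= on & t < off
    v[rising] <- v[rising] + a * (1 - exp(-(t[rising] - on) / tau))
    fallen <- t >= off
    v_off <- a * (1 - exp(-(off - on) / tau))
    v[fallen] <- v[fallen] + v_off * exp(-(t[fallen] - off) / tau)
  }
  structure(data.frame(time_s = t, v = v),
            class = c("voltage_trace", "data.frame"),
            sampling_rate = protocol$sampling_rate)
}

#' Fit the series RC model to an impedance spectrum
#'
#' Least-squares fit in log-magnitude plus phase space. In the series
#' topology only the total resistance R_s + R_P and C_P are identifiable
#' from Z(omega); the solution resistance is therefore supplied as a
#' known quantity (as in potentiostat practice) and the polymer
#' resistance reported as the fitted total minus `r_s`.
#'
#' @param frequencies Frequencies in Hz (>= 5 values spanning >= 2
#'   decades).
#' @param z Complex impedance values.
#' @param r_s Known solution resistance in Ohm (default 0: report the
#'   total as `r_p`).
#' @param misfit_tol Relative residual norm above which the fit is
#'   flagged as a model misfit (default 0.05).
#' @return A `circuit_params` with attributes `residual_norm`,
#'   `converged` and `misfit`.
#' @export
fit_eis <- function(frequencies, z, r_s = 0, misfit_tol = 0.05) {
  if (length(frequencies) < 5) {
    stop("need >= 5 frequencies", call. = FALSE)
  }
  if (diff(log10(range(frequencies))) < 2) {
    stop("frequencies must span >= 2 decades", call. = FALSE)
  }
  obs <- c(log10(Mod(z)), Arg(z))
  # starting values: high-frequency magnitude ~ total R, low-frequency
  # imaginary part ~ capacitance
  i_hi <- which.max(frequencies); i_lo <- which.min(frequencies)
  r0 <- max(Mod(z[i_hi]), .Machine$double.eps)
  c0 <- 1 / (2 * pi * frequencies[i_lo] * max(abs(Im(z[i_lo])), 1e-12))
  resid <- function(p) {
    zm <- exp(p[1]) + 1 / complex(real = 0,
                                  imaginary = 2 * pi * frequencies * exp(p[2]))
    c(log10(Mod(zm)), Arg(zm)) - obs
  }
  fit <- minpack.lm::nls.lm(par = c(log(r0), log(c0)), fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  converged <- fit$info %in% 1:4
  r_tot <- exp(fit$par[1]); c_fit <- exp(fit$par[2])
  rn <- sqrt(sum(fit$fvec^2) / sum(obs^2))
  if (!converged) {
    warning("EIS fit did not converge (info = ", fit$info, ")",
            call. = FALSE)
  }
  misfit <- rn > misfit_tol
  if (misfit) {
    warning(sprintf("EIS fit residual %.3g exceeds tolerance %.3g: %s",
                    rn, misfit_tol,
                    "spectrum is poorly described by a series RC"),
            call. = FALSE)
  }
  out <- circuit_params(r_s = max(r_s, .Machine$double.xmin),
                        r_p = max(r_tot - r_s, .Machine$double.xmin),
                        c_p = c_fit)
  attr(out, "residual_norm") <- rn
  attr(out, "converged") <- converged
  attr(out, "misfit") <- misfit
  out
}

#' Write / read an EIS spectrum as delimited text
#'
#' Tab-separated columns `frequency_hz`, `z_real_ohm`, `z_imag_ohm`.
#'
#' @param frequencies Frequencies in Hz.
#' @param z Complex impedances in Ohm.
#' @param path File path.
#' @return `write_eis` returns the path invisibly; `read_eis` a list
#'   with `frequencies` and `z`.
#' @export
write_eis <- function(frequencies, z, path) {
  utils::write.table(
    data.frame(frequency_hz = frequencies, z_real_ohm = Re(z),
               z_imag_ohm = Im(z)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eis
#' @export
read_eis <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  list(frequencies = d$frequency_hz,
       z = complex(real = d$z_real_ohm, imaginary = d$z_imag_ohm))
}
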