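# Luo-Rudy 1991 guinea-pig ventricular action potential model and its
# one-way coupling to the cell-antenna interface circuit: the membrane
# potential drives the junctional cleft through R_j, the cleft leaks to
# the bath through R_Seal, and the sensor's own RC branch reads the
# cleft potential.

# Fixed LR91 constants (original 1991 parameter set)
lr91_const <- local({
  R <- 8314; Temp <- 310; Fc <- 96484.6
  RTF <- R * Temp / Fc
  Nao <- 140; Nai <- 18; Ko <- 5.4; Ki <- 145
  PRNaK <- 0.01833
  list(
    RTF = RTF,
    ENa = RTF * log(Nao / Nai),
    EK = RTF * log((Ko + PRNaK * Nao) / (Ki + PRNaK * Nai)),
    EK1 = RTF * log(Ko / Ki),
    GK = 0.282 * sqrt(Ko / 5.4),
    GK1 = 0.6047 * sqrt(Ko / 5.4)
  )
})

# Hodgkin-Huxley rate constants; V in mV, rates in 1/ms. The V >= -40
# branch switch for h and j is part of the published formulation.
lr91_rates <- function(V) {
  am <- if (abs(V + 47.13) < 1e-9) 3.2 else
    0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
  bm <- 0.08 * exp(-V / 11)
  if (V >= -40) {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp((V + 10.66) / -11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    ah <- 0.135 * exp((80 + V) / -6.8)
    bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
    aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  ad <- 0.095 * exp(-0.01 * (V - 5)) / (1 + exp(-0.072 * (V - 5)))
  bd <- 0.07 * exp(-0.017 * (V + 44)) / (1 + exp(0.05 * (V + 44)))
  af <- 0.012 * exp(-0.008 * (V + 28)) / (1 + exp(0.15 * (V + 28)))
  bf <- 0.0065 * exp(-0.02 * (V + 30)) / (1 + exp(-0.2 * (V + 30)))
  ax <- 0.0005 * exp(0.083 * (V + 50)) / (1 + exp(0.057 * (V + 50)))
  bx <- 0.0013 * exp(-0.06 * (V + 20)) / (1 + exp(-0.04 * (V + 20)))
  c(am = am, bm = bm, ah = ah, bh = bh, aj = aj, bj = bj, ad = ad,
    bd = bd, af = af, bf = bf, ax = ax, bx = bx)
}

#' Luo-Rudy 1991 membrane state
#'
#' @param v_m Membrane potential in mV.
#' @param m,h,j,d,f,x Gating variables in \[0, 1\].
#' @param ca_i Intracellular calcium in mM (> 0).
#' @return Named numeric state vector (class `lr91_state`).
#' @export
lr91_state <- function(v_m = -84, m = NULL, h = NULL, j = NULL, d = NULL,
                       f = NULL, x = NULL, ca_i = 2e-4) {
  r <- lr91_rates(v_m)
  inf <- function(a, b) if (a + b == 0) 0 else a / (a + b)
  s <- c(v_m = v_m,
         m = if (is.null(m)) inf(r["am"], r["bm"]) else m,
         h = if (is.null(h)) inf(r["ah"], r["bh"]) else h,
         j = if (is.null(j)) inf(r["aj"], r["bj"]) else j,
         d = if (is.null(d)) inf(r["ad"], r["bd"]) else d,
         f = if (is.null(f)) inf(r["af"], r["bf"]) else f,
         x = if (is.null(x)) inf(r["ax"], r["bx"]) else x,
         ca_i = ca_i)
  names(s) <- c("v_m", "m", "h", "j", "d", "f", "x", "ca_i")
  gates <- s[c("m", "h", "j", "d", "f", "x")]
  if (any(gates < 0 | gates > 1)) stop("gates must be in [0, 1]",
                                       call. = FALSE)
  if (ca_i <= 0) stop("ca_i must be > 0", call. = FALSE)
  class(s) <- c("lr91_state", "numeric")
  s
}

#' Right-hand side of the Luo-Rudy 1991 model
#'
#' The six published currents (fast sodium, slow inward calcium,
#' time-dependent potassium, time-independent potassium, plateau
#' potassium, background) with the original rate constants; membrane
#' capacitance 1 uF/cm^2, time in ms.
#'
#' @param state Named state vector (see [lr91_state()]).
#' @param stimulus_current Applied depolarizing current in uA/cm^2.
#' @return Named vector of time derivatives (per ms).
#' @export
lr91_derivatives <- function(state, stimulus_current = 0) {
  V <- state[["v_m"]]; m <- state[["m"]]; h <- state[["h"]]
  j <- state[["j"]]; d <- state[["d"]]; f <- state[["f"]]
  x <- state[["x"]]; cai <- state[["ca_i"]]
  k <- lr91_const
  r <- lr91_rates(V)
  i_na <- 23 * m^3 * h * j * (V - k$ENa)
  e_si <- 7.7 - 13.0287 * log(cai)
  i_si <- 0.09 * d * f * (V - e_si)
  xi <- if (V > -100) {
    2.837 * (exp(0.04 * (V + 77)) - 1) / ((V + 77) * exp(0.04 * (V + 35)))
  } else 1
  i_k <- k$GK * x * xi * (V - k$EK)
  ak1 <- 1.02 / (1 + exp(0.2385 * (V - k$EK1 - 59.215)))
  bk1 <- (0.49124 * exp(0.08032 * (V - k$EK1 + 5.476)) +
            exp(0.06175 * (V - k$EK1 - 594.31))) /
    (1 + exp(-0.5143 * (V - k$EK1 + 4.753)))
  i_k1 <- k$GK1 * ak1 / (ak1 + bk1) * (V - k$EK1)
  kp <- 1 / (1 + exp((7.488 - V) / 5.98))
  i_kp <- 0.0183 * kp * (V - k$EK1)
  i_b <- 0.03921 * (V + 59.87)
  dv <- -(i_na + i_si + i_k + i_k1 + i_kp + i_b - stimulus_current)
  c(v_m = dv,
    m = r[["am"]] * (1 - m) - r[["bm"]] * m,
    h = r[["ah"]] * (1 - h) - r[["bh"]] * h,
    j = r[["aj"]] * (1 - j) - r[["bj"]] * j,
    d = r[["ad"]] * (1 - d) - r[["bd"]] * d,
    f = r[["af"]] * (1 - f) - r[["bf"]] * f,
    x = r[["ax"]] * (1 - x) - r[["bx"]] * x,
    ca_i = -1e-4 * i_si + 0.07 * (1e-4 - cai))
}

lr91_rhs_desolve <- function(t, y, parms) {
  stim <- if (t >= parms$stim_start &&
                t < parms$stim_start + parms$stim_duration) {
    parms$stim_amplitude
  } else 0
  list(lr91_derivatives(y, stim))
}

#' Resting steady state of the LR91 model
#'
#' Integrates the unstimulated model until the membrane potential is
#' stationary.
#'
#' @param settle_ms Settling time in ms (default 2000).
#' @param rtol,atol Solver tolerances.
#' @return Named state vector at rest.
#' @export
lr91_resting_state <- function(settle_ms = 2000, rtol = 1e-8, atol = 1e-8) {
  y0 <- unclass(lr91_state())
  sol <- deSolve::lsoda(y0, c(0, settle_ms), lr91_rhs_desolve,
                        parms = list(stim_start = Inf, stim_duration = 0,
                                     stim_amplitude = 0),
                        rtol = rtol, atol = atol)
  s <- sol[nrow(sol), -1]
  names(s) <- names(y0)
  s
}

#' Simulate a Luo-Rudy 1991 action potential
#'
#' Settles to rest, applies a rectangular stimulus current, and
#' integrates with a stiff-capable solver (lsoda), returning dense
#' output on a uniform grid.
#'
#' @param stim_amplitude Stimulus current in uA/cm^2 (default 40).
#' @param stim_start Stimulus onset in ms (default 10).
#' @param stim_duration Stimulus duration in ms (default 1).
#' @param duration Total simulated time in ms (>= 500 to cover the AP;
#'   default 600).
#' @param dt Output grid step in ms (default 0.05).
#' @param rtol,atol Solver tolerances (default 1e-8).
#' @param initial_state Optional starting state; default is the settled
#'   resting state.
#' @return Data frame (class `ap_trace`) with columns `time_ms`, `v_m`
#'   and the gate/calcium columns.
#' @export
simulate_ap <- function(stim_amplitude = 40, stim_start = 10,
                        stim_duration = 1, duration = 600, dt = 0.05,
                        rtol = 1e-8, atol = 1e-8, initial_state = NULL) {
  if (duration < 500) {
    warning("duration < 500 ms may truncate the action potential",
            call. = FALSE)
  }
  y0 <- if (is.null(initial_state)) {
    lr91_resting_state(rtol = rtol, atol = atol)
  } else unclass(initial_state)
  times <- seq(0, duration, by = dt)
  sol <- deSolve::lsoda(y0, times, lr91_rhs_desolve,
                        parms = list(stim_start = stim_start,
                                     stim_duration = stim_duration,
                                     stim_amplitude = stim_amplitude),
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    stop("LR91 integration failed: ",
         paste(attr(sol, "istate"), collapse = " "), call. = FALSE)
  }
  d <- as.data.frame(sol)
  names(d)[1] <- "time_ms"
  # gating variables are mathematically confined to [0,1]; remove
  # floating-point undershoot at the boundaries
  for (g in c("m", "h", "j", "d", "f", "x")) {
    d[[g]] <- pmin(pmax(d[[g]], 0), 1)
  }
  class(d) <- c("ap_trace", "data.frame")
  d
}

#' Cell-antenna interface circuit parameters
#'
#' @param r_seal Seal resistance cleft-to-bath in Ohm (default 2e8).
#' @param r_j Junctional resistance cell-to-cleft in Ohm (default 5e8).
#' @param sensor_circuit A `circuit_params` for the sensor branch
#'   (default: the 1.4-um-cap antenna circuit).
#' @return An object of class `interface_params`.
#' @export
interface_params <- function(r_seal = 2e8, r_j = 5e8,
                             sensor_circuit = default_circuit(
                               antenna_geometry(cap_diameter = 1400))) {
  if (r_seal <= 0 || r_j <= 0) {
    stop("resistances must be > 0", call. = FALSE)
  }
  stopifnot(inherits(sensor_circuit, "circuit_params"))
  structure(list(r_seal = r_seal, r_j = r_j,
                 sensor_circuit = sensor_circuit),
            class = "interface_params")
}

#' Voltage transferred from a cell to the sensor
#'
#' One-way coupling: the membrane potential v_m drives the junctional
#' cleft through r_j, the cleft is shunted to the bath by r_seal, and
#' the sensor branch (the polymer resistance and capacitance in series)
#' loads the cleft. The sensor voltage is read across the whole polymer
#' element, i.e. the cleft node potential less the negligible solution
#' drop.
#'
#' In `"dynamic"` mode the sensor capacitor state is integrated against
#' the interpolated v_m(t); in `"quasistatic"` mode the sensor branch is
#' treated as infinite-impedance and v_sensor is the pure resistive
#' divider v_m r_seal / (r_seal + r_j).
#'
#' @param ap An `ap_trace` from [simulate_ap()].
#' @param params An `interface_params`.
#' @param mode `"dynamic"` (default) or `"quasistatic"`.
#' @return The `ap_trace` with columns `v_sensor` (mV) and `v_cleft`
#'   added.
#' @export
interface_transfer <- function(ap, params = interface_params(),
                               mode = c("dynamic", "quasistatic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "interface_params"))
  vm <- ap$v_m; tt <- ap$time_ms
  divider <- params$r_seal / (params$r_seal + params$r_j)
  if (mode == "quasistatic") {
    ap$v_cleft <- vm * divider
    ap$v_sensor <- ap$v_cleft
    return(ap)
  }
  sc <- params$sensor_circuit
  r_b <- sc$r_p + sc$r_s       # series resistance of the sensor branch
  c_p <- sc$c_p
  g_tot <- 1 / params$r_j + 1 / params$r_seal + 1 / r_b
  vmf <- stats::approxfun(tt, vm, rule = 2)
  rhs <- function(t, y, p) {
    v_cleft <- (vmf(t) / params$r_j + y[1] / r_b) / g_tot
    # t in ms -> factor 1e-3
    list((v_cleft - y[1]) / (r_b * c_p) * 1e-3)
  }
  vc0 <- vm[1] * (1 / params$r_j) / (1 / params$r_j + 1 / params$r_seal)
  sol <- deSolve::lsoda(c(vc = vc0), tt, rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-9)
  vc <- sol[, "vc"]
  ap$v_cleft <- (vm / params$r_j + vc / r_b) / g_tot
  ap$v_sensor <- ap$v_cleft
  ap
}

#' Peak-to-peak amplitude of a trace channel
#'
#' @param trace Data frame (e.g. an `ap_trace`).
#' @param channel Column name (default `"v_m"`).
#' @return max - min of the channel.
#' @export
peak_amplitude <- function(trace, channel = "v_m") {
  if (!nrow(trace)) stop("empty trace", call. = FALSE)
  v <- trace[[channel]]
  max(v) - min(v)
}

#' Write an action-potential trace as delimited text
#' @param ap An `ap_trace`.
#' @param path File path.
#' @export
write_ap_trace <- function(ap, path) {
  keep <- intersect(c("time_ms", "v_m", "v_sensor"), names(ap))
  utils::write.table(ap[, keep], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
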