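# Voltage-dependent complex permittivity of PEDOT:PSS.
#
# The doped (conducting) state is described by a Drude free-carrier model,
# the dedoped (dielectric) state by a sum of Lorentz and Tauc-Lorentz
# oscillators, and intermediate doping levels by linear interpolation of
# the two endpoint permittivities. All oscillators are parameterized in
# photon energy (eV) and evaluated on wavelength grids (nm).

#' Photon energy of a vacuum wavelength
#'
#' @param wavelength_nm Wavelength in nm.
#' @return Photon energy in eV, using E = 1239.84193 / lambda.
#' @export
photon_energy <- function(wavelength_nm) {
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop("wavelengths must be finite and positive", call. = FALSE)
  }
  1239.84193 / wavelength_nm
}

#' Drude model parameters for the fully doped state
#'
#' @param eps_inf High-frequency relative permittivity (dimensionless,
#'   >= 1).
#' @param plasma_energy Plasma energy in eV (>= 0).
#' @param damping_energy Damping (collision broadening) energy in eV
#'   (> 0).
#' @return An object of class `drude_params`.
#' @export
drude_params <- function(eps_inf = 2.97, plasma_energy = 2.06,
                         damping_energy = 0.80) {
  stopifnot(is.numeric(eps_inf), is.numeric(plasma_energy),
            is.numeric(damping_energy))
  if (eps_inf < 1) stop("eps_inf must be >= 1", call. = FALSE)
  if (plasma_energy < 0) stop("plasma_energy must be >= 0", call. = FALSE)
  if (damping_energy <= 0) stop("damping_energy must be > 0", call. = FALSE)
  structure(list(eps_inf = eps_inf, plasma_energy = plasma_energy,
                 damping_energy = damping_energy),
            class = "drude_params")
}

#' Oscillator set for the fully dedoped state
#'
#' A high-frequency permittivity plus any number of Lorentz and
#' Tauc-Lorentz terms. Lorentz terms are given as a data frame with
#' columns `amplitude` (dimensionless), `center_energy` and
#' `width_energy` (eV); Tauc-Lorentz terms additionally carry a
#' `gap_energy` (eV) below which their imaginary part vanishes, and their
#' amplitude is in eV following the Jellison-Modine convention.
#'
#' @param eps_inf High-frequency relative permittivity.
#' @param lorentz Data frame of Lorentz terms (may have zero rows).
#' @param tauc_lorentz Data frame of Tauc-Lorentz terms (may have zero
#'   rows).
#' @return An object of class `oscillator_set`.
#' @export
oscillator_set <- function(eps_inf = 1,
                           lorentz = data.frame(amplitude = numeric(),
                                                center_energy = numeric(),
                                                width_energy = numeric()),
                           tauc_lorentz = data.frame(amplitude = numeric(),
                                                     center_energy = numeric(),
                                                     width_energy = numeric(),
                                                     gap_energy = numeric())) {
  lorentz <- as.data.frame(lorentz)
  tauc_lorentz <- as.data.frame(tauc_lorentz)
  need_l <- c("amplitude", "center_energy", "width_energy")
  need_t <- c(need_l, "gap_energy")
  if (!all(need_l %in% names(lorentz))) {
    stop("lorentz needs columns ", paste(need_l, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_t %in% names(tauc_lorentz))) {
    stop("tauc_lorentz needs columns ", paste(need_t, collapse = ", "),
         call. = FALSE)
  }
  if (any(lorentz$width_energy <= 0) || any(tauc_lorentz$width_energy <= 0)) {
    stop("all oscillator widths must be > 0 (width 0 is an exact pole)",
         call. = FALSE)
  }
  if (any(tauc_lorentz$gap_energy < 0)) {
    stop("gap_energy must be >= 0", call. = FALSE)
  }
  structure(list(eps_inf = eps_inf, lorentz = lorentz,
                 tauc_lorentz = tauc_lorentz),
            class = "oscillator_set")
}

#' Default doped-state Drude model
#'
#' Literature-guided default for electrochemically doped PEDOT:PSS in
#' physiological saline. These values are documented defaults for a
#' metallic free-carrier response in the visible range, not a fit to any
#' particular ellipsometry dataset, and can be replaced wholesale via
#' [drude_params()] or a model config file.
#'
#' @return A `drude_params` object.
#' @export
default_doped_model <- function() drude_params(2.97, 2.06, 0.80)

#' Default dedoped-state oscillator model
#'
#' Default for fully dedoped (neutral) PEDOT:PSS: a visible Lorentz band
#' near 2.1 eV (the neutral-polymer pi-pi* absorption that makes dedoped
#' films blue), a Tauc-Lorentz ultraviolet edge with a 1.7 eV gap, and a
#' high-frequency background. Documented default, editable.
#'
#' @return An `oscillator_set` object.
#' @export
default_dedoped_model <- function() {
  oscillator_set(
    eps_inf = 1.92,
    lorentz = data.frame(amplitude = 0.78, center_energy = 2.10,
                         width_energy = 1.00),
    tauc_lorentz = data.frame(amplitude = 5.0, center_energy = 3.0,
                              width_energy = 1.0, gap_energy = 1.7)
  )
}

check_wavelengths <- function(wavelengths) {
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0)) {
    stop("wavelengths must be finite and positive", call. = FALSE)
  }
  if (any(wavelengths < 300) || any(wavelengths > 1200)) {
    warning("wavelengths outside the 300-1200 nm validity range",
            call. = FALSE)
  }
  invisible(wavelengths)
}

#' Complex permittivity spectrum container
#'
#' @param wavelengths Strictly increasing wavelength grid in nm.
#' @param eps_real Real part per wavelength.
#' @param eps_imag Imaginary part per wavelength (must be >= 0: passive
#'   material).
#' @return An object of class `permittivity_spectrum`.
#' @export
permittivity_spectrum <- function(wavelengths, eps_real, eps_imag) {
  stopifnot(length(wavelengths) == length(eps_real),
            length(wavelengths) == length(eps_imag))
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(eps_imag < -1e-12)) {
    stop("eps_imag must be >= 0 everywhere (passive material)",
         call. = FALSE)
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 eps_real = as.numeric(eps_real),
                 eps_imag = as.numeric(pmax(eps_imag, 0))),
            class = "permittivity_spectrum")
}

#' @export
print.permittivity_spectrum <- function(x, ...) {
  cat(sprintf("<permittivity spectrum: %d wavelengths, %.0f-%.0f nm>\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
as.data.frame.permittivity_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, eps1 = x$eps_real,
             eps2 = x$eps_imag)
}

#' Complex values of a permittivity spectrum
#'
#' @param spectrum A `permittivity_spectrum`.
#' @return Complex vector eps1 + i eps2.
#' @export
eps_complex <- function(spectrum) {
  complex(real = spectrum$eps_real, imaginary = spectrum$eps_imag)
}

#' Drude permittivity on a wavelength grid
#'
#' eps(E) = eps_inf - E_p^2 / (E^2 + i E Gamma) with E the photon energy.
#'
#' @param params A `drude_params` object.
#' @param wavelengths Wavelength grid in nm (default 400-1000 nm in
#'   10-nm steps).
#' @return A `permittivity_spectrum`.
#' @export
drude_permittivity <- function(params, wavelengths = default_wavelengths()) {
  stopifnot(inherits(params, "drude_params"))
  check_wavelengths(wavelengths)
  E <- photon_energy(wavelengths)
  eps <- params$eps_inf -
    params$plasma_energy^2 /
    complex(real = E^2, imaginary = E * params$damping_energy)
  permittivity_spectrum(wavelengths, Re(eps), Im(eps))
}

#' Default 400-1000 nm evaluation grid (10-nm step)
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function() seq(400, 1000, by = 10)

lorentz_eps <- function(amplitude, center_energy, width_energy, E) {
  amplitude * center_energy^2 /
    complex(real = center_energy^2 - E^2, imaginary = -width_energy * E)
}

# Tauc-Lorentz single term: eps2 per Jellison & Modine (1996), eps1 from
# the published Kramers-Kronig closed form (with erratum).
tauc_lorentz_eps <- function(A, E0, C, Eg, E) {
  eps2 <- ifelse(E > Eg,
                 A * E0 * C * (E - Eg)^2 /
                   (((E^2 - E0^2)^2 + C^2 * E^2) * E),
                 0)
  a_ln <- (Eg^2 - E0^2) * E^2 + Eg^2 * C^2 - E0^2 * (E0^2 + 3 * Eg^2)
  a_atan <- (E^2 - E0^2) * (E0^2 + Eg^2) + Eg^2 * C^2
  alpha <- sqrt(pmax(4 * E0^2 - C^2, .Machine$double.eps))
  gamma2 <- E0^2 - C^2 / 2
  zeta4 <- (E^2 - gamma2)^2 + alpha^2 * C^2 / 4
  eps1 <-
    A * C * a_ln / (2 * pi * zeta4 * alpha * E0) *
      log((E0^2 + Eg^2 + alpha * Eg) / (E0^2 + Eg^2 - alpha * Eg)) -
    A * a_atan / (pi * zeta4 * E0) *
      (pi - atan((2 * Eg + alpha) / C) + atan((-2 * Eg + alpha) / C)) +
    2 * A * E0 / (pi * zeta4 * alpha) * Eg * (E^2 - gamma2) *
      (pi + 2 * atan(2 * (gamma2 - Eg^2) / (alpha * C))) -
    A * E0 * C * (E^2 + Eg^2) / (pi * zeta4 * E) *
      log(abs(E - Eg) / (E + Eg)) +
    2 * A * E0 * C / (pi * zeta4) * Eg *
      log(abs(E - Eg) * (E + Eg) / sqrt((E0^2 - Eg^2)^2 + Eg^2 * C^2))
  complex(real = eps1, imaginary = eps2)
}

#' Dedoped-state permittivity on a wavelength grid
#'
#' eps(E) = eps_inf + sum of Lorentz terms + sum of Tauc-Lorentz terms.
#' The Tauc-Lorentz real part is the standard Kramers-Kronig closed form
#' of its imaginary part, so the model is causal by construction.
#'
#' @param params An `oscillator_set`.
#' @param wavelengths Wavelength grid in nm.
#' @return A `permittivity_spectrum`.
#' @export
dedoped_permittivity <- function(params, wavelengths = default_wavelengths()) {
  stopifnot(inherits(params, "oscillator_set"))
  check_wavelengths(wavelengths)
  E <- photon_energy(wavelengths)
  eps <- complex(real = rep(params$eps_inf, length(E)),
                 imaginary = rep(0, length(E)))
  lt <- params$lorentz
  if (nrow(lt)) {
    for (i in seq_len(nrow(lt))) {
      eps <- eps + lorentz_eps(lt$amplitude[i], lt$center_energy[i],
                               lt$width_energy[i], E)
    }
  }
  tl <- params$tauc_lorentz
  if (nrow(tl)) {
    for (i in seq_len(nrow(tl))) {
      eps <- eps + tauc_lorentz_eps(tl$amplitude[i], tl$center_energy[i],
                                    tl$width_energy[i], tl$gap_energy[i], E)
    }
  }
  permittivity_spectrum(wavelengths, Re(eps), Im(eps))
}

#' Linear interpolation between doped and dedoped permittivities
#'
#' Endpoint permittivities vary linearly with the volumetric charge
#' carrier density, so an intermediate doping level c gives pointwise
#' eps = c * eps_doped + (1 - c) * eps_dedoped.
#'
#' @param doped,dedoped `permittivity_spectrum` objects on identical
#'   wavelength grids.
#' @param doping Doping fraction in \[0, 1\] (1 = fully doped).
#' @return A `permittivity_spectrum`.
#' @export
mix_permittivity <- function(doped, dedoped, doping) {
  stopifnot(inherits(doped, "permittivity_spectrum"),
            inherits(dedoped, "permittivity_spectrum"))
  if (length(doped$wavelengths) != length(dedoped$wavelengths) ||
      any(doped$wavelengths != dedoped$wavelengths)) {
    stop("doped and dedoped spectra must share the wavelength grid",
         call. = FALSE)
  }
  if (!is.numeric(doping) || length(doping) != 1 || is.na(doping) ||
      doping < 0 || doping > 1) {
    stop("doping must be a single value in [0, 1]", call. = FALSE)
  }
  permittivity_spectrum(
    doped$wavelengths,
    doping * doped$eps_real + (1 - doping) * dedoped$eps_real,
    doping * doped$eps_imag + (1 - doping) * dedoped$eps_imag
  )
}

#' Bias-voltage to doping-level calibration
#'
#' Logistic map c(V) = 1 / (1 + exp(-(V - v_half) / v_width)): more
#' positive bias means more doped. Defaults place the transition so that
#' the modeled scattering-vs-bias curve is sigmoidal with its sensitivity
#' peak near -0.5 V vs Ag/AgCl.
#'
#' @param v_half Bias of half doping, V vs Ag/AgCl.
#' @param v_width Transition width in V (> 0).
#' @return An object of class `doping_calibration`.
#' @export
doping_calibration <- function(v_half = -0.52, v_width = 0.07) {
  if (!is.numeric(v_width) || v_width <= 0) {
    stop("v_width must be > 0", call. = FALSE)
  }
  structure(list(v_half = v_half, v_width = v_width),
            class = "doping_calibration")
}

#' Doping level at a bias voltage
#'
#' @param v_bias Bias voltage(s), V vs Ag/AgCl.
#' @param cal A `doping_calibration`.
#' @return Doping fraction(s) in (0, 1), monotone increasing in bias.
#' @export
voltage_to_doping <- function(v_bias, cal = doping_calibration()) {
  stopifnot(inherits(cal, "doping_calibration"))
  1 / (1 + exp(-(v_bias - cal$v_half) / cal$v_width))
}

#' Complex refractive index from permittivity
#'
#' Solves (n + ik)^2 = eps on the passive branch k >= 0.
#'
#' @param eps Complex permittivity value(s).
#' @return Data frame with columns `n` and `k`.
#' @export
index_from_permittivity <- function(eps) {
  s <- sqrt(as.complex(eps))
  flip <- Im(s) < 0
  s[flip] <- -s[flip]
  data.frame(n = Re(s), k = Im(s))
}

#' Write a permittivity spectrum as delimited text
#'
#' Tab-separated columns `wavelength_nm`, `eps1`, `eps2`.
#'
#' @param spectrum A `permittivity_spectrum`.
#' @param path Output file path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(as.data.frame(spectrum), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a permittivity spectrum written by [write_spectrum()]
#'
#' @param path Input file path.
#' @return A `permittivity_spectrum`.
#' @export
read_spectrum <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  permittivity_spectrum(d$wavelength_nm, d$eps1, d$eps2)
}

#' Read a full electro-optic model configuration
#'
#' Reads a nested key-value (YAML) config describing the doped Drude
#' model, the dedoped oscillator set, the doping calibration, and the
#' antenna geometry. See `system.file("extdata", "default_model.yaml",
#' package = "escat")` for the shipped default.
#'
#' @param path Path to a YAML config file.
#' @return Named list with elements `doped`, `dedoped`, `calibration`,
#'   `geometry`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  doped <- do.call(drude_params, cfg$doped)
  ded <- oscillator_set(
    eps_inf = cfg$dedoped$eps_inf,
    lorentz = do.call(rbind.data.frame, cfg$dedoped$lorentz),
    tauc_lorentz = do.call(rbind.data.frame, cfg$dedoped$tauc_lorentz)
  )
  cal <- do.call(doping_calibration, cfg$calibration)
  geom <- do.call(antenna_geometry, cfg$geometry)
  list(doped = doped, dedoped = ded, calibration = cal, geometry = geom)
}
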