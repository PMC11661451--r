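# Voltage-dependent light scattering of a single antenna, modeled as a
# homogeneous sphere in water whose volume equals the mushroom-shaped
# antenna (hemispherical cap on a cylindrical stem). The sphere is solved
# with the Mie series; absolute cross sections therefore differ from a
# full-wave simulation of the antenna-on-substrate geometry, but the
# voltage -> permittivity -> scattering mechanism and its monotone trends
# are preserved.

#' Mushroom antenna geometry
#'
#' @param cap_diameter Cap diameter in nm (>= stem_diameter).
#' @param stem_diameter Stem diameter in nm (the nitride opening,
#'   default 250).
#' @param stem_height Stem height in nm (the nitride thickness,
#'   default 50).
#' @return An object of class `antenna_geometry`.
#' @export
antenna_geometry <- function(cap_diameter = 1000, stem_diameter = 250,
                             stem_height = 50) {
  if (stem_diameter <= 0 || stem_height <= 0) {
    stop("stem dimensions must be > 0", call. = FALSE)
  }
  if (cap_diameter < stem_diameter) {
    stop("cap_diameter must be >= stem_diameter", call. = FALSE)
  }
  structure(list(cap_diameter = cap_diameter, stem_diameter = stem_diameter,
                 stem_height = stem_height),
            class = "antenna_geometry")
}

#' Optical properties of the surrounding medium
#'
#' @param eps_medium Relative permittivity (default 1.77, water in the
#'   visible).
#' @return An object of class `medium_optics` with the refractive index
#'   precomputed.
#' @export
medium_optics <- function(eps_medium = 1.77) {
  if (eps_medium <= 0) stop("eps_medium must be > 0", call. = FALSE)
  structure(list(eps_medium = eps_medium, n_medium = sqrt(eps_medium)),
            class = "medium_optics")
}

#' Volume-equivalent sphere radius of an antenna
#'
#' The cap is modeled as a hemisphere of `cap_diameter` sitting on a
#' cylindrical stem; the returned radius is that of the sphere with the
#' same total volume.
#'
#' @param geometry An `antenna_geometry`.
#' @return Radius in nm.
#' @export
equivalent_sphere_radius <- function(geometry) {
  stopifnot(inherits(geometry, "antenna_geometry"))
  v_cap <- 2 / 3 * pi * (geometry$cap_diameter / 2)^3
  v_stem <- pi * (geometry$stem_diameter / 2)^2 * geometry$stem_height
  (3 * (v_cap + v_stem) / (4 * pi))^(1 / 3)
}

#' Mie scattering cross section of a homogeneous sphere
#'
#' Standard Mie series (Bohren-Huffman recurrences) with size parameter
#' x = 2 pi n_medium r / lambda and relative index m = particle / medium,
#' truncated at the Wiscombe order n_max = x + 4 x^(1/3) + 2 unless
#' overridden.
#'
#' @param radius Sphere radius in nm (> 0).
#' @param particle_index Complex refractive index of the particle.
#' @param medium_index Real refractive index of the medium (> 0).
#' @param wavelength Vacuum wavelength(s) in nm (> 0).
#' @param n_max Optional series truncation override (single integer).
#' @return Scattering cross section(s) in nm^2.
#' @export
mie_cross_section <- function(radius, particle_index, medium_index,
                              wavelength, n_max = NULL) {
  if (any(is.na(c(radius, particle_index, medium_index))) ||
      any(is.na(wavelength))) {
    stop("NaN/NA inputs to mie_cross_section", call. = FALSE)
  }
  if (radius <= 0 || medium_index <= 0 || any(wavelength <= 0)) {
    stop("radius, medium_index and wavelength must be > 0", call. = FALSE)
  }
  vapply(wavelength, function(lam) {
    x <- 2 * pi * medium_index * radius / lam
    m <- as.complex(particle_index) / medium_index
    qsca <- mie_qsca(m, x, n_max)
    qsca * pi * radius^2
  }, numeric(1))
}

# Scattering efficiency Q_sca for relative index m and size parameter x.
# Logarithmic derivative by downward recurrence; Riccati-Bessel functions
# of the outside argument by upward recurrence.
mie_qsca <- function(m, x, n_max = NULL) {
  nstop <- if (is.null(n_max)) ceiling(x + 4 * x^(1 / 3) + 2) else n_max
  nmx <- max(nstop, ceiling(Mod(m * x))) + 16
  D <- complex(length.out = nmx + 1)
  mx <- m * x
  for (n in nmx:1) {
    D[n] <- n / mx - 1 / (D[n + 1] + n / mx)
  }
  psi0 <- cos(x); psi1 <- sin(x)
  chi0 <- -sin(x); chi1 <- cos(x)
  xi1 <- complex(real = psi1, imaginary = -chi1)
  qsca <- 0
  for (n in seq_len(nstop)) {
    psi <- (2 * n - 1) / x * psi1 - psi0
    chi <- (2 * n - 1) / x * chi1 - chi0
    xi <- complex(real = psi, imaginary = -chi)
    dn <- D[n + 1]
    an <- ((dn / m + n / x) * psi - psi1) / ((dn / m + n / x) * xi - xi1)
    bn <- ((dn * m + n / x) * psi - psi1) / ((dn * m + n / x) * xi - xi1)
    qsca <- qsca + (2 * n + 1) * (Mod(an)^2 + Mod(bn)^2)
    psi0 <- psi1; psi1 <- psi
    chi0 <- chi1; chi1 <- chi
    xi1 <- xi
  }
  2 / x^2 * qsca
}

#' Rayleigh small-particle scattering cross section
#'
#' Closed form sigma = (8/3) pi k^4 a^6 |(m^2-1)/(m^2+2)|^2 with
#' k = 2 pi n_medium / lambda, valid for size parameters << 1. Used as an
#' independent check of the Mie series.
#'
#' @inheritParams mie_cross_section
#' @return Cross section(s) in nm^2.
#' @export
rayleigh_cross_section <- function(radius, particle_index, medium_index,
                                   wavelength) {
  k <- 2 * pi * medium_index / wavelength
  m <- as.complex(particle_index) / medium_index
  8 / 3 * pi * k^4 * radius^6 * Mod((m^2 - 1) / (m^2 + 2))^2
}

#' Electro-optic model bundle
#'
#' Convenience container tying together the two endpoint permittivity
#' models and the bias-to-doping calibration.
#'
#' @param doped A `drude_params` (default [default_doped_model()]).
#' @param dedoped An `oscillator_set` (default [default_dedoped_model()]).
#' @param calibration A `doping_calibration`.
#' @return An object of class `permittivity_model`.
#' @export
permittivity_model <- function(doped = default_doped_model(),
                               dedoped = default_dedoped_model(),
                               calibration = doping_calibration()) {
  stopifnot(inherits(doped, "drude_params"),
            inherits(dedoped, "oscillator_set"),
            inherits(calibration, "doping_calibration"))
  structure(list(doped = doped, dedoped = dedoped,
                 calibration = calibration),
            class = "permittivity_model")
}

# Mixed permittivity spectrum at a doping level, from a model bundle.
model_eps_at_doping <- function(model, doping, wavelengths) {
  mix_permittivity(drude_permittivity(model$doped, wavelengths),
                   dedoped_permittivity(model$dedoped, wavelengths),
                   doping)
}

#' Scattering spectra versus bias voltage
#'
#' For each bias: doping level from the calibration, mixed permittivity,
#' refractive index, and the Mie cross section of the volume-equivalent
#' sphere.
#'
#' @param geometry An `antenna_geometry`.
#' @param biases Bias voltages, V vs Ag/AgCl. Values outside
#'   \[-0.8, 0.2\] V trigger a warning.
#' @param model A `permittivity_model`.
#' @param wavelengths Wavelength grid in nm.
#' @param medium A `medium_optics`.
#' @return Named list (one element per bias, names are the bias values)
#'   of data frames with columns `wavelength_nm`, `sigma_sc_nm2`.
#' @export
scattering_spectrum_vs_bias <- function(geometry, biases,
                                        model = permittivity_model(),
                                        wavelengths = default_wavelengths(),
                                        medium = medium_optics()) {
  stopifnot(inherits(geometry, "antenna_geometry"),
            inherits(model, "permittivity_model"))
  if (any(biases < -0.8 | biases > 0.2)) {
    warning("biases outside the characterized [-0.8, 0.2] V window",
            call. = FALSE)
  }
  r <- equivalent_sphere_radius(geometry)
  doped <- drude_permittivity(model$doped, wavelengths)
  dedoped <- dedoped_permittivity(model$dedoped, wavelengths)
  out <- lapply(biases, function(v) {
    c_dop <- voltage_to_doping(v, model$calibration)
    eps <- eps_complex(mix_permittivity(doped, dedoped, c_dop))
    nk <- index_from_permittivity(eps)
    sigma <- vapply(seq_along(wavelengths), function(i) {
      mie_cross_section(r, complex(real = nk$n[i], imaginary = nk$k[i]),
                        medium$n_medium, wavelengths[i])
    }, numeric(1))
    data.frame(wavelength_nm = wavelengths, sigma_sc_nm2 = sigma)
  })
  names(out) <- as.character(biases)
  out
}

# Cross section at one wavelength and one bias (scalar helper).
sigma_at_bias <- function(geometry, v_bias, model, wavelength,
                          medium = medium_optics()) {
  r <- equivalent_sphere_radius(geometry)
  c_dop <- voltage_to_doping(v_bias, model$calibration)
  eps <- eps_complex(model_eps_at_doping(model, c_dop, wavelength))
  nk <- index_from_permittivity(eps)
  mie_cross_section(r, complex(real = nk$n, imaginary = nk$k),
                    medium$n_medium, wavelength)
}

#' Scattering sensitivity d(sigma_sc)/dV versus bias
#'
#' Central finite differences of the cross section at a fixed wavelength
#' over the supplied bias grid (one-sided at the ends).
#'
#' @inheritParams scattering_spectrum_vs_bias
#' @param wavelength Evaluation wavelength in nm (default 640, the
#'   characterization laser line).
#' @return Data frame with columns `bias_v`, `sigma_sc_nm2`,
#'   `sensitivity_nm2_per_v`.
#' @export
sensitivity_vs_bias <- function(geometry, biases,
                                model = permittivity_model(),
                                wavelength = 640,
                                medium = medium_optics()) {
  if (length(biases) < 3) {
    stop("need at least 3 biases for finite differencing", call. = FALSE)
  }
  biases <- sort(biases)
  sigma <- vapply(biases, function(v) {
    sigma_at_bias(geometry, v, model, wavelength, medium)
  }, numeric(1))
  n <- length(biases)
  dv <- numeric(n)
  dv[1] <- (sigma[2] - sigma[1]) / (biases[2] - biases[1])
  dv[n] <- (sigma[n] - sigma[n - 1]) / (biases[n] - biases[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    dv[i] <- (sigma[i + 1] - sigma[i - 1]) / (biases[i + 1] - biases[i - 1])
  }
  data.frame(bias_v = biases, sigma_sc_nm2 = sigma,
             sensitivity_nm2_per_v = dv)
}

#' Write a scattering spectrum as delimited text
#'
#' @param spectrum Data frame with `wavelength_nm`, `sigma_sc_nm2`.
#' @param path Output file path.
#' @export
write_scattering_spectrum <- function(spectrum, path) {
  utils::write.table(spectrum, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
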