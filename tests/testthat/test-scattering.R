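test_that("index-matched particles do not scatter and small spheres follow Rayleigh", {
  expect_equal(mie_cross_section(100, 1.33 + 0i, 1.33, 640), 0,
               tolerance = 1e-20)
  # Rayleigh closed form at small size parameters
  for (x in c(0.01, 0.05, 0.1)) {
    lam <- 640; nm <- 1.33
    r <- x * lam / (2 * pi * nm)
    mie <- mie_cross_section(r, 1.5 * nm + 0i, nm, lam)
    ray <- rayleigh_cross_section(r, 1.5 * nm + 0i, nm, lam)
    expect_equal(mie, ray, tolerance = 0.01)
  }
  expect_error(mie_cross_section(NaN, 1.5, 1.33, 640), "NaN")
  expect_error(mie_cross_section(-5, 1.5, 1.33, 640), "> 0")
})

test_that("the Mie series is converged at the Wiscombe truncation order", {
  for (r in c(300, 600)) {
    x <- 2 * pi * 1.33 * r / 640
    n_wis <- ceiling(x + 4 * x^(1 / 3) + 2)
    s1 <- mie_cross_section(r, 1.7 + 0.4i, 1.33, 640)
    s2 <- mie_cross_section(r, 1.7 + 0.4i, 1.33, 640, n_max = n_wis + 25)
    expect_lt(abs(s1 - s2) / s1, 1e-6)
  }
})

test_that("volume-equivalent radius follows hand arithmetic and linear scaling", {
  # hemispherical cap of 1000 nm, negligible stem:
  # r = (r_cap^3 / 2)^(1/3) = 396.85 nm
  g <- antenna_geometry(cap_diameter = 1000, stem_diameter = 250,
                        stem_height = 1e-9)
  expect_equal(equivalent_sphere_radius(g), 500 / 2^(1 / 3),
               tolerance = 1e-6)
  # stem-only degenerate case: hemisphere of the stem plus the cylinder
  g2 <- antenna_geometry(cap_diameter = 250, stem_diameter = 250,
                         stem_height = 50)
  v <- 2 / 3 * pi * 125^3 + pi * 125^2 * 50
  expect_equal(equivalent_sphere_radius(g2), (3 * v / (4 * pi))^(1 / 3))
  # doubling all linear dimensions doubles the equivalent radius
  g3 <- antenna_geometry(2000, 500, 100)
  expect_equal(equivalent_sphere_radius(g3),
               2 * equivalent_sphere_radius(antenna_geometry(1000, 250, 50)))
  expect_error(antenna_geometry(cap_diameter = 100), "stem")
})

test_that("scattering at 640 nm brightens monotonically toward negative bias for both cap sizes", {
  biases <- seq(0.2, -0.8, by = -0.05)
  for (cap in c(750, 1500)) {
    sv <- sensitivity_vs_bias(antenna_geometry(cap), biases)
    ord <- order(sv$bias_v)  # increasing V
    expect_true(all(diff(sv$sigma_sc_nm2[ord]) < 0))
  }
})

test_that("identical biases give identical spectra and larger caps scatter more everywhere", {
  g <- antenna_geometry(750)
  sp <- scattering_spectrum_vs_bias(g, c(-0.3, -0.3))
  expect_identical(sp[[1]], sp[[2]])
  small <- scattering_spectrum_vs_bias(antenna_geometry(750),
                                       c(0.2, -0.3, -0.8))
  large <- scattering_spectrum_vs_bias(antenna_geometry(1500),
                                       c(0.2, -0.3, -0.8))
  for (i in seq_along(small)) {
    expect_true(all(large[[i]]$sigma_sc_nm2 > small[[i]]$sigma_sc_nm2))
    expect_true(all(small[[i]]$sigma_sc_nm2 >= 0))
  }
  expect_warning(scattering_spectrum_vs_bias(g, -1.5, wavelengths = 640),
                 "window")
})

test_that("enlarging the cap never decreases the cross section on the default grid", {
  caps <- c(600, 900, 1200, 1500, 1800)
  model <- permittivity_model()
  for (v in c(0, -0.52)) {
    spectra <- lapply(caps, function(cap) {
      scattering_spectrum_vs_bias(antenna_geometry(cap), v,
                                  model = model)[[1]]$sigma_sc_nm2
    })
    for (i in seq_len(length(caps) - 1)) {
      expect_true(all(spectra[[i + 1]] >= spectra[[i]]))
    }
  }
})

test_that("voltage sensitivity peaks near -0.5 V and vanishes for a clamped transfer", {
  biases <- seq(0.2, -0.8, by = -0.02)
  for (cap in c(750, 1000, 1500)) {
    sv <- sensitivity_vs_bias(antenna_geometry(cap), biases)
    v_peak <- sv$bias_v[which.max(abs(sv$sensitivity_nm2_per_v))]
    expect_gte(v_peak, -0.6)
    expect_lte(v_peak, -0.4)
  }
  # doping clamped constant (zero-width transition far away): flat sigma
  clamped <- permittivity_model(
    calibration = doping_calibration(v_half = 50, v_width = 1e-3))
  sv0 <- sensitivity_vs_bias(antenna_geometry(1000), biases,
                             model = clamped)
  expect_true(all(abs(sv0$sensitivity_nm2_per_v) < 1e-9))
  expect_error(sensitivity_vs_bias(antenna_geometry(1000), c(0, -0.1)),
               "3 biases")
})

test_that("finite-difference sensitivity matches the chain-rule derivative at 10 mV steps", {
  g <- antenna_geometry(1000)
  model <- permittivity_model()
  cal <- model$calibration
  for (v0 in c(-0.40, -0.52, -0.60)) {
    fd <- sensitivity_vs_bias(g, c(v0 - 0.01, v0, v0 + 0.01),
                              model = model)
    fd_val <- fd$sensitivity_nm2_per_v[fd$bias_v == v0]
    # chain rule: dsigma/dV = dsigma/dc * c'(V), logistic slope analytic
    cc <- voltage_to_doping(v0, cal)
    dc <- 1e-5
    r_eq <- equivalent_sphere_radius(g)
    sig_of_c <- function(cl) {
      eps <- eps_complex(mix_permittivity(
        drude_permittivity(model$doped, 640),
        dedoped_permittivity(model$dedoped, 640), cl))
      nk <- index_from_permittivity(eps)
      mie_cross_section(r_eq, complex(real = nk$n, imaginary = nk$k),
                        sqrt(1.77), 640)
    }
    dsig_dc <- (sig_of_c(cc + dc) - sig_of_c(cc - dc)) / (2 * dc)
    dcdv <- cc * (1 - cc) / cal$v_width
    expect_equal(fd_val, dsig_dc * dcdv, tolerance = 0.01)
  }
})

test_that("spectra computed per bias equal spectra from pre-tabulated doping levels", {
  g <- antenna_geometry(1000)
  model <- permittivity_model()
  wl <- seq(500, 800, by = 50)
  biases <- c(-0.2, -0.5, -0.7)
  via_bias <- scattering_spectrum_vs_bias(g, biases, model = model,
                                          wavelengths = wl)
  r_eq <- equivalent_sphere_radius(g)
  doped <- drude_permittivity(model$doped, wl)
  ded <- dedoped_permittivity(model$dedoped, wl)
  for (i in seq_along(biases)) {
    cc <- voltage_to_doping(biases[i], model$calibration)
    eps <- eps_complex(mix_permittivity(doped, ded, cc))
    nk <- index_from_permittivity(eps)
    direct <- vapply(seq_along(wl), function(k) {
      mie_cross_section(r_eq, complex(real = nk$n[k], imaginary = nk$k[k]),
                        sqrt(1.77), wl[k])
    }, numeric(1))
    expect_equal(via_bias[[i]]$sigma_sc_nm2, direct, tolerance = 1e-12)
  }
})
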