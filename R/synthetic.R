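# Ground-truthed synthetic data: camera stacks of a modulating antenna
# array rendered through the electro-optic twin, and noisy
# single-time-constant impedance spectra. Every quantity the analysis
# pipeline estimates has a programmed true value serialized alongside
# the generated stack.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Antenna array layout for rendering
#'
#' @param n_rows,n_cols Array dimensions (default 16 x 16).
#' @param pitch Antenna pitch in um (default 5).
#' @param pixel_size Pixel size in um/px (default 1; the pitch must be
#'   >= 4 px).
#' @param spot_sigma Gaussian point-spread width in px (default 0.8).
#' @param peak_counts Peak spot amplitude in camera counts
#'   (default 40000).
#' @return An object of class `array_layout`.
#' @export
array_layout <- function(n_rows = 16, n_cols = 16, pitch = 5,
                         pixel_size = 1, spot_sigma = 0.8,
                         peak_counts = 40000) {
  if (pitch / pixel_size < 4) {
    stop("pitch must be at least 4 px (pitch/pixel_size >= 4)",
         call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
                 pixel_size = pixel_size, spot_sigma = spot_sigma,
                 peak_counts = peak_counts),
            class = "array_layout")
}

#' Camera noise model
#'
#' @param read_noise_sd Gaussian read noise SD in counts (default 6).
#' @param shot_noise Apply Poisson shot noise on expected counts
#'   (default TRUE).
#' @param background_level Constant background in counts (default 400).
#' @param speckle_drift_sd Per-frame innovation SD of the slowly
#'   drifting per-pixel speckle background, counts (default 0; AR(1)
#'   with coefficient `speckle_rho`).
#' @param speckle_rho AR(1) coefficient of the speckle background
#'   (default 0.999, i.e. a long correlation time).
#' @param jitter_sd Per-frame rigid jitter SD in px (default 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(read_noise_sd = 6, shot_noise = TRUE,
                        background_level = 400, speckle_drift_sd = 0,
                        speckle_rho = 0.999, jitter_sd = 0) {
  vals <- c(read_noise_sd, background_level, speckle_drift_sd, jitter_sd)
  if (any(vals < 0)) stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 background_level = background_level,
                 speckle_drift_sd = speckle_drift_sd,
                 speckle_rho = speckle_rho, jitter_sd = jitter_sd),
            class = "noise_model")
}

# Antenna grid centers (px, 1-based) and frame size for a layout.
layout_geometry <- function(layout) {
  pitch_px <- layout$pitch / layout$pixel_size
  margin <- ceiling(4 * layout$spot_sigma) + 3
  rows_px <- margin + (seq_len(layout$n_rows) - 1) * pitch_px
  cols_px <- margin + (seq_len(layout$n_cols) - 1) * pitch_px
  list(rows_px = rows_px, cols_px = cols_px,
       nr = ceiling(max(rows_px) + margin),
       nc = ceiling(max(cols_px) + margin))
}

# Separable Gaussian basis: matrix [pixel, center] of exp(-d^2/2s^2).
gauss_basis <- function(n_px, centers, sigma) {
  outer(seq_len(n_px), centers, function(p, c0) {
    exp(-(p - c0)^2 / (2 * sigma^2))
  })
}

#' Render a synthetic camera stack of a modulating antenna array
#'
#' The expected image is a constant background plus one Gaussian spot
#' per antenna whose amplitude follows the electro-optic twin's
#' sigma(t) / sigma(bias) under the programmed protocol. Noise is
#' applied in order: speckle drift, shot (Poisson), read (Gaussian),
#' then quantization to the bit depth. Fully reproducible for a fixed
#' seed.
#'
#' @param layout An `array_layout`.
#' @param transfer A `sigmoid_transfer` (the twin's static transfer).
#' @param circuit A `circuit_params` (the twin's dynamics).
#' @param protocol A `stimulus_protocol`.
#' @param noise A `noise_model`.
#' @param seed Mandatory integer seed.
#' @param antenna_rel_sd Relative SD of per-antenna amplitude variation
#'   (default 0.05).
#' @param bit_depth Camera bit depth (default 16); counts exceeding it
#'   raise an explicit clipping error.
#' @return List with `sequence` (an `image_sequence`) and `truth` (a
#'   `ground_truth` list; see [predict_electro_optics()]).
#' @export
render_sequence <- function(layout, transfer, circuit, protocol,
                            noise = noise_model(), seed,
                            antenna_rel_sd = 0.05, bit_depth = 16) {
  stopifnot(inherits(layout, "array_layout"),
            inherits(transfer, "sigmoid_transfer"),
            inherits(circuit, "circuit_params"),
            inherits(protocol, "stimulus_protocol"),
            inherits(noise, "noise_model"))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  pitch_px <- layout$pitch / layout$pixel_size
  if (pitch_px < 6 * layout$spot_sigma) {
    stop("spots overlap: pitch must be >= 6 spot_sigma", call. = FALSE)
  }
  geom <- layout_geometry(layout)
  opt <- dynamic_optical_response(protocol, circuit, transfer)
  sigma0 <- transfer_sigma(transfer, protocol$v_bias)
  modulation <- opt$sigma_nm2 / sigma0
  nt <- length(modulation)
  with_seed(seed, {
    amp <- layout$peak_counts *
      (1 + antenna_rel_sd * stats::rnorm(layout$n_rows * layout$n_cols))
    amp_mat <- matrix(amp, layout$n_rows, layout$n_cols)
    shifts <- if (noise$jitter_sd > 0) {
      s <- matrix(stats::rnorm(2 * nt, sd = noise$jitter_sd), nt, 2)
      s[1, ] <- 0
      s
    } else matrix(0, nt, 2)
    speckle <- NULL
    if (noise$speckle_drift_sd > 0) {
      speckle_state <- matrix(0, geom$nr, geom$nc)
    }
    frames <- array(0, dim = c(nt, geom$nr, geom$nc))
    max_count <- 2^bit_depth - 1
    for (ti in seq_len(nt)) {
      gy <- gauss_basis(geom$nr, geom$rows_px + shifts[ti, 1],
                        layout$spot_sigma)
      gx <- gauss_basis(geom$nc, geom$cols_px + shifts[ti, 2],
                        layout$spot_sigma)
      expected <- noise$background_level +
        modulation[ti] * (gy %*% amp_mat %*% t(gx))
      if (noise$speckle_drift_sd > 0) {
        speckle_state <- noise$speckle_rho * speckle_state +
          matrix(stats::rnorm(geom$nr * geom$nc,
                              sd = noise$speckle_drift_sd),
                 geom$nr, geom$nc)
        expected <- expected + speckle_state
      }
      img <- if (noise$shot_noise) {
        matrix(stats::rpois(length(expected), pmax(expected, 0)),
               geom$nr, geom$nc)
      } else expected
      if (noise$read_noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img),
                                         sd = noise$read_noise_sd),
                            geom$nr, geom$nc)
      }
      img <- round(pmax(img, 0))
      if (max(img) > max_count) {
        stop("counts exceed the ", bit_depth,
             "-bit range: lower peak_counts or background", call. = FALSE)
      }
      frames[ti, , ] <- img
    }
    seqc <- image_sequence(frames, protocol$sampling_rate,
                           layout$pixel_size, bit_depth)
    truth <- list(layout = layout, protocol = protocol, noise = noise,
                  seed = seed,
                  centers = expand.grid(row = geom$rows_px,
                                        col = geom$cols_px),
                  amplitude = as.vector(amp_mat),
                  modulation = data.frame(time_s = opt$time_s,
                                          rel = modulation),
                  shifts = shifts,
                  tau_ms = time_constant(circuit) * 1000)
    class(truth) <- "ground_truth"
    list(sequence = seqc, truth = truth)
  })
}

#' Predicted electro-optic figures of merit from the ground truth
#'
#' Computes, analytically from the programmed spot amplitudes, noise
#' model and modulation trace, the values an ideal analysis would
#' report: per-antenna plateau Z response per pulse, the segmented pixel
#' mask at the inclusion threshold, trace noise 1 / sqrt(n_mask),
#' sensitivity (slope of plateau Z vs |amplitude| in mV), and SNR at the
#' reference amplitude. Valid when the speckle drift is negligible
#' (per-pixel Z variance is then unity by construction).
#'
#' @param truth A `ground_truth` from [render_sequence()].
#' @param inclusion_threshold Z threshold for pixel membership
#'   (default 3).
#' @param snr_amplitude Reference amplitude in mV (default 100).
#' @param plateau_frac Final fraction of each pulse averaged as plateau
#'   (default 0.5).
#' @param roi_radius ROI radius in px the analysis will use (default 2,
#'   matching [layout_rois()]); the predicted mask is confined to it.
#' @return Data frame, one row per antenna: `sensitivity_z_per_mv`,
#'   `noise_z`, `snr`, `lod_mv`, `n_mask_px`, `tau_ms`.
#' @export
predict_electro_optics <- function(truth, inclusion_threshold = 3,
                                   snr_amplitude = 100,
                                   plateau_frac = 0.5, roi_radius = 2) {
  stopifnot(inherits(truth, "ground_truth"))
  layout <- truth$layout; noise <- truth$noise
  p <- truth$protocol$pulses
  if (nrow(p) < 3) {
    stop("need >= 3 pulses in the protocol to predict a sensitivity",
         call. = FALSE)
  }
  tmod <- truth$modulation
  plateau_rel <- vapply(seq_len(nrow(p)), function(i) {
    sel <- tmod$time_s >= p$onset[i] + (1 - plateau_frac) * p$duration[i] &
      tmod$time_s < p$onset[i] + p$duration[i]
    mean(tmod$rel[sel]) - 1
  }, numeric(1))
  amp_mv <- abs(p$amplitude) * 1000
  # pixel footprint of one spot out to where it matters
  ext <- ceiling(roi_radius)
  offs <- expand.grid(dy = -ext:ext, dx = -ext:ext)
  offs <- offs[offs$dy^2 + offs$dx^2 <= roi_radius^2, ]
  g <- exp(-(offs$dy^2 + offs$dx^2) / (2 * layout$spot_sigma^2))
  n_ant <- nrow(truth$centers)
  out <- data.frame(sensitivity_z_per_mv = numeric(n_ant),
                    noise_z = numeric(n_ant), snr = numeric(n_ant),
                    lod_mv = numeric(n_ant), n_mask_px = integer(n_ant),
                    tau_ms = rep(truth$tau_ms, n_ant))
  i_ref <- which.max(abs(plateau_rel))
  for (a in seq_len(n_ant)) {
    base_counts <- noise$background_level + truth$amplitude[a] * g
    sd_pix <- sqrt(ifelse(rep(noise$shot_noise, length(g)),
                          base_counts, 0) + noise$read_noise_sd^2)
    dz_ref <- truth$amplitude[a] * g * plateau_rel[i_ref] / sd_pix
    mask <- abs(dz_ref) > inclusion_threshold
    n_mask <- sum(mask)
    if (n_mask == 0) {
      out[a, 1:5] <- c(NA, NA, NA, NA, 0L)
      next
    }
    plateau_z <- vapply(seq_along(plateau_rel), function(i) {
      mean(truth$amplitude[a] * g[mask] * plateau_rel[i] / sd_pix[mask])
    }, numeric(1))
    fit <- stats::lm(plateau_z ~ amp_mv)
    sens <- unname(stats::coef(fit)[2])
    nz <- 1 / sqrt(n_mask)
    i_snr <- which(abs(amp_mv - snr_amplitude) < 1e-9)
    snr <- if (length(i_snr)) abs(plateau_z[i_snr[1]]) / nz else NA_real_
    out[a, ] <- list(sens, nz, snr, nz / sens, n_mask, truth$tau_ms)
  }
  out
}

#' Antenna ROI specs for a rendered layout
#'
#' @param truth A `ground_truth`.
#' @param radius ROI radius in px (default 2, suited to the synthetic
#'   5-px pitch; use 20 for experimental-scale images).
#' @return List of `roi_spec`, one per antenna (row-major over the
#'   grid).
#' @export
layout_rois <- function(truth, radius = 2) {
  lapply(seq_len(nrow(truth$centers)), function(i) {
    roi_spec(c(truth$centers$row[i], truth$centers$col[i]), radius)
  })
}

#' Synthetic noisy impedance spectrum
#'
#' Log-spaced frequencies with multiplicative complex Gaussian noise of
#' relative standard deviation `noise_frac`.
#'
#' @param params A `circuit_params`.
#' @param noise_frac Relative noise SD (0 gives the exact model).
#' @param n_freq Number of frequencies (>= 5, default 30).
#' @param seed Integer seed.
#' @param f_min,f_max Frequency range in Hz (default 1 to 1e5).
#' @return List with `frequencies` (Hz) and `z` (complex Ohm).
#' @export
synth_eis <- function(params, noise_frac = 0, n_freq = 30, seed = 1,
                      f_min = 1, f_max = 1e5) {
  if (n_freq < 5) stop("need n_freq >= 5", call. = FALSE)
  freqs <- 10^seq(log10(f_min), log10(f_max), length.out = n_freq)
  z <- impedance_spectrum(params, freqs)
  if (noise_frac > 0) {
    with_seed(seed, {
      pert <- complex(real = stats::rnorm(n_freq, sd = noise_frac / sqrt(2)),
                      imaginary = stats::rnorm(n_freq,
                                               sd = noise_frac / sqrt(2)))
      z <- z * (1 + pert)
    })
  }
  list(frequencies = freqs, z = z)
}

#' Write an image sequence as multi-page TIFF plus sidecar metadata
#'
#' 16-bit unsigned grayscale pages; the sidecar is a versioned YAML
#' key-value file holding `frame_rate`, `pixel_size` and `bit_depth`.
#'
#' @param seq An `image_sequence`.
#' @param path TIFF output path; the sidecar is `path` + ".yaml".
#' @return The path, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  max_count <- 2^seq$bit_depth - 1
  if (max(seq$frames) > max_count) {
    stop("counts exceed the ", seq$bit_depth,
         "-bit range: refusing to clip on write", call. = FALSE)
  }
  nt <- dim(seq$frames)[1]
  pages <- lapply(seq_len(nt), function(i) seq$frames[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(format_version = 1L,
                        frame_rate = seq$frame_rate,
                        pixel_size = seq$pixel_size,
                        bit_depth = seq$bit_depth),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image sequence written by [write_sequence()]
#'
#' @param path TIFF path (sidecar expected at `path` + ".yaml").
#' @return An `image_sequence`.
#' @export
read_sequence <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nt <- length(pages)
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(nt, d[1], d[2]))
  for (i in seq_len(nt)) frames[i, , ] <- pages[[i]]
  image_sequence(frames, meta$frame_rate, meta$pixel_size, meta$bit_depth)
}

#' Write, read back and return an image sequence (round trip)
#'
#' @param seq An `image_sequence`.
#' @param path TIFF path.
#' @return The re-read `image_sequence` (frames bit-identical to the
#'   input).
#' @export
roundtrip_sequence <- function(seq, path) {
  write_sequence(seq, path)
  read_sequence(path)
}
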