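# Array-scale bookkeeping: recording-site density and the number of
# antennas visible in a microscope field of view.

#' Recording-site density of a square antenna array
#'
#' @param pitch_um Antenna pitch in um.
#' @return Sites per cm^2 (1e4 / pitch_um)^2.
#' @export
site_density <- function(pitch_um = 5) {
  (1e4 / pitch_um)^2
}

#' Field-of-view diameter on the sample
#'
#' @param field_number_mm Microscope field number (field diameter at the
#'   intermediate image) in mm, default 25.
#' @param magnification Objective magnification.
#' @return Field diameter on the sample in um.
#' @export
field_diameter <- function(magnification, field_number_mm = 25) {
  field_number_mm * 1000 / magnification
}

#' Number of antennas within a circular field of view
#'
#' Field area divided by the squared pitch, optionally rounded to the
#' nearest multiple (e.g. the nearest thousand for headline counts).
#'
#' @param field_diameter_um Field diameter on the sample in um.
#' @param pitch_um Antenna pitch in um (default 5).
#' @param round_to Round to the nearest multiple of this (default 1:
#'   no rounding beyond the integer count).
#' @return Antenna count.
#' @export
antennas_in_field <- function(field_diameter_um, pitch_um = 5,
                              round_to = 1) {
  n <- pi * (field_diameter_um / 2)^2 / pitch_um^2
  round(n / round_to) * round_to
}
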