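# Default electro-optic model parameters (editable; documented defaults,
# not a fit to any single device).
doped:
  eps_inf: 2.97
  plasma_energy: 2.06
  damping_energy: 0.80
dedoped:
  eps_inf: 1.92
  lorentz:
    - amplitude: 0.78
      center_energy: 2.10
      width_energy: 1.00
  tauc_lorentz:
    - amplitude: 5.0
      center_energy: 3.0
      width_energy: 1.0
      gap_energy: 1.7
calibration:
  v_half: -0.52
  v_width: 0.07
geometry:
  cap_diameter: 1000
  stem_diameter: 250
  stem_height: 50
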