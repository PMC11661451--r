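---
title: "The electro-optic model behind escat: assumptions, defaults, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The electro-optic model behind escat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escat)
```

# The transduction chain

An electrochromic polymer antenna converts a local potential change into
a change of scattered light intensity. `escat` models that chain as four
composable stages — voltage → doping level → complex permittivity →
scattering cross section — plus the circuit dynamics that decide how much
of an applied stimulus actually appears across the polymer, and an image
analysis pipeline that works backwards from camera counts to the figures
of merit a sensor developer cares about. This vignette records the model
assumptions, why each default was chosen, and what the package does and
does not claim.

# Voltage, doping, and permittivity

PEDOT:PSS at high doping behaves like a poor metal; its permittivity is
described by a Drude term

$$\varepsilon(E) = \varepsilon_\infty - \frac{E_p^2}{E^2 + iE\Gamma},$$

with photon energy $E = 1239.84193/\lambda[\mathrm{nm}]$ eV. Fully
dedoped, the material is a lossy dielectric described by
$\varepsilon_\infty$ plus Lorentz oscillators and a Tauc-Lorentz band
edge; the Tauc-Lorentz real part is the published Kramers-Kronig closed
form of its imaginary part, so the model is causal by construction (the
test suite re-derives $\varepsilon_1$ by numerical principal-value
integration and checks agreement to better than 0.5%).

Because both endpoint permittivities vary linearly with the volumetric
density of charge carriers, an intermediate doping level $c \in [0,1]$
gives the pointwise mixture
$\varepsilon = c\,\varepsilon_\mathrm{doped} +
(1-c)\,\varepsilon_\mathrm{dedoped}$.

**Default oscillator parameters.** The shipped defaults
(`default_doped_model()`, `default_dedoped_model()`, and
`inst/extdata/default_model.yaml`) are literature-guided and editable;
they are *not* a fit to any single device:

* doped: $\varepsilon_\infty = 2.97$, $E_p = 2.06$ eV, $\Gamma = 0.80$
  eV, giving $\varepsilon(640\,\mathrm{nm}) \approx 2.00 + 0.40i$ — a
  weakly absorbing quasi-metal in the visible;
* dedoped: $\varepsilon_\infty = 1.92$, one visible Lorentz band at
  2.10 eV (the neutral-polymer π–π* absorption that makes dedoped films
  blue) and a Tauc-Lorentz ultraviolet edge with a 1.7 eV gap, giving
  $\varepsilon(640\,\mathrm{nm}) \approx 2.90 + 1.61i$.

These values were fixed once, by requiring that the *trends* every
downstream result relies on hold simultaneously on the default grid:
$\varepsilon_2 \ge 0$ everywhere (passivity), dedoping raising
$\varepsilon_1$ across 600–800 nm, the 640-nm cross section growing
monotonically toward negative bias for both 750-nm and 1500-nm caps, and
larger caps scattering more at every wavelength and bias. Absolute
permittivity values are secondary; every package-level guarantee is a
parameter-robust property, not a value match.

**Voltage-to-doping calibration.** The map is a logistic,
$c(V) = 1/(1+\exp(-(V-V_{1/2})/w))$ — the minimal monotone, saturating
form — with defaults $V_{1/2} = -0.52$ V and $w = 0.07$ V vs Ag/AgCl.
These were chosen so that the modeled scattering-vs-bias curve is
sigmoidal over the operating window $[-0.8, +0.2]$ V and its voltage
sensitivity $|d\sigma_\mathrm{sc}/dV|$ at 640 nm peaks near $-0.5$ V
(between $-0.48$ and $-0.42$ V for caps from 750 to 1500 nm). A wider,
more positive transition (e.g. $V_{1/2} = -0.35$ V, $w = 0.12$ V) would
place the brightness mid-slope near $-0.35$ V but pushes the sensitivity
peak to $-0.2\ldots-0.3$ V, because the Mie response is convex in doping
level; the defaults favor the sensitivity-peak placement, which is the
property the operating-bias recommendation rests on.

# The Mie surrogate

The real device is a mushroom on a layered substrate under
total-internal-reflection illumination; solving it exactly requires
full-wave electromagnetics, which is out of scope here. `escat` instead
reduces the geometry to a homogeneous sphere in water whose volume
equals hemisphere-cap plus cylinder-stem, and evaluates the exact Mie
series (Bohren–Huffman recurrences, Wiscombe truncation
$n_\mathrm{max} = x + 4x^{1/3} + 2$, convergence-tested to $10^{-6}$;
the Rayleigh closed form is the independent small-particle oracle).

What survives the reduction: the voltage → permittivity → scattering
mechanism, the monotone bias and size trends, and realistic orders of
magnitude. What does not: absolute cross sections (no substrate
interference or TIR evanescent illumination), angular radiation
patterns, and any collection-NA weighting — the surrogate integrates
over all angles. Absolute $\sigma_\mathrm{sc}$ values should therefore
not be compared against full-wave simulations or calibrated
measurements; ratios and trends can be.

# The equivalent circuit

The antenna–electrolyte interface is a series
$R_s$–$R_\mathrm{PEDOT:PSS}$–$C_\mathrm{PEDOT:PSS}$ circuit; the
transferred voltage — what the electrochromic element actually sees — is
read across $C_P$, giving first-order dynamics with
$\tau = (R_s + R_P)\,C_P$. The step response is computed analytically
per pulse segment (the circuit is linear, pulses superpose); the test
suite checks it against a general-purpose stiff integration to
$10^{-6}$ relative.

**Parameter identifiability.** In this topology only the total
resistance $R_s + R_P$ and $C_P$ are identifiable from an impedance
spectrum: `fit_eis()` therefore takes the solution resistance as a known
input, as potentiostat software does, and reports the polymer resistance
as the fitted total minus $R_s$. The fit is least squares in
log-magnitude plus phase space, which weights the decades evenly. A
spectrum from a different topology (e.g. a parallel RC, whose impedance
collapses at high frequency) leaves a large residual and is flagged as a
misfit rather than silently fitted. Note that a pure resistor is *nested*
in the series model (the $C_P \to \infty$ limit) and is consequently not
detectable as a misfit from $Z(\omega)$ alone.

**Default values per geometry.** Printed equivalents for $R_P$ and $C_P$
are not available, so `default_circuit()` derives them from two
anchors: the polymer's volumetric capacitance (39 F/cm³, a standard
literature value for PEDOT:PSS) times the antenna volume gives $C_P$ —
tens of picofarads for micrometer caps — and the measured single-antenna
time constants (6.0, 34.7, 233.9 ms for 0.7, 1.4, 1.8 µm caps,
log-log-interpolated in between) then fix $R_P = \tau/C_P - R_s$, at the
gigaohm scale the narrow 250-nm stem implies. The picofarad/gigaohm
split matters downstream: it is what makes the sensor branch
high-impedance relative to the cell-interface divider. An optional
doping-dependent resistance multiplier
$R_P(V) = R_{P0}(1 + \kappa(1-c))$ is deliberately *not* enabled by
default ($\kappa = 0$): the dedoping-slows-dynamics mechanism is real
but unquantified, and a default of zero keeps $\tau$ exactly equal to
the printed formula.

# The digital twin

`fit_sigmoid_transfer()` fits $\sigma(V)$ with a four-parameter
logistic; `dynamic_optical_response()` composes that static transfer
with the *instantaneous transferred voltage* (not the applied bias) —
the polymer responds to the voltage that actually develops across it.
Consequences that the tests pin down: optical deflections have the
opposite sign of the pulse (negative pulses brighten), small signals
linearize to slope × ΔV within 1%, the optical rise time equals the
circuit τ within 2%, and the output is always bounded by
$[\sigma_\mathrm{min}, \sigma_\mathrm{max}]$.

# The imaging pipeline

Design choices, each of which was genuinely open:

* **Registration.** Rigid translation only: phase correlation provides
  the coarse shift, and a Gauss-Newton refinement of the sum of squared
  differences (gradients computed spectrally) polishes it to millipixel
  precision — plain correlation-peak interpolation is an order of
  magnitude worse, which matters because sub-pixel jitter against
  40&#8239;000-count spots otherwise dominates the per-pixel baseline
  variance. Rotation and shear are out of scope. Sub-pixel accuracy also
  requires an adequately sampled point-spread function; on grids that
  undersample the spot (σ below ~1 px) aliasing biases shift estimates
  by a few percent of the shift.
* **Z scoring.** Per pixel, $z(t) = (x(t) - \mu)/s$ with $\mu, s$ from a
  stimulus-free baseline window (default: the second preceding the
  first pulse; sample SD). Pixels with zero baseline variance are
  flagged invalid and excluded downstream instead of propagating NaN.
* **Segmentation.** "Part of the antenna" is read as: max $|z|$ over the
  stimulation window exceeds 3, within a circular ROI around the known
  antenna center (ROI centers are inputs; the array layout is known by
  design). An empty mask is reported explicitly as "no responsive
  pixels", distinct from a zero trace.
* **Figures of merit.** Sensitivity is the least-squares slope of the
  plateau Z versus |amplitude| in mV, where the plateau is the mean over
  the final 50% of each pulse (pulses last ≫ τ, so the choice of
  fraction is uncritical); noise is the SD of the trace over a
  stimulus-free second; SNR divides the 100-mV plateau by the noise; and
  the limit of detection is noise/sensitivity — the amplitude at which
  SNR = 1, an identity the code preserves exactly.
* **Time constants.** Least-squares fit of $A(1-e^{-(t-t_0)/\tau})$ over
  $[t_0, t_0 + 5\hat\tau]$, with the window re-derived from the current
  estimate (initialized at the 63.2% crossing) and refined twice.
* **Box charts.** Linearly interpolated quartiles (R's default type 7 —
  chosen over Tukey hinges for determinism across implementations),
  whiskers at the most extreme values within 1.5 IQR, outliers beyond.

# The cell–antenna interface

The Luo-Rudy 1991 ventricular model is implemented with its original
1991 parameter set (six currents, Hodgkin-Huxley gating, calcium
handling) and integrated with a stiff-capable solver; an independently
written implementation of the same published equations provides the
frozen reference values the tests compare against (resting potential
−84.55 mV; +42.08 mV overshoot for a 40 µA/cm², 1-ms stimulus).

Coupling is one-way — the membrane drives the interface, the sensor does
not load the cell — justified by interface impedances (hundreds of
megaohms) far above the membrane's. The cleft node is driven by $v_m$
through $R_j$, shunted to the bath by $R_\mathrm{Seal}$, and loaded by
the sensor branch ($R_P$ in series with $C_P$); the sensor voltage is
read across the whole polymer element, i.e. the cleft potential less the
negligible solution drop. Junctional-membrane and cleft capacitances
default to zero (config hooks exist), so the divider itself is purely
resistive.

With the defaults ($R_\mathrm{Seal} = 200$ MΩ, $R_j = 500$ MΩ, the
1.4-µm sensor circuit), the dynamic solution transfers a peak-to-peak
**32.5 mV**. The decomposition is instructive: the resistive divider
ratio is $200/700 = 2/7$, which applied to the full 126.6-mV action
potential would give 36.2 mV, but the sensor branch's own time constant
(≈40 ms) filters the 2-ms sodium spike while passing the plateau — the
slow content is transferred at the divider ratio, the overshoot is not.
In the $C_P \to 0$ limit the dynamic solution collapses onto the
resistive divider within 2%, and the transferred amplitude is monotone
increasing in $R_\mathrm{Seal}$ and decreasing in $R_j$.

# Synthetic data: what it emulates, what it does not

`render_sequence()` produces camera stacks of a regular antenna array
(default 16×16 at 5-µm pitch) whose Gaussian spots modulate according to
the digital twin under a programmed protocol, with noise applied in a
physical order: slowly drifting per-pixel speckle background (AR(1) with
coefficient 0.999 — a random walk on experimental timescales, standing
in for the interference background that dominates coherent dark-field
setups; its magnitude is config-exposed because no quantitative value is
established), Poisson shot noise on expected counts, Gaussian read
noise, and 16-bit quantization with an explicit error — never silent
wraparound — on overflow. Optional rigid jitter displaces all spot
centers analytically, which keeps sub-pixel ground truth exact. Every
stack is bit-reproducible from its seed and carries a ground-truth
object from which `predict_electro_optics()` computes, analytically from
the noise model, the values an ideal analysis would report — programmed
sensitivity, trace noise $1/\sqrt{n_\mathrm{mask}}$, SNR, mask size, τ.

Deliberately not emulated: diffraction ring structure (spots are
isotropic Gaussians), cell silhouettes, physically rigorous evanescent
illumination, and detector nonlinearity. Passing recovery tests
therefore demonstrates the pipeline's correctness on well-specified
optics and noise, not robustness to every structured artifact of a real
microscope.

**Problem sizes used by the test suite** (chosen to exercise the study
conditions at desk scale): recovery runs use the full 16×16 array at
200 fps with four pulse amplitudes (−25…−100 mV) over 7 s, five seeds;
time-constant recovery uses fifty 2000-fps single-antenna stacks with
τ programmed at 34.7 ms; the Poisson-calibration property uses 10⁴
frames; the registration-invariance check uses a 3×3 array sampled at
0.625 µm/px so the point-spread function (σ = 1.2 px) is above Nyquist.
Default synthetic spots are sampled coarser (1 µm/px, σ = 0.8 px) for
speed, which is adequate for everything except sub-pixel registration —
the aliasing caveat above.

# Numerical choices

* Photon-energy convention 1239.84193 eV·nm; default wavelength grid
  400–1000 nm in 10-nm steps; 640 nm as the default readout wavelength.
* Mie series: downward recurrence for the logarithmic derivative
  (started 16 orders above the Wiscombe cutoff), upward Riccati-Bessel
  recurrences outside.
* ODE integration: `deSolve::lsoda` with rtol = atol = 10⁻⁸ for the
  action potential (halving the tolerance moves the peak by <0.1 mV),
  10⁻⁹ for the interface filter.
* Nonlinear fits: Levenberg-Marquardt (`minpack.lm`), positivity via
  log- or absolute-value parameterizations; non-convergence and
  degenerate fits set attributes and warn, they never fail silently.
* All stochastic generators take explicit seeds and restore the RNG
  state of the session.

# Known limitations

* Absolute scattering cross sections are surrogate-level (see above).
* The series RC circuit has no constant-phase element, Warburg
  diffusion, or faradaic branch; cyclic-voltammetry currents are out of
  scope.
* The voltage-to-doping calibration is a modeling default, not an
  electrochemical measurement; users with measured doping curves should
  replace it via `doping_calibration()` or the YAML config.
* LR91 is the original guinea-pig parameterization; human or stem-cell
  cardiomyocyte waveforms differ in rate and plateau shape, which will
  shift the transferred amplitude through the spike-filtering mechanism
  described above.
* The imaging pipeline assumes known antenna positions; spot detection
  is intentionally not provided.
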