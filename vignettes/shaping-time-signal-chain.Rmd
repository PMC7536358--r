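---
title: "The pcdsim signal-chain model: shaping time, noise and counting in an edge-on silicon photon-counting channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pcdsim signal-chain model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdsim)
```

## The problem

Silicon strip detectors in edge-on geometry are a candidate sensor for
photon-counting spectral CT. Each channel integrates the current induced by
a photon interaction, shapes it into a semi-Gaussian voltage pulse, and
counts threshold crossings with a bank of clocked comparators. The shaping
time $\tau$ of the filter is the central design knob:

* longer $\tau$ narrows the noise bandwidth, lowering the electronic noise
  $\sigma$ and therefore the lowest usable counting threshold — important in
  silicon, where Compton interactions deposit only a few keV and a low
  threshold directly buys dose efficiency;
* longer $\tau$ also lengthens the pulses, which forces a longer deadtime
  and degrades count-rate capability at high flux;
* the preamplifier noise scales as $\sigma \propto 1/\sqrt{P}$ with its
  power budget $P$, so an adjustable $\tau$ can buy back the noise cost of a
  power reduction.

`pcdsim` simulates this chain end to end — interaction, charge transport,
shaping, noise, clocked counting, spectra — and implements the calibration
procedures used to characterize such a channel from threshold scans. This
vignette records the model, its assumptions, the tunable parameters, and
the numerical and design choices, in the order signal flows through the
chain.

## Charge transport and induced current

A photon of energy $E$ entering the edge of the silicon strip is tracked
with a deliberately simplified interaction model (`sample_interaction()`):

* interaction type is photoelectric (full deposit) or Compton, with
  probabilities from the silicon photoelectric and incoherent interaction
  coefficients; Compton electron energies are drawn from the free-electron
  Klein–Nishina angular distribution. Coherent scattering deposits nothing
  and is treated as no interaction;
* no fluorescence (the silicon K line at 1.74 keV is almost always
  reabsorbed locally), no Rayleigh deposit, no secondary-photon or electron
  transport: deposits are point-like. Photoelectron ranges at CT energies
  (tens of µm) are small against the 400 µm pixel pitch, and tungsten
  shielding between modules suppresses cross-pixel secondaries, so the
  spectral features that matter here — the full-energy peak and the Compton
  continuum below ~40 keV — survive this reduction;
* the interaction depth along the strip follows exponential attenuation
  over the 30 mm active length; the position across the wafer thickness is
  uniform (the beam is collimated onto the pixel center, so lateral effects
  such as charge sharing do not arise).

The deposit is converted to charge at 3.6 eV per electron–hole pair (the
standard silicon value) and represented by 1000 charge-weighted carrier
pairs, enough to make the induced current smooth on the 2 ns grid at
negligible cost.

The drift field comes from the 1-D Poisson equation across the wafer
thickness $d$ (default 500 µm — the wafer thickness is a configurable
parameter of `detector_geometry()` rather than a fixed constant) with
$\varphi(0)=0$ at the collecting strip, $\varphi(d)=V$ at the backside and
uniform space charge from the net doping $N = 4.6\times10^{11}$ cm$^{-3}$.
A finite-difference solve (`solve_field()`) is validated against the
closed-form over-depleted planar solution
$E(x) = V/d + (eN/\epsilon)(d/2 - x)$ to below 0.1%; the depletion voltage
$eNd^2/2\epsilon \approx 88$ V is checked against the 400 V bias at
construction time.

Carriers drift with $v = \mu E$ using constant low-field mobilities
$\mu_e = 1350$, $\mu_h = 480$ cm$^2$/Vs at 300 K. This is the literal
reading of a drift-velocity model and is the package default; a Canali-type
velocity-saturation model is available behind the `saturate` flag of
`transport_step()`. At the operating fields here (8–10 kV/cm) saturation
slows the electrons appreciably, but the shaped-pulse observables the
package reproduces (gain ratios, pulse lengths) shift by less than 0.5%
between the two models, so the simpler default stands. Diffusion adds
independent Gaussian displacements in the drift and lateral directions with
variance $2D\,\mathrm{d}t$ per step, $D = kT\mu/e$, resampled every step;
lateral excursions reflect at the pixel boundary (with a centered beam the
boundary treatment is immaterial, and reflection conserves charge).

The induced current uses the Shockley–Ramo theorem with the planar
weighting field $E_w = 1/d$: $i(t) = \sum_k q_k v_k / d$. Displacements are
clamped at the electrodes, which makes Ramo charge conservation — the time
integral of the induced current equals the generated charge — exact to
rounding for every completed trajectory; the test suite asserts it at
$10^{-9}$ relative tolerance. Electrons and holes both contribute while
drifting, so a mid-thickness interaction produces a fast electron edge and
a slower hole tail, with total durations of roughly 4–15 ns depending on
the interaction depth.

## The shaping chain

The readout channel is modeled entirely by its rational transfer function
(`transfer_function()`): a charge-sense amplifier (CSA) with feedback
capacitance $C_f$, a pole-zero cancellation stage ($C_{pz}$), a shaper
amplifier with time constant $\tau_s$, and two cascaded lossy Gm-C
integrator stages contributing one real pole each:

$$
H(s) \;=\; \frac{1}{C_f}\,\frac{C_{pz}}{C_s}\;
\frac{\tau_s}{1+s\tau_s}\;\frac{2}{1+s\tau_1}\;\frac{2}{1+s\tau_2},
\qquad s = j2\pi f .
$$

Two channel variants are provided by `shaper_config()`:

| variant | $\tau_s$ | $\tau_1$ | $\tau_2$ | shaping time |
|---|---|---|---|---|
| `prototype` | 14 ns | $B\tau_0$ | $2B\tau_0$ | $\tau = 2B\tau_0$ |
| `ideal` | $\tau_0$ | $\tau_0$ | $\tau_0$ | $\tau = 2\tau_0$ |

In the prototype the comparator bank loads the second Gm-C stage, which
doubles its time constant; the selectable shaping setting is expressed by
$B$ ($B=1$ long, $0.5 \le B < 1$ short). The ideal variant describes a
future channel without that parasitic load, with the shaper-amplifier time
constant tracking $\tau_0$. Note that the prototype long setting does
*not* reduce to the ideal channel: the factor 2 on $\tau_2$ remains.

Two details of this algebra are worth recording. First, each Gm-C stage
enters once — the filter is second order in the Gm-C stages, third order in
total — which is what the stage-per-pole architecture implies and what the
noise transfer functions below assume; a reading that squares the first
stage factor produces pulse lengths and gain ratios inconsistent with the
rest of the model (the 100 keV pulse at τ = 40 ns would measure ≈160 ns
instead of ≈140 ns at its deadtime threshold). Second, the shaper-amplifier
term is written in its DC-coupled low-pass form $\tau_s/(1+s\tau_s)$. An
AC-coupled description $s\tau_s/(1+s\tau_s)$ preceded by the explicit CSA
integration $1/(sC_f)$ reduces to exactly the same expression, which is how
the two common ways of writing this chain reconcile; a literal band-pass
numerator (without the explicit integration) is nevertheless available via
`transfer_function(..., numerator = "bandpass")` for comparison.

`shape_pulse()` applies $H$ in the frequency domain: the induced current is
zero-padded to at least 20 shaping times (power-of-two window), multiplied
by $H(f)$, and transformed back. The padding guarantees the shaped pulse
decays below 1% of its peak inside the window for $\tau$ up to 500 ns, and
an error is raised otherwise rather than silently wrapping. Peaks are taken
as the maximum over the 2 ns grid without sub-sample refinement — the
physical comparators also see sampled values — while threshold-crossing
times (`pulse_length()`) are linearly interpolated between grid points,
bounding the discretization error at about ±1 ns.

Useful closed-form anchors, all asserted in the tests: the DC gain is
$(1/C_f)(C_{pz}/C_s)\,\tau_s\cdot 4$ (3200 mV/µA for the ideal 40 ns
configuration); the ideal-variant impulse-response peak is independent of
$\tau_0$ (the $\tau_s$ numerator cancels the $1/\tau$ time scaling), so the
ideal channel's gain is nearly flat in shaping time, while the prototype's
fixed 14 ns $\tau_s$ makes its long setting about 23% lower in gain than
its short setting.

The channel gain in mV/keV (`gain()`, `channel_gain()`) is the regression
slope of shaped peak voltage on deposited energy over a seeded ensemble of
full-energy pulses at 40–80 keV and ≥ 20 interaction depths, mirroring how
gain is obtained from monochromatic threshold scans.

## Electronic noise

Noise is modeled by two uncorrelated white input-referred sources: a CSA
noise current (nominal 0.45 µA rms) and a filter noise voltage (2.72 mV
rms), both defined as discrete white noise on the 2 ns grid, i.e. with
one-sided PSD $2\,\mathrm{rms}^2\,\mathrm{d}t$. Their output PSDs
(`output_psd()`) are

$$
\mathrm{PSD}_{\mathrm{CSA}}(f) =
\left(\frac{1}{G_f}\frac{C_{det}}{C_f}\frac{C_{pz}}{C_s}\right)^{\!2}
\frac{|2\pi f\tau_s|^2}{|1+j2\pi f\tau_s|^2}
\frac{4}{|1+j2\pi f\tau_1|^2}\frac{4}{|1+j2\pi f\tau_2|^2}\, I^2_{\mathrm{in}}(f),
$$

$$
\mathrm{PSD}_{\mathrm{filter}}(f) =
\frac{4}{|1+j2\pi f\tau_1|^2}\frac{4}{|1+j2\pi f\tau_2|^2}\, V^2_{\mathrm{in}}(f),
$$

with $G_f = 5$ mS and $C_{det} = 5$ pF. The CSA term is band-pass (the
detector capacitance differentiates the CSA's voltage noise), so it
vanishes at DC; the filter term is flat at $16\,V^2_{\mathrm{in}}$ there.
The complex denominators are used throughout — written with moduli of
$1 + j2\pi f\tau$ — as the dimensionally consistent form.

**Normalization.** The nominal source levels, taken literally with the
discrete-white convention above, put about 92% of the output noise power in
the CSA path at the reference configuration, while the architecture is
characterized by a 4/5–1/5 CSA/filter split. The package treats the split
and the absolute level as the defining calibration: two per-source scale
constants are computed once (`noise_normalization()`) so that the ideal
channel at $\tau = 40$ ns has exactly $\sigma = 2$ keV of calibrated noise
with exactly 4/5 of the output power from the CSA. This absorbs any
unit-convention mismatch in the PSD prefactors, and every downstream number
(thresholds, ratios, the power tradeoff) is anchored to that reference.
The constants and the reference gain are memoised and reported by
`run_pipeline()` for auditability. The keV scale uses the simulated channel
gain of a standard 60 keV pulse ensemble (seed 0) — the channel itself has
no intrinsic keV axis.

$\sigma$ versus $\tau$ (`sigma_total()`, `sigma_vs_tau()`) integrates the
PSDs on a logarithmic grid from 1 kHz to 2 GHz (6000 points, trapezoid
rule), which covers all pole frequencies for $\tau \in [20, 500]$ ns with
truncation error below 0.1% of the closed-form rational integrals. For the
ideal variant all three time constants scale together and both component
variances scale exactly as $1/\tau$, so $\sigma_{\mathrm{mV}} \propto
1/\sqrt{\tau}$: from 2 keV at 40 ns the model gives 1.26 keV at 100 ns
(4σ threshold 5.0 keV) and 0.89 keV at 200 ns. A channel whose measured
noise at long shaping times falls faster than this (for example a reported
1.9 keV at 400 ns, where the scaling gives 2.5) is not described by these
two white sources; the package documents this as a known limitation of the
two-source model rather than adjusting it.

Time-domain realizations (`noise_realization()`) draw per-sample Gaussian
white noise for each source, propagate it through the respective transfer
magnitude by FFT, and sum. Parseval consistency between the sample variance
and the PSD integral is asserted at the 5% level for single 150 µs frames
and at 3 standard errors over 100-frame ensembles.

## Clocked counting and the E$_{1/2}$ method

The comparator bank (`comparator_bank()`) holds up to eight strictly
increasing thresholds, a clock period $\tau_c = 10$ ns, and a deadtime
$\tau_d$ that must be a clock multiple. `count_frame()` samples the
waveform at $n\tau_c + \varphi$ with a per-frame uniform random phase
$\varphi$: a sample above the lowest threshold triggers a count, the pulse
is classified by the highest threshold exceeded among the samples inside
the deadtime window (peak-hold semantics), and the channel is live again
exactly $\tau_d$ after the trigger. Re-triggering on a still-high signal is
deliberate — it is what produces double counts — and the deadtime window is
fixed from the first trigger (no restart when a higher comparator fires
mid-window).

These semantics fix the central measurement identity. A pulse that stays
above the lowest threshold for a length $L$ is double counted when the
first live sample, $u + \tau_d$ with trigger delay $u \sim U(0, \tau_c)$,
still finds it high, i.e. with probability $P(u < L - \tau_d)$. The
normalized threshold-scan curve therefore steps from 2 to 1, crossing 1.5
at the threshold $E_{1/2}$ where $L = \tau_d + \tau_c/2$. That turns a
deadtime-stepped scan of the lowest DAC threshold into a pulse-shape
measurement: each $(E, \tau_d)$ pair yields one point of the pulse profile.
`extract_e_half()` finds the 1.5 crossing by linear interpolation,
excluding thresholds below 15 keV where noise counts and triple-counted
pulses distort the curve (a configurable constant). The identity — pulse
length at $E_{1/2}$ equals $\tau_d + \tau_c/2$ within half a clock — is
asserted across beam energies and deadtimes in the test suite. A
consequence of the live-at-$\tau_d$ convention is that a saturated channel
counts once per $\tau_d$, not per $\tau_d + \tau_c$.

`simulate_threshold_scan()` has two backends: `"fast"` applies the trigger
arithmetic per pulse to the noise-free pulse shape with an independent
uniform phase per pulse (counts per pulse $= \lceil (L-u)/\tau_d \rceil$
for $u < L$), and `"frame"` synthesizes a long waveform of well-separated,
sub-clock-jittered pulses — optionally with an electronic-noise realization
— and runs the comparator logic sample by sample. The two agree within
counting statistics and the 2 ns waveform discretization; the fast backend
carries the large parameter-recovery studies, the frame backend everything
involving noise.

Operating points couple noise to deadtime (`deadtime_for()`): the lowest
threshold is $4\sigma(\tau)$ — one expected noise count per 150 µs frame —
and the deadtime is the length of a 100 keV pulse at that threshold,
rounded up to a clock multiple. At $\tau = 40$ ns this gives 8 keV and
140 ns; at 100 ns, 5.0 keV and 380 ns. Count-rate curves
(`count_rate_curve()`) run Poisson pulse trains (photon count
$\sim$ Poisson($fT$), uniform arrival times, energies drawn from a
deposited spectrum) through this logic; the output rate rises linearly with
slope equal to the above-threshold fraction, then saturates below
$1/\tau_d$, with the 40 ns setting saturating later than 200 ns.

## Tube spectrum, silicon response and dose efficiency

The incident spectrum (`tube_spectrum()`) is a semi-empirical tungsten-tube
model chosen for transparency over fidelity: Kramers bremsstrahlung photon
fluence $N(E) \propto (E_0 - E)/E$, an effective 2 µm tungsten
self-filtration path scaled by the anode takeoff angle (10.5° default), and
the four K characteristic lines added as 9% of the bremsstrahlung fluence
when the tube voltage exceeds the K edge — a standard ballpark for a
120 kVp tungsten spectrum. Beryllium (0.8 mm), aluminum (8.38 mm) and
soft-tissue (20–40 cm) filtration follow Beer–Lambert per bin
(`attenuate()`), with mass attenuation coefficients log-log interpolated
from embedded 10-node tables (ICRU-44-style soft tissue; standard
compilation values for Al, Be, Si, W). After 8+ mm of aluminum and tens of
cm of tissue the surviving spectrum is insensitive to the fine structure of
the unfiltered model, which is what makes the semi-empirical form adequate
here.

The silicon response (`detector_response()`) Monte-Carlo samples each
photon: attenuation in the 0.6 mm dead layer at the pixel top (interactions
there are lost photons — they neither count nor enter the denominator,
which keeps the efficiency normalization at 100% for a zero threshold),
interaction over the 30 mm strip with probability $1 - e^{-\mu L}$, then a
photoelectric or Klein–Nishina deposit as in the transport module. Deposits
are histogrammed on the 0.5 keV grid starting at 1 keV; deposits below the
lowest bin edge (0.75 keV) are physically unregistrable and are excluded
like zero-deposit events. This registration floor matters: roughly 5% of
Compton events at CT energies deposit less than 0.75 keV (forward
scattering), and whether they count in the denominator shifts the dose
efficiency by several percentage points. No electronic-noise broadening is
applied to the deposited spectrum — it represents the physics deposits
before the readout chain.

Dose efficiency (`dose_efficiency()`) is the counting-only definition: the
fraction of the deposited-energy histogram above the lowest threshold, with
the straddling bin counted fractionally, always evaluated on the same
histogram it thresholds. For the 120 kVp / 20 cm beam the model gives
68.2% above 8 keV and 83.5% above 4 keV (10⁶ photons, seed 42) — lowering
the threshold from 8 to 4 keV buys about 15 percentage points, which is the
quantitative case for long shaping times at low flux. The curves for 20,
30 and 40 cm of tissue lie within 5 points of each other over 0–20 keV:
beam hardening moves the mean energy but barely reshapes the deposit
histogram's low-energy share.

## Calibration fitting

`fit_erfc()` fits the six-parameter modified complementary error function

$$
f(x) = \tfrac12\,\mathrm{erfc}\!\left(\tfrac{x-\mu}{\sqrt2\sigma}\right)
\big(A_1(x-\mu) + A_2\big) + A_3(x-\mu) + A_4
$$

to threshold-scan counts by Levenberg–Marquardt least squares. The model
has shallow directions in $A_1/A_3$, so the fit multi-starts from a
data-driven guess (transition located at the half-plateau crossing) and a
dispersed fallback, keeping the best converged optimum; thresholds below
15 keV are excluded for beam scans (noise/triple-count region), and 0 for
noise-only scans. `calibrate_gain()` regresses the fitted $\mu$ against
beam energy — the slope is the gain in mV/keV — and divides the noise-only
$\sigma$ by it to express noise in keV.

`fit_shape_params()` recovers the prototype time constants from
pulse-length data by exhaustive grid search over
$\tau_0 \in [10, 30]$ ns in 0.1 ns steps and
$B_{\mathrm{short}} \in [0.5, 1)$ in 0.01 steps. Each measured record
$(E, \tau_d, E_{1/2}, \mathrm{setting})$ contributes the squared difference
between the simulated pulse length at the $E_{1/2}$ threshold and the
measured length $\tau_d + \tau_c/2$; the mean over records is unweighted
(no principled weighting presents itself), ties break towards smaller
$\tau_0$, and the search is a true brute-force minimum (no early exit),
asserted against the returned error surface. All candidates share one
seeded charge-transport pulse ensemble, so the search costs one FFT per
candidate (about 10⁴ FFTs, a few seconds). Round-trip recovery — generate
scans from known $(\tau_0, B)$, extract $E_{1/2}$, fit — lands within one
grid step for random draws across the full parameter box; this is the
module's core test.

## Power versus shaping time

`sigma_at()` combines $\sigma \propto 1/\sqrt{P}$ with $\sigma(\tau)$ from
the noise model. Two scopes are exposed because "power to the
preamplifier" is ambiguous about the filter stage: `"csa_only"` (default)
scales only the CSA output-noise component by $1/P$, `"total"` scales the
whole variance. `required_shaping_time()` solves the constant-noise
condition by bisection to 0.1 ns. With the exact $1/\tau$ variance scaling
of the ideal channel both scopes have closed forms for the compensation
factor at power fraction $p$:

$$
\frac{\tau^*}{\tau_{\mathrm{ref}}} = 1 + s\left(\frac{1}{p} - 1\right)
\quad (s = \text{CSA power share} = 4/5) \qquad\text{or}\qquad \frac{1}{p},
$$

giving 1.8 and 2.0 at $p = 1/2$ — independent of the reference shaping
time. The numerical solver matches the closed form to 1%, which is why the
tradeoff solves on the output-voltage $\sigma$ (the ideal channel's keV
gain is flat in $\tau$ to under 1%, so recalibrating per $\tau$ would move
the factor by less than that). A reported compensation factor that differs
between reference shaping times — 1.875 at 40 ns but 2.5 at 200 ns — cannot
arise from any noise model whose variance scales as a single power of
$\tau$; the package reports both scopes and leaves that residual
discrepancy documented rather than fitted.

## Reproducibility, problem sizes, limitations

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; expensive deterministic intermediates (reference
gains, the standard pulse shape, the noise normalization) are memoised per
configuration. The shipped test suite and the acceptance script run at
desk scale by design: gain ensembles use 20–32 interaction positions per
energy (the gain ratio's Monte-Carlo scatter is then below 0.3%), threshold
scans 2000–3000 pulses (E$_{1/2}$ repeatability ≈ 0.1 keV), the
dose-efficiency histograms 10⁶ photons (binomial error ≈ 0.05 pp), and the
parameter-recovery study 10 random draws; these sizes were chosen so that
Monte-Carlo error is comfortably below the tolerances being asserted.

What the synthetic model does not capture, and passing tests therefore do
not demonstrate about real devices: charge sharing and cross-talk between
strips or depth segments (the beam is centered by assumption), K
fluorescence and Doppler broadening, trapping and ballistic deficit from
non-uniform fields, 1/f and shot noise components (the sources are white),
comparator offsets/dispersion, and any absolute dosimetry — spectra are
relative and dose efficiency is a count fraction, not a dose ratio.
Measured absolute gains of real modules differ from the ideal transfer
function's prediction by circuit-level factors the model does not contain;
the package's validated observables are the *ratios* and *lengths* that
survive those factors.
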