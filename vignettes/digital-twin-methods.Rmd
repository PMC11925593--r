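---
title: "Methods: a digital twin of a portable PCR thermal cycler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a digital twin of a portable PCR thermal cycler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrtwin)
```

## What the package models

pcrtwin is a hardware-free simulation of a portable, low-cost PCR thermal
cycler: a four-well aluminium block driven by a thermoelectric (Peltier)
element through an H-bridge, an LM35 analog temperature sensor read by a
10-bit ADC, a resistive heated lid under an on/off thermostat, and an
8-bit-PWM "piecewise" PID controller that switches gain sets between PCR
stages. The twin closes the same loop in software:

1. **sensor** — the block temperature is converted to a voltage, corrupted
   by noise, quantized by the ADC, and mapped back through the calibration
   line;
2. **controller** — the stage's PID computes a signed PWM command from the
   measured error;
3. **plant** — a lumped thermal model integrates the block (and lid)
   temperature forward.

Everything a user touches is tabular: simulations return a tibble trace
(one row per 0.1 s), metrics functions return tibbles, and fitted objects
have `tidy()`/`glance()`/`autoplot()` methods.

## Sensor and ADC model

The sensor obeys the linear law
\[T = (V_\mathrm{out} + a)/b,\]
with offset $a$ (mV) and sensitivity $b$ (mV/°C); the nominal device
sensitivity is 10 mV/°C and the reference calibrated line is
$a = 19.50$, $b = 10.14$. Calibration (`fit_calibration()`) is ordinary
least squares of recorded voltage on bath temperature; voltage is
regressed on temperature (not the reverse) because the bath temperature is
the controlled variable in a water-bath calibration. The measurement chain
(`measure_temperature()`) applies noise in the *voltage* domain
(`noise_sd_C` is scaled by $b$), then quantizes to the ADC grid
(5000 mV / 2^10 ≈ 4.88 mV per count ≈ 0.48 °C per count at this
sensitivity), so quantization acts after noise exactly as in the physical
chain. Temperatures are clamped (with a warning) to the −40…110 °C
operating range of the sensor variant used, since transient overshoot may
exceed range without being an error.

The packaged noise level is 0.08 °C (1 s.d.). With quantization
(±0.24 °C worst case) this keeps the simulated single-reading error
within the ±0.55 °C figure verified for the calibrated instrument;
`calibration_error_report()` recomputes that bound by simulation.

**Oversampling.** Each *controller* measurement averages 25 ADC
conversions (`adc_oversample`), standard practice in microcontroller
analog firmware. It suppresses noise by ~5× and dithers the quantization
staircase, which matters because the annealing approach crosses its target
at only ~0.1–0.2 °C/s: with single-read control the noise-driven
first-passage jitter of the cooling-ramp duration is about ±1 s, while
with oversampling the closed loop tracks its noiseless calibration to
within ~0.1–0.2 s. Single readings (as used in the calibration error
report) are never averaged.

## The discrete PID law

The controller implements, verbatim, the raw-sum discrete law
\[E(n) = T_t(n) - T_s(n),\quad I = \sum_i E(i),\quad D(n) = E(n)-E(n-1),\]
\[U(n) = K_p E(n) + K_i I(n) + K_d D(n),\]
with the command magnitude saturated at 255 counts (8-bit PWM) and the
sign of $U$ selecting heat or cool through the H-bridge abstraction. The
published saturation expression reads "Max(255, |U|)", which taken
literally would *floor* the magnitude at 255; since its stated purpose is
to keep the signal within 8-bit PWM range we read it as
$\min(255, |U|)$ and treat the original as a typo.

The gain schedule maps the five PCR stage kinds to controllers PID1–PID5:
(15, 1, 7) at 95 °C for initial denaturation and denaturation,
(9, 0.1, 5) at 55 °C for annealing, and (13, 1, 10) at 72 °C for
extension and final extension. The PID state is reset at every stage
transition, matching the picture of five separate controllers and
suppressing derivative kick; on the first update after a reset the
previous error is taken as zero, so the derivative contribution is
$K_d E$.

### Controller update period

The firmware loop rate is not part of the published design, yet with raw
sums it *scales* the integral and derivative action: at update period
$h$, the integral term grows as $K_i E / h$ per second and the derivative
term is $-K_d \dot T h$. We fix the plant integration and trace sampling
at $dt = 0.1$ s and update the controller every 0.2 s (zero-order hold on
the PWM in between). This choice was made by elimination during design:

* at 0.1 s updates the integral acts twice as fast and the derivative is
  half as strong; the loop then cannot keep every hold within 1 °C
  (worst settled errors slightly above 1 °C at the extension stage);
* at 1 s updates the derivative damping is so strong that the heating
  ramp cannot reach 95 °C in the published 38 s for any loss coefficient;
* at 0.2 s both the published ramp durations and the sub-1 °C holds are
  met simultaneously.

### Anti-windup

Three safeguards shape the integral, all documented in `pid_step()`:

* **integral separation**: $I$ accumulates only while $|E| \le 2$ °C, so
  the tens-of-degrees errors of a ramp never wind it up. The band must
  exceed the worst proportional droop (≈1.3 °C at the 95 °C target with
  the fitted plant), and widening it to 2.5 °C makes the Ki = 1 stages
  overshoot more than 1 °C — 2 °C is the working point;
* **conditional integration**: accumulation is skipped on any update
  whose output saturates;
* **clamping**: $|K_i I| \le 255$.

Two alternatives were tried and rejected: pure conditional integration
(the integral tops itself up each time the output momentarily
desaturates, so ramps ride the saturation boundary at full drive — the
heating ramp would take ~25 s instead of the observed controller-limited
38 s, and the annealing stage accumulates an integral that its small
$K_i = 0.1$ cannot drain, wrecking the 55 °C hold), and integral reset on
error zero-crossing (sensor noise near the setpoint triggers spurious
resets, stalling the final approach in a seed-dependent way).

## Thermal plant

The block (and, with its own parameters, the lid) is a single thermal
state driven by the signed PWM command $u \in [-255, 255]$:
\[\frac{dT}{dt} = g(u)\,\frac{u}{255} - \lambda\,(T - T_\mathrm{amb}),
\qquad g(u) = \begin{cases} g_\mathrm{heat} & u \ge 0\\
g_\mathrm{cool} & u < 0\end{cases}\]
integrated by explicit Euler at $dt = 0.1$ s. The asymmetric gains absorb
the different efficiencies of thermoelectric heating and cooling; a
richer Peltier model (Seebeck/Joule terms, heat-sink state) is
unidentifiable from the published observables, which are two ramps and a
steady-state bound. $dt\,\lambda$ is orders of magnitude below the Euler
stability limit, and halving $dt$ changes a 120 s trajectory by far less
than 0.05 °C (tested).

### Calibrating the plant to the published ramps

`fit_plant_to_observables()` finds $(g_\mathrm{heat}, g_\mathrm{cool},
\lambda)$ so that the *closed-loop* simulation (Table-of-gains schedule,
noiseless but quantized sensor) reproduces the measured ramps: heating
26.39 → 95 °C in 38 s with a 2.8 °C/s maximum rate, and cooling
94.83 → 55 °C in 26 s. Three nearly decoupled monotone relationships are
solved by nested one-dimensional root finding (`uniroot`): the maximum
heating rate pins $g_\mathrm{heat}$ (full drive at ramp start ≈ ambient),
the heating duration pins $\lambda$ (the loss term sets how slowly the
controlled approach crawls), and the cooling duration pins
$g_\mathrm{cool}$. The procedure is deterministic, so the packaged
reference config regenerates bit-identically (`make_reference_configs()`).

**Identifiability.** The cooling maximum rate (2.2 °C/s published) is
over-determined: under the annealing gains the descent is saturated early
and controller-limited late, and any first-order plant matching the 26 s
duration necessarily cools faster than 2.2 °C/s at full drive (the fit
achieves ~5.4 °C/s). The residual is reported in the fit object rather
than hidden; matching it would require plant structure (e.g. a thermal
lag) that the published data cannot constrain.

The fitted loss coefficient is small (~2.4 × 10⁻⁴ s⁻¹): over the 25–110 °C
range the insulated block–sink stack loses heat slowly relative to what
the Peltier element pumps, so both ramps are essentially actively driven.

## Heated lid

The lid has no PID or PWM regulation: a hysteresis thermostat
(`lid_thermostat()`, band 2 °C centred on 105 °C) switches the full 14 W
drive. Its plant gain is 0.8 °C/s at full drive, and its loss coefficient
is set to 0.8/195 s⁻¹ so that the unregulated equilibrium equals the
element's ~220 °C dry-firing surface temperature — the one lid constant
the bill of materials provides. There are no published lid ramp data to
fit against; the simulated lid settles within ±2 °C of the setpoint, the
published stability band, verified by `simulate_lid()` +
`lid_statistics()`.

## Protocol engine

`expand_protocol()` unrolls a protocol into `2 + 3 × cycles` stages. The
packaged reference protocol is 30 cycles of 95 °C/15 s, 55 °C/15 s,
72 °C/60 s with the lid at 105 °C; the initial-denaturation (180 s) and
final-extension (300 s) holds are conventional values, *not* published
ones. A stage's hold timer starts when the *measured* temperature first
enters a ±1 °C band around the target — sized to the published
steady-state figure — and the timer does not pause if the temperature
briefly leaves the band (the device's behaviour here is unpublished; not
pausing is the simpler reading and is documented). A stage that has not
entered its band after 300 s aborts with a stalled-protocol error naming
the stage, which distinguishes mis-tuned configurations from infinite
loops.

Ramp segments belong to the stage being entered, so the 95 → 55 °C
descent is the annealing stage's ramp; this makes per-stage metrics
unambiguous.

## Metrics

`detect_ramps()` spans each ramp from the stage-transition sample to the
first sample at or beyond the new target; the start temperature is taken
at the transition sample, matching how the instrument's ramps are quoted.
The average rate is $|\Delta T|$ divided by the un-rounded duration. The
maximum rate uses a centred 1 s moving-window slope: per-tick differences
at 10 Hz would be dominated by the ≈0.48 °C sensor quantization steps and
would fabricate rate spikes. The window width is a choice (the published
analysis does not state one); 1 s resolves the fastest observed rate
while averaging ~10 samples.

`hold_statistics()` drops the first 5 s of each hold (the published
"steady state" has no stated onset; 5 s covers the entry transient) and
reports the maximum absolute and mean signed errors, plus the peak
overshoot beyond the target over the whole stage. `lid_statistics()`
reports the maximum deviation after the first setpoint crossing.

## What the twin does and does not emulate

The generator reproduces the *control* physics: gain-scheduled discrete
PID with 8-bit saturation, asymmetric first-order thermal response fitted
to the published ramps, ADC quantization, Gaussian sensor noise, and an
unregulated lid. It deliberately omits: spatial gradients across the four
wells (the infrared-verified uniformity), the thermal lag between block
and tube contents, heat-sink and fan dynamics as separate states, supply
voltage sag, and sensor self-heating. Consequently, passing tests show
that the control algorithm and its published performance envelope are
mutually consistent under this plant model — they do not certify
amplification performance or cross-well uniformity of any physical
device.

Two published observables are knowingly not matched exactly: the cooling
maximum rate (see identifiability above), and the quotient subtleties of
rounded ramp figures (68.61 °C / 38 s = 1.805 °C/s versus the published
average 1.78 °C/s — the published duration is evidently rounded to whole
seconds; the twin is calibrated to the printed durations and its average
rates agree with the printed ones to within ~0.04 °C/s).

## Problem sizes and runtime

The full 30-cycle protocol is ~82 simulated minutes ≈ 49 000 plant ticks
and ~24 500 controller updates, about 4 s of wall time in plain R; the
plant calibration solves ~200 short closed-loop ramps in under 2 s. The
test suite runs one full-protocol simulation (shared across tests), the
plant calibration twice, and property checks on hundreds of randomized
controller/plant steps.

## Reproducibility

Every random draw in a simulation derives from the `seed` in
`simulation_config()`; identical seeds give bit-identical traces, and
trace CSVs round-trip exactly (readr writes shortest round-trippable
doubles). The packaged reference configurations are committed *and*
regenerable; the regeneration path (`make_reference_configs()`, also
exposed as the `make-fixtures` CLI subcommand) is the source of truth.
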