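# pcrtwin

A hardware-free digital twin of a portable, low-cost PCR thermal cycler.

Polymerase chain reaction (PCR) amplifies DNA by cycling a sample block
through denaturation (~95 °C), annealing (~55 °C) and extension (~72 °C)
stages, 25–35 times. Portable instruments built around a thermoelectric
(Peltier) block, an Arduino-class microcontroller, an LM35 analog sensor
and a heated lid regulate those stages with a *piecewise* (gain-scheduled)
PID controller on an 8-bit PWM drive. pcrtwin reproduces that whole
control loop in software so that the controller design, calibration
procedure and published performance envelope can be studied, re-derived
and regression-tested without hardware. It is aimed at instrument
developers and teaching labs who want to probe the control algorithm —
gains, loop rate, anti-windup, quantization effects — before touching a
soldering iron.

## The model

Each controller update evaluates the discrete PID law exactly as the
firmware writes it,

    E(n) = Tt(n) − Ts(n),   I = Σ E(i),   D(n) = E(n) − E(n−1)
    U(n) = Kp·E(n) + Ki·I(n) + Kd·D(n)

with |U| saturated at 255 (8-bit PWM) and the sign of U choosing heat or
cool. Gains switch per PCR stage: (Kp, Ki, Kd) = (15, 1, 7) at 95 °C,
(9, 0.1, 5) at 55 °C, (13, 1, 10) at 72 °C (controllers PID1–PID5).
The block is a lumped first-order plant with asymmetric drive gains,

    dT/dt = g(u)·u/255 − λ·(T − T_ambient),

whose three parameters are calibrated so the closed loop reproduces the
instrument's measured ramps (26.39→95 °C in 38 s, max 2.8 °C/s;
94.83→55 °C in 26 s). The sensor chain applies the calibration line
T = (Vout + a)/b with a = 19.50 mV, b = 10.14 mV/°C, Gaussian voltage
noise and 10-bit ADC quantization (4.88 mV ≈ 0.48 °C per count). The
heated lid runs open-loop under a ±1 °C hysteresis thermostat at 105 °C.
See `vignette("digital-twin-methods")` for assumptions, parameter
rationale and known limitations.

## Worked example

Simulate the packaged 30-cycle protocol (95 °C/15 s, 55 °C/15 s,
72 °C/60 s, bracketed by 180 s / 300 s holds) on the reference instrument
model and summarise its performance:

```r
library(pcrtwin)
library(dplyr)

tr <- run_protocol(config = simulation_config(seed = 1))

detect_ramps(tr) |>
  select(stage_label, start_temp_C, duration_s, avg_rate_C_per_s,
         max_rate_C_per_s) |>
  head(4)
#>   stage_label              start_temp_C duration_s avg_rate_C_per_s max_rate_C_per_s
#> 1 001_initial_denaturation         26.4       37.8            1.82            2.80
#> 2 002_denaturation                 95.1       NA             NA               0.0126
#> 3 003_annealing                    95.1       25.7            1.56            5.38
#> 4 004_extension                    54.7       21.6            0.803           2.34

hold_statistics(tr) |>
  group_by(target_C) |>
  summarise(holds = n(), worst_error_C = max(max_abs_error_C))
#>   target_C holds worst_error_C
#> 1       55    30         0.366
#> 2       72    31         0.904
#> 3       95    31         0.747

lid_statistics(tr)
#>   first_crossing_s max_abs_dev_C
#> 1             129.          1.24
```

The first ramp reaches 95 °C in 38 s (average 1.8 °C/s, peaking at
2.8 °C/s), the first cooling ramp reaches 55 °C in about 26 s, every one
of the 92 holds stays within 1 °C of its target after a 5 s settling
exclusion, and the lid holds 105 ± 2 °C — the published performance
envelope of the physical instrument. (The `002_denaturation` row has no
ramp duration because the block is already at temperature when that stage
begins.) Calibration works the same way in simulation as at the bench:

```r
fit <- fit_calibration(make_calibration_fixture())
fit
#> <calibration_fit> a = 19.5000 mV, b = 10.1400 mV/degC (n = 15, max |resid| = 1.64e-14 degC)
calibration_error_report(cal = fit, seed = 1)
#>   max_abs_error_C mean_abs_error_C     n
#> 1           0.414            0.139   300
```

`autoplot(tr)` draws the full thermal-cycling curve;
`plot_hold_errors(tr)` shows per-stage hold accuracy.

## Command-line tool

A thin CLI wraps the same functions (find it with
`system.file("cli", "pcrtwin", package = "pcrtwin")`):

```sh
pcrtwin simulate  --protocol protocol.yaml --out trace.csv --seed 1
pcrtwin calibrate --samples bath.csv --out sensor.yaml
pcrtwin analyze   --trace trace.csv --out report     # exits non-zero on QC failure
pcrtwin make-fixtures --out fixtures/
```

Configs are YAML, traces and calibration samples CSV, reports JSON+text;
every simulation writes a JSON run manifest alongside its trace.

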