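---
title: "Estimating ENDS aerosol emission factors from exposure-chamber measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ENDS aerosol emission factors from exposure-chamber measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberEF)
```

## The measurement problem

Electronic nicotine delivery systems (ENDS) release dense aerosols whose
number and mass output per puff — the *emission factor* (EF) — is the
quantity that exposure and toxicology studies need. EFs cannot be read off a
particle counter directly: a puff machine fires puffs into a ventilated or
unventilated exposure chamber, instruments sample size-resolved number
concentrations (an SMPS covering roughly 7–300 nm and an OPS covering
0.3–10 µm), and the emission must be reconstructed from the chamber
concentration history while particles are simultaneously being lost to
deposition and air exchange.

chamberEF implements that reconstruction, together with a forward model of
the chamber that generates synthetic instrument data with known ground
truth, so every estimator in the chain can be validated by recovery tests.

## The chamber model

Each diameter bin of a well-mixed chamber of volume $V_c$ obeys the
first-order mass balance

$$\frac{dC}{dt} = \frac{S(t)}{V_c} - (\lambda + \beta_{dep})\,C,$$

where $C$ is the bin's number concentration (#/cm³), $S(t)$ the source rate,
$\lambda = \mathrm{ACH}/3600$ the ventilation rate in s⁻¹ and $\beta_{dep}$
a first-order deposition loss. `simulate_chamber()` injects each puff as an
instantaneous well-mixed impulse $E_{bin}/V_c$: a 3 s puff and the 1 L
mixing volume of the generator are three to four orders of magnitude smaller
than chamber time scales (a 6 m³ chamber turns over in 20 min at 3 h⁻¹), so
resolving the within-puff transient would change nothing downstream while
giving up the exact piecewise-analytic solution

$$C(t) = \sum_{p:\,t_p \le t} \frac{E_{bin}}{V_c}\,
  e^{-(\lambda + \beta_{dep})(t - t_p)}.$$

Per-puff particles are allocated to bins by the cumulative lognormal of the
source modes evaluated at the bin edges. The allocation is not renormalized:
particles whose diameters fall outside the instrument grid are simply never
seen, exactly as in a real measurement, and the captured fraction is
attached to the simulation output (`capture_fraction`; it exceeds 0.999 for
the default sources on the default 7–10000 nm composite grid). Conservation
tests therefore compare airborne particles against the number injected *into
the grid*.

Two instrument behaviours are modelled. Measurement noise is multiplicative
lognormal (`noise_spec()`, default geometric SD 1.05 — a typical
scan-to-scan repeatability for condensation-counter-based sizers) with
optional Poisson counting noise; it is applied to the exact solution, after
which `apply_instrument()` clips values at the detection ceiling (3000 #/cm³
for the OPS used in the study conditions) and flags them. Saturated samples
are excluded from decay windows rather than treated as data.

What the generator deliberately does **not** emulate: coagulation,
condensation/evaporation and hygroscopic growth. Real ENDS aerosol coarsens
over a run (the averaged geometric mean diameter of pod emissions drifts
from roughly 68 to 97 nm as puffs accumulate); in the simulator a drift can
only be imposed, not emerge. Passing recovery tests therefore demonstrate
that the estimators are correct *for first-order chamber physics*, not that
the physics captures every aerosol process in a real chamber.
`gmd_trajectory()` exists to quantify such drifts in measured data.

## Loss coefficient

After the last puff the source term vanishes and every bin decays as
$e^{-\beta t}$ with $\beta = \lambda + \beta_{dep}$. `fit_decay()` estimates
$\beta$ as minus the slope of the ordinary least-squares regression of
$\ln C$ on $t$ — closed-form, scale-invariant, and exact on clean
exponentials; a Levenberg–Marquardt fit of the exponential itself is
available via `method = "nls"` for cases where log-transformation would
distort the error structure. The estimate is deliberately *empirical*: in
the ventilated scenario it absorbs ventilation and deposition together,
because that combined rate is precisely what the emission estimator must
undo. A negative fitted rate (rising concentration in the window) is
flagged, never silently used. Units are s⁻¹ throughout — a first-order loss
coefficient must carry inverse time for the mass balance to be dimensionally
consistent.

`pick_decay_window()` applies the window rule: start at the last puff plus a
mixing lag (default 120 s, a conservative chamber mixing time at the default
fan-stirred conditions) and run to the end of the series, truncating before
the first saturated sample.

## Total emission and emission factors

Integrating the mass balance over one sampling interval $\Delta t$ gives the
per-interval source reconstruction

$$\Delta TP_i = V_c\left(C(t_i) - C(t_{i-1})\,e^{-\beta \Delta t}\right),$$

and `total_emission()` sums the increments over the emission window
(default: one interval before the first puff to 120 s after the last). Two
limiting cases pin the estimator down and are enforced in tests: at
$\beta = 0$ the sum telescopes exactly to $V_c(C_{stop} - C_{start})$, and
for constant concentration it returns the loss-replenishment rate
$V_c C (1 - e^{-\beta\Delta t})$ per interval. A published variant of the
estimator reads as carrying an extra $e^{-\beta\Delta t}$ divisor; it is
available as `form = "alt"` and agrees with the default to first order in
$\beta\Delta t$, but only the default telescopes exactly, which is why it is
the default. Negative increments are kept (unbiased under symmetric noise);
`clip_negative = TRUE` exists for heavily saturated traces.

Emission factors divide by the puff count and rescale by the dilution
factor — the ratio of flow into the generator to flow into the chamber,
applied identically to number and mass since a flow split acts on all
particles alike (`EF = DF × TP / n_{puffs}`, `dilution_factor()` returns 1
for the static chamber). Mass conversion assumes spheres of density
1 g/cm³ (e-liquid aerosol is a PG/VG/water droplet, density within a few
percent of 1): per-bin mass is $(\pi/6) d^3 \rho$ at the geometric bin
midpoint, reported in µg.

Because which $\beta$ (total-trace or per-bin) underlies published mass EFs
is ambiguous, both modes exist; `estimate_emissions()` uses the total-trace
$\beta$ with per-bin increments, so number and mass EFs derive from one
consistent loss correction.

## Size modes

`normalize_distribution()` produces $dN/d\log_{10}D_p$; `fit_modes()` fits a
1- or 2-mode lognormal mixture by Levenberg–Marquardt in linear
concentration space (matching how such fits are judged against plotted
spectra; a log-space objective is available for dynamic-range-heavy coarse
tails). Parameters are transformed so the optimizer is unconstrained:
amplitudes as $\log N$, locations as $\log_{10}$ GMD, widths as
$\log(\mathrm{GSD} - 1)$.

Model selection (`n_modes = "auto"`) uses BIC under a *multinomial*
likelihood: the per-bin integrated counts are a size-$N$ multinomial sample
of the fitted bin fractions, so $\mathrm{BIC} = -2\sum_i n_i \log p_i +
3k \log N$. An equal-variance Gaussian criterion was rejected because
counting noise scales with bin counts, which lets a spurious second mode
"absorb" peak noise; the multinomial form selects the true mode count in
at least 95% of sampled spectra at $N = 10^4$ in the test suite, for both
unimodal (100 nm) and bimodal (58.2 nm / 794 nm, the Aitken/accumulation
pair typical of mod-type devices) truths.

Bimodal initialization is deterministic: split the 3-point-smoothed spectrum
at its deepest internal minimum, requiring at least 5% of the total count on
each side (without the mass constraint, noise dips in the sparse tails
masquerade as the inter-mode valley), then moment-estimate each side; a
median split is the fall-back. Non-convergence raises an error carrying the
optimizer diagnostics.

Two GMD conventions exist in practice — the GMD of the time-averaged
distribution and the per-scan GMD trajectory — and the package exposes both
(`gmd_gsd()` on an averaged distribution; `gmd_trajectory()` per scan)
rather than guessing which a given report used.

## Replicates and comparisons

A replicate is one vaping experiment. `summarize_group()` reports
mean ± standard error; `compare_groups()` runs a two-sided unpaired t-test
at $\alpha = 0.05$, Welch by default (device types and scenarios differ in
variance; the pooled Student form is available by flag, and pairing is not
assumed since replicate experiments are independent runs). Zero-variance
groups are flagged as degenerate rather than reported with a meaningless
statistic. A Monte-Carlo calibration in the test suite checks the Welch
path holds its nominal size, using 10 replicates per group — small enough
to be experiment-like, large enough that the Welch statistic is near
nominal and 1000 null replicates resolve the rejection rate.

## Default study conditions

The defaults encode the study conditions the package is built around: a
6 m³ chamber; static (0 ACH) and dynamic (3 h⁻¹) scenarios; the CORESTA
square-wave puff (55 mL over 3 s, 1.1 LPM mean flow); 20-puff pod and
4-puff mod static experiments; loss coefficients of 1.34 × 10⁻⁴ s⁻¹ (pod)
and 2.20 × 10⁻⁴ s⁻¹ (mod); a unimodal ~100 nm pod source and a bimodal
58.2/794 nm mod source (GSDs 1.7 and 1.6 — values typical of fresh
vaping aerosol, since source widths are rarely printed); 10⁹–10¹⁰ particles
per puff; 32 SMPS bins and 16 OPS bins. Schedules place the first puff 60 s
into the record so the pre-vaping baseline brackets the first concentration
step — without a baseline sample the first puff's rise is invisible to any
increment-based estimator. Per-puff device power declines linearly with
puff index in synthesis (7 W pod intercept, −0.005 W/puff) to emulate coil
ageing across the initial/middle/late puff fractions (1–50, 51–100,
101–150, inclusive on both ends).

Test problem sizes were chosen so the full suite exercises every stage at
instrument-like resolution (48-bin composite grids, hundreds to ~2000 time
samples, 50–100 stochastic replicates for calibration checks) while running
in seconds.

## Known limitations

* First-order, size-independent losses by default; a per-bin `beta_dep`
  vector can emulate faster coarse-mode deposition but no mechanistic
  deposition model (and no coagulation/condensation) is included.
* The well-mixed assumption is adopted without a mixing-time model; the
  mixing lag is a user parameter, not an estimate.
* Absolute published EF magnitudes cannot be reproduced from summary
  statistics alone; the package instead ships the published reference EF
  table (`reference_emission_factors()`) for ratio and unit-conversion
  work, and validates its own estimators by recovery on synthetic truth.
* The power–mass-EF correlation analysis runs on synthetic per-fraction
  data; real per-fraction power traces must be supplied by the user.
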