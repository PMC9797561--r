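---
title: "Methods: in-silico cardiomyocyte twitches in hypertrophic cardiomyopathy"
author: "hcmtwitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico cardiomyocyte twitches in hypertrophic cardiomyopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hcmtwitch` simulates stimulus-evoked twitches of human cardiomyocytes and
uses them to ask a genotype-specific question about hypertrophic
cardiomyopathy (HCM): which sarcomeric remodelling reproduces the cellular
phenotype of each variant, and which pharmacology undoes it. The package
covers three variant classes — a thick-filament mutation that destabilises
the myosin super-relaxed state (`MYH7` R403Q), and two thin-filament
mutations acting through troponin/tropomyosin calcium handling (`TNNT2`
R92Q, `TNNI3` R21C) — plus in-silico trials of Mavacamten, calcium-handling
interventions and an idealised thin-filament calcium desensitiser.

This vignette is the package's methods account: the model, its
assumptions, the tunable parameters, the synthetic-data rationale, the
numerical choices, and the known limitations.

## The cell model

The model couples two subsystems through calcium-troponin buffering into a
seven-state ODE system integrated per pacing cycle.

### Myofilament activation

Four states describe thin-filament activation and crossbridge cycling:
troponin calcium occupancy `CaTRPN`, blocked tropomyosin fraction `B`,
weakly bound crossbridges `W` and strongly bound, force-generating
crossbridges `S`; the unblocked, non-crossbridge fraction is the
complement `U = 1 - B - W - S`, so occupancy conservation is exact by
construction.

$$
\begin{aligned}
\frac{d\,\mathrm{CaTRPN}}{dt} &=
  k_{on}\left(\frac{[\mathrm{Ca}^{2+}]_i}{\mathrm{Ca_{50,eff}}}\right)^{n_{trpn}}
  (1-\mathrm{CaTRPN}) - k_{off}\,\mathrm{CaTRPN} \\
\frac{dB}{dt} &= k_{ub}\,\min(\mathrm{CaTRPN}^{-n_{tm}/2},
  c_{max})\,U - k_{bu}\,\mathrm{CaTRPN}^{n_{tm}/2}\,B \\
\frac{dW}{dt} &= k_{uw}\,\alpha(R)\,U - (k_{wu}+k_{ws})\,W \\
\frac{dS}{dt} &= k_{ws}\,W - k_{su}\,S
\end{aligned}
$$

Active tension is the isometric map $T_a = T_{ref}\,S$ (the extension
ratio is fixed at 1; there is no length or velocity dependence).

The troponin rate constants are split deliberately: `Ca50` enters only the
binding (driving) term, while `k_off_trpn` is an independent dissociation
rate. This is what lets the `TNNI3` remodelling scale `k_off` without
redefining `Ca50` — with the documented consequence that scaling `k_off`
alone also shifts effective steady-state sensitivity, which is acceptable
because the thin-filament remodellings scale `Ca50` and `k_off` jointly.

### Myosin availability (DRX:SRX)

Myosin heads partition between the super-relaxed state (SRX; unavailable
for actin binding) and the disordered relaxed state (DRX; available). The
parameter $R$ rescales the control DRX:SRX odds $\rho_0$, giving the DRX
fraction $f(R) = R\rho_0/(1+R\rho_0)$ and the availability multiplier
$\alpha(R) = f(R)/f(1)$ that scales crossbridge attachment ($k_{uw}$).
$R = 1$ is control; $R = 1.3$ is the experimentally measured SRX deficit of
`MYH7` R403Q. A configuration switch (`r_on_tref`) alternatively routes the
multiplier through `T_ref`; the attachment-rate route is the default
because it keeps duty-cycle dynamics responsive to availability.

### Myosin-to-thin-filament feedback

Availability alone turns out to raise twitch amplitude without slowing
relaxation. To express the hypothesis that myosin-based activation feeds
back onto thin-filament calcium sensitivity, the effective
$\mathrm{Ca_{50,eff}}$ carries a feedback factor:

* `fb_mode = "off"` — no feedback (default),
* `fb_mode = "static"` — factor $1 - \gamma_{fb}(R-1)$, clipped to
  `[fb_lo, fb_hi]` (default `[0.5, 1.5]`); excess available myosin
  sensitises the thin filament,
* `fb_mode = "dynamic"` — an exploratory form driven by instantaneous
  crossbridge occupancy `(W+S)` relative to a configured control reference.

The static form is the default study choice because it is the simplest
form that captures the mechanism and makes drug effects on $R$
automatically reverse the feedback. The gain default
$\gamma_{fb} = 0.5$ was calibrated once so that the `MYH7` scenario
($R = 1.3$, feedback on) prolongs tension RT90 appreciably (about +15%)
while feedback off leaves it essentially unchanged (< 2%).

### Calcium handling

A reduced calcium subsystem replaces a full ventricular electrophysiology
model: states are free cytosolic calcium `Cai`, SR calcium `Ca_sr` and a
release gate `g` incremented by `g_amp` at each stimulus and decaying with
time constant `tau_rel`. Fluxes: SR release `k_rel * g * Ca_sr`, SERCA
reuptake with Hill kinetics (`V_serca`, `K_serca`, `h_serca`), linear
extrusion towards diastolic calcium (`k_ncx`, `Ca_dia`), and a square
trigger-influx pulse (`A_in` for `d_in` ms) standing in for L-type current.
Instantaneous calmodulin-like buffering enters through the rapid-buffering
factor $\beta(\mathrm{Cai})$, and troponin buffering couples
bidirectionally through $J_{trpn} = \mathrm{TRPN}_{tot}\,
d\mathrm{CaTRPN}/dt$ — this bidirectional coupling is essential: it is how
`k_off` remodelling reshapes the calcium transient (accelerated rise,
decelerated decay).

Because there is no membrane model, late-sodium block is represented
phenomenologically as enhanced forward extrusion (`alpha_nal`, default
0.3): reduced sodium load strengthens forward exchange. Only its
directional behaviour (mildly faster relaxation, partial
anti-hypercontractility) is asserted.

## Parameter defaults

All defaults are calibration values, fixed once against the target control
phenotype at 1 Hz pacing: diastolic calcium near 0.1 uM, calcium-transient
amplitude 0.3-0.5 uM, tension amplitude near 15 kPa, tension RT90 near
400 ms, convergence to a periodic twitch well inside 500 beats. Units are
ms, uM and kPa throughout. Two defaults deserve explanation:

* **Trigger influx shape** (`A_in = 0.04` uM/ms for `d_in = 100` ms,
  4 uM total charge per beat). A short, sharp pulse puts a kink in the
  calcium transient exactly at the pulse end, and for many sampled models
  that kink becomes the global maximum — pinning the time-to-peak
  biomarker to the pulse duration and erasing its dependence on troponin
  kinetics. Spreading the same charge over 100 ms at low amplitude leaves
  the peak release- and buffering-driven, which is the regime in which
  slowed troponin dissociation (TNNI3) visibly accelerates the calcium
  rise.
* **SERCA Hill coefficient 3 with half-saturation 0.5 uM.** With a shallow
  pump curve the pump outcompetes extrusion at diastolic calcium and the
  SR loads without bound; the steeper curve gives a stable diastolic
  balance point near `Ca_dia` while still dominating the decay phase.

## Simulation protocol

Cells are paced at cycle length 1000 ms (1 Hz). The release-gate increment
is applied as a discontinuous state update at each cycle start, and the
integrator restarts at these events. Integration uses `deSolve::lsoda`
(stiff-capable, adaptive) over a compiled C right-hand side; the exported
R derivative functions implement the same equations and the two routes are
cross-checked in the test suite. Steady state is declared when the state
vector sampled at successive cycle starts changes by less than `tol`
(default 1e-6 relative, floored at 1e-9 absolute), with a 500-beat cap
that reports `converged = FALSE` rather than failing. Recorded traces are
resampled on a 1 ms grid; biomarker threshold crossings are linearly
interpolated below grid resolution.

Solver tolerances default to `rtol = 1e-8`, `atol = 1e-10`, maximum step
10 ms; tightening them tenfold moves steady-state biomarkers by less than
0.5%, which is the package's definition of solver robustness.

## Biomarkers

Per channel (tension, calcium): amplitude = peak minus pre-stimulus
baseline; time to peak from the stimulus; RT50/RT90 from the peak to
50%/90% decay of the amplitude; TD50/TD95 from the stimulus to the decay
crossing (used for calibration); diastolic value. The baseline is the
pre-stimulus sample — at steady state this is identical to the
end-diastolic minimum, which settles the ambiguity between the two
conventions. Flat channels report amplitude 0 with undefined time metrics;
truncated decays flag the affected metric as undefined with a warning
instead of fabricating a value (strong myosin inhibition can genuinely
push the 90% crossing out of the window). The tie-break for noisy plateaus
takes the first crossing after the last sample within `1e-3 * amplitude`
of the peak.

## Populations of models

An initial population is built by Latin hypercube sampling of
multiplicative scalings in [50%, 200%] of baseline over eight
calcium/myofilament axes: `g_amp`, `V_serca`, `K_serca`, `k_ncx`, `Ca50`,
`k_uw`, `k_ws`, `TRPN_tot`. The reference pipeline samples membrane
conductances as well; without a membrane model those axes cannot be
represented, which is a documented deviation — the population expresses
calcium-handling and myofilament variability only.

Calibration accepts a model iff every calibrated biomarker (tension
amplitude and RT90, calcium amplitude, TD50, TD95) lies inside its range.
Experimental calibration ranges are not available, so the package derives
synthetic ranges as percentiles of the simulated control population
(`synth_calibration_ranges`, defaults 2.5/97.5). The study pipeline
(`build_study_population`) calibrates more stringently, at the 15th-85th
percentile per biomarker. The reasoning: experimentally calibrated
populations of this kind typically reject most of the raw sample (on the
order of 80%), and at that selectivity the control population is
homogeneous enough for genotype effects (15-25% shifts in relaxation) to
stand out of the inter-model spread. At 2.5/97.5 joint acceptance is about
85% and the genotype structure drowns. The 15/85 choice (joint acceptance
roughly 35-40%) is the loosest stringency that approximates the reference
selectivity; users supply their own ranges file for experimentally
grounded calibration.

Default problem sizes: the sampling routine reproduces full paper-scale
draws (n = 2000 is exercised in the test suite for the stratification
property); simulation-backed studies in the tests and the acceptance
script use n = 300 sampled models (about 110 accepted), which is the size
at which population medians of all reported biomarkers are stable to a few
percent across seeds.

## Genotypes, drugs and interventions

* `MYH7_R403Q`: `R = 1.3` with static feedback on.
* `TNNT2_R92Q`: `Ca50 x 0.7` and `k_ub x 0.8` (the blocked/unblocked
  reverse rate, i.e. the K_B knob).
* `TNNI3_R21C`: `Ca50 x 0.7` and `k_off_trpn x 0.5`.

Scaling specs compose by elementwise multiplication, so drugs apply on top
of genotypes; `R` composes multiplicatively like any other factor.

Mavacamten is modelled as Hill inhibition of `R`:
$R(c) = R_{base}(1 - E_{max} c^h/(c^h + IC_{50}^h))$. The dose-response
constants are calibration products, not literature constants: the shipped
defaults ($E_{max} = 0.6$, $IC_{50} = 0.65$ uM, $h = 1.8$) solve the
reference-rescue condition that 0.5 uM returns the `MYH7` availability
excess to control ($1.3 \to 1.0$), and `calibrate_dose_response()`
reproduces them from amplitude-ratio target points by deterministic
Nelder-Mead least squares. Clinical ng/ml concentrations convert to uM
through `ng_per_ml_to_uM()`, which requires the molar mass and plasma free
fraction as explicit inputs (no defaults are assumed for compound
constants).

Interventions: L-type block scales the trigger influx by `(1 - level)`;
SERCA upregulation scales uptake by `(1 + level)`; late-sodium block sets
the extrusion-enhancement fraction; the designed desensitiser scales
`Ca50` by `(1 + level)`, chosen because at level 0.5 it approximately
inverts the variants' `Ca50 x 0.7` sensitisation (a reciprocal mapping
`1/(1 - level)` is selectable).

## Sensitivity analysis

Absolute sensitivities are normalised central differences: simulate at
parameter scalings `1 - delta` and `1 + delta` and divide the relative
biomarker change by `2 delta`. The measure is unit-free and symmetric;
one-sided variants exist for biomarkers undefined on one side, and
undefined cells propagate as missing rather than fabricated. Conventional
perturbations are 30% for `Ca50` and `k_ub` and 50% for `k_off_trpn`.
Sensitivities are evaluated on the baseline model by default — in the
reference workflow the sensitivity analysis is what selects the variant
remodelling before any population exists — with a `population` argument
for population-median summaries (median chosen for robustness to skewed
biomarker distributions; time-to-peak medians are additionally quantised
by the 1 ms grid, another reason the baseline default is the cleaner
surface).

## Statistics

Simulated population comparisons use the Mann-Whitney U test (exact null
distribution for combined n of 12 or fewer without ties, tie-corrected
normal approximation otherwise) and Kruskal-Wallis with Dunn's post hoc
pairwise z-tests. The Dunn multiplicity adjustment defaults to the
classical Dunn-Bonferroni family correction and is selectable. The
significance convention is p < 0.05. Normality-based tests are not
implemented for simulation output; they belong to experimental-data
workflows out of this package's scope.

## Synthetic data

Every fixture is generated in code from seeds. The synthetic twitch is a
two-exponential pulse chosen because its peak time and decay have closed
forms, giving exact oracles for the biomarker extractor; synthetic cohorts
are Gaussian groups with specified shifts for calibrating the statistics
layer (type-I error and power are checked by Monte Carlo in the
acceptance suite). What the generators do not emulate: motion artefacts,
photobleaching and baseline drift of fluorescence recordings, beat-to-beat
alternans, or inter-lab normalisation differences — so passing tests
demonstrate correctness of the computational pipeline on clean,
in-distribution inputs, not robustness to raw experimental recordings.

## Known limitations

* Dual therapy (SERCA upregulation 0.5 plus 0.5 uM Mavacamten on
  `TNNT2` R92Q) resolves the relaxation defect, and the Mavacamten
  component reliably reduces the SERCA inotropic excess, but the residual
  median tension amplitude stays somewhat above the control interquartile
  range: in this reduced model SERCA's positive inotropy outweighs a
  0.5 uM availability reduction. The package asserts the relaxation
  resolution and the direction of the amplitude correction, not full
  amplitude normalisation by the dual arm.

* No membrane electrophysiology: no action-potential biomarkers, no
  AP-based calibration, no conductance population axes; late-sodium block
  is phenomenological.
* Isometric, length-fixed contraction: no length-dependent activation,
  shortening velocity, or passive viscoelasticity; tension is `T_ref * S`.
* The feedback form and gain, the control DRX:SRX proportions
  (`rho0 = 1`), and the dose-response constants are calibration choices
  constrained by directional behaviour, not measured quantities.
* Organ-level endpoints (ejection fraction, ECG, pressure-volume loops)
  are out of scope; cellular biomarkers are the terminal output.

## A worked pipeline

```{r pipeline}
library(hcmtwitch)

pop <- build_study_population(n = 300, seed = 1)
ctrl <- pop[pop$accepted, ]

tnnt2 <- run_population(pop, variant_spec("TNNT2_R92Q"))
rescue <- run_population(
  pop, combine_specs(variant_spec("TNNT2_R92Q"),
                     intervention_spec("desensitiser", 0.5)))

scenario_report(list(control = ctrl, TNNT2 = tnnt2, rescued = rescue),
                compare = "kruskal_dunn")
```
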