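---
title: "Nucleosome mechanics from magnetic-tweezers trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome mechanics from magnetic-tweezers trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtweezers)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices behind the results, and what
the bundled simulators can and cannot say about real data.

## The physical picture

A nucleosome reconstituted on a DNA fragment is held between a glass surface
and a superparamagnetic bead. Moving a magnet pair toward the bead ramps the
tension; the tether's extension reports the wrapping state. Under a slow
ramp an intact nucleosome unfolds in two discrete steps — the outer DNA wrap
at low force and the inner wrap at high force — each visible as a sudden
extension jump. A tetrasome (DNA on an H3–H4 tetramer only) unfolds in one
step. Between discrete transitions the extension follows equilibrium polymer
elasticity.

## Worm-like-chain elasticity

All extensions are modelled by the Marko–Siggia interpolation for an
inextensible worm-like chain,

$$\frac{fA}{k_BT} \;=\; \frac{1}{4(1-z)^2} \;-\; \frac14 \;+\; z,
\qquad z = x/L,$$

with persistence length $A$ (50 nm for dsDNA, the default everywhere) and
contour length $L$. The relation is strictly monotone in $z$, so the inverse
$z(f)$ is obtained by bracketed bisection on $z \in [0, 1-10^{-12}]$,
stopped when the force residual falls below $10^{-9}$ pN. Bisection is
slower than Newton iterations but unconditionally convergent, and the
inversion is vectorised so whole force grids are solved at once.

No stretch modulus is included: the experiments modelled stay below about
30 pN, where enthalpic stretching of dsDNA contributes little, and adding a
stretch modulus would introduce a parameter the data cannot constrain.

Thermal energy is $k_BT$ at 25 °C ($T = 298.15$ K, $k_B = 0.0138065$
pN nm/K, so $k_BT = 4.1164$ pN nm); energies convert to molar units at
0.60221 kJ/mol per pN nm.

## Free energy of unfolding the outer wrap

The force-dependent free-energy difference between the unfolded chain
(contour $L_{dna}$, extension $x_{dna}(f)$) and the folded particle
(contour $L_{ncp}$, extension $x_{ncp}(f)$) splits into a force-independent
cost $\Delta G_0$ and the stretching-work term

$$\Delta\Phi(f) = -\int_0^f \left[x_{dna}(f') - x_{ncp}(f')\right] df'.$$

At the equilibrium force $F_{eq}$ — where folding and unfolding rates are
equal, $\Delta G(F_{eq}) = 0$ — the unfolding cost is $\Delta G_0 =
-\Delta\Phi(F_{eq})$. The package computes this two ways:

* **Quadrature** (`delta_g0_quadrature()`): composite trapezoid integration
  of the extension difference on a force grid with step $5\times10^{-4}$ pN.
  The step was chosen so the quadrature agrees with an exact closed form
  (integration of the Marko–Siggia relation by parts) to better than
  $10^{-6}$ relative error, which the test suite verifies on random
  parameter triples. Trapezoid on a fixed grid was preferred to adaptive
  quadrature because it is trivially verifiable against that closed form.
* **Rip work** (`delta_g0_ripwork()`): the rectangle
  $F_{eq}\,[x_{dna}(F_{eq}) - x_{ncp}(F_{eq})]$.

For the reference outer-wrap geometry ($L_{dna} = 119$ nm, $L_{ncp} =
99$ nm, $F_{eq} = 3.5$ pN) the quadrature gives 35.7 kJ/mol and the rip
work 38.9 kJ/mol. The rip work always exceeds the quadrature (the WLC
relative extension increases with force), and the two conventions coexist in
the field's reports; `outer_wrap_energy()` therefore returns both rather
than silently preferring one.

Determining $F_{eq}$ itself (`equilibrium_force()`) follows two
conventions: the root of a straight-line fit to $\ln(k_{fold}/k_{unfold})$
against force when constant-force kinetics are available, and otherwise —
the default — the sample median of the outer-wrap rupture forces, which is
cheap and robust but biased slightly above the true equilibrium force for
any finite ramp rate.

## Trajectory simulation

Since the package must be exercisable without experimental data, every input
is generated by a seeded simulator, and the simulator's defaults *are* the
study conditions.

**Force ramp.** The magnet approaches at 10 μm/s; tension follows a
double-exponential force versus magnet-distance law
$F(z) = a_1 e^{-z/d_1} + a_2 e^{-z/d_2}$. The default law
$(a_1, d_1, a_2, d_2) = (80\ \mathrm{pN}, 0.3\ \mathrm{mm}, 6\ \mathrm{pN},
1.2\ \mathrm{mm})$ is a representative setup calibration: magnet laws are
per-instrument quantities that are re-fitted from calibration tables
(`fit_force_magnet_law()`) in any real analysis. Each cycle ramps from the
0.1 pN rest force up to 32 pN; the minutes-long rest between cycles is
collapsed to an instantaneous state reset (refold if allowed), recorded in
the trajectory metadata, because simulating idle minutes adds data volume
and no information.

**State kinetics.** Transitions between wrapping states follow Bell rates
$k(f) = k_0 e^{f x^\ddagger / k_BT}$, sampled by exact exponential waiting
times with the rate frozen at the interval-start force within each sample
interval. At the default sampling rates the force changes by well under
0.05 pN per interval, so the freezing error is far below the rupture-force
spread $k_BT/x^\ddagger$ (≈1.4 pN for the outer wrap). The zero-force rates
per condition are calibration constants committed once so that the detected
median rupture forces under the default protocol sit near the observed
medians (≈4/23 pN for the unmodified nucleosome, ≈2/15 pN for ubH2B,
≈10/20 pN for ubH2B with FACT, 16 pN for the tetrasome, ≈7 pN with FACT);
the barrier distances (3 nm outer, 1.5 nm inner) are typical of nucleosome
unwrapping. No dwell-time data or Bell parameters are published for these
constructs, so these are defaults that make the simulator realistic, not
claims about the molecules; no test asserts them except through
self-consistent recovery.

**Contour ladder.** Only the 119/99 nm pair is documented, so the state
ladder uses +20 nm for outer-wrap opening, +27 nm for the inner wrap
(roughly the remaining wrapped DNA of a 147 bp core particle), and +24 nm
for the single tetrasome step. All are configurable.

**Reversibility.** A nucleosome that fully unfolds without a chaperone does
not reassemble: with `reassemble = FALSE` later cycles start (and stay)
fully unfolded, so the two-step pattern appears in cycle 1 only. FACT-bound
conditions set `reassemble = TRUE` and refold at every reset.

**Noise.** Bead fluctuations ride on the extension as a stationary
Ornstein–Uhlenbeck process (exact discretisation), default sd 2 nm and
relaxation 10 ms. The calibration simulator derives its OU parameters
physically instead: stiffness $\kappa = F/\ell$, drag $\gamma = 6\pi\eta r$
(≈$2.35\times10^{-5}$ pN s/nm for a 1.4 μm bead in water), stationary
variance $k_BT\,\ell/F$ and corner frequency $F/(2\pi\gamma\ell)$
(22.6 Hz at 10 pN and 3 μm).

**Binding cycles.** Each force-jump cycle is an independent Bernoulli draw
with occupancy $[\mathrm{FACT}]/([\mathrm{FACT}] + K_d)$. The observable is
whether a disruption occurred at the probe force: 11 pN probes the
unmodified nucleosome (the inner wrap yields only when FACT is bound);
6 pN probes the ubH2B nucleosome (the outer wrap yields only when FACT is
absent). `classify_binding_cycle()` encodes exactly this complementary
logic.

**Reproducibility.** One root seed; stretch cycles use per-cycle substreams
seeded as $(\mathrm{seed} + 7919k) \bmod (2^{31}-1)$, so cycle $k$ is
reproducible independently of how many cycles precede it. Identical
configuration and seed give byte-identical output.

## Event detection choices

The detectors' thresholds are explicit parameters because the corresponding
experimental analyses rarely publish theirs.

* **Ruptures**: a sustained forward jump of ≥8 nm (≈4× the default noise
  sd) between adjacent window means (default 5 samples). The rupture force
  is read at the last pre-jump sample, which is what "rupture force" means
  under a monotone ramp; the jump size is re-measured with a 2-sample guard
  band around the located boundary so that a boundary mislocated by a sample
  under noise does not bias the size. The contour gain is the jump divided
  by the WLC relative extension at the rupture force.
* **Wrap classification**: first event in a cycle = outer, second = inner;
  a lone event is split at a 12 pN boundary (between the two force scales);
  in tetrasome mode every event is the inner wrap. The boundary is
  configuration, not a claim.
* **Dwells**: half-amplitude threshold with a ±25% hysteresis band;
  censored first/last dwells are dropped; no censoring-corrected MLE is
  attempted. Durations are quantised to the sampling interval.
* **Steps**: recursive binary segmentation on mean shifts, a split accepted
  when its Welch statistic exceeds 10 (pure-noise best splits grow only like
  $\sqrt{2\log n}$), followed by a pruning pass that re-tests each break
  against its adjacent final segments and drops the weakest — without
  pruning, genuine steps occasionally acquire a spurious neighbouring split.

## Kd estimation and uncertainty

$K_d = (N_{nucleosome}/N_{complex})\,[\mathrm{FACT}]$ over all cycles.
Uncertainty is a cycle-level nonparametric bootstrap (2000 resamples,
percentile CI, bootstrap SD as SE); resamples with no bound cycle leave the
estimate unbounded and are dropped with a reported count. How the original
measurements pooled molecules into one SE is not specified, so cycle-level
resampling is this package's declared choice; it treats cycles as
exchangeable, which the Bernoulli simulator satisfies by construction and
real data satisfy only approximately (molecule-to-molecule variability would
widen the truth). Condition comparison uses the bootstrap difference
distribution as the primary two-sided test with an exact two-proportion test
as cross-check, since the original significance statement names no test.

## Calibration choices

The spectral estimator is the mean of Hann-windowed, 50%-overlapping
modified periodograms (segment length the power of two nearest 4096),
normalised so the one-sided spectrum integrates to the variance. The
Lorentzian is fitted by least squares on log-PSD over log-spaced bins
between 0.5 Hz and half the Nyquist frequency: log-spacing balances the
decades, and capping at Nyquist/2 keeps aliasing of the sampled process out
of the fit. The plateau provides an independent force estimate
($F = \ell\sqrt{4k_BT\gamma/S_0}$) reported as a cross-check; variance and
spectral routes agree within 10% on simulated 5-minute records, which the
tests assert. Camera blur and aliasing corrections are deliberately
omitted — the modelled recordings specify none.

The magnet-law fit is multi-start nonlinear least squares with positivity
enforced through log-parameterisation. When the data are genuinely
single-exponential the two components are not identifiable, and only
prediction-level accuracy is promised.

## Problem sizes in the test suite

The simulation-backed tests run at desk scale, chosen once: ramp traces at
10–25 Hz rather than the 200 Hz protocol default (the force moves by
≈0.03 pN per sample at 25 Hz near the inner-wrap transition, far finer than
the 0.1 pN recovery tolerance), 200 cycles for detector recovery, 50
molecules × 5 cycles per condition for reversibility, 1000 force-jump
cycles per Kd estimate, 300 s of 500 Hz bead data for calibration, and 100
seeds for deposition-step recovery. These sizes keep the whole suite under
a minute while leaving every statistical tolerance dominated by the
estimator, not the sample size.

## Limitations

* The simulators emulate idealised instruments: no drift, no camera blur or
  aliasing, no bead-to-bead magnetisation spread, no surface hydrodynamic
  corrections, and OU noise of fixed amplitude rather than
  force-dependent tracking noise. Passing recovery tests therefore
  demonstrates correctness of the estimators under the stated model, not
  robustness to every artefact of real traces.
* Refolding transitions during the ramp are neglected (rates are heavily
  force-suppressed over the relevant range); hopping near equilibrium must
  be studied with the constant-force simulator instead.
* Dwell analysis drops censored dwells rather than modelling them; rates
  are biased for traces much shorter than a few dozen dwells.
* The two ΔG₀ conventions differ by design; users comparing against
  published numbers must pick the matching convention.
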