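---
title: "A population model of pancreatic insulin secretion by heterogeneous firing units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population model of pancreatic insulin secretion by heterogeneous firing units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletsim)
```

## The model

`isletsim` treats the endocrine pancreas as a large population of
independent secretory *firing units* — β-cells, islets of Langerhans, or
synchronized cell clusters — that share no coupling other than the glucose
concentration they all sense.  Unit $n$ carries a glycemic threshold
$B_n(t)$ (mM), a releasable insulin packet $J_n(t)$ (pmol/kgBW), and a
potentiation level $D_n(t)$ (pmol/kgBW):

* **Firing and refractoriness.**  Whenever sensed glycemia $G(t) \ge
  B_n(t)$ the unit discharges its entire packet, $J_n$ resets to zero, and
  the threshold jumps to a refractory level $R_n \gg G$; between firings the
  threshold relaxes as $\dot B_n = -\alpha_n (B_n - G_n)$ toward the resting
  threshold $G_n$.  At constant supra-threshold glycemia a single unit
  therefore fires periodically, with period
  $\log\{(R_n - G_n)/(G - G_n)\}/\alpha_n$.
* **Potentiation.**  The packet recharges toward the potentiation level,
  $\dot J_n = \zeta_n (D_n - J_n)$, while the potentiation level itself
  relaxes toward its basal value and is driven by delayed glycemia through a
  steep Hill function:
  $\dot D_n = -k_n (D_n - \bar D_n) + \rho_n \,
  G^{\gamma_n}(t-\tau) / \{G^{\gamma_n}(t-\tau) + \Gamma_n^{\gamma_n}\}$.
  Under constant glycemia $G_b$ the packet converges to
  $\rho_n/k_n \cdot G_b^{\gamma_n}/(G_b^{\gamma_n} + \Gamma_n^{\gamma_n}) +
  \bar D_n$ (`asymptotic_packet_size()`).  With $\Gamma \approx 9$ mM and
  $\gamma \approx 10$ potentiation is effectively a glycemia switch: packets
  stay basal below ~7 mM and grow many-fold above it.

Heterogeneity enters through the unit parameters: all are independent
log-normals whose arithmetic means and standard deviations are the
species meta-parameters (`load_defaults()`), except the resting thresholds
$G_n$, which follow a Hill-shaped CDF
$F(g) = g^\nu / (g_{1/2}^\nu + g^\nu)$ fitted by ordinary least squares to
percent-activation data from classical step-stimulation experiments on the
perfused rat pancreas (`fit_threshold_cdf()`).  Our fit of the six shipped
points gives $\nu = 2.528$, $g_{1/2} = 9.770$ mM; the fit is checked in the
test suite against a brute-force grid oracle.  Recruitment — the fraction of
units whose thresholds lie below current glycemia — is what shapes the
organ's dose response.

Total insulin secretion is the sum of the discharged packets.  Two
environments close the model:

* **In vitro** (perfused pancreas, `simulate_in_vitro()`): glucose is an
  imposed concentration; released insulin flows through a loss-free linear
  chain portal → serum → measurement compartment ($k_{ip}$, $k_{mi}$), and
  the measured secretion rate is the forward difference of the cumulative
  measurement compartment over 0.5-min intervals (`isr_measure()`).
* **In vivo** (`simulate_in_vivo()`): released insulin passes an
  $L$-compartment liver chain (transfer $h_d$, destruction $h_x$; the liver
  destroys $h_x/(h_d+h_x) \approx 36\%$ of secreted insulin), enters plasma
  (clearance $k_4$, volume $V_I$), and drives tissue glucose uptake.
  Glycemia obeys
  $\dot G = -k_1 \max(0, G - G_u) - k_2 I G + \{k_3(t) + k_{ga} A +
  k_{ex}(t)\}/V_G$: renal loss above the threshold $G_u$ and
  insulin-dependent uptake act on the glucose concentration directly, while
  net hepatic output $k_3$, splanchnic absorption from the gut compartment
  $A$ (first-order, rate $k_{ga}$, fed by enteral input), and intravenous
  infusion are mass fluxes converted by the distribution volume $V_G$.
  Hepatic output fluctuates as $k_3(t) = \bar k_3 + \tilde s(\xi)$, where
  $\xi$ is an Ornstein–Uhlenbeck process (reversion $a$, volatility $b$,
  stationary SD $b/\sqrt{2a}$) clipped to $[m, M]$ so glycemia can neither
  run away nor go negative.

## Numerical scheme

Firing is a state-triggered impulse, so the simulators use a fixed-step
hybrid scheme: at each step the firing set is evaluated on start-of-step
values, impulses are applied (packet release into the portal/liver
compartment, threshold jump), and all continuous states then advance one
explicit Euler step.  Steps are 0.1 min in vivo and 0.5 min in vitro, the
integration intervals at which the replicated experiments were originally
simulated.  Ties fire simultaneously; a unit fires at most once per step.
Two deliberate exceptions to plain Euler:

* the in vitro measurement chain has $k_{mi}\,\Delta t = 2.4 > 1$, where
  explicit Euler is unstable, so that linear chain is advanced with its
  exact exponential propagator — unconditionally stable and mass-conserving
  to machine precision (the mass-conservation test asserts exact
  bookkeeping);
* in vivo, the released mass is added to the first liver compartment before
  the chain update and the post-impulse masses are used throughout the step,
  which makes the discrete insulin bookkeeping telescope exactly.

The delayed glycemia $G(t-\tau)$ uses a ring buffer at step resolution with
pre-history $G(t<0) = G_b$ (in vitro $\tau = 0$).  The inner loop is
compiled (Rcpp); a pure-R reference (`step_units()`,
`step_environment()`) defines the semantics and the test suite asserts that
both routes produce identical trajectories.

Initial conditions: in vitro, units start at the zero-glucose basal state
($B_n = G_n$, $J_n = D_n = \bar D_n$), which is what gives the first-phase
spike when glucose is first applied.  In vivo, packets start at their
asymptotic size for $G_b$ and the closed loop is burned in for 600 min
(seeded) before any protocol; the experiments the package replicates are
insensitive to the burn-in length once it exceeds a few multiples of the
slowest loop time constant (~1 h).  The OU state starts from its stationary
distribution.

Threshold samples are drawn by inverse-CDF on $(0.1, 100)$ mM — the Hill
CDF has a heavy upper tail and the truncation only removes physically
meaningless thresholds (≈0.5% of mass).  Log-normal sampling interprets the
tabulated mean/SD pairs as arithmetic moments, moment-matched to log space;
the tables do not state the scale, and arithmetic moments are the
conventional reading.  When the population size $n$ differs from the
reference size (1e5 in vivo, 1e4 in vitro), the packet-size means
($\bar D$, $\rho$) are scaled by $n_\mathrm{ref}/n$ so the organ's total
available insulin is invariant — the test suite checks that ultradian
period estimates agree between $n = 10^5$ and $2\times10^5$.

## Emergent behaviour and the replicated experiment families

A single species-specific parameter set reproduces, qualitatively, eight
experiment families:

* **Perfused pancreas** (rat set): staircase stimulation gives a spike at
  each step with increasing amplitude (fresh recruitment at every level);
  constant levels 50–500 mg/dl give initial peaks ordered by level and a
  potentiation-driven second phase; restimulation after a 5-min pause gives
  a second peak larger than the first (potentiation persists across the
  pause); a ramp-then-hold shows a drop in secretion once recruitment stops
  at the hold; a pure ramp shows steadily rising secretion.  The ramp of the
  ramp-then-hold experiment is 0→300 mg/dl over 10 min by default: the
  original reports do not state the slope, and the post-hold drop is only
  expressed in the recruitment-dominated (steep-ramp) regime — at slopes
  much shallower than ~0.5 mM/min, packet recycling and potentiation growth
  mask the recruitment cutoff.  Both ramp parameters are configurable.
* **Fasting and enteral feeding** (human set): the closed loop settles to a
  stochastically stationary fasting state (glycemia ≈ 5.2 mM, insulin ≈
  70 pM) with irregular slow insulin oscillations excited by the hepatic
  noise.  Constant enteral feeding (90 kcal/h ≈ 0.035 mmol glucose/kgBW/min
  at 60 kg) moves the loop to a strongly underdamped operating point:
  ultradian oscillations are amplified roughly tenfold and regularised.
  Note the fasting point is an emergent property of the closed loop, not a
  parameter: it sits ≈1 mM above the nominal basal glycemia $G_b$ = 4.25 mM
  used for initialisation.
* **Sinusoidal entrainment**: under constant intravenous infusion of
  6 mg/kgBW/min the loop oscillates with an endogenous period
  $T_\mathrm{end}$ ≈ 90–100 min; sinusoidal modulation (33% amplitude) at
  $0.8\,T_\mathrm{end}$ or $1.2\,T_\mathrm{end}$ locks the insulin
  oscillation to the forcing period (within ~1% over the 24-h infusions of
  the original protocol).  Over shorter (12-h) windows the fast-forcing arm
  can transiently lock 2:1 — entrainment should be assessed on the full
  24-h run.
* **Pulsed entrainment**: 1-min pulses of 6 mg/kgBW/min every 10 min
  entrain minute-scale insulin pulses 1:1 at the forcing period; 2 mg
  pulses produce responses below assay resolution, and the unforced state
  shows only small irregular fast fluctuations.
* **IVGTT phenotypes**: a 0.36 g/kgBW bolus over 3 min in the normal (NGT)
  parameter set gives the classical biphasic insulinemia (first-phase peak
  ~4 min after the bolus) and glycemia restored to the fasting level by
  180 min.  The scenarios multiply $k_2$ (peripheral sensitivity),
  $\bar k_3$ (hepatic output), $\mu(\rho_n)$ (secretory efficiency) and
  $\mu(\bar D_n)$ (basal packet size); scenario SDs are scaled with the
  means so coefficients of variation are preserved.  IFG raises fasting
  glycemia; IGT raises the insulin response; T2DM attenuates the first
  phase and sustains hyperglycemia, most markedly in the variant that also
  left-shifts the threshold distribution to $g_{1/2} = 4$ mM.

## Analysis choices

The detectors in the analysis module are deliberately simple and fully
deterministic given their inputs:

* `detect_pulses()` calls local maxima by topographic prominence, with an
  SD-relative threshold, an optional moving-mean detrend, and an optional
  absolute prominence floor.
* `insulin_pulse_metrics()` is the package's canonical pipeline for
  minute-scale insulin pulsatility and is applied identically to forced and
  unforced runs: 3-point moving average (the low-pass filter applied to all
  measured in vivo signals, matching how such recordings are processed),
  10-min moving-mean detrend (removes the ultradian component), then a
  prominence floor equal to the insulinemia intra-assay CV (5.8%) divided
  by $\sqrt3$ (the averaging of three uncorrelated measurements) times the
  mean level.  The floor is what operationalises "no appreciable response":
  the model responds deterministically to arbitrarily small glucose pulses,
  so without a measurement-resolution floor any periodic response, however
  tiny, would count as entrainment.  The mean inter-pulse interval excludes
  gaps longer than 1.5× the median interval, the standard guard against
  missed detections biasing the mean upward.
* `estimate_period()` detrends with a long moving mean and takes the first
  significant autocorrelation peak; series with no peak above the
  Bonferroni-corrected white-noise band are flagged as having no
  significant period.  For ultradian work we use a 240-min detrend window
  (a 60-min window would attenuate 100-min oscillations substantially) and
  discard the first 120 min of forced runs (`settle`), whose onset
  transient otherwise dominates the autocorrelation.
* `add_assay_noise()` is multiplicative Gaussian noise floored at zero
  (concentrations cannot be negative).

## What the simulations do and do not show

All inputs are self-generated: the package ships only the six
percent-activation points and the two species parameter tables; every
experiment is simulated from those.  Passing tests therefore show that the
*model* reproduces the qualitative phenomenology of the replicated
experiment families — spike ordering, potentiation, entrainment windows,
phenotype ordering — under the stated parameter tables.  They do not show
agreement with any particular experimental recording: published figure
data are not tabulated, so figure-level quantitative comparison is out of
scope, and amplitudes (e.g. of the fast insulin pulses) are not calibrated
to assay recordings.  The unit populations in the tests use the reference
sizes ($10^5$ in vivo, $10^4$ in vitro) for the acceptance-level checks and
smaller populations (with the total-insulin rescaling) for fast unit tests.

## Known limitations

* No glucagon, incretin or neural modulation; the liver is a single linear
  compartment by default (the chain length is configurable but untested
  beyond small $L$).
* The firing rule recycles units indefinitely at constant supra-threshold
  glycemia; sustained-stimulation experiments longer than a few hours would
  overstate late-phase secretion if depletion mechanisms matter.
* The fasting operating point emerges ≈1 mM above the nominal $G_b$; a
  recalibration of $\bar k_3$ or $k_2$ could re-centre it, but the shipped
  tables are kept verbatim.
* Explicit Euler at fixed dt is first-order: halving dt shifts single-unit
  firing times by a few steps (the tests pin the discrete-scheme closed
  form and check convergence toward the continuous limit).
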