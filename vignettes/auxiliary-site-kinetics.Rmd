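---
title: "Modelling cooperative auxiliary ATP sites and transfer-fed catalysis in RecBCD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooperative auxiliary ATP sites and transfer-fed catalysis in RecBCD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recbcdkin)
```

## The scientific problem

RecBCD is a bacterial helicase–nuclease that unwinds double-stranded DNA at
up to ~1600 bp/s while consuming about two ATP per base pair — a hydrolysis
rate of at least 3200 ATP s⁻¹ per enzyme, far above what simple diffusional
delivery of ATP to its two catalytic motor sites (in RecB and RecD) would
comfortably sustain through the whole concentration range where the enzyme
is active.  `recbcdkin` implements a kinetic model in which a set of
non-catalytic, cooperative *auxiliary* ATP-binding sites (mapped to RecC)
acts as an ATP buffer: ATP binds weakly and cooperatively to the auxiliary
sites and is handed to a free catalytic site by a direct *transfer* step,
without release to solution.  The package fits this model jointly to the
four experimental modalities that constrain it — equilibrium titrations,
equilibrium dialysis, stopped-flow binding transients, and real-time
unwinding — and provides the single-molecule trace analysis used to
characterise pausing.

## The kinetic scheme

A state of the enzyme is a pair $(w, c)$: $w \in \{0,\dots,4\}$ ATP on the
auxiliary sites and $c \in \{0,1,2\}$ on the catalytic sites.  The allowed
transitions and their rates are

| transition | rate |
|---|---|
| $(w,c) \to (w{+}1,c)$ | $k_w^+ T$ for $w = 0$; $a\,k_w^+ T$ for $w \ge 1$ |
| $(w,c) \to (w{-}1,c)$ | $k_w^-$ |
| $(w,c) \to (w,c{+}1)$ | $k_s^+ T$ |
| $(w,c) \to (w,c{-}1)$ | $k_s^-$ |
| $(w,c) \to (w{-}1,c{+}1)$ | $k_{tr}^+$ (transfer) |
| $(w,c) \to (w{+}1,c{-}1)$ | $k_{tr}^-$ |
| $(w,c) \to (w,c{-}1)$, hydrolysis | $v_{max}\, c$ |

with $T$ the free ATP (or mant-nucleotide) concentration.  Three rates
depend linearly on solution conditions, clamped at zero:
$k_w^+ = \max(0, \beta + \alpha\,[\mathrm{adenosine}])$ (adenosine blocks
the auxiliary sites), $k_w^- = \max(0, \delta + \gamma\,[\mathrm{NaCl}])$,
and $k_{tr}^+ = \max(0, \kappa + \epsilon\,[\mathrm{NaCl}])$.  Together with
$k_s^\pm$, $k_{tr}^-$, the cooperativity factor $a$ and the per-site
catalysis rate $v_{max}$, this gives the **eleven free parameters** of the
joint fit.

At equilibrium the occupancy statistics follow from the binding polynomial.
Because the model assumes no interaction between the two site classes, the
polynomial factorises into the product of the catalytic chain
$1 + K_sT + K_s^2T^2$ and the cooperative auxiliary chain
$1 + K_wT + aK_w^2T^2 + a^2K_w^3T^3 + a^3K_w^4T^4$, where
$K_i = k_i^+/k_i^-$ are sequential macroscopic association constants.  The
mean number of bound ligands is $\partial \ln \Psi / \partial \ln T$.
`binding_polynomial()` evaluates this product form by default; the
`"as_printed"` variant reproduces the published coefficient table verbatim,
which differs from the product in exactly two terms (its $T^4$ term has
$aK_sK_w^3$ where the product gives $a^2K_sK_w^3$, and its $T^5$ term
$a^2K_sK_w^3$ where the product gives $a^2K_s^2K_w^3$).  We treat the two
coefficients as typographical slips — the microscopic scheme can only
reproduce one canonical polynomial, and it is the product — but both forms
are exposed and never silently reconciled.

Two structural choices deserve emphasis:

* **No statistical multiplicity factors.**  The printed polynomial uses
  sequential macroscopic constants ($K_sT$, $K_s^2T^2$), so the microscopic
  chain uses the same rate for every sequential step rather than per-site
  rates with binomial factors.  A consequence worth knowing: the catalytic
  chain then relaxes with two close eigenmodes rather than a single
  exponential, which is why `predict_kobs()` reports what a
  double-exponential fit of the simulated observable measures (that is what
  the instrument analysis does), not raw eigenvalues.
* **Cooperativity acts on the on-rate** of the 2nd–4th auxiliary bindings;
  the off-rate is occupancy-independent.  Equilibrium weights therefore
  carry $a^{\max(w-1,\,0)}$.

Catalysis consumes the bound ATP at $v_{max}$ per occupied catalytic site
(premise: unwinding is proportional to hydrolysis; a flag switches to the
any-occupied variant), and product release is lumped into the hydrolysis
transition since the scheme carries no ADP-bound states.  The unwinding
rate is the quasi-steady slope of cumulative hydrolysis (by default fitted
over the final 80% of the trace — the window is not prescribed by the
source analyses, and the early transient decays within a fraction of a
second) times a bp-per-ATP coupling of 0.5 (two ATP per bp), configurable.

Thermodynamic consistency between the transfer rates and the binding
constants is *not* enforced by default: whether the original global fit
constrained the cycle $k_{tr}^+/k_{tr}^- = K_s/(a^{\min(w-1,1)}K_w)$ is not
stated, and with a state-independent $k_{tr}^\pm$ the constraint cannot hold
on every cycle anyway once $a \ne 1$.  The ODE stationary state therefore
matches the polynomial occupancy exactly only under cycle-consistent rates
(tested with $a = 1$ and with a single auxiliary site), and approximately
otherwise.

## Numerical choices

State probabilities evolve under the master equation; `deSolve::lsoda`
integrates it with relative tolerance 1e-8 and absolute tolerance 1e-10 on a
fixed output grid.  Where only the observable is needed on a grid
(`exact_observable()`), the generator is diagonalised instead — exact and
~50× faster for the 15-state scheme.  The stationary distribution comes
from the augmented least-squares null-space solve.  Exponential fits use
variable projection (amplitudes solved linearly, rates optimised on the log
scale) with several separated starting rate pairs; lag-plus-decay fits use
Nelder–Mead multi-start over a 20-point grid of lag candidates because the
objective is only piecewise smooth in the lag.  Weighted nonlinear least
squares throughout uses Levenberg–Marquardt with box bounds
(`minpack.lm`), with standard errors from the Gauss–Newton covariance.

## The joint fit

`run_global_fit()` minimises a sum of normalised squared errors: residuals
standardised by the per-record uncertainties and each modality block
divided by its residual count so that no modality dominates by point count.
Stopped-flow traces enter as baseline-corrected, occupancy-proportional
time courses (the instrument's concentration baseline
$\alpha[\mathrm{mD}]+\beta$ is measured independently by buffer–nucleotide
control mixes) with one remaining amplitude scale profiled out analytically;
derived $k_{obs}$ curves are also accepted as records.  The optimiser is a
seeded multi-start scheme standing in for a scatter-search global solver,
chosen for reproducibility: log-uniform scatter inside box bounds (slopes
get a log-uniform magnitude with sign from the bounds), a deterministic
centre start, and a *data-driven* start whose well-identified entries come
from single-modality estimates (catalytic rates from the concentration
dependence of single-exponential transient fits, phase dissociation
constants from per-condition double-Hill fits, $v_{max}$ from the largest
unwinding rate), spread over the transfer-rate and cooperativity dimensions
it cannot estimate.  Starts are screened briefly on a 3×-decimated dataset
and the best few are polished on the full one.  One pitfall is handled
explicitly: when the fitted adenosine slope drives $k_w^+$ to zero at the
highest measured adenosine, the objective is flat in that direction
(clamping), so the fitter retries once from a half-blocked slope.

Identifiability requires condition contrast: with fewer than two adenosine
(NaCl) levels, the corresponding slope coefficients are fixed at zero with
a warning, leaving the eight-parameter core set.

`bootstrap()` perturbs every measured value by a Gaussian with the stated
uncertainty, refits each replicate warm-started from the point estimate,
and summarises each parameter's replicate histogram by its Gaussian mean
and s.d. (100 replicates by default).  `select_weak_site_count()` refits
the scheme for candidate auxiliary-site counts and ranks them by the
small-sample-corrected information criterion; since every candidate has the
same free-parameter count, the ranking reflects pure fit quality, with
equilibrium isotherms (and the dialysis stoichiometry, which caps the total
site number) as the discriminating data.

## What the synthetic data emulate

The generators produce every modality with known ground truth: model
isotherms plus Gaussian noise (2% of span, 20 log-spaced points to 550 µM);
dialysis pairs from the exact closed-system equilibrium (protein 45 µM with
1 mM nucleotide, and 17 µM with 200 µM); binding transients from the master
equation mapped through the linear fluorescence baseline (1% of span noise,
1 ms dead time, 0–100 µM concentration set, with a 350 µM point added for
the joint-fit design); lag-plus-decay unwinding traces at 24/38/52 bp with
0.005 anisotropy-unit noise; and 2500 Hz tweezers traces built from a
piecewise-constant velocity profile with scheduled pauses, pushed through
the extensible worm-like chain (Odijk high-force form; persistence 50 nm,
rise 0.34 nm/bp, stretch modulus 1200 pN — the WLC constants are not stated
in the source analyses and are configurable) at a 10→15 pN force ramp with
2 nm r.m.s. extension noise.  Noise magnitudes are deliberate, documented
choices matched by eye to published figures.

The default ground-truth parameters echo the system's qualitative findings
— strong-site $K_D$ ~ 7.5 µM, cooperative weak phase centred near 380 µM
(above 280 µM), $a = 18$, fast and strongly directional transfer — but are
synthetic.  Several of them are pinned by qualitative signatures rather
than taste:

* $\gamma > 0$ (salt destabilises the auxiliary sites): with the opposite
  sign the salt-strengthened weak binding compensates the transfer loss and
  salt can *raise* the simulated unwinding rate at 350 µM ATP, contradicting
  the central salt signature.
* $k_{tr}^- = 5\,\mathrm{s^{-1}}$ (small): any larger value makes the
  no-auxiliary-binding limit ($k_w^+ = 0$, the adenosine/mutant emulation)
  visibly biexponential through the reverse-transfer/shedding pathway,
  contradicting the observed single-exponential behaviour.  The price is
  that $k_{tr}^-$ influences every observable by only a few percent, which
  bounds how well it can be recovered.
* $k_s^+ T$ saturates the direct pathway early relative to the weak-phase
  centre, so the auxiliary boost extends the rise of the flux–ATP curve —
  this is what makes removing the auxiliary sites shift the apparent
  $K_M$ upward in this scheme (robustly so across the whole plausible
  parameter range we explored).

What passing tests on these data do **not** show about real data: the
generators use ideal Gaussian noise, no photobleaching, drift, or baseline
curvature; transient traces are pre-calibrated to occupancy units; the
tweezers traces have no bead–trap dynamics, force noise, or tether
compliance fluctuations beyond the WLC; and the fitted model is exactly the
generating model, so recovery results measure information content and
optimiser quality, not model misspecification.

## Parameter-recovery limits

With the reference design (isotherms at NaCl 75/200/300 mM × adenosine
0/2 mM; transients at seven concentrations for three conditions; unwinding
rates at six ATP concentrations for three conditions; dialysis at two
loads) and the stated noise, the catalytic parameters, $v_{max}$ and the
adenosine dependence are recovered tightly.  The weak-site block
($\delta, \gamma, \kappa, \epsilon, a$) lies on a soft likelihood ridge:
oracle-started optimisation (descent initialised at the generating truth)
still leaves that block outside a 20% relative error on a substantial
fraction of noise seeds, with the likelihood optimum genuinely located
there.  The titration
range ends at 550 µM, truncating the upper half of the cooperative
transition that would pin $a$; dialysis caps the total stoichiometry but
not the shape.  Recovery statements in the tests are therefore reported
against this information-theoretic limit, not against optimiser failures.

## Single-molecule analysis choices

The Chung–Kennedy filter combines past- and future-window means weighted by
inverse local predictor variance to the power $p = 2$ (variance floor
1e-12), run at window lengths 25/50/100 samples and averaged with equal
weights — the published description fixes the windows and equal weights but
not the exponent or the combination rule, so both are documented options.
Pause detection histograms the filtered contour in 2 bp bins (below the
5 bp minimum contour-change threshold, above sampling noise), takes peaks
holding more than 50 samples as dwell candidates, merges candidates split
by less than the minimal translocation time and contour change, and applies
the duration (0.002 s), translocation-time (0.001 s) and contour-change
(5 bp) thresholds.  The pause-density confidence half-width is provided in
the published form $1.96\sqrt{tp/tc}$ (the reproduction default) and as
the standard Poisson counting error $1.96\sqrt{tp}/tc$, which is the
recommended variant for new analyses — the printed formula is dimensionally
inconsistent with a count-based error.

## A worked example

```{r example, eval = FALSE}
truth <- synthetic_truth()
ds <- gen_dataset(truth, seed = 1)
fit <- run_global_fit(ds, n_starts = 12, seed = 1)
summary(fit)
predict(fit, "unwinding", condition = recbcd_condition(ligand_conc = 350),
        conc = c(100, 350, 700))
bs <- bootstrap(fit, n = 100, seed = 1)
```

The chunk is not evaluated here (a full joint fit takes a few minutes); the
README shows a complete run with its printed output.

## Problem sizes used by the test-suite studies

Simulation studies in the tests are scaled to what the checks need:
coverage studies use 100–200 replicates of the cheap fitters; the
phase-classification study uses 20 seeds × 3 concentrations; the
pause-detection study 40 traces of 4 s; the joint-fit recovery study uses a
reduced multi-start budget and a handful of seeds, with site-count
selection run on the equilibrium blocks where the discrimination lives.

## Known limitations

No force dependence of rates, no DNA-sequence or Chi-site effects, no
ADP-bound states, no inner-filter or photophysics corrections, and no
Bayesian uncertainty quantification (the bootstrap is the uncertainty
instrument).  The `as_printed` polynomial variant exists for comparison
only; every model-based computation uses the product form.
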