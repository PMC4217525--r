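---
title: "Modelling calcium noise in buffered microdomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium noise in buffered microdomains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camnoise)
```

## The problem

At resting conditions a cell holds roughly 100 nM of free Ca²⁺, which in a
femtoliter corresponds to only about 60 ions; in the 0.1–1 fl volumes
occupied by calcium sparks, channel clusters or a confocal observation spot,
the copy-number fluctuations of free calcium are therefore substantial
relative to the mean. Those fluctuations are not white: reversible binding
to buffer molecules (calmodulin, troponin C, parvalbumin, chelators and
indicator dyes) and diffusive exchange with the surroundings give the
fluctuating free-calcium signal a finite memory. `camnoise` characterizes
this *colored* noise — its stationary mean, variance and autocorrelation
time — and simulates it with four mutually consistent engines.

## Model

A well-mixed cubic voxel of volume $V$ (fl) holds free calcium $X_t$
(counts) and $M$ buffers, each reacting as
$\mathrm{Ca}^{2+} + \mathrm{B}_j \rightleftharpoons \mathrm{CaB}_j$ with
association rate $k^+_j$ (µM⁻¹ ms⁻¹) and dissociation rate $k^-_j$ (ms⁻¹),
so $K_{D,j} = k^-_j / k^+_j$. At equilibrium the bound fraction follows mass
action,
$\tilde z_j = B_{T,j} / (1 + K_{D,j}/\tilde x)$,
and every equilibrium quantity is determined by the totals. Copy numbers and
concentrations are related by 602.214076 molecules per µM·fl; bimolecular
stochastic rates are $c^+_j = k^+_j / (602.214076\,V)$, monomolecular rates
are unchanged, and optional diffusive exchange with an equilibrated
surrounding pool (the "constant pool" boundary) contributes a hop rate
$c_d = D_{\mathrm{Ca}}/L^2$ with $L = V^{1/3}$: efflux at rate $c_d X_t$,
influx at the constant rate $c_d \tilde X$.

Under the excess buffer approximation (EBA) — free buffer pinned at its
equilibrium value, accurate whenever bound calcium is a small perturbation
of the buffer pool — the kinetics linearize:
$\dot x = -K_1 x + K_2$ with $K_1 = k^+\tilde y + k^-$ and
$K_2 = k^- x_T$, giving mono-exponential relaxation with time constant
$1/K_1$. Applying the same reduction to the chemical Langevin equation
yields an Ornstein–Uhlenbeck (OU) surrogate
$$dX_t = -\tfrac{1}{\tau}(X_t - \mu)\,dt + \sigma\,dW_t$$
with stationary parameters

* $\mu = \tilde X$ (counts),
* $\tau = 1 / \bigl(\sum_j (k^+_j \tilde y_j + k^-_j) + c_d\bigr)$ (ms),
* $\sigma^2 = \sum_j (c^+_j \tilde X \tilde Y_j + c^-_j \tilde Z_j) + 2 c_d \tilde X$,

and stationary variance $\sigma^2 \tau / 2$. Detailed balance makes each
buffer's two volatility terms equal, so for a single closed buffer
$\sigma^2 = 2 c^- \tilde Z$. The correlation time is volume-free while
$\sigma$ scales as $\sqrt V$. When several buffers *and* diffusion are both
present we add their rates in the denominator of $\tau$: all relaxation
channels enter the linearized drift additively, so this combination follows
from the same derivation as each case separately.

The central physical statement is a fluctuation–dissipation identity: the
autocorrelation time of stationary equilibrium fluctuations equals the
relaxation time constant after a macroscopic perturbation, $\tau = \hat\tau$.

```{r theory}
sys <- ca_system("CaM", volume = 0.125, ca_eq = 0.1)
noise_params(sys)
tau_theory(ca_system(c("CaM", "EGTA"), ca_eq = 0.1))
tau_theory(ca_system(c("CaM", "Fluo-4"), ca_eq = 0.1))
```

## The four engines

* **`ssa_simulate()`** — Gillespie's exact stochastic simulation algorithm,
  direct-method variant (the reaction set here is tiny, so the simplest
  exact sampler is also the appropriate one). Initial copy numbers are the
  equilibrium values rounded half-to-even, a reproducible choice. Jump
  paths are resampled onto a uniform grid by linear interpolation
  (`resample_path()`, default `dt` = 0.01 ms); a zero-order-hold mode is
  provided because occupancy statistics compared against the master
  equation must not be smoothed by interpolation.
* **`cle_simulate()`** — Euler–Maruyama integration of the chemical
  Langevin equation. Each buffer channel receives one combined Gaussian
  increment (variances of the binding and unbinding channels add), applied
  anti-symmetrically to $X$ and $Z_j$ so per-buffer mass is conserved
  pathwise — mathematically equivalent to independent Wiener terms per
  channel, and cheaper.
* **`cle_eba_simulate()`** — the same integrator with free buffer pinned at
  $\tilde Y_j$; for one buffer this is a scalar mean-reverting equation
  whose volatility frozen at equilibrium is exactly an OU generator.
* **`oup_simulate()`** — the OU surrogate itself, by Euler–Maruyama or by
  the exact conditional-Gaussian discretization (no step-size error; used
  wherever an exact reference process is needed).

Numerical choices: the default step `dt` = 0.01 ms is used for all
integrators and for resampling. The Gaussian approximation can propose
negative copy numbers in small volumes; we clamp propensity arguments at
zero inside square roots and species at zero after each step, and count the
occurrences in the trajectory metadata so the impact of this choice is
auditable. Clamping is the least-surprising of the possible fixes (the
alternatives — reflection, or replacing the Gaussian by a Poisson draw —
change the process); at 0.125 fl the calmodulin system clamps rarely, but
the zero boundary does bias the CLE mean upward by a percent-level amount,
which is why mean-accuracy checks are run at 1 fl where the boundary is
never reached.

Every engine takes an integer seed and is bit-for-bit reproducible for a
given seed within this implementation (reproducibility across RNG
algorithms is not promised).

## Estimators

`autocorrelation()` computes the mean-removed, biased (1/N) sample ACF —
the biased normalization keeps it positive semi-definite.
`estimate_tau()` fits an ordinary least-squares line to the log-ACF over
the contiguous initial lag range with values above 0.05 and returns
$-1/\text{slope}$; the processes here are mono-exponential by construction,
and the threshold keeps the noisy tail out of the fit. `fit_relaxation()`
applies the same log-linear idea to a perturbed trajectory over the window
where the deviation exceeds 10% of its initial value. Both window rules are
design choices (no canonical fit range exists for this problem); they are
deliberately simple and are validated against exactly sampled OU paths.
Relaxation experiments fit each trajectory separately and average the
estimates over seeds (n = 10 by convention) rather than fitting the
averaged trace.

A caveat worth knowing: a single stationary run of length $T$ carries
$\mathcal{O}(\sqrt{\tau/T})$ relative uncertainty in $\hat\tau$, so slow
systems (e.g. $\tau = 5$ ms at $T = 10^4$ ms) show ±15% single-run scatter;
seed-averaging is part of the protocol, not a luxury. For fast systems the
Euler engines carry an $\mathcal{O}(dt/\tau)$ discretization bias (about
10% for $\tau \approx 0.045$ ms at `dt` = 0.01), visible in the OUP and CLE
rows of the fluctuation–dissipation comparison; the exact-discretization OU
mode avoids it.

```{r fd, eval = FALSE}
# fluctuation-dissipation table across all reference buffers (~seconds)
run_scenario("fig3", seeds = 1:10)$relaxation
```

## Exact oracle

`cme_stationary()` solves the stationary chemical master equation exactly
for closed single-buffer systems: conservation reduces the state to the
free-calcium count alone, leaving a finite birth–death chain whose
generator null space is computed directly. SSA occupancy (time-weighted, by
`state_occupancy()`) must match it in total-variation distance; the test
suite also checks the solver against the detailed-balance product form,
keeping implementation and oracle independent.

## Colored noise driving a bistable switch

`dw_simulate()` integrates motion in the double well
$V(x) = -\tfrac{a}{2}x^2 + \tfrac{b}{4}x^4$ (Euler, `dt` = 0.01 ms) driven
by a supplied noise trajectory whose samples enter as per-step additive
increments; scaling a white sequence by $\sqrt{dt}$ recovers the standard
white-noise limit. Defaults $a = b = 1$ place the minima at ±1 with barrier
0.25 — the canonical normalization of the colored-noise literature. The
noise mean is removed before integration to respect the symmetry of the
potential. With OU noise of fixed volatility $\sigma = 1$ and `t_end` =
2000 ms (the documented defaults; varying $\tau$ at fixed $\sigma$ changes
the noise variance as $\sigma^2\tau/2$, which is part of the effect being
illustrated), fast noise ($\tau = 0.01$ ms) drives well-to-well switching
that is nearly uncorrelated with the instantaneous noise value, while slow
noise ($\tau = 0.75$ ms) produces switching strongly coupled to the noise:

```{r bistable}
dw <- double_well()
r <- sapply(c(0.01, 0.75), function(tau) {
  xi <- oup_simulate(make_noise_params(0, tau, 1), dt = 0.01,
                     t_end = 2000, seed = 1, exact = TRUE)
  coupling_correlation(xi, dw_simulate(xi, dw))
})
round(r, 3)
```

The quantitative acceptance surface for this demonstration is the ordering
(slow-noise correlation at least threefold the fast-noise one, joint
distribution near-factorized for fast noise), not point values: the
amplitude and run length of the original illustration are not published,
so ours are package defaults chosen once and documented here.

## What the synthetic conditions do and do not show

All validation data are generated by the package itself under the study
conditions: the six tabulated buffers (each alone at 0.1 µM free calcium,
volumes 0.125 or 1 fl), the CaM+EGTA / CaM+Fluo-4 mixtures, diffusion at
$D_{\mathrm{Ca}} = 0.2$ µm²/ms, relaxation from 1 µM, and runs of
$10^3$–$10^4$ ms. Problem sizes in the test-suite (e.g. $10^4$ ms stationary
runs, $9\times10^5$ ms for the master-equation comparison, ten seeds per
stochastic estimate) were chosen so that sampling error sits comfortably
below the tolerances being checked. Passing tests therefore demonstrate
internal consistency of the four engines, the closed-form parameters and
the estimators — they do not validate the chemistry against real cells.
In particular the model assumes a well-mixed voxel, single-site buffers,
no buffer diffusion, no channel gating and no buffer saturation; close to
an open channel pore the excess buffer approximation itself fails.

## Known limitations

* The CLE and its EBA reduction admit (clamped) boundary artifacts for
  mean counts below ~10; prefer the SSA there, or a larger volume.
* `fit_relaxation()` assumes mono-exponential decay; perturbations large
  enough to saturate a buffer violate the EBA and bend the log-deviation
  curve (the 1 µM perturbations used here shift the effective rate by a
  few percent, well inside the 15% acceptance band).
* With diffusion enabled the reported $\tau$ formula combines buffer and
  diffusion rates additively; no closed-form was derived for the
  diffusion + multi-buffer master equation itself, so the oracle there is
  simulation only.
* `totals_to_equilibrium()` assumes a strictly positive off-rate;
  irreversible binding ($k^- = 0$) makes the free concentration collapse
  to a boundary rather than a root.
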