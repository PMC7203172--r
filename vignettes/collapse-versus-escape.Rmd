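---
title: "Deforestation-driven collapse versus technological escape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deforestation-driven collapse versus technological escape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcollapse)
```

# The question

World forest cover is being removed at a rate that, extrapolated, exhausts
it within one or two centuries. `forestcollapse` asks a sharply posed
version of the ensuing sustainability question: if the human population
grows logistically on a forest-dependent carrying capacity while consuming
that forest, and if technological capability grows stochastically in
stop-and-go spurts, what is the probability that capability reaches a
civilisation-saving level **before** the population dynamics passes its
point of no return? The "saving" level is taken to be the Dyson limit,
$E_D \approx 4\times10^{26}$ W — the energy throughput at which a
civilisation could exploit its whole solar system and thereby decouple its
fate from the home planet's ecology. This is a weak-sustainability
assumption: the package does not model *how* technology substitutes for
forest, it only ties survival probabilistically to reaching the threshold
in time.

# The deterministic side: humans and forest

The population $N(t)$ and forested surface $R(t)$ follow the coupled
logistic system

$$\frac{dN}{dt} = r N \left(1 - \frac{N}{\beta R}\right), \qquad
  \frac{dR}{dt} = r' R \left(1 - \frac{R}{R_c}\right) - a_0 N R,$$

a Lotka–Volterra-like resource–consumer model in which the human carrying
capacity $\beta R$ is proportional to the remaining forest. The defaults
([`forest_params()`]) are world-scale estimates:

| parameter | default | meaning |
|---|---|---|
| $r$ | 0.01 yr⁻¹ | human population growth rate |
| $r'$ | 0.001 yr⁻¹ | forest regrowth (renewability) rate |
| $\beta$ | 170 | persons sustainable per km² of forest; $N_c/R_c$ with $N_c \sim 10^{10}$ |
| $a_0$ | $10^{-12}$ yr⁻¹ person⁻¹ | extraction (technology) parameter |
| $R_c$ | $6\times10^{7}$ km² | forest carrying capacity (intact forest) |
| $N_0, R_0$ | $6\times10^{9}$, $4\times10^{7}$ | initial population and forest (year 2000) |

`estimate_beta()` and `estimate_a0()` reproduce the two calibrations:
$\beta = N_c/R_c \approx 170$, and $a_0 \approx 9\times10^{-13}$ from the
observed 2000–2012 global forest loss ($2.3\times10^{6}$ km² over 12
years at $R \approx 3\times10^{7}$ km², $N \approx 7.5\times10^{9}$),
rounded to its order of magnitude $10^{-12}$. Fits of $\beta$ to recent
population trajectories give larger values (up to 700–900); the package
treats $\beta \in \{170, 300, 700\}$ as scenario values, with 170 the
conservative planetary-capacity estimate. Note the hybrid unit convention:
$a_0 N$ is a per-year relative deforestation rate with $N$ in persons.
`rescale_to_continental()` re-expresses the state as fractions of the
total continental area $R_W \simeq 1.5\times10^{8}$ km², turning $a_0$
into $a = a_0 R_W$ (km² yr⁻¹, baseline $1.5\times10^{-4}$); the sweep
grids are specified in $a$.

For $a_0$ above a small threshold the trajectory rises to a population
maximum and then collapses, because the forest is consumed faster than it
regrows. The package calls the time of that maximum the **no-return
point**: past it the model's population cannot be stabilised, and the
analysis deliberately avoids trusting the post-peak dynamics (a real
decline under severe environmental degradation would be anything but
orderly). With the defaults the peak comes ≈ 20 years after 2000 for
$\beta = 170$ and ≈ 120 years for $\beta = 700$ (peak population
$\approx 1.05\times10^{10}$, the estimated Earth carrying capacity).

**Numerical choices.** Integration is by explicit (forward) Euler — the
method the analysis is defined with — at a default step of 0.01 yr. The
fastest system rate is $\sim 0.01$ yr⁻¹, so the step resolves the dynamics
by a factor of $10^4$; the test suite verifies that halving the step moves
the no-return time by far less than 1%, that the decoupled case
($a_0 = 0$, $R \equiv R_c$) matches the closed-form logistic to $10^{-3}$
relative error, and that rescaled and absolute-unit integrations agree to
$10^{-9}$. A step too large to keep the state positive and finite aborts
with an error naming the step. No-return detection takes the first
interior strict local maximum of $N$ followed by at least a 1% cumulative
decline within the horizon (default 500 yr); the decline guard ignores
floating-point plateaus, and boundary maxima are never reported. When no
qualifying maximum exists (very small $a$), downstream stages use the
horizon as the deadline and flag the cell `censored_deadline`.

# The stochastic side: stop-and-go technology growth

Technological capability $T(t)$ — proxied by world energy consumption,
starting at $E_c \approx 10^{13}$ W — grows exponentially at rate
$\alpha$, but only while the economy permits:

$$\frac{dT}{dt} = \alpha\, T\, \xi(t), \qquad \xi(t) \in \{0, 1\},$$

with $\xi$ a two-state renewal (telegraph) process with exponentially
distributed sojourns. The optimistic benchmark rate is the Moore-law value
$\alpha = \log 2 / 2 \approx 0.345$ yr⁻¹ (`alpha_moore()`), a doubling
every two years.

Because growth is multiplicative and only accrues in the on state, the
first-passage time to a target satisfies a hard bound
$t \ge \log(T_\mathrm{target}/T_\mathrm{init})/\alpha$
(`min_passage_time()`), and the crossing time on any given noise
realisation is available in closed form on the on-interval where the
cumulative on-time reaches that requirement. The package therefore never
discretises the growth equation: `integrate_technology()` is exact in
$\log T$, `first_passage_time()` solves the crossing exactly, and the
Monte Carlo sampler `sample_fpt_batch()` advances all trajectories in
lock-step sojourn rounds with no grid error. (A fine-step Euler
integration of the same noise realisation is used in the tests as an
independent cross-check of the exact path.)

**Calibration of the sojourn means — a consequential choice.** The
economic record motivates alternating spells of growth and stagnation
with mean durations of order 1 and 4 years. The assignment of those two
numbers to the two states changes the conclusion qualitatively: the
long-run growth fraction is $m_{on}/(m_{on}+m_{off})$, i.e. 0.2 under
(growth 1 yr, stagnation 4 yr) but 0.8 under the opposite pairing. Under
the 0.8 pairing the expected passage time to the Dyson limit at the Moore
rate (≈ 113 yr) beats even the $\beta = 700$ deadline of ≈ 120 yr, and
escape would be nearly certain — erasing the analysis's central tension.
The package adopts the pessimistic pairing, `mean_on = 1`,
`mean_off = 4`, as its default ([`dichotomous_spec()`]): it is the only
assignment consistent with the headline results this analysis is known
for (sub-10% escape probability at $\beta = 700$ with Moore-rate growth,
and a nonzero-escape threshold well above the Moore rate at
$\beta = 170$). Both pairings are a constructor argument away, and the
renewal-theory mean $S(1 + m_{off}/m_{on})$ is property-tested for both.
The initial state is drawn from the stationary occupancy by default
(`fixed-on`/`fixed-off` are available); the experiment's conclusions are
insensitive to this because deadlines span many sojourns.

# Closed forms for the symmetric case

When both sojourn means equal $2/\gamma$ the centred noise
$\bar\xi = 2(\xi - \langle\xi\rangle)$ is the classic telegraph process
with autocorrelation $e^{-\gamma|\tau|}$ (each state flips at rate
$\gamma/2$ — the convention is pinned down by a brute-force correlation
test), and the drift-removed coordinate
$W = (2/\alpha)\log(T/T_0) - t$ performs a persistent random walk whose
density solves the telegrapher's equation. The package implements:

* `telegrapher_density()` — the walk's density at time $t$: two ballistic
  atoms of mass $e^{-\gamma t/2}/2$ at $W = \pm t$ (trajectories that
  never switched) plus a modified-Bessel ($I_0$, $I_1$) continuous part
  inside the light cone $|W| < t$;
* `level_density()` — its exact change of variables to the level $T$,
  with atoms at $T_0$ (never grown) and at the envelope
  $T_0 e^{\alpha t}$;
* `fpt_dist()` / `fpt_density()` — the first-passage-time law to a target
  coordinate, for a process started in the growth state: an atom of mass
  $e^{-\gamma t_{\min}/2}$ at the minimum time
  $t_{\min} = (x - x_1)/2$ and an $I_1$ tail;
* `mean_fpt()` — its exact mean $(2/\alpha)\log(T/T_1)$: **twice** the
  uninterrupted-growth time, independent of $\gamma$. For
  $10^{13} \to 4\times10^{26}$ W at $\alpha = 0.345$ this is
  ≈ 181.6 yr, conventionally rounded to 180.

Singular components are represented explicitly as (location, mass) pairs
— never as narrow kernels — so normalisation (atoms + quadrature $= 1$)
is asserted to $10^{-5}$ in the tests, and the simulator is validated
against the closed forms by Kolmogorov–Smirnov distance (< 0.02 at
$n = 10^4$ for $\gamma = 4$ and $\gamma = 1/4$), with the KS statistic
computed tie- and atom-aware. Bessel factors are evaluated in scaled form
(`besselI(..., expon.scaled = TRUE)` with the exponent folded in), which
keeps every exponent non-positive and overflow-free at large $\gamma t$.
The fixed-on start is what makes the mean exactly $\gamma$-free; a
stationary start would add $\approx 1/\gamma$. The level density's two
atoms carry mass $e^{-\gamma t/2}/2$ each — the only weighting under
which the distribution integrates to one, as the normalisation tests
verify.

# The survival experiment

`run_trial()`, `estimate_success_probability()` and `sweep_success()`
couple the two sides. The population dynamics does not feel the noise, so
the no-return time is computed once per $(\beta, a)$ cell and shared by
all trials — a memoisation the tests verify against a standalone
evaluation of the first-passage distribution at the deadline (the two
routes agree within three binomial standard errors). Success is
`crossing_time <= t_nr` (a closed inequality; the boundary event has
probability zero). Conditional mean times are reported per cell: the mean
crossing time over successes, and over failures the no-return time itself
(deterministic per cell); empty classes are `NA`, never zero.

Reproducibility is counter-based: a master seed is mixed with the cell
indices (`mix_seed()`) so that any cell can be re-run in isolation and a
re-run of the whole sweep is byte-identical, which the suite asserts on
the exported CSV. Default grids mirror the study ranges:
$\alpha \in [0.25, 4.25]$ in steps of 0.25, $a \in [10^{-5},
3\times10^{-4}]$ km² yr⁻¹ (8 values), $\beta \in \{170, 300, 700\}$,
$10^4$ trials per cell.

With the defaults the experiment reproduces the analysis's conclusions:
at $\beta = 700$, $a = 1.5\times10^{-4}$ and Moore-rate growth the escape
probability is below 10% (in our runs, zero successes in $10^4$ trials —
the expected passage time of ≈ 450 yr under the 0.2 growth fraction is
far beyond the ≈ 120-yr deadline); at $\beta = 170$ the first growth rate
with any success on the 0.25-grid is 2.25–2.5, and over the full
extraction range the nonzero-success region begins at $\alpha = 0.5$
(driven by the slowest-extraction cell $a = 10^{-5}$, whose no-return
time is ≈ 271 yr). That last boundary sits *at* 0.5 rather than strictly
above it — the one place where our reproduction sharpens, rather than
matches, the qualitative threshold usually quoted.

# What the generator emulates — and what it does not

The synthetic stochastic input is an alternating-renewal 0/1 process with
exponential sojourns. It captures the aggregate stop-and-go character of
economic/technological growth and makes the first-passage problem
analytically tractable in the symmetric case, but it does not emulate:
heavy-tailed or autocorrelated cycle durations, partial slowdowns
(growth is all-or-nothing), feedback from ecological state to growth
rate, or any coupling from technology back into the extraction parameter
$a_0$ (higher technology plausibly increases extraction — the model holds
$a_0$ fixed per cell). Passing tests therefore demonstrate internal
consistency and correct mathematics, not forecasting skill on real
trajectories. Equally, the deterministic side holds $r$, $r'$ and $a_0$
constant over centuries and treats the population maximum as the point of
irreversibility; both are deliberate simplifications that set time scales
rather than predict paths.

# Problem sizes and run times

The package's own validation uses $10^4$ trials per headline cell and per
KS comparison, $10^3$ trials per cell for the 136-cell full sweep, Euler
step 0.01 yr over a 500-yr horizon, and $n \in [1500, 10^4]$ for
property-style Monte Carlo checks with 3-standard-error tolerances —
sizes chosen so the whole suite runs in well under a minute on one core
while leaving every stochastic assertion at least three standard errors
of slack.

# Known limitations

* The no-return detection needs the maximum inside the horizon; cells
  whose collapse is slower than the horizon are deadline-censored and
  flagged rather than extrapolated.
* The closed-form first-passage law (and its $\gamma$-independent mean)
  applies to the symmetric process started in the growth state; the
  asymmetric default has no closed form here and is handled purely by
  Monte Carlo with renewal-theory checks.
* Binomial confidence intervals use the normal approximation; at
  $p \approx 0$ they degenerate, and "zero successes in $n$ trials"
  should be read via the rule of three ($p \lesssim 3/n$) rather than
  the reported half-width.
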