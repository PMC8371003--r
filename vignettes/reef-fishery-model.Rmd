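---
title: "Modelling an artificial reef in a no-take zone under illegal fishing"
author: "reefar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an artificial reef in a no-take zone under illegal fishing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefar)
```

## The system being modelled

`reefar` models a small coastal fishery managed by deploying an artificial
reef (AR) inside a circular no-take zone, surrounded by an open-access
fishing annulus. The scientific question is bio-economic: how do the reef's
two effects on fish — *production* (extra habitat capacity) and
*attraction* (movement toward the reef beyond what habitat alone explains)
— interact with *illegal fishing* (a fraction of the fleet's effort
deployed inside the ban) to set the equilibrium catch, and who ends up
catching it?

The model is a two-patch fast–slow system. Patch 1 is the no-take zone
containing the reef; patch 2 the fishing area. The state is fish biomass
and fishing effort per patch, $(n_1, n_2, E_1, E_2)$.

**Fast processes** (timescale of hours):

* Fish move between patches. Immigration into the no-take zone happens at
  rate $a/K_2 + \beta(V)$ and emigration at $a/K_1$, where $a$ is a
  mobility constant, $K_1 = \alpha K + V\,\delta_k$ and
  $K_2 = (1-\alpha)K$ are the patch carrying capacities ($\alpha$ the
  protected fraction of the area, $V$ the reef volume, $\delta_k$ the
  added capacity per m³ of reef — the production effect). With
  $\beta = 0$ the stationary split is the ideal free distribution (IFD):
  biomass proportional to capacity. The attraction function $\beta(V)$ is
  the non-IFD perturbation caused by the reef.
* Effort redistributes at rates $m_1 = \gamma\mu$ (into the no-take zone)
  and $m_2 = (1-\gamma)\mu$ (out of it), so the stationary effort share on
  the reef is exactly $\gamma$, the illegal-fishing rate.

**Slow processes** (months), scaled by $\varepsilon \ll 1$: logistic
growth of each patch population with its own capacity, harvest
$q_i n_i E_i$, and open-access effort adjustment — effort grows when
profit $p q_i n_i E_i - c E_i$ is positive and leaves when it is negative.

### The reduced model

Assuming fish and boats redistribute much faster than populations grow
(aggregation of variables), the four-dimensional system collapses onto the
fast-equilibrium manifold $n_1 = \nu_1^* n$, $E_1 = \gamma E$, with

$$\nu_1^* = \frac{B}{A + B}, \qquad
A = \frac{a}{K_1}, \quad B = \frac{a}{K_2} + \beta(V),$$

giving two slow equations for total biomass $n$ and total effort $E$:

$$\frac{dn}{dt} = r n\left(1 - \frac{\nu_1^{*2} n}{K_1}
  - \frac{(1-\nu_1^*)^2 n}{K_2}\right) - qQ\,nE, \qquad
\frac{dE}{dt} = (pqQ\,n - c)\,E,$$

where $Q = \gamma\nu_1^* + (1-\gamma)(1-\nu_1^*)$ is the effective harvest
weight. The logistic bracket defines an aggregate capacity
$K_\mathrm{eff} = (\nu_1^{*2}/K_1 + (1-\nu_1^*)^2/K_2)^{-1}$, which equals
$K_1 + K_2$ exactly when $\beta = 0$.

### Equilibrium and catch decomposition

Setting both derivatives to zero gives the open-access (bionomic)
equilibrium in closed form:

$$n^* = \frac{c}{pqQ}, \qquad
E^* = \frac{r}{qQ}\left(1 - \frac{n^*}{K_\mathrm{eff}}\right),$$

with zero profit ($pqQ n^* = c$) pinning the stock. The fishery is
*viable* iff $n^* < K_\mathrm{eff}$; otherwise effort collapses and the
model reports the boundary equilibrium $E = 0$, $n = K_\mathrm{eff}$ as a
complete record (not an error), so parameter sweeps stay total.
Equilibrium catch splits into an illegal reef component
$q\gamma\nu_1^* n^* E^*$ and a fishing-area component
$q(1-\gamma)(1-\nu_1^*) n^* E^*$; they balance exactly at
$\gamma = 1 - \nu_1^*$, independent of $n^*$ and $E^*$
(`catch_crossing_gamma()`).

## Parameters

| symbol | meaning | unit | default |
|---|---|---|---|
| `r` | fish population growth rate | / slow time | 0.5 |
| `K` | carrying capacity of the whole area | tons | 100 |
| `a` | fish mobility | / fast time | 2 |
| `c` | cost per unit effort | money / effort | 1 |
| `p` | fish price | money / ton | 1 |
| `q` (`q1`, `q2`) | catchability | / effort / slow time | 1 |
| `alpha` | protected fraction of the area | — | 0.2 |
| `V` | reef volume | m³ | scenario |
| `delta_k` | production effect | tons / m³ | 0.1 **or** 5 |
| `beta0` | attraction strength | — | 0.1 **or** 1 |
| `sigma` | attraction saturation scale | / m³ | 0.1 |
| `gamma` | illegal effort fraction | — | 0–1, swept |
| `epsilon` | timescale separation (full model only) | — | 0.1 |
| `mu` | effort redistribution speed (full model only) | / fast time | 1 |

`beta0` and `delta_k` deliberately have **no defaults** in
`reef_params()`: the reference parameter set lists two candidate values
for each (weak/strong attraction, low/high production), and silently
picking one would bake a scenario choice into every analysis. Presets
(`reef_preset()`) make the standard choices explicit: the figure scenarios
use `delta_k = 5`, `beta0 = 1`.

`epsilon` and `mu` only affect the full model; every reduced-model result
is independent of them. `epsilon = 0` is admitted as the pure-movement
singular limit, useful for checking that movement alone conserves
$n_1 + n_2$ and $E_1 + E_2$.

### The attraction function

The closed form of $\beta(V)$ is the one genuinely open modelling choice.
`reefar` ships three registered forms (`attraction_forms()`), defaulting
to the *multiplicative-saturating* variant

$$\beta(V) = \beta_0\,\frac{a}{(1-\alpha)K}\,(1 - e^{-\sigma V}),$$

chosen because (i) it is dimensionally an increment to the baseline
immigration rate $a/((1-\alpha)K)$, exactly where $\beta$ enters the
movement terms, and (ii) with the reference parameters it reproduces the
6 % catch-crossing for a 120 m³ reef. An absolute-saturating form
($\beta_0(1-e^{-\sigma V})$) and a linear form ($\beta_0\sigma V$) are
also registered, and `register_attraction()` accepts any user-supplied
`function(V, params)`, so an authoritative closed form can be dropped in
without touching the rest of the package.

Under all three shipped forms, the equilibrium catch at $\gamma = 0$ is
*monotone increasing* in $V$ (with `delta_k = 5`, `beta0 = 1`): no
interior optimum volume, no volume beyond which a fully protected reef
makes the fishery non-viable, and no small positive illegal-fishing rate
that maximizes catch. Model variants with other attraction closed forms
can produce all three features, which is precisely why the form is kept
pluggable. `find_optimal_volume()` returns an
explicit *monotone* verdict rather than presenting a bracket endpoint as
an optimum, and the finders are validated against dense-grid oracles on
synthetic attraction forms constructed to have interior structure.

## Numerical choices

* **Integration** uses `deSolve::lsodar` with `rtol = 1e-10`,
  `atol = 1e-12` and an early-exit root function. Convergence is declared
  when the relative right-hand-side norm
  $\max_i |\dot x_i|/(|x_i| + 10^{-8})$ falls below `conv_tol` (default
  $10^{-8}$) over the components that have not collapsed below
  $10^{-10}$; a collapsed effort component is treated as the boundary
  equilibrium. Scaling by the component's own magnitude matters: the
  open-access transient is a damped oscillation whose deep troughs pass
  exponentially close to the extinction saddle $(0,0)$, where the state is
  tiny but the dynamics are still fast relative to it — a norm scaled by
  the overall state size would declare spurious convergence there.
* **Non-negativity**: the solver evaluates the vector field at
  `pmax(state, 0)`; output values driven below zero by solver error are
  clipped to zero and counted, with a warning if any clip exceeds
  $\sqrt{\texttt{atol}}$.
* **Default horizon** `t_end = 2000` slow-time units with early exit; the
  damping rate of the equilibrium is $r n^*/(2K_\mathrm{eff})$, which can
  be of order $10^{-4}$ for large reefs, so convergence studies scale the
  horizon as $\sim 7/\lambda$ per scenario instead of fixing a short one.
* **Equilibrium-vs-integration checks** start from interior points at
  1.01–1.5× the analytic equilibrium. Far-off starts (e.g. $(50, 0.5)$)
  are also exercised once with a long horizon; they converge to the same
  point, but their troughs reach $n \sim 10^{-9}$, where effort can be
  numerically absorbed at any finite tolerance — a property of the
  numerics, not of the model.
* **Viability classification** uses
  $n^* < K_\mathrm{eff}(1 - 10^{-12})$ to avoid floating ties, and
  `find_viability_threshold()` bisects the margin
  $K_\mathrm{eff} - n^*$ to relative $10^{-6}$.
* **Optimum finding** is a coarse scan (121 points) plus golden-section
  refinement in the bracketing cell; plateau ties break to the smallest
  volume; monotone profiles return verdicts.

## What the scenario engine emulates — and what it does not

`sweep_volume()`, `sweep_gamma()` and `grid_attraction_production()`
regenerate the regime structure of the model family's standard panels:
catch against volume for illegal-effort levels 0–75 %, catch
decomposition against $\gamma$ at 120/200/500 m³, and the attraction ×
production grid at 200 m³ (grids of 2 m³ and 0.01 in $\gamma$, fine
enough to resolve percent-level features). Default grids and presets are
regeneration-deterministic: identical configurations produce
byte-identical CSV output.

These are *equilibrium* predictions of a deliberately minimal
demonstration model: one aggregated fish pool with logistic growth, no
species interactions, no migration across the domain boundary, no
seasonality or stochastic forcing, and effort that responds to profit
with no regulation other than the (imperfect) ban. Passing tests
therefore show the model's internal consistency and its qualitative
regime structure — they say nothing about predictive accuracy for any
real fishery.

Qualitative regime results the equations do support, and which the test
suite asserts: below the crossing volume, any illegal fishing lowers
total catch (catch strictly decreasing in $\gamma$ at 120 m³); under
heavy illegal fishing ($\gamma = 0.75$) catch declines with reef volume;
with an unfished reef, stronger attraction raises catch; raising cost
$c$ raises equilibrium catch while raising price $p$ lowers it, and
lowering catchability $q$ raises it (the usual open-access paradoxes:
whatever raises the zero-profit stock raises the sustainable yield).

## Worked example

```{r example}
m <- reef_model(beta0 = 1, delta_k = 5, V = 120, gamma = 0.05)
summary(m)
```

The fast–slow consistency diagnostic confirms the aggregation: the
long-time aggregate of the full system approaches the reduced
equilibrium as $\varepsilon$ shrinks.

```{r fastslow}
fast_slow_gap(reef_params(beta0 = 0, delta_k = 5, V = 0, gamma = 0.2),
              epsilon_list = c(0.2, 0.05, 0.01))[, c("epsilon", "gap")]
```

## Known limitations

* The closed form of $\beta(V)$ is the model's main degree of freedom:
  the shipped forms are dimensionally consistent with the movement terms
  and reproduce the 6 % crossing, but none of them produces an interior
  optimum volume at $\gamma = 0$; conclusions that hinge on an optimum
  volume require committing to a specific attraction form first.
* The reduced model requires a single catchability ($q_1 = q_2$);
  distinct values are allowed only in the full system.
* Stability is established numerically (trajectory convergence), not
  symbolically.
* Equilibrium catch accounting ignores the transient; with damping rates
  down to $10^{-4}$, real-time convergence to equilibrium can take
  thousands of slow-time units, which is itself a finding worth keeping
  in mind when interpreting equilibrium predictions.
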