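---
title: "Modeling radicalization as a three-compartment contact process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling radicalization as a three-compartment contact process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcon)
```

## The model and its assumptions

`radcon` implements a compartmental contagion model of radicalization in a
mixed population. A fixed fraction $\sigma_I$ of *inflexible* core agents
never changes state. The complement — the *sensitive* or flexible
subpopulation — is split at time $t$ into a *peaceful* fraction
$\sigma_P(t)$ and an *opponent* (radicalized) fraction $\sigma_O(t)$, with
$\sigma_I + \sigma_P(t) + \sigma_O(t) = 1$ at all times. Only two
transitions exist, both driven by pairwise contacts in a well-mixed
population:

* an opponent meeting an inflexible agent turns peaceful, at average rate
  $\alpha$ per unit time;
* a peaceful agent meeting an opponent turns opponent, at average rate
  $\beta$.

Mathematically this is an SIS-type mean-field model:
$$\frac{d\sigma_P}{dt} = \alpha\,\sigma_I\,\sigma_O - \beta\,\sigma_O\,\sigma_P,
  \qquad \sigma_O = 1 - \sigma_I - \sigma_P.$$

The assumptions worth keeping in mind: the population is well mixed (no
interaction topology), $\alpha$ and $\beta$ are constant on the time scale
of the dynamics, and time units are arbitrary — only the products
$\alpha t$, $\beta t$ matter, so rates and horizons can be rescaled
jointly.

## Closed-form algebra

Substituting the conservation constraint reduces the system to a
one-dimensional Riccati equation that factors as
$$\frac{d\sigma_P}{dt} = \beta\,(p_1 - \sigma_P)(p_2 - \sigma_P),
  \qquad p_1 = 1 - \sigma_I,\quad p_2 = \frac{\alpha}{\beta}\sigma_I.$$

Linearization gives eigenvalues $\lambda_1 = \beta(p_1 - p_2)$ at $p_1$ and
$\lambda_2 = -\lambda_1$ at $p_2$: the smaller root is always the stable
one. The opponent-free equilibrium ($\sigma_P = p_1$, $\sigma_O = 0$) is
selected exactly when
$$\sigma_I \ge I_c \equiv \frac{\beta}{\alpha + \beta}
  \quad\Longleftrightarrow\quad
  \frac{\alpha}{\beta} \ge \frac{1}{\sigma_I} - 1,$$
otherwise the coexistence equilibrium $\sigma_P = p_2$,
$\sigma_O = 1 - \frac{\alpha+\beta}{\beta}\sigma_I$ is reached.
`min_core_engagement()` inverts the threshold: given $\sigma_I$ and
$\beta$ it returns the engagement $\alpha^* = (1/\sigma_I - 1)\beta$ above
which radicalization is thwarted. `classify_regime()` reports two
*independent* labels: the core-majority case ($\sigma_I$ above, at, or
below $1/2$) and the thwarted flag. They are deliberately not merged — a
core majority still faces permanent radicalization when $\beta$ is large
enough, which is easy to miss if the two ideas are conflated.

Between the roots the ODE integrates in closed form:
$$\sigma_P(t) = p_2 + \frac{p_1 - p_2}
  {1 - \frac{\sigma_P(0) - p_1}{\sigma_P(0) - p_2}\,
       e^{\beta (p_1 - p_2) t}}.$$

```{r}
p <- model_params(sigma_I = 0.1, alpha = 12, beta = 2)
stability(p)
closed_form_sigma_P(p, sigma_P0 = 0.5, t = c(0, 1, 5, 50))
```

## Numerical choices

**Two independent routes.** Trajectories can be produced by the analytic
formula (`closed_form_sigma_P()`) or by `deSolve`'s `lsoda`
(`integrate_trajectory()`, tolerances `1e-12`); the test suite requires
them to agree below `1e-8` in sup-norm on all nine benchmark scenarios.
The opponent fraction is always derived pointwise from the conservation
constraint, so $\sigma_I + \sigma_P + \sigma_O = 1$ holds to machine
precision by construction.

**Degenerate closed form.** At the marginal threshold $p_1 = p_2 = p$
(exactly $\sigma_I = I_c$) the generic formula is $0/0$. The double-root
limit of the Riccati solution is
$$\sigma_P(t) = p + \frac{u_0}{1 - \beta u_0 t}, \qquad u_0 = \sigma_P(0) - p,$$
and since $u_0 \le 0$ in the physical domain the denominator never
vanishes for $t \ge 0$. This form was verified against the numerical
integrator before being adopted. The approach to equilibrium here is a
power law, not an exponential; the marginal case is classified as thwarted
in the limit ($\sigma_O \to 0$), which keeps the equilibrium surface
continuous across the critical curve.

**Overflow guard.** For large $\beta(p_1-p_2)t$ the exponential in the
closed form is never evaluated; the analytic limit (the stable root) is
returned instead.

**$\beta = 0$.** The coexistence root $p_2$ is undefined; the dynamics
degenerate to exponential decay of $\sigma_O$ at rate $\alpha\sigma_I$.
`equilibrium_roots()` and `stability()` report this as a flagged
degenerate case with $\sigma_O^{eq} = 0$ rather than dividing by zero.
The closed form refuses $\beta = 0$; the integrator handles it.

**Horizons and grids.** The default output grid is 512 evenly spaced times
on $[0, t_{\max}]$ with $t_{\max} = 20/|\lambda|$ of the stable root, so
the equilibrium is resolved to $e^{-20} \approx 2\times 10^{-9}$ relative
accuracy; in the marginal case $t_{\max}$ defaults to $200/\beta$. Both
are configurable.

**Tolerances.** Floating-point comparisons (root coincidence, domain
checks, boundary cells in the phase grid) use a single configurable
absolute tolerance, default $10^{-9}$ (`model_params(tol = )`). Extinction
is declared at $\alpha \ge \alpha^*$ — non-strict, with the equality case
flagged marginal — consistent with treating the closure of the thwarted
region as thwarted.

## Radicalization indices

Two indices summarize a state: $\zeta = \sigma_O/(1-\sigma_I) \in [0,1]$,
the opponents' share of the flexible subpopulation, and
$\eta = \sigma_O/\sigma_I \in [0,\infty)$, opponents per core agent. Both
recover $\sigma_O$ algebraically ($\eta\sigma_I = \zeta(1-\sigma_I) =
\sigma_O$), which the tests check to $10^{-12}$. Edge cases are flagged,
not fatal: $\zeta := 0$ when $\sigma_I = 1$ (no flexible agents), and
$\eta = \infty$ with a flag when $\sigma_I = 0$.

`interpret_radicalization()` maps $(\zeta, \eta, \sigma_I)$ onto advisory
labels. The underlying theory describes the regions only qualitatively
("$\zeta$ close to 1", "high $\eta$"), so the numeric cutoffs are package
defaults, chosen once: $\zeta_{low} = 0.25$, $\zeta_{high} = 0.75$, and
$\eta_{high} = 1$ — the natural scale at which opponents outnumber the
core. All three are arguments; the labels are never used in computation.

## The stochastic counterpart

`run_abm()` simulates the finite-$N$ contact process whose large-$N$ limit
is the ODE: $N$ agents, two aggregate reaction channels,
$$O \to P \text{ at rate } \alpha\,\tfrac{n_I}{N}\,n_O, \qquad
  P \to O \text{ at rate } \beta\,\tfrac{n_O}{N}\,n_P,$$
simulated exactly with the Gillespie direct method (compiled code, R's
RNG, bit-reproducible under a seed). The per-capita hazards are normalized
by $N$ precisely so that the expected dynamics of the densities $n_X/N$
obey the mean-field equations with the *same* $\alpha, \beta$. The
underlying theory specifies the rates and the contact-process reduction
but not an event-scheduling scheme; the exact continuous-time Markov chain
was chosen because it removes the ambiguity that discrete-time activation
regimes are known to introduce in opinion-dynamics models. A discrete-time
polling scheme would be a possible alternative backend; it is not
implemented.

What the stochastic runs emulate — and what they do not: they reproduce
demographic (finite-size) noise around the deterministic flow, absorption
at $n_O = 0$, and the $O(1/\sqrt{N})$ convergence of replicate means to
the ODE equilibrium, all in a well-mixed population. They do not emulate
network structure, agent heterogeneity in $\alpha, \beta$, or time-varying
rates, so agreement here says nothing about those effects in real data.

```{r}
cfg <- abm_config(n_I = 100, n_P = 500, n_O = 400, alpha = 12, beta = 2,
                  t_max = 15, seed = 7, replicates = 4)
summarize_replicates(run_abm(cfg))$mean_sigma_O  # ODE equilibrium: 0.3
```

## Phase diagrams

`classify_grid()` maps the thwarted/permanent classification over
$(\sigma_I, \alpha/\beta)$ — the fate depends on the rates only through
their ratio. Default grids are 99 points on $\sigma_I \in [0.01, 0.99]$
and 100 log-spaced points on $\alpha/\beta \in [0.01, 100]$; log spacing
resolves the critical curve $1/\sigma_I - 1$, which diverges as
$\sigma_I \to 0$. Cells on the curve (within tolerance) carry a distinct
marginal flag so renderers can draw the boundary. The tabular grid is the
tested artifact; `plot_phase_diagram()` is cosmetic.

## Benchmark scenarios and problem sizes

`worked_scenarios()` ships nine named parameter sets (`a`–`i`) spanning
the regimes: symmetric rates with coexistence, strong opponent activism
($\beta \gg \alpha$), and core engagement above the critical threshold.
They are the fixtures used throughout the tests and by
`scripts/acceptance.R`. The test suite integrates each on the default
512-point grid, sweeps 200 random parameter sets for the algebraic
invariants, and validates the stochastic simulator at
$N \in \{10^2, 10^3, 10^4\}$ with 8–32 replicates — sizes at which every
check runs in seconds while finite-size errors are already an order of
magnitude below the acceptance tolerances.

## Known limitations

* No estimation: $\alpha, \beta$ are inputs, never fitted to data.
* Constant rates and a well-mixed population; no networks, no multiplex
  structure, no time-varying $\alpha(t), \beta(t)$.
* Exactly three compartments; the inflexible fraction never changes.
* The advisory labels attach no validated real-world meaning to their
  thresholds.
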