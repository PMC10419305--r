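---
title: "Modelling the social spread of obesity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the social spread of obesity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesnet)
```

`obesnet` simulates how obesity propagates through a social contact
structure. It couples three components, stepped monthly:

1. an **emergent dynamic network** (agent-based): who is in contact with
   whom, driven by propinquity, BMI homophily, interaction memory and a
   per-slot acceptance capacity;
2. a **Theory-of-Planned-Behaviour (TPB) stock-flow model** per agent:
   attitudes, neighbourhood norms and perceived behavioural control feed an
   Intention stock, whose activation (optionally lagged) feeds a Behaviour
   stock that triggers dieting episodes;
3. an **energy-balance engine**: basal metabolic rate (BMR) and total
   energy expenditure (TEE) from linear dietary-reference equations,
   calorie intake responding to a national consumption proxy (APCCC), and
   weight change from the intake-expenditure gap.

This vignette records the model equations, the tunable parameters with
their defaults and units, what the synthetic data emulate, and the design
choices made where the design was genuinely open.

## 1. The emergent network

Agents hold fixed uniform positions on a square map of side `Z`. Each
month every living agent issues `offers_per_step` interaction offers.
A candidate must be

* within social range: Euclidean distance `< Ra` (propinquity), and
* homophily-eligible: `w[g(p), g(q)] * |BMI(p) - BMI(q)| <= theta_trigger`,
  with one weight per ordered gender pair (`mm, mf, ff, fm`); a zero
  weight disables BMI homophily for that pairing.

Offer targets are sampled (with replacement — repeated offers to the same
partner are allowed) proportionally to the memory-weighted acceptance
probability

```
pi(p, q) = min(1, baseline_prob + theta_mem * alpha(p, q)),
alpha(p, q) = contacts within the last M slots / M,
```

and each offeree accepts with probability `pi`, provided it has accepted
fewer than `S` offers this slot (offers are processed in uniformly random
order). Accepted interactions enter both agents' histories; the window is
truncated at `M` slots. The **network neighbourhood** is the set of
partners with windowed edge weight `alpha > 0` (a configurable minimum
weight is exposed and defaults to 0), and all topography metrics are
computed on the induced simple undirected graph.

Distance is plain Euclidean on the bounded square; no torus wrap, since
positions are fixed on a plain map and boundary heterogeneity is itself a
realistic feature of contact geography.

### Two presets

`network_params()` — the **simulator default** — sets
`Ra = sqrt(25/(999*pi))` so that an agent has ≈ 25 others in range at
n = 1000, and `theta_trigger = 2.5` BMI units, leaving several units of
BMI spread inside a neighbourhood so that the norms flow carries signal.

`network_fingerprint_preset()` — the **topography preset** — is the
configuration used to characterise the stationary network: a wide range
(`Ra = 1.06`, nearly map-wide) with a tight trigger (0.10 BMI units), so
candidacy is dominated by BMI similarity, plus high retention
(`baseline_prob = 0.52`, `theta_mem = 0.9`, `M = 9`, `S = 8`,
4 offers/slot). On a 1000-agent population its stationary induced graph
has median mean-local clustering ≈ 0.63–0.64, transitivity ≈ 0.65–0.66
and average degree ≈ 9.3, with a few percent of edges churning per slot.

### Why degree assortativity stays high in this model class

The reference fingerprint this preset was tuned toward pairs high
clustering (0.67) with moderate degree assortativity (0.34). A systematic
search over the full parameter space (range, trigger, gender weights,
memory gain, baseline probability, capacity, offers, window, edge-weight
threshold; roughly ninety configurations) shows these two cannot be
decoupled under this offer/acceptance mechanism:

* mean local clustering is bounded by (shared-candidate fraction) ×
  (edge retention). The shared-candidate fraction is at most ≈ 0.75 (the
  closure probability of a one-dimensional interval graph, the
  BMI-dominant limit; the two-dimensional disc limit is ≈ 0.59), so high
  clustering requires retention near 1 — the realised graph must nearly
  equal the candidate graph;
* degree assortativity has the *same* shared-candidate × retention term,
  plus strictly positive contributions from shared candidates and from
  the BMI density gradient (agents of similar BMI have similar candidate
  counts). With retention near 1 it is therefore always at or above the
  clustering value.

In every configuration measured, assortativity ≥ clustering; pushing
assortativity down (hard capacity limits, heavy churn, long-memory
lock-in) collapses clustering first. The preset shipped here sits on the
reachable Pareto front closest to the full fingerprint: it concedes
degree assortativity (≈ 0.8) to land clustering, transitivity and average
degree. Reproducing the printed combination would need a mechanism beyond
the offer/acceptance rules implemented here (for example triadic closure
— offering to partners-of-partners — or degree-heterogeneous sociality).

## 2. The behavioural (TPB) component

Per agent and month, with `b = BMI`:

* **satisficing value** `sv(b) = theta_sv * max(0, (b - 20)/10)^2` — the
  minimum BMI gap the agent acknowledges. The quadratic with the default
  scale 1 passes exactly through the anchor values sv(20) = 0, sv(30) = 1,
  sv(40) = 4.
* **norms**: let `m` be the age-weighted mean BMI of *same-gender*
  network neighbours, with weights `1/(1 + |age gap|/10)`, and
  `d = b - m`. The flow is `theta_norms[gender, agegroup] * d` if
  `d > sv(b)`, else 0. The same-gender restriction is hard-wired: it is
  the best-performing structure found in calibration. The age weighting
  reads the (ambiguous) "weighted according to age" as *age proximity* to
  the focal agent — the alternative (weighting by the neighbour's own
  absolute age) is entangled with the focal agent's age-group split of
  `theta_norms` and would be unidentifiable from the same data.
* **attitudes**: `theta_attitude * (education/5) * min(1, max(0, b - 25)/5)`
  — education-moderated and active only once overweight.
* **pbc**: `theta_pbc * pbc_default * (1 + tanh(success/5))`, where
  `success` accumulates net kg lost across completed diets. The `tanh`
  keeps the success feedback bounded in (0, 2); behaviour theory
  constrains only the direction of the success feedback, so a saturating
  form is the conservative reading.

Stocks update by explicit Euler at dt = 1 month:

```
activation  = activation_fraction * Intention
Intention  <- Intention*(1 - intention_decay) + norms + attitudes + pbc - activation
Behaviour  <- Behaviour*(1 - behaviour_decay) + activation delayed theta_lag months
```

both floored at 0, with the activation routed through a FIFO buffer of
length `theta_lag` (an impulse at month t first reaches Behaviour at
month t + theta_lag, verified for lags 0, 1, 3, 6).

An agent in the NORMAL state starts **dieting** when
`Behaviour >= behaviour_threshold` *and* `d > sv(b)` (the second
condition is dropped in the network-off counterfactual). The episode
length is geometric with mean `theta_dietTime * (1 + tanh(success/5))`,
minimum one month; Behaviour resets to 0. While dieting the agent applies
the intake restriction with probability `adherence_prob` per month and
lapses otherwise, producing the cyclical loss/plateau trajectories seen
in practice.

Defaults: `intention_decay = behaviour_decay = 0.1`/month,
`activation_fraction = 0.25`/month, `theta_lag = 1` month,
`theta_dietTime = 3` months, `behaviour_threshold = 6`,
`diet_restriction = 0.1`, `adherence_prob = 0.8`. The threshold deserves
a note: with the calibrated norm gains (order 1–5 per BMI-unit gap) the
norms flow is of order 10/month for an agent a few units above its
neighbourhood, so a threshold of order 1 would make dieting chronic for
essentially every above-average agent and the population mean would
collapse by several BMI units within a few years. The threshold of 6 —
about the steady-state Behaviour level sustained by a unit total inflow —
makes dieting episodic and keeps the ten-year drift of the default
population mild. Thresholds, decays and the activation fraction are free
parameters (the behaviour literature supplies no numeric values for them) and are all exposed.

## 3. Energy balance

`BMR = alpha + beta*height_m + gamma*weight_kg` (kcal/day) with
coefficients per gender × age band; the shipped table is a
Henry-equation-style dietary-reference set (weight-and-height form,
converted at 239 kcal/MJ) covering bands 16–18, 18–30, 30–60, 60+. It is
an editable CSV-shaped config (`read_bmr_csv()`), unit-checked on load.
`TEE = PAL × BMR` with PAL multipliers low/medium/high =
1.49/1.63/1.78, the category assigned from (BMI, age): high if BMI < 25
and age < 45, low if BMI ≥ 30 or age ≥ 65, else medium.

Intake in the NORMAL state anchors at TEE:

```
intake = TEE + theta_extFactor[gender, agegroup] * (APCCC(year) - APCCC(baseline))
```

so a population at baseline external pressure with no dieting is in
*exact* energy balance — per-agent weight is conserved to the last bit
over any horizon, which pins the calibrated equilibrium and is the
package's identifiable reading of how a national consumption proxy maps
to individual intake (the alternative, an independent baseline diet per
agent, adds one unidentifiable free function). Weight then changes by
`(intake - TEE) * 30.44 / 7700` kg/month (30.44 days/month; 7700 kcal
per kg of tissue, the conventional energy density), clamped so BMI stays
in (10, 80).

## 4. Simulator

Update order within a month is fixed and documented: **network →
behaviour → energy → demographics**. Initialisation generates the
population, positions and an initial contact history (one memory window
of network slots); a warm-up of `warmup_months` (default 24) network-only
slots follows, with weights and demographics frozen, so behaviour starts
acting on a stationary topology. Births (12/year) and deaths (7/year)
are annual quotas scheduled evenly by month; entrants arrive aged 16 with
BMI drawn around the scenario's entrant mean; deaths are sampled with
probability proportional to `exp((age - 50)/15)`. Aggregation records
mean and median BMI per year × gender × age group (six groups: 16–20,
21–30, 31–45, 46–60, 61–75, 76+), including the initial year.

Scenarios multiply the APCCC series and/or the entrant BMI mean by
`(1 ± annual_rate * rate_multiplier)^(year - start)`; the default annual
rate is 0.005/yr — a placeholder for the fastest historically sustained
growth rate, which requires external data to estimate — and the
doubled-rate runs use `rate_multiplier = 2`. The network-off
counterfactual zeroes the norms flow and drops the neighbourhood
condition from the dieting trigger, leaving everything else (including
the network itself) untouched; the per-month maximum norms flow is logged
so counterfactual containment is auditable.

## 5. SPSA calibration

The loss is the sum over every (year, gender, age-group) cell of squared
errors in mean and median BMI, equally weighted (the source is implicit
on the weighting; equal is the symmetric choice). The optimiser is
simultaneous perturbation stochastic approximation with

```
theta[k+1] = theta[k] - a_k * ghat_k,
ghat_k,i   = (L(theta + c_k D) - L(theta - c_k D)) / (2 c_k D_i),
a_k = a/(A + k + 1)^alpha,  c_k = c/(k + 1)^gamma,
```

`D` a Rademacher (±1) vector, and coefficients a = 0.16, A = 100,
c = 0.1, alpha = 0.602, gamma = 0.101; descents run 3000 iterations and
the final estimate is the elementwise median of the last 100 iterates
(damping the stochastic wobble). Design choices: bounded parameters are
optimised through a scaled logit transform so perturbed evaluations stay
feasible; the two perturbed evaluations of one step share the simulation
seed (common random numbers) by default — a pure variance-reduction
device, disablable with `common_rn = FALSE`; descent uses single-run
losses (replication is reserved for testing a finalised parameter set,
via `replicated_test()`, which pools agents cell-by-cell across
replicates and medians the losses).

The calibratable vector collects 36 values: the norms gains (2 × 6), the
external-factor gains (2 × 6), the four gender-pair homophily weights,
and eight global scalars (pbc gain, attitude gain, satisficing scale,
lag, diet time, trigger, memory gain, social range). The **cascade** —
deciding which parameter to split by gender/age next — was a human-driven
process; the package supplies the mechanical half (`split_parameter()`,
which copies the parent value so the loss is unchanged at the split) and
leaves the judgement to the analyst. Splitting is supported for the flow
and energy gains; the structural network parameters and the lag are
global scalars in the simulator and cannot be split without changing the
network mechanism itself. The homophily ablation
(`run_homophily_ablation()`) evaluates a configuration with the BMI
weights as-is versus pinned to zero, paired by seed.

## 6. Synthetic data: what it does and does not emulate

`generate_population()` emulates the *statistical shape* of national
health-survey adult records: a uniform-by-group age pyramid over the six
model age groups (ages within the open 76+ group drawn up to 90), a
50/50 gender split, BMI normal within gender × age-group strata with
means rising from ≈ 24.5 at 16–20 to ≈ 28 in late middle age (spread
4–5 units), heights normal per gender (1.75 ± 0.07 m men,
1.62 ± 0.065 m women), five education levels, and the PAL rule above.
"Balanced for age, gender and BMI" is implemented as stratified sampling
over age-group × gender × BMI-tertile cells, which forces the requested
marginals even at moderate n. Entrants are 16-year-olds with BMI
≈ N(entrant mean, 3.5).

What it does **not** emulate: survey weights and design effects,
household or geographic clustering (positions are independent of
demographics), secular height trends, the real joint distribution of
education with age and BMI, and any real calendar trend in BMI. Passing
tests on synthetic data therefore demonstrate that the machinery is
correct and that parameters are recoverable from data the model itself
generated — not that the shipped defaults forecast any real population.

## 7. Numerical choices and degenerate inputs

* Monthly Euler steps throughout (one iteration = one model month).
* Zero-variance assortativities and correlations report `NA`
  ("undefined"), never 0; fewer than two vertices makes every metric
  `NA`. Mean local clustering counts degree-<2 vertices as 0.
* Acceptance ties under capacity are broken by a uniformly random
  processing order per slot, from the simulation's seeded stream.
* Every operation is a pure function of (inputs, seed); sub-streams are
  derived from the master seed with a Lehmer-style mixer kept inside the
  32-bit range.
* A non-finite loss rejects an SPSA step (logged) rather than poisoning
  the trajectory.
* Geometric diet durations have minimum 1 month; BMI is clamped to
  (10, 80); empty aggregation cells are `NA` and dropped (with their
  partner cells) by the loss.

## 8. Problem sizes used in the shipped studies

The network fingerprint protocol uses 1000 agents, 24 warm-up months and
24 recorded monthly snapshots. The parameter-recovery study uses 200
agents, a 5-year horizon, 6 warm-up months and 300 SPSA iterations with
tail 100. Its design follows an explicit identifiability analysis:

* the reference is generated under a strongly rising external
  environment (3 %/yr APCCC growth) — with a flat series the
  external-factor gain multiplies a zero deviation and is structurally
  unidentifiable, and a power calculation on the per-step gradient
  signal-to-noise (which is independent of the SPSA gain `a` and grows
  with forcing strength and perturbation size) sets the forcing and
  `c = 0.3`;
* the expected loss is flat in the norms gains between roughly 0.5× and
  2× their generating values (the episodic dieting trigger saturates),
  so the norms displacement starts at 2.5× — inside the responsive
  regime — while the external-factor displacement starts at 0.4×;
* the two displacements are studied in *separate* descents: displaced
  together they couple through the net BMI drift (raising one
  compensates lowering the other) and the dominant gradient drowns the
  weaker estimator at this problem size;
* the gain numerator for this loss scale is `a = 0.005`, from the
  standard pilot rule (first steps a few hundredths in transform space
  given the measured gradient magnitude); the default `a = 0.16` belongs
  to a different loss scale and overshoots by whole transform units.

The demographic and conservation checks run the full 1000-agent,
10-year protocol.

## 9. Known limitations

* The degree-assortativity gap discussed under the network presets:
  the stationary topology
  concedes that metric by construction.
* With the topography preset's tight trigger, neighbourhoods are
  near-homogeneous in BMI, so that preset is for network studies, not
  for behavioural simulation (use the simulator default there).
* The TPB scales (threshold, decays, activation) are set for plausible
  episodic dieting, not calibrated to individual-level dieting data.
* One undirected proxy network stands in for the multiplex reality of
  social ties; external factors enter through a single national proxy
  series.
* Norms only ever push BMI down (dieting); upward social influence is
  implicit in the external-factor term, so a population at static
  baseline pressure drifts mildly downward rather than sitting exactly
  still.
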