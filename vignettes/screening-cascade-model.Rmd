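---
title: "A stochastic screening cascade feeding a treatment queue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic screening cascade feeding a treatment queue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenflow)
```

## What the model is

`screenflow` simulates, in discrete time, a population screened for a
condition and routed toward treatment: each period a cohort enters, is
screened (or not), screens positive (or not), is offered a referral,
completes it, and joins a treatment queue served by a finite, changing
workforce. The motivating application is universal trauma screening for
children entering foster care, where the decision-relevant questions are
not about the instrument alone but about the *system*: demand for
treatment, workforce capacity, waitlists, and the sensitivity of the whole
process of care rather than of the screener.

The model is deliberately simple — counts, not agents. Every cascade stage
is a binomial thinning of the previous one, because no individual-level
covariates exist in the model; individual bookkeeping is kept only where
first-in-first-out queueing requires it (arrival-period tags on waitlist
entries). Two strata are tracked throughout, entrants with and without the
condition, because referral and retention probabilities plausibly differ
between them and because the false-positive load on the treatment system
is itself a planning quantity.

## The cascade

With cohort inflow $N$, prevalence $\pi$, reach $r$, instrument operating
point $(Se, Sp)$ and stratum-specific referral/completion probabilities,
one period's counts are drawn as

$$n_{+} \sim \mathrm{Bin}(N, \pi), \qquad
  \text{screened} \sim \mathrm{Bin}(n, r),$$
$$\text{positive} \sim \mathrm{Bin}(\text{screened}, Se)\ \text{or}\
  \mathrm{Bin}(\text{screened}, 1-Sp),$$

and so on down the chain. Successive binomial thinning keeps every stage
count marginally binomial with success probability the product of stage
probabilities, so the deterministic companion `expected_cascade()` is an
*exact* expectation, not an approximation — the test suite uses it as the
oracle for law-of-large-numbers checks (ensemble means within 3 Monte-Carlo
standard errors at inflow 10,000).

Screening happens once, at entry; screen-negatives and referral
non-completers leave the model for good. Re-screening and re-entry are out
of scope.

## The instrument

Rather than specifying sensitivity and specificity per threshold as free
inputs, the instrument is a binormal latent-score model: class-conditional
scores $X_0 \sim N(\mu_0,\sigma_0)$ and $X_1 \sim N(\mu_1,\sigma_1)$, a
screen being positive when the score strictly exceeds the cut $c$ (ties
score negative; with a continuous score ties have measure zero, but the
rule matters for integer-score extensions). Then

$$Se(c) = 1 - \Phi\!\left(\frac{c-\mu_1}{\sigma_1}\right), \qquad
  Sp(c) = \Phi\!\left(\frac{c-\mu_0}{\sigma_0}\right),$$

which realizes the cut-score trade-off — raising $c$ lowers $Se$ and
raises $Sp$, monotonically — with five interpretable parameters and closed
forms that an independent numerical-integration oracle verifies to 1e-8 in
the tests. The binormal family is the standard ROC model in the screening
literature; a direct per-threshold Se/Sp table can be emulated by choosing
means/SDs that pass through the desired operating point.

## The service system

Completed referrals arrive on a FIFO waitlist. Each provider carries
`slots_per_provider_per_period` concurrent cases; a treatment occupies its
slot for `treatment_duration_periods` periods, so new-start capacity is
total slots net of the continuing caseload (steady-state throughput per
provider is slots/duration starts per period).

The within-period event order is fixed, documented, and pinned by tests,
because the results depend on it:

1. pending hires maturing this period join the provider pool;
2. provider quits are drawn Binomial(providers, quit probability);
3. treatments in progress advance; completions release slots;
4. waitlist dropout is drawn per waiting person;
5. the period's arrivals join the waitlist tail;
6. up to capacity, waitlist entries are scheduled FIFO; each scheduled
   start misses with the missed-appointment probability — a miss wastes
   the slot for the period (when configured) and returns the person to the
   *head* of the waitlist, the one documented exemption from strict FIFO;
7. the reactive hiring rule is evaluated on the post-step
   waitlist-per-provider ratio; orders mature after the hiring lag and are
   never cancelled, mirroring real procurement lags and keeping the state
   monotone.

When a scheduling batch cuts partway through the group of people who
arrived in the same period, the split between strata is hypergeometric —
people within a period are served in random order, so neither stratum is
systematically favoured.

Missed appointments implement the mechanism by which a miss can expend a
provider's slot while simultaneously adding back to the waitlist; with
miss probability $m$, wasted slots, and saturated demand, long-run
throughput is capacity × (1 − m), which the tests verify against a
500-period run.

Treatment duration is deterministic; geometric completion is a listed
extension, not implemented.

## Feedback loops

Long waits plausibly feed back on the system: families decline or fail to
complete referrals, and providers burn out and quit. The model exposes
this as an optional saturating (Michaelis–Menten-form) multiplier on an
expected-wait proxy $w = \text{waitlist} / \max(\text{capacity}, 1)$
(a Little's-law-style estimate computable without individual tracking):

$$f(w) = \frac{w}{w + w_{1/2}} \in [0, 1),$$

with `wait_scale_periods` $w_{1/2}$ the wait at which the effect reaches
half its maximum. Referral and completion probabilities are scaled by
$1 - s_{\max} f(w)$ and the quit probability by $1 + a_{\max} f(w)$
(capped at 1). The functional form is a package design choice — bounded,
monotone, two interpretable parameters; the qualitative direction (longer
waits, fewer completions, more quits) is the substantive claim, and the
paired-ensemble tests check direction, not shape.

## Parameters, units, defaults

A period is one month (`periods_per_year = 12`, overridable): reported
dynamics of interest play out over "the first 2 years", and hiring lags of
a few months need sub-annual resolution. Ensembles default to 20 seeded
runs (run $i$ uses `base_seed + i - 1`), summarized by the per-period mean
(the darkened average line over the fan of trajectories) and the min/max
envelope — the envelope is min/max rather than quantile bands because with
20 runs the full fan is the honest display.

The bundled scenarios are *illustrative*, chosen once from plausible
published ranges; no administrative data are fitted. The baseline
describes a mid-size system: 200 children entering per month, prevalence
0.40, reach 0.90, instrument $N(0,1)$ vs $N(1.5,1)$ with recommended cut
0.5 ($Se \approx 0.84$, $Sp \approx 0.69$) and raised cut 1.5
($Se = 0.50$, $Sp \approx 0.93$), referral probabilities 0.8/0.6 and
completion probabilities 0.7/0.5 by stratum, six providers with 12
concurrent slots each, 3-month treatments, 1%/month quits, reactive hiring
(trigger ratio 3, one hire per trigger, 3-month lag), 1%/month waitlist
dropout and 5% missed appointments over a 60-month horizon.

These values were sized by expected-value arithmetic so that the
qualitative phenomena of interest are present: expected demand at the recommended cut
is ≈ 44 completed referrals/month against an initial steady-state
throughput of ≈ 24 starts/month, so a waitlist builds and — with reactive
hiring catching up at roughly one provider per month after the 3-month lag
— peaks around month 9–12, inside the first two simulated years. At the
raised cut expected demand is ≈ 22/month, just under initial throughput,
so waitlists stay short while cumulative treated with-condition children
drop by roughly 40%.

## Fixture regimes and what the tests do (and do not) show

Randomized test scenarios are drawn from regimes that make each
qualitative claim testable: `over_capacity` (expected demand above initial
throughput — waitlist growth), `under_capacity` (throughput at least twice
demand — unconstrained-queue oracles), `balanced` (within 25%),
`feedback_on`, and `deterministic` (all probabilities 0 or 1 — exact
fluid-limit checks). The regime relation is solved at generation time from
the expected cascade, then re-verified, so every draw honours its
guarantee.

The generator emulates stationary inflow with a fixed prevalence and a
single screen per entrant. It does **not** emulate time-varying prevalence
or caseness definitions that differ between instrument validation and
clinical practice, seasonal inflow, provider heterogeneity, or re-entry —
so green tests demonstrate internal correctness of the simulator and the
direction of its trade-offs under stationary assumptions, not numerical
fidelity to any real system. No published figure values exist to calibrate
against, and the package makes no such claim.

## Numerical choices and degenerate inputs

* All randomness flows through R's global RNG, seeded once per run;
  identical config + seed is byte-identical output, and sweeps and
  experiments reuse per-run seeds across arms (common random numbers) so
  monotone contrasts are reliable at 20 runs.
* "Time to balance" is the first period with ensemble-mean capacity ≥
  ensemble-mean arrivals sustained for 3 consecutive periods (`NA` if
  never) — an artifact definition, stated because no standard one exists.
* Process metrics guard their denominators: a stratum with no entrants (or
  no treated individuals, for the false-positive fraction) yields `NA`
  plus an `undefined` flag, never 0/0.
* Zero providers, zero inflow, reach 0, probabilities at exactly 0 or 1,
  and empty optional config blocks are all legal and tested.
* YAML round-trips write numerics at 15 significant digits; config hashes
  canonicalize at 10 digits so a hash is recomputable from a saved file.
* Problem sizes in the test suite (ensembles of 2–20 runs over 4–60
  periods; one 500-period single run; 1,000 fixture draws) were chosen to
  make Monte-Carlo assertions sharp at 3 standard errors while keeping the
  suite quick to run.

## Known limitations

Counts-based thinning cannot carry individual covariates, so any policy
whose effect differs across unmodelled subgroups is out of reach. The
expected-wait proxy understates waits when capacity is transiently zero.
Hiring rules are deliberately coarse (ratio trigger or fixed schedule);
the package does not claim either matches any specific system's
procurement process, and the choice between them — like the lag length —
is a scenario input, not an estimate.
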