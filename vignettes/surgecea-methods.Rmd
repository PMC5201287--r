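---
title: "Methods: an agent-based extended cost-effectiveness analysis of surgical care delivery"
author: "surgecea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an agent-based extended cost-effectiveness analysis of surgical care delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

In many low-income health systems, surgery for cancer is simultaneously
life-saving and financially ruinous: patients who reach care risk
catastrophic out-of-pocket spending, and patients who cannot reach it risk
death — which itself can impoverish the household left behind.  `surgecea`
implements an extended cost-effectiveness analysis (ECEA) of this
trade-off: a daily-cycle agent-based microsimulation of a Ugandan-style
surgical oncology system, evaluated jointly on health (cancer deaths
averted), financial risk protection (catastrophic expenditure and
impoverishment averted) and equity (the distribution of those benefits
across wealth quintiles), under nine policy and delivery-platform
scenarios compared against the status quo:

* **UPF** — universal public financing: surgery free at the point of care
  in public hospitals; non-medical costs untouched.
* **TS** — task shifting: surgical provider supply (and hence daily
  capacity) expanded at first-level hospitals; prices untouched.
* **UPFTS** — both.
* **UPF^V^, TS^V^, UPFTS^V^** — each combined with transport vouchers
  that move travel costs onto the program.
* **2W** — semi-annual two-week surgical mission trips to a regional
  referral hospital, rotating round-robin across trips.
* **MS** — a mobile surgical unit cycling an itinerary of regional sites
  (one site active every day).
* **CH** — a free-standing charitable cancer hospital at a fixed site.

Each simulated day cycles: cancer incidence → care-seeking for untreated
cases → treatment outcomes and cost booking → financial flagging →
untreated progression → background births and deaths.  An experiment runs
the status quo and every scenario for each of `n` probabilistic parameter
sets (default 100) over a 50-year horizon (18,250 days), with common
random numbers across arms so that "averted" quantities difference out
shared Monte-Carlo noise.

## The synthetic world

All inputs are generated, with documented statistical structure, by the
`generate_*` family; every value is a function argument and can be
overridden.  The generator emulates the *structure* of the Ugandan data
environment (a DHS-style demographic survey, a gamma income distribution,
a geolocated public hospital network, seven-cancer registry magnitudes);
it does not claim to reproduce any specific published parameter table,
and results from the default fixture should be read as
methods-demonstration output, not country estimates.

* **Cohort** (default 10,000 agents): ages and sexes from a young,
  high-fertility pyramid; households drawn from a size distribution with
  mean ≈ 4.7 and placed on a 50 × 50 raster of 10-km cells with two urban
  hotspots; members are co-located.  Background mortality (0.009 per
  person-year) and fertility (0.18 per woman 15–49 per year) keep the
  cohort open.
* **Income and poverty**: annual individual income is gamma(shape 1.5,
  scale 550); the national poverty line is *endogenous*, defined as the
  income quantile below which 19.5% of the instantiated cohort lives, so
  the poverty headcount is calibrated by construction.  The line sits
  midway between the k-th and (k+1)-th order statistics, k = round(0.195
  n), making the strictly-below share exact up to 1/n quantization.
  Wealth quintiles are assigned once, by baseline income rank, and are
  never re-ranked mid-run (they index the distributional outcome tables).
* **Facilities**: 53 public hospitals (37 district, 14 regional, 2
  national) sampled proportional to population density, the
  highest-level hospitals in the densest cells.  Level determines price
  ($150/$250/$400 per case), perioperative mortality (8/5/3%),
  complication rate (15/12/10%), providers and daily surgical capacity
  (1/2/4 cases).
* **Cancers**: the seven most common (Kaposi sarcoma, cervical, breast,
  prostate, esophageal, liver, non-Hodgkin lymphoma) with 2012-vintage
  population-wide crude incidence magnitudes summing to ~75 per 100,000
  person-years, untreated median survivals of 4–46 months, and surgical
  cure probabilities that rise with provider level.
* **Uncertainty**: every uncertain scalar carries a descriptor from the
  closed family set {point, gamma, beta, lognormal, uniform}:
  probabilities are beta with an effective sample size of 50 around their
  point value, costs gamma with CV 0.2, survival medians lognormal with
  sdlog 0.2, incidence uniform ±25%.  A parameter set is a reproducible
  draw keyed by (base seed, index); per-cancer quantities are drawn once
  per cancer, per-level quantities once per cancer × level.

## Care-seeking

Whether, and where, to seek care is a two-level nested logit: a singleton
"no care" nest against a "seek care" nest containing every public
facility and active platform site within 300 km (capacity-exhausted
facilities drop out of that day's choice set).  The systematic utility of
a care alternative is

V = β~cost~ (price + transport) + β~dist~ distance + β~qual~ quality +
β~wc~ (price + transport)/income,

with within-nest probabilities softmax(V/λ), the care nest entering the
upper level through its inclusive value λ·log Σ exp(V/λ), and λ = 0.7 by
default (λ = 1 recovers plain multinomial logit — a tested identity).
Quality is the cure probability of the agent's cancer at the
alternative's provider level.  The wealth–cost interaction makes a given
price weigh more on poorer agents, which is what generates the
distributional gradients in the outcome tables.  Published Ugandan
choice-model coefficients are not available in the source material; the
defaults (β~cost~ = −0.004, β~dist~ = −0.015, β~qual~ = 3, β~wc~ = −0.5,
ASC~no-care~ = 0) were chosen once as order-of-magnitude plausible — they
produce treatment probabilities of roughly 20–60% with a visible wealth
gradient — and are fully configurable.  Untreated agents re-evaluate
every 90 days.

## Disease and treatment

Onset is a per-cancer daily Bernoulli at rate/100,000/365 per eligible
agent, at most one active episode per agent.  Untreated survival is
exponential with hazard ln(2)/median (the functional form is the
package's choice; sources behind such models typically report medians
only).  Treatment resolves by sequential draws: perioperative death, then
cure versus residual disease — residual reverts to the untreated hazard —
plus an independent complication flag that adds 30% to the medical cost
of the case but no extra mortality.  Time since onset does not modify
cure probability in the base model.

## Money

Each treated case books a medical price (facility level price plus a
cancer-specific consumables cost, with the complication increment where
drawn) and a round-trip transport cost (2 × distance × $0.10/km).  The
financing levers only move these between payer columns: UPF shifts the
medical price to the program, vouchers shift transport, and NGO platforms
charge the patient nothing while the program bears a unit cost per case
constructed as reported NGO cost over reported case volume (2W $1,500,
MS $150 — an in-country, lean reference unit — CH $600).  The 12× MS
sensitivity multiplies that unit cost.  Societal cost is always patient +
program (a tested conservation law); the Ministry-of-Health perspective
keeps only the program column.

Financial flags are *incident*, once per person per episode, evaluated on
cumulative episode out-of-pocket spending against annual pre-illness
income: catastrophic iff spending strictly exceeds 10% of pre-illness
income; impoverishing iff it moves the agent from at-or-above to below
the poverty line.  A household head's cancer death counts every surviving
member as impoverished (base definition); the conservative variant counts
them only if the survivors' per-capita pooled income falls below the
line.  Background (non-cancer) deaths censor episodes and trigger no
impoverishment counting.

## Outcomes

Counts are normalized per 100,000 person-years within quintile; the
"overall" cell is always the equal-weight mean of the five quintile
values (quintiles are equal-sized by construction).  The equity index is
a concentration measure: the cumulative benefit-share curve over
quintiles ordered poorest → richest, index = 2 × (area under the curve −
0.5), so uniform benefit scores 0 and full concentration in the poorest
or richest quintile scores +0.8 or −0.8 (the quintile-granularity
bounds); the sign convention is *positive = pro-poor*.  Negative benefit
totals are scored on absolute shares with the sign flipped, so harm
concentrated on the poor is anti-poor — the index is antisymmetric under
reversing the quintile order.  Efficiency frontiers remove strictly
dominated options, then extended-dominated ones (non-increasing ICERs),
leaving strictly increasing ICERs; acceptability curves report, per
willingness-to-pay threshold, the fraction of parameter sets in which
each arm maximizes net monetary benefit.  Discounted aggregate reporting
(default 3%/year when enabled) is provided as an alternative to yearly
averages.

## Numerical and design choices

* **Randomness**: one root seed spawns named substreams (cohort,
  incidence, choice, outcome, progression, vitals) keyed by parameter-set
  index but not by scenario; a lever therefore perturbs only the draws it
  touches, and a do-nothing scenario reproduces the status-quo ledger bit
  for bit.  After arms diverge behaviorally the streams drift apart —
  that is inherent to state-dependent draws, and is why averted outcomes
  are computed per parameter set before averaging.
* **Geometry** is planar km on a synthetic rectangle; distance only
  enters utilities and transport costs, so geodesy would add nothing.
* **Headship** is the oldest member aged ≥ 18 (fallback: oldest);
  newborns join the mother's household with an equal share of pooled
  income and the head's quintile.
* **Softmax overflow** is guarded by max-subtraction at both nest levels.
* A year is 365 days; within-day event ordering is fixed as listed above.
* Tables are written as headered CSV with 17 significant digits, so every
  fixture and result round-trips losslessly; identical seeds give
  byte-identical files.

## What a green test establishes — and what it does not

The test suite verifies the machinery: calibration identities (the 19.5%
headcount), closed-form reductions (exponential survival, multinomial
logit at λ = 1), accounting conservation, dominance logic against a
brute-force oracle, published-table aggregation identities, and
bit-reproducibility.  Because the default parameter values are the
package's own plausible choices rather than a transcribed country
dataset, the *magnitudes* of scenario outcomes from the default fixture
(for example, which platform wins at which willingness-to-pay) are
demonstrations of the method, not policy estimates for Uganda.  Known
limitations mirror the method's scope: no queueing at capacity (the
"third delay"), no private sector, no adjuvant-therapy costs, no
persistence of impoverishment over time, and no NGO externalities.

## A worked smoke run

```{r, eval = FALSE}
library(surgecea)
cfg <- run_config(horizon_days = 1825L, base_seed = 1L,
                  population_spec = population_spec(n_agents = 1000L))
exp <- run_experiment(c("UPF", "MS"), n_parameter_sets = 2L, cfg)
ot <- outcome_table(exp)
ot[ot$quintile == "overall", ]
```

The same pipeline, with fixture generation and CSV/figure output, is
what `scripts/acceptance.R` and the `cli_*` functions drive.
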