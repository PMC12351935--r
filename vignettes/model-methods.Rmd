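---
title: "Methods: cost-utility modelling of SMA newborn screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-utility modelling of SMA newborn screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Spinal muscular atrophy (SMA) is an autosomal-recessive motor-neuron
disease caused by loss of *SMN1*; severity is modulated by *SMN2* copy
number.  Disease-modifying therapies (nusinersen, onasemnogene
abeparvovec "OA", risdiplam) are dramatically more effective when started
before symptom onset, which is the case for population newborn screening
(NBS) via dried blood spot with ddPCR confirmation.  `smanbs` implements
a full cost-utility comparison of *screening + early treatment* versus
*no screening + late treatment* for an annual birth cohort: a decision
tree allocates SMA cases to treatment pathways, and a six-state Markov
cohort model follows each pathway for 80 years (960 monthly cycles),
accumulating discounted costs and quality-adjusted life years (QALYs).

## Model structure

**Decision tree.**  Conditional on being an SMA case in the screening
arm, a case is detected by NBS with probability
`p_screened * (1 - p_false_negative)` (0.9556 × 0.95).  Detected cases
split by *SMN2* copies (48/35/17% for 2/3/4 copies, Dirichlet(18, 13, 6)
in sampling).  Two-copy newborns are symptomatic at screening with
probability 0.14; 99% of symptomatic newborns receive a single nusinersen
dose as a bridge before OA.  Presymptomatic 2- and 3-copy newborns
receive OA, 5% of them with a four-dose nusinersen bridge (preterm or
AAV9-antibody-positive).  Four-copy newborns are funded for treatment
only in Quebec (23% of the cohort), where 60% are treated (80% risdiplam,
20% nusinersen); the rest follow natural history.  Every treated branch
carries a 1% treatment-decline probability; decliners and untreated
4-copy patients follow natural-history hazards (the only internally
consistent reading of a "decline treatment" branch).  Unscreened cases
and false negatives present clinically and are routed through the same
structure as the no-screening arm: types 1/2/3 with probability
60/25/15%, type 1 treated with OA, type 2 with OA/nusinersen/risdiplam
(50/25/25%), type 3 with nusinersen/risdiplam (50/50%).

**Markov model.**  States are the WHO motor-milestone levels: A (broad
range of normal development, BRND), B (walking), C (sitting), D (not
sitting), E (permanent assisted ventilation, PAV), F (death).  Milestone
gains are single-step (D→C→B→A), PAV is reachable from D, death from
every living state, and treated patients never regress.  NBS cases enter
state D at age 1 month; clinical presenters enter D at 3.9 months
(type 1), C at 4.4 years (type 2), and B (76%) or C (24%) at 8.9 years
(type 3), with entry ages rounded to whole cycles for the Markov start
while pre-entry accrual (below) uses the exact durations.

The engine assembles an age-dependent generator `Q(t)` from fitted
hazard functions and converts it to one-month transition probabilities
by the matrix exponential, `P = exp(Q)`; occupancy advances as
`X(t+1) = X(t) P`.  Death rates come from a life table for states A and
B, and from natural-history survival fits for C (type 2/3 histories), D
(type 1 histories) and E (ventilated cohorts).  A milestone-window
override recognizes that a child in D at ≤ 9 months, or in C/B at ≤ 18
months, is still within the normal achievement window: such children
receive state A's death rate, costs, and utility.  The ≤ boundaries are
inclusive, in whole months.

### Numerical choices

* **Cycle rates.**  `Q` is held constant within each one-month cycle.
  Fitted hazards run on the *treatment clock* (time since model entry,
  matching the clinical-trial time axis) and are evaluated at the cycle
  midpoint `t + 0.5`: at the cycle start the clock reads 0, where
  decreasing-hazard families (Weibull or log-logistic with shape < 1)
  have an unbounded rate.  Life-table mortality uses the absolute age at
  cycle start.
* **Rate cap.**  Rates entering `Q` are capped at 100/month.  A capped
  rate empties a state within one cycle (staying probability `e^-100`),
  so the cap is behaviourally neutral; it protects the matrix
  exponential from overflow when, for example, a Gompertz fit is
  extrapolated decades beyond its data.
* **Matrix exponential.**  `Matrix::expm` computes `P`; the test suite
  checks it element-wise (1e-8) against an independent scaled
  truncated-Taylor oracle on random generators, and enforces row sums of
  1 within 1e-9 across all 960 cycles.
* **Background mortality** is *not* added to the C, D, E death hazards
  (the natural-history fits are treated as total mortality); a switch
  (`include_background`) is provided.
* **No half-cycle correction**: accumulation is plain per-cycle, with
  state occupancy at the cycle start accruing that month's cost and
  utility.

## Survival fitting

Milestone-achievement and mortality inputs are right-censored event-time
datasets.  Six families are fitted by censored maximum likelihood
(exponential, Weibull, Gompertz, log-logistic, log-normal, generalized
gamma in the (mu, sigma, Q) parameterization with its documented special
cases).  The log-likelihood is `sum(events) log h(t) + sum(all) log
S(t)`, maximized over log-transformed positive parameters with a 3-point
deterministic multi-start (for the generalized gamma the starts vary Q
across the Weibull-like, log-normal-like, and negative-Q branches);
convergence tolerance 1e-10 on the relative objective.  The covariance
is the inverse observed information at the optimum.  Model selection
uses the corrected AIC, `-2 loglik + 2k + 2k(k+1)/(n-k-1)`, appropriate
at trial-scale n per parameter; exact ties go to the smaller parameter
count, then to the fixed family order.  For long-term mortality inputs
an affine-invariant ensemble MCMC sampler (stretch move, a = 2) over the
censored Weibull likelihood is available, with flat priors on the
log-parameters and the first 25% of steps discarded as burn-in — the
paper-trail for priors and burn-in is thin everywhere this method is
used in practice, so these are package choices.

Parameter uncertainty propagates into the probabilistic analysis by
multivariate-normal draws around the estimates; draws violating the
family's parameter constraints are rejected and redrawn (falling back to
the point estimate after 100 rejections, which in practice never
happens at trial-scale information).

## Costs, utilities and discounting

Monthly health-state costs (CAD: E 15,508; D 7,758; C 6,906; B 3,723; A
16.67, i.e. two neurologist visits a year) and annual utilities (E 0.00;
D 0.32; C 0.46; B 0.65; A 0.92 under age 18, 0.864 from 18) follow the
configured base case; monthly utility is annual/12.  In sampling, each
cost is Gamma-distributed with mean matched to the base case, and each
utility is `1 - Gamma` on the monthly disutility so that draws can fall
below zero (states worse than death) — at the configured parameters this
effectively concerns E, D and C only.  Drug costs: OA 2,910,500 per
single dose; nusinersen 118,000 per dose with 4 loading doses in ~2
months then one dose every 4 months for life (3 doses/year at steady
state); risdiplam at the printed annual costs, 93,456 under age 2 and
354,000 after (the per-mg price of 193.97 is retained for custom
regimens).  Recurring doses are charged in proportion to the surviving
fraction; the single OA dose is charged unconditionally at its scheduled
cycle.  Screening costs are 10.76 per screened newborn (first tier) and
250 per ddPCR confirmation.

Costs and QALYs are discounted at 1.5%/year from birth,
`(1.015)^(-month/12)`.  Clinical presenters accrue pre-entry utilities
from birth to model entry (type 1: state A for 3.9 months; type 2: A for
18 months then C to entry; type 3: A for 18 months then the entry state
to entry), and — by a symmetry choice that can be toggled — the matching
state costs.  NBS cases accrue one month of state A before their
one-month entry, keeping QALY accounting from birth consistent across
arms.

Costs split into direct health-system, out-of-pocket, and indirect
components.  The societal perspective (the default) sums all three; the
public-payer perspective keeps health-system costs (including all drug
and screening costs) only.  The main configuration prints only total
monthly state costs, so the per-state component shares are package
defaults (state A all health-system; other states 55/15/30), stated here
as a modelling convention, configurable in the JSON, not a published
breakdown.  Newborns without SMA contribute screening costs only; their
health outcomes are identical in both arms and cancel from every
increment.

## Uncertainty analysis

The probabilistic sensitivity analysis draws every parameter with a
distribution (incidence Beta(6.57, 5.3e4); the *SMN2* Dirichlet; the
symptomatic fraction Beta(0.177, 1.09); the first-tier screening cost
Gamma(3.07, 3.50); the five state costs; the six utilities) plus one MVN
draw of every fitted hazard parameter, evaluates both arms, and stores
per-iteration incremental cost, incremental QALYs, and net monetary
benefit `NMB = lambda dE - dC` at willingness-to-pay 1,000 / 10,000 /
50,000 CAD per QALY.  Parameters without a listed distribution (e.g.
screening coverage and drug prices) are point masses.  Iteration `i` of
master seed `m` uses the documented substream seed
`(7919 m + 104729 i) mod (2^31 - 1)`, so any subset of iterations is
reproducible independently of the run length.  Failed iterations are
redrawn once, then skipped; more than 5% failures aborts the run.
Summaries report means with 2.5/97.5 percentile intervals, and the
cost-effectiveness acceptability curve reports the fraction of
iterations with positive NMB per threshold.

The deterministic analysis sweeps each distributional parameter
one-at-a-time across the 1st, 10th, ..., 90th, 99th percentiles of its
distribution (Dirichlet components via their marginal Beta with the
other components renormalized; utilities on the utility scale so
quantiles increase in the percentile), recording the incremental cost
and ranking parameters by output range for the tornado table.  Fitted
hazard parameters are included through their marginal normal quantiles
and flagged as such in the output, since published practice is ambiguous
about whether they belong in the sweep.

## Synthetic data: what it emulates and what it does not

The packaged `"paper_like"` trial suite stands in for digitized
milestone-achievement curves of early-treatment trials in presymptomatic
2/3-copy infants (OA) and 4-copy-like infants (nusinersen), late
treatment in symptomatic type 1 and type 2/3 cohorts, and
natural-history survival for the sitting, not-sitting, and ventilated
states.  Ground-truth parameters are documented package constants chosen
for direction and broad realism only: early treatment reaches each
milestone faster than late treatment (e.g. median time to sitting 5.0
vs 15.7 months), untreated not-sitting median survival is under 24
months as in severe infantile SMA, the ventilated state has a
months-scale median survival, and the sitting state a decades-scale one.
Dataset sizes (300–500 subjects) and censoring horizons (2–30 years)
give trial-scale information.  The life-table fixture uses a
Gompertz–Makeham monthly hazard `a + b exp(c * age_years)` with
a = 6e-5, b = 1e-6, c = 0.10, whose discrete life expectancy is ~82
years, in line with a contemporary Canadian period table; a real table
can be supplied as CSV.

Consequently, passing tests demonstrate that the machinery — tree
arithmetic, generator assembly, matrix exponentials, accrual,
selection, sampling — is correct and that the qualitative conclusion
(screening dominant when early treatment truly dominates) follows, but
they do not certify the published point estimates, which depend on
digitized per-patient trial data that is not publicly deposited.
Headline outputs computed here (e.g. incremental cost around -110
million CAD and a few hundred incremental QALYs at base case) therefore
sit in the published order of magnitude without matching it exactly.

## Problem sizes used in checks

The packaged verification runs use: the full 960-cycle horizon for every
trace; 100-iteration scaled PSA runs; 200 replicates at n = 500 for the
family-selection recovery rate; n = 2,000–5,000 for parameter-recovery
checks; 32 walkers × 800 steps for MCMC recovery.  These sizes were
chosen so the whole verification suite completes on a single CPU in
minutes while leaving Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* No microsimulation: cohort fractions only, no individual variability.
* No regression to lower-functioning states for treated patients; the
  durability of treatment effect is an assumption.
* The allowed-arrow set (PAV only from D; single-step milestone gains)
  is a declared default; the generator assembly accepts any configured
  sparsity pattern.
* No currency conversion, inflation adjustment, price-rebate scenarios,
  carer QALYs, or value-of-information analysis.
* Four-copy untreated patients share the natural-history hazard set,
  including PAV access; their true trajectory is milder and this choice
  is conservative against screening.

## Worked example

```{r, eval = FALSE}
library(smanbs)
params <- load_parameters()
suite <- generate_trial_suite("paper_like", seed = 1)
hazards <- fit_hazard_library(suite)
model <- build_model(params, hazards, generate_life_table())
run_base_case(model)
psa <- run_psa(model, n = 100, master_seed = 1)
psa
ceac(psa)
```
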