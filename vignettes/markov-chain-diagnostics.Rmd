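---
title: "Markov chain diagnostics for 5CSRTT trial sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov chain diagnostics for 5CSRTT trial sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markov5csrtt)
```

## The question the package answers

In the five-choice serial reaction time task (5CSRTT) every trial ends in
one of five states: correct rewarded (`R`), correct non-rewarded (`NR`,
possible under partial reinforcement where a correct response is rewarded
only with probability p(R)), `premature` (a nose-poke before the visual
cue — the operational measure of motor impulsivity), `incorrect`, or
`omission`. Session-level totals of these outcomes hide the trial-by-trial
structure: does the outcome of trial *t* depend on what happened at trial
*t−1*? In particular, is an animal more likely to respond prematurely after
an unrewarded correct trial — a frustrative non-reward effect — or after
another premature response?

The package treats the outcome sequence $X_1, X_2, \dots$ of a session as a
discrete-time chain over the $S = 5$ states and compares two nested models:

* a **first-order homogeneous Markov chain**, where
  $P(X_t \mid X_{t-1}, \dots, X_1) = P(X_t \mid X_{t-1})$, estimated by the
  row-normalised transition frequencies
  $\hat P_{ij} = O_{ij} / \sum_j O_{ij}$; and
* a **zeroth-order (independence) model**, where
  $P(X_t \mid \text{history}) = P(X_t)$, estimated from the per-state
  frequencies, with expected transition frequencies
  $E_{ij} = \hat p_j \cdot n_{i\cdot}$ — the familiar contingency-table
  product form.

## The diagnostics

**Full-table test.** The likelihood-ratio statistic
$W = 2 \sum_{ij} O_{ij}\,\ln(O_{ij}/E_{ij})$ (the G statistic; cells with
$O_{ij}=0$ contribute nothing) approximates Pearson's $\chi^2$ and is
referred to $\chi^2$ with $(S-1)^2 = 16$ degrees of freedom. At
$\alpha = 0.05$ the decision rule is the fixed critical value
`chi2_critical(0.05, 16)` = 26.30: independence is rejected when
$W > 26.30$. A p-value is reported alongside, but the `reject` flag follows
the critical-value rule.

**Restricted test.** To focus on transitions that *end* in a premature
response, $\chi^2 = \sum_i (O_{i\,\mathrm{prem}} -
E_{i\,\mathrm{prem}})^2 / E_{i\,\mathrm{prem}}$ over the five start states,
referred to $\chi^2$ with 5 degrees of freedom (critical value 11.07). Five
degrees of freedom — one per start state, without subtracting one for the
estimated column total — is the decision rule reproduced here; the `dof`
argument exposes the 4-dof variant for sensitivity analysis.

**Deviation profile.** The standardized residual
$Y_i = (O_{i\,\mathrm{prem}} - E_{i\,\mathrm{prem}}) /
\sqrt{E_{i\,\mathrm{prem}}}$ localises the deviation: $Y > 0$ means more
transitions into premature from start state $i$ than independence predicts.

**Split-half homogeneity.** Each session is split at $\lfloor n/2 \rfloor$
trials (by trial count, not elapsed time; no transition spans the split),
halves are pooled separately, and per-half transition matrices and W tests
are reported together with the maximum absolute difference between the two
halves' transition probabilities into the target state. No formal
equivalence criterion is imposed — the report is descriptive, which is all
a 100-trial half supports.

```{r worked}
seq12 <- c("NR", "premature", "premature", "R", "NR", "premature",
           "omission", "R", "R", "incorrect", "NR", "NR")
s <- csrtt_session(session_meta("r1", "demo", p_reward = 0.5), seq12)
cnt <- count_transitions(s)
fit <- estimate_zeroth_order(cnt)
w_statistic(cnt, fit)
y_deviation(cnt, fit)
```

## Estimation conventions

* **Canonical ordering.** All matrices are indexed `R, NR, premature,
  incorrect, omission` (start states as rows, end states as columns).
* **Margins.** Row totals count trials 1..n−1 (trials that have a
  successor), so row margins agree exactly with the transition table; the
  state probabilities of the independence model default to the end margin
  (trials 2..n), which makes $E_{ij}$ the exact product formula. Both
  choices differ from "all n trials" by at most one count per state at
  session scale; `estimate_zeroth_order(margin =)` exposes the
  alternatives so the conventions are never silently conflated.
* **Pooling.** Counts are summed across sessions and animals; transitions
  never bridge a session boundary. Pooling buys statistical robustness at
  a price made explicit below.
* **Degenerate cells.** Start states that never occur give undefined
  (flagged, not smoothed) transition rows and are skipped by the tests;
  a cell with $E = 0$ but $O > 0$ is an error, not a silent skip. Sessions
  shorter than 4 trials are excluded from split-half analysis with a
  warning.

## The synthetic task generator

No raw trial sequences are publicly deposited for this task, so the
package ships a generator that reproduces the *statistical structure* the
analysis assumes, and every empirical claim in the tests is made against
it.

A **behavioural policy** emits one of four actions per trial (`correct`,
`incorrect`, `omission`, `premature`); the **task layer** maps `correct`
through the reinforcement schedule to `R` or `NR`. Schedules are blockwise
pseudo-randomised: every 20-slot block contains exactly
`round(20 * p_reward)` rewarded slots in seeded-random order, and each
*correct action* consumes one slot. Consuming per correct action (rather
than per trial) guarantees the planned R:NR ratio among correct responses
— which is exactly the contingency the diagnostics condition on; the
alternative (per trial) would let the realised ratio drift with the error
rate.

Policies come in two kinds. An *independence* policy draws actions i.i.d.;
the default (`default_independence_policy()`: correct .55, incorrect .12,
omission .13, premature .20) represents a trained animal at stable
baseline — choice accuracy .55/.67 = 82 % (the training criterion is
> 80 %), omissions 13 % (< 20 %), premature responding at the level
challenge conditions provoke — while keeping the rarest outcomes frequent
enough (≥ 12 %) that expected transition counts at session scale stay in
the range where the $\chi^2$ reference is meaningful. A *first-order*
policy conditions the action distribution on the previous **outcome** (5
states, not 4 actions), so rewarded and non-rewarded correct trials can
shape behaviour differently — the mechanism needed to produce elevated
premature responding specifically after reward omission.

`frustration_policy()` builds the canonical alternative: premature-action
probability .10 after `R`, .30 after `NR`, .20 after errors, and after a
`premature` outcome a value solved numerically (via the stationary
distribution of the implied outcome chain) so that
$P(\mathrm{prem}\mid\mathrm{prem})$ exceeds the marginal premature
probability by exactly 0.25. Remaining row mass is split correct :
incorrect : omission = .75 : .125 : .125. The solved value is ≈ .565
against a stationary marginal of ≈ .315.

Between-subject heterogeneity perturbs log-probabilities with Gaussian
noise and renormalises, so perturbed policies are always valid; an
optional log-normal latency model (with a premature-propensity coupling)
exists purely so macro-level correlation plumbing can be exercised — it
makes no claim of behavioural realism.

**What the generator does not emulate:** within-session drift (fatigue,
satiation), time-outs as durations (ITI and TO are metadata only), session
time caps (trial caps only), perseverative responses, and any
reinforcement-learning structure. Passing tests therefore show the
estimators and tests behave correctly for sequences with first-order (or
no) dependence — not that real rats are first-order.

## Operating characteristics, sizes used, and an honest caveat

The test suite and `analysis/05_operating_characteristics.R` measure, at
fixed seeds:

* **Size:** 2000 single sessions of 200 trials from the default
  independence policy; the W test at $\alpha = .05$ rejects ~6.9 % of the
  time, against ~4.4 % for the Pearson form on the same tables.
* **Power:** 500 sessions of 200 trials from `frustration_policy()`; W
  rejects > 96 %, and the mean Y profile peaks, correctly, at
  premature→premature.
* **Recovery:** one 10,000-trial session; the maximum absolute error of
  $\hat P$ against the policy's implied transition matrix is < 0.05
  (observed ≈ 0.027).

Two caveats the numbers above surface deserve emphasis. First, the G form
of W is mildly anticonservative when rare-by-rare cells have expected
counts near 3, as they do for error→error transitions in a 200-trial
session; the Pearson comparison isolates this. Second, the blockwise-exact
schedule and pooling over heterogeneous subjects are both *real* (if weak)
departures from a single homogeneous zeroth-order chain — drawing rewards
without replacement within a block induces slight negative autocorrelation
in R/NR, and mixing subjects with different outcome rates induces apparent
history dependence. At pooled cohort scale (~2400 transitions) these are
detectable by Pearson and G alike. Rejections of independence on pooled
null-policy cohorts are therefore not necessarily test error; the
`analysis/03` driver prints this expectation next to its results.

## Other design choices

* Quartile screening (`classify_impulsivity()`) uses R's default
  linear-interpolation percentile convention (`quantile(type = 7)`);
  subjects strictly above the 75th percentile are HI, strictly below the
  25th LI, ties and the middle MID — HI/LI stay strict extremes, and a
  cohort of identical subjects is all MID. Which sessions count as
  screening sessions is the caller's choice; nothing is hard-coded.
* `p_reward = 1` sessions must contain no `NR`; the reader enforces this
  at ingestion, the generator by construction.
* Probability vectors must sum to 1 within 1e-12; defined transition rows
  sum to 1 within 1e-12; expected tables preserve start margins within
  1e-9.
* Reported `reject` flags always follow the fixed critical values (26.30,
  11.07), matching the decision rules of the analyses this package
  reproduces, even where a p-value would be more informative.

## Limitations

Tests are asymptotic; no exact or permutation variants are provided, and
no multiple-testing correction is applied across conditions. Only
first-order structure is modelled — a significant W says "not
zeroth-order", not "first-order is adequate" (the split-half report is the
only homogeneity check). Latencies never enter the Markov analysis.
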