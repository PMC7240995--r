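---
title: "Minimax, optimal and admissible two-stage phase II designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimax, optimal and admissible two-stage phase II designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ph2design)
```

## The model and its assumptions

A single-arm phase II trial observes a binary response in each patient
and tests H0: p ≤ p0 against H1: p > p0, with power evaluated at a
pre-specified alternative p1 > p0. The package assumes

* responses are independent Bernoulli(p) across patients (exact binomial
  arithmetic, no normal approximation, no continuity correction);
* the stage sizes n1 and n2 are met exactly (no accrual overrun or
  under-run, no attained-n deviations);
* the only interim look is at the end of stage 1.

Because the sample space is discrete, a design's *attained* type I
error and power are step functions of its integer thresholds; feasible
designs undershoot the nominal (α, 1 − β). Feasibility is always
decided on the unrounded attained values with inclusive comparisons
(α_T ≤ α, power ≥ 1 − β); three-decimal displays are formatting only.

## Stopping-rule conventions

Two families are implemented, with the threshold semantics used by
their published tabulations:

* **Simon** (`r1`, `r` are rejection points): stop at stage 1 iff
  x1 ≤ r1 (reject the treatment); at the end reject iff x1 + x2 ≤ r.
* **Fleming** (`a1` a rejection point, `r1`, `r` acceptance points):
  stop at stage 1 iff x1 ≤ a1 (reject) or x1 ≥ r1 (accept); the
  continuation region is a1 < x1 < r1, and the final analysis accepts
  iff x1 + x2 ≥ r.

The asymmetry — Simon's `r` is the largest count that still rejects,
Fleming's `r` the smallest that accepts — mirrors how each family's
designs are printed in the trial-design literature, so a design copied
from a published table can be typed in verbatim. We verified this
convention by reproducing the published operating characteristics of
both families' reference tables; the test suite pins it down.

With these conventions,

* PET1 = B(r1; n1, p0) (Simon) or
  B(a1; n1, p0) + 1 − B(r1 − 1; n1, p0) (Fleming),
* EN = n1 + (1 − PET1) n2,
* P(reject) = B(r1; n1, p) + Σ b(x; n1, p) B(r − x; n2, p) over the
  continuation region (Simon; Fleming analogously with the shifted
  acceptance threshold),

where out-of-range cumulative arguments use the 0/1 conventions of
`binom_cdf()`, so boundary cases need no special-casing. Every
rejection decision is binary: a trial either rejects or accepts the
treatment, and PET1 + continuation probability = 1 by construction.

Fleming designs whose continuation region is empty (a1 ≥ r1 − 1) are
rejected as invalid rather than silently treated as single-stage tests:
a user asking for a two-stage rule almost certainly mistyped a
threshold.

Both EN and PET1 are evaluated under p0 whenever designs are ranked;
`expected_n()` and `pet1()` accept arbitrary p for simulation and
diagnostic use, but ranking never uses them. Optimising EN under the
null reflects the ethical goal of these trials — stop early when the
drug is inactive; optimality under the alternative (and mixed
weightings of the two) is a documented non-goal.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `p0`, `p1` | null / alternative response rates | — | clinical inputs |
| `alpha`, `beta` | error bounds | — | clinical inputs |
| `n_min` | smallest total n scanned | 1 | no reason to exclude |
| `n_max` | largest total n scanned | `max(100, 2 × single_stage_n)` | see below |

The search cap must contain the optimal design without making the scan
unbounded. The single-stage sample size for the same (p0, p1, α, β) is
the natural yardstick: a two-stage design that needs more than twice it
would never be used in practice, and 100 comfortably exceeds every
total sample size in the conventional phase II range (the largest
tabulated reference design totals 63). If the global EN minimum
nevertheless lands exactly on `n_max`, `candidate_set()` warns that the
cap may be truncating the search; if no feasible design exists at all
below the cap, it fails with an explicit search-cap-exhaustion error
rather than returning an empty set.

## The search

For every total n, `candidate_set()` finds the feasible rule minimising
EN under p0 (the *candidate design* at n). The enumeration is exact:
for each (n1, stage-1 rule) the rejection probabilities for *all* final
thresholds r at once come from cumulative-sum tables of
b(x; n1, p)·B(·; n2, p), and the only eliminations are

* necessary conditions: a rule whose stage-1 futility stop alone
  already costs more than β in power, or whose stage-1 efficacy stop
  alone already spends more than α, has no feasible r (monotonicity of
  the rejection probability in r makes these exact);
* dominance: a stage-1 rule whose EN is not below the best EN found so
  far at this n cannot become the candidate (EN does not depend on r).

Neither cut can drop a feasible EN-minimising rule, and the test suite
checks the kernels against a literal, unpruned re-enumeration.

Ties in EN (compared within 1e-12) are broken deterministically:
smallest n1, then smallest r1, then (Fleming) largest a1, then smallest
r. Earliest-look (small n1) rules are preferred because early
termination is the point of these designs; since EN is independent of
r, the smallest feasible final threshold is reported, which is also the
choice that maximises attained power at that stage-1 rule. The optimal
design breaks EN ties across n towards the smallest n, which dominates
on both loss components.

## Admissibility

Over the candidate set R, the loss ρ(q, d) = q·n(d) + (1 − q)·EN(d)
defines for each weight q ∈ [0, 1] a Bayes design attaining
inf ρ(q, d). Candidates attaining the Bayes risk for some q are
admissible; they are exactly the vertices of the lower convex hull of
the (n, EN) points, with minimax (q = 1) and optimal (q = 0) as the
extreme hull points. `classify_designs()` labels each candidate and
reports the q-interval on which it is the Bayes design; intervals are
closed, adjacent designs sharing the breakpoint
q = ΔEN / (ΔEN + Δn) of the hull edge between them.

Two numerical-precision choices deserve explanation:

* **Hull membership uses unrounded EN** (with a 1e-9 relative
  collinearity tolerance; exactly collinear candidates are all retained
  as admissible, the middle one with a degenerate interval, since all
  attain the Bayes risk). Deciding admissibility on rounded values
  could promote a candidate that is strictly above the hull by less
  than the display precision.
* **Interval endpoints are computed from EN at the 0.1-patient display
  precision of the output table** (then rounded half-up to three
  decimals). This makes the printed table self-consistent: a reader
  recomputing ΔEN/(ΔEN + Δn) from the printed EN column recovers
  exactly the printed interval, which is also how the reference tables
  in the literature were evidently produced. The two precisions can
  shift a breakpoint by a few thousandths; the hull itself is never
  affected.

Rounding for display is half-up (23.45 → 23.5), not R's round-half-even,
again matching table conventions.

## The simulator

`simulate_trial()` / `estimate_oc()` draw x1 and x2 from the binomial
model and walk the decision tree directly, independently of the
closed-form machinery; a single root seed makes the replicate stream
reproducible. The simulator emulates exactly what the analytic model
assumes — ideal accrual, i.i.d. responses, thresholds applied at the
planned looks. It deliberately does *not* emulate features of real
trials (staggered accrual and overrun while stage-1 responses mature,
response misclassification, non-constant p across accrual periods), so
agreement between simulation and the exact values validates the
arithmetic, not the realism of the binomial model for any particular
trial. In the test suite the simulator must agree with the exact
operating characteristics within three standard errors at 200,000
replicates; it is never used to rank designs.

## Problem sizes used by the tests

The suite reruns the full search (cap 100) for both families on the
nine conventional parameter settings (p1 − p0 = 0.2 at p0 = 0.05, 0.10,
0.30 crossed with (α, β) = (0.05, 0.20), (0.10, 0.10), (0.05, 0.10))
and on the practical-example setting (0.05, 0.2, 0.1, 0.1), checking
the published optimal/minimax rows, hulls and q-intervals. Exhaustive
outcome-path enumeration verifies the rejection/termination formulas
for *every* valid rule with n ≤ 12, and a 1001-point q-grid brute-force
argmin verifies every hull. These sizes were chosen so the whole suite
re-derives the package's claims from first principles in about a
minute.

## Known limitations

* Designs with three or more stages, adaptive second-stage sizes,
  curtailment, and randomized two-arm phase II comparisons are out of
  scope.
* Loss functions weighting EN under the alternative hypothesis are not
  implemented; admissibility here is always with respect to
  (n, EN under p0).
* No inference after the trial (point estimates or confidence intervals
  following a two-stage design) is provided.
* The search cap default is a package decision; published tables
  produced with a smaller (often unstated) cap can label as "optimal" a
  design that a deeper scan strictly improves. The candidate set makes
  this visible: rerun with an explicit `n_max` to match any external
  table's search range.
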