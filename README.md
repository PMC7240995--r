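# ph2design

Exact design of single-arm two-stage phase II trials with a binary
(tumour response) endpoint, for trial statisticians choosing between
**minimax**, **optimal** and **admissible** designs under Simon's
(futility-only) or Fleming's (futility + efficacy) stopping rules.

## The problem

A single-arm phase II trial tests

> H0: p ≤ p0  vs.  H1: p > p0

where `p` is the true response rate, `p0` the highest rate consistent
with an uninteresting treatment and `p1 > p0` the smallest rate that
would warrant further development. A two-stage design enrols `n1`
patients, may stop at stage 1, and otherwise enrols `n2` more
(`n = n1 + n2`):

* **Simon's rule** — stop for futility at stage 1 if `x1 ≤ r1`; at the
  end, reject the treatment (conclude "not promising") iff the total
  number of responses is ≤ `r`.
* **Fleming's rule** — stop for futility if `x1 ≤ a1`, stop *and accept*
  for efficacy if `x1 ≥ r1`; at the end, accept iff the total is ≥ `r`.

Every operating characteristic is exact binomial arithmetic:
`PET1 = B(r1; n1, p0)` (Simon) or `B(a1; n1, p0) + 1 − B(r1−1; n1, p0)`
(Fleming), `EN = n1 + (1 − PET1)·n2`, and the rejection probability is a
sum of `b(x1; n1, p) · B(·; n2, p)` terms over the continuation region.
A design is *feasible* when its attained type I error `α_T` is ≤ α and
its attained power is ≥ 1 − β.

For each total `n`, the feasible design minimising EN under `p0` is the
*candidate design*. The candidate with the smallest `n` is the
**minimax** design; the candidate with the globally smallest EN is the
**optimal** design. With the loss `ρ(q, d) = q·n(d) + (1 − q)·EN(d)`,
a candidate is **admissible** when it attains the Bayes risk
`inf_d ρ(q, d)` for some weight `q ∈ [0, 1]` — geometrically, when it is
a vertex of the lower convex hull of the `(n, EN)` points; minimax and
optimal are the `q = 1` and `q = 0` endpoints. The package reports, for
every admissible design, the `q` interval on which it is the Bayes
design, and labels the remaining candidates inadmissible.

## Worked example

The classical setting `(p0, p1, α, β) = (0.05, 0.25, 0.05, 0.10)`:

```r
library(ph2design)
res <- run_search(0.05, 0.25, 0.05, 0.10, family = "simon")
res$table
#  alpha_T power n1 r1  pet1  n r   en        label  q_lo  q_hi
#    0.049 0.902  9  0 0.630 30 3 16.8      Optimal 0.000 0.167
#    0.042 0.900 15  1 0.829 29 3 17.4 Inadmissible    NA    NA
#    0.043 0.906 10  0 0.599 28 3 17.2   Admissible 0.167 0.375
#    0.040 0.908 11  0 0.569 27 3 17.9 Inadmissible    NA    NA
#    0.036 0.905 12  0 0.540 26 3 18.4   Admissible 0.375 0.667
#    0.034 0.901 15  0 0.463 25 3 20.4      Minimax 0.667 1.000
```

Reading the table: the optimal design enrols 9 patients, stops (and
gives up on the drug) if none responds — which happens 63% of the time
when the drug is inactive — and otherwise continues to 30 patients,
rejecting the drug unless more than 3 respond in total. It costs 16.8
patients on average under H0 but up to 30 in the worst case. The
minimax design caps enrolment at 25 at the price of a 20.4-patient
average. If the worst case matters with weight `q` between 0.167 and
0.375, the `n = 28` compromise is the rational (Bayes) choice; the
`n = 27` and `n = 29` candidates are never rational for any weight.

Evaluating and stress-testing one design by hand:

```r
d <- two_stage_design("fleming", n1 = 9, n2 = 21, a1 = 0, r1 = 4, r = 4)
operating_chars(d, design_params(0.05, 0.25, 0.05, 0.10))
# alpha_T = 0.0489, power = 0.9019, PET1 = 0.6309, EN = 16.75
estimate_oc(d, p = 0.05, reps = 200000, seed = 1)
# Monte Carlo (200000 trials):
#   P(reject treatment) = 0.9512 (SE 0.0005)
#   PET1                = 0.6307 (SE 0.0011)
#   mean sample size    = 16.755 (SE 0.023)
```

## Command line

The same searches run from a shell via the installed script:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ph2design", package = "ph2design"))')
Rscript "$CLI" search --family simon --p0 0.05 --p1 0.2 \
  --alpha 0.1 --beta 0.1 --out table.csv --curve curve.csv
Rscript "$CLI" evaluate --family fleming --n1 9 --n2 21 --a1 0 --r1 4 --r 4 \
  --p0 0.05 --p1 0.25
Rscript "$CLI" simulate --family simon --n1 9 --n2 8 --r1 0 --r 2 \
  --p 0.05 --reps 200000 --seed 1
```

`search` writes the result table (CSV or `--format json`) and, with
`--curve`, the EN-versus-n scatter data (one `(n, en, label)` record per
candidate) from which the usual design plots are drawn. Options can
also come from a flat `key = value` file via `--config`; explicit flags
win.

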