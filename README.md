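# ahparas

Hybrid AHP–ARAS multi-criteria decision analysis in R: derive criterion
weights from expert pairwise comparisons, check how self-consistent those
judgments are, and rank alternatives by additive-ratio utility degrees
against the weights.

The package is aimed at analysts running structured evaluations — here,
the worked example is a health-technology assessment in which a panel of
clinicians and computer scientists ranks eight computer-based
health-monitoring applications (Ap1..Ap8) on eight criteria: real-time
ability (C1), dynamic nature (C2), surgical services (C3), data security
(C4), telecommunication (C5), disease monitoring (C6), usability (C7) and
convenience (C8).

## The method

**Stage 1 — AHP (Analytic Hierarchy Process).** Experts fill an n × n
reciprocal matrix *A* of pairwise judgments on the Saaty 1–9 scale
(*a<sub>ij</sub>* = how strongly criterion *i* beats criterion *j*;
*a<sub>ji</sub>* = 1/*a<sub>ij</sub>*). Each column is normalized to unit
sum and each row averaged, giving weights

&nbsp;&nbsp;*w<sub>i</sub>* = (1/n) Σ<sub>j</sub> *a<sub>ij</sub>* / Σ<sub>k</sub> *a<sub>kj</sub>*.

Judgment coherence is quantified by λ<sub>max</sub> = mean<sub>i</sub>[(A w)<sub>i</sub> / w<sub>i</sub>],
the consistency index CI = (λ<sub>max</sub> − n)/(n − 1), and the
consistency ratio CR = CI/RI(n) against Saaty's random-index table
(RI(8) = 1.41). CR ≤ 0.10 is the conventional acceptance bound; above it
the fit carries a warning status but still returns weights. The principal
eigenvector (Saaty's original estimator) is computed alongside as a
cross-check.

**Stage 2 — ARAS (Additive Ratio Assessment).** The m × n decision matrix
of raw scores is extended with an optimal-value row *x<sub>0j</sub>*
(column maximum for benefit criteria, minimum for cost criteria). Each
column is share-normalized over all m + 1 rows (cost criteria via
reciprocals first), weighted by *w<sub>j</sub>*, and summed per row into
optimality values *S<sub>i</sub>* = Σ<sub>j</sub> *w<sub>j</sub> x̄<sub>ij</sub>*.
The utility degree *K<sub>i</sub>* = *S<sub>i</sub>* / *S<sub>0</sub>*
measures each alternative against the ideal; rank 1 goes to the largest
*K*.

## Worked example

```r
library(ahparas)
fit <- hybrid_mcda(health_pairwise(), health_decision())
fit
```

```
Hybrid AHP-ARAS evaluation
==========================

AHP weighting (8 criteria, column-mean method)

  C1   C2   C3   C4   C5   C6   C7   C8
0.12 0.03 0.08 0.14 0.10 0.17 0.35 0.02

lambda_max = 9.41, CI = 0.2, RI = 1.41, CR = 0.143
Judgments exceed the CR threshold of 0.1 -- interpret the weights with caution.

ARAS ranking (8 alternatives, 8 criteria)

        S     K rank
Ap2 0.130 0.769    1
Ap3 0.117 0.691    2
Ap8 0.108 0.637    3
Ap5 0.104 0.618    4
Ap4 0.098 0.581    5
Ap6 0.096 0.568    6
Ap1 0.092 0.545    7
Ap7 0.086 0.509    8

S0 (optimal row) = 0.169
```

Usability (C7, weight 0.35) dominates the evaluation and convenience
(C8, 0.02) barely matters; application Ap2 comes closest to the ideal
alternative, attaining 76.9% of the optimal row's score, while Ap7 trails
at 50.9%. The CR of 0.143 exceeds the 0.10 convention, so the panel's
judgments are mildly contradictory — the fit says so rather than
aborting.

Beyond the core pipeline:

```r
rank_stability(fit, epsilon = 0.05, samples = 1000, seed = 1) # weight jitter
criterion_knockout(fit)                                       # drop-one-criterion rankings
write_report(fit, "report.json", markdown = "report.md")      # auditable report
simulate_pairwise(c(0.5, 0.3, 0.2), seed = 1, inconsistency = 0.2) # synthetic panels
```

A command-line front end with `ahp`, `aras`, `run`, `simulate` and
`sensitivity` subcommands is installed at
`system.file("cli", "mcda.R", package = "ahparas")`.

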