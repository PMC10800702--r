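---
title: "Weighting and ranking with the hybrid AHP-ARAS pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighting and ranking with the hybrid AHP-ARAS pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahparas)
```

## The decision problem

Structured evaluations — which health-monitoring application should a
clinic adopt, which vendor should a program fund — involve several
criteria of very unequal importance, scored by a panel of experts. The
hybrid pipeline in this package separates the two judgments involved:
how much each criterion *matters* (stage 1, AHP) and how well each
alternative *performs* (stage 2, ARAS). The packaged worked example
evaluates eight computer-based health-monitoring applications on eight
benefit criteria.

```{r}
fit <- hybrid_mcda(health_pairwise(), health_decision())
fit
```

## Stage 1: criterion weights from pairwise comparisons

The panel expresses importance as an $n \times n$ reciprocal matrix $A$
on the Saaty scale: $a_{ij} \in \{1, \dots, 9\}$ when criterion $i$
dominates $j$ (1 = equal, 9 = extreme dominance), $a_{ji} = 1/a_{ij}$,
$a_{ii} = 1$. `pairwise_matrix()` enforces that contract. Its default
reciprocity tolerance is a *relative* 0.05 on $a_{ij} a_{ji}$, chosen so
that matrices transcribed with two-decimal roundings of reciprocals
(0.33 for 1/3, 0.13 for 1/8) validate; at 0.01 the packaged matrix would
be rejected for a transcription artifact rather than a substantive flaw.
Zero or negative judgments are always hard errors — they have no meaning
on a ratio scale and are never clamped.

Weights use the column-mean estimator:
$$w_i = \frac{1}{n}\sum_j \frac{a_{ij}}{\sum_k a_{kj}},$$
i.e. normalize each column to unit sum, then average rows. Saaty's
principal-eigenvector estimator is available via
`ahp(x, method = "eigenvector")` and is always computed as a cross-check
(`fit$ahp$eigen_diff`); the two coincide exactly on consistent matrices
and to about $10^{-2}$ on mildly inconsistent ones. The column-mean
method is the default because it is the estimator whose intermediate
tables (normalized matrix, weighted sum values) practitioners publish
and audit line by line.

### Consistency diagnostics

With $\mathrm{WSV} = A w$, the chain is
$$\lambda_{\max} = \frac{1}{n}\sum_i \frac{\mathrm{WSV}_i}{w_i}, \qquad
  \mathrm{CI} = \frac{\lambda_{\max} - n}{n - 1}, \qquad
  \mathrm{CR} = \frac{\mathrm{CI}}{\mathrm{RI}(n)},$$
with $\mathrm{RI}$ Saaty's random index ($\mathrm{RI}(8) = 1.41$;
overridable table, orders 1–15). $\lambda_{\max} \ge n$ always, with
equality iff $A$ is consistent ($a_{ij} = w_i / w_j$). A CR above the
threshold (default 0.10) sets a `"warning"` status instead of aborting:
real panels are routinely somewhat inconsistent and the analyst, not the
software, should decide whether to re-elicit. The worked example's CR is
0.143 — above the convention, and reported as such at full precision.

Every chained quantity is computed at full precision; rounding happens
only in `print()`/`summary()`. This matters: recomputing the published
intermediate tables of the worked example from two-decimal weights would
drift in the second decimal, while the full-precision chain reproduces
them within the printed resolution (the test suite checks every cell).
One consequence worth knowing: summary tables of this kind are sometimes
themselves produced from rounded intermediates, so the package's
full-precision $\lambda_{\max}$ of 9.41 for the example sits 0.02 below
the value obtained by averaging the two-decimal ratio column (9.43).

## Stage 2: additive ratio assessment

The $m \times n$ score matrix gains an optimal-value row
$x_{0j}$ — column maximum for benefit criteria, minimum for cost
criteria — playing the role of an ideal alternative. Each column,
*including the optimal row*, is share-normalized
$$\bar{x}_{ij} = \frac{x_{ij}}{\sum_{i=0}^{m} x_{ij}}$$
(cost criteria are first replaced by reciprocals $1/x_{ij}$, again
including the optimal row). The optimal row's membership in the
denominator is stated explicitly because ARAS write-ups are often
ambiguous here; it is what makes each column of the normalized matrix a
probability vector over $m+1$ rows. Then
$$\hat{x}_{ij} = w_j \bar{x}_{ij}, \qquad
  S_i = \sum_j \hat{x}_{ij}, \qquad
  K_i = \frac{S_i}{S_0}.$$
Useful invariants follow directly and are enforced by the tests: columns
of $\hat{X}$ sum to $w_j$, all $S_i$ sum to 1, $K_i \in (0, 1]$ whenever
the optimal row is derived, and $K$ is invariant to rescaling any raw
column (so criteria need not share units). Rank 1 goes to the largest
$K_i$; ties take the minimum (competition) rank in input order — the
worked example has none, but a deterministic convention must exist.

A user-supplied optimal row is accepted (`decision_matrix(optimal = )`
or an `OV` row in the CSV); if an actual alternative beats it, a warning
is attached since utility degrees may then exceed 1.

The two stages are joined by criterion *id*, never by column position:
`hybrid_mcda()` refuses matrices whose criterion sets differ, listing
the unmatched ids, because two separately authored CSV files silently
misaligning is the most dangerous failure mode this tool has.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `reciprocity_tol` | 0.05 | relative slack on $a_{ij} a_{ji} = 1$ and the unit diagonal |
| `cr_threshold` | 0.10 | CR above which the fit is flagged `"warning"` |
| `method` | `"colmean"` | weight estimator; `"eigenvector"` as alternative |
| `ri_table` | Saaty's | random-index table, orders 1–15, overridable |
| `epsilon` (sensitivity) | — | *relative* weight perturbation half-width |

Sensitivity perturbation is relative (each weight scaled by an
independent factor in $[1-\epsilon, 1+\epsilon]$, then renormalized)
because MCDA weights commonly span an order of magnitude — the worked
example runs 0.02 to 0.35 — and an absolute jitter would obliterate the
small weights while barely touching the large ones.

## The scenario generator

`simulate_pairwise(weights, seed, inconsistency, snap)` builds judgment
matrices around a known ground truth: $a_{ij} = (w_i/w_j)\,
\varepsilon_{ij}$ with log-normal jitter of scale `inconsistency` on the
upper triangle, mirrored as exact reciprocals (so reciprocity survives
any perturbation, which is why jitter is applied to the upper triangle
only). With `snap = TRUE` each judgment moves to the nearest Saaty value
— nearest in log space, so a ratio and its reciprocal snap mutually
consistently — and ratios beyond 9 are clamped with a warning.
`simulate_decision()` draws uniform integer scores on 1–9, matching the
observed range of expert ratings in the worked example;
`perturb_decision()` adds truncated score noise (re-rounded to integers
when the input is integer) for rank-stability studies. Every stochastic
function takes an explicit `seed` and restores the global RNG state.

What the generator emulates: a single aggregated panel matrix with
controllable inconsistency, and independent uniform scores. What it does
not: correlation between criteria scores, systematic expert bias, or the
aggregation of multiple experts into one matrix. Passing recovery tests
therefore demonstrates the estimator chain is correct, not that any
particular real panel is well modelled.

Parameter-recovery behaviour, as measured by the test suite: at zero
jitter without snapping the matrix is exactly consistent and weights are
recovered to $10^{-10}$; with Saaty snapping, recovery error stays below
0.06 per weight for $n \le 8$ when all weight ratios are representable
(uniform-simplex weights; the bound is empirical and sits near its edge
for weight ratios close to 9). Mean CR rises monotonically with the
jitter scale, which the tests use to verify the inconsistency dial
actually turns.

## Numerical choices and degenerate inputs

- Weight recovery, conservation and oracle-equivalence tests run at
  tolerances $10^{-10}$–$10^{-12}$; validation tolerances (reciprocity,
  diagonal) are the loose 0.05 discussed above. The two families serve
  different purposes and are deliberately far apart.
- $\mathrm{CR}$ at $n \le 2$ is defined as 0 ($\mathrm{RI} = 0$ and a
  $2 \times 2$ reciprocal matrix is always consistent).
- A zero weight in the $\lambda_{\max}$ ratio is a named error, not a
  NaN; an all-equal utility vector ranks everyone 1.
- Knocking out a criterion renormalizes the remaining weights to the
  simplex; knocking out a zero-weight criterion provably leaves the
  ranking unchanged (and the tests check it).
- Problem sizes in the property suite — 200 recovery scenarios at
  $n \in \{3..8\}$, 1000 random ARAS instances, 300-replicate
  sensitivity runs — keep the whole suite under half a minute while
  exercising every branch; they are comfortably beyond the sizes at
  which the estimators stabilize.

## Known limitations

- Single-level criteria hierarchy only; no sub-criteria trees.
- No aggregation of multiple experts' matrices (geometric-mean or
  otherwise) — the tool ingests one finished judgment matrix.
- No fuzzy/interval extensions of either stage, and no alternative
  MCDM rankers (TOPSIS, VIKOR, COPRAS); the sensitivity suite is the
  intended robustness check.
- The column-mean and eigenvector estimators can diverge materially for
  severely inconsistent matrices (CR well above 0.2); the cross-check
  difference is reported so such cases are visible.
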