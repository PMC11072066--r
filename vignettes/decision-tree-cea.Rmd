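---
title: "Decision-tree cost-effectiveness modelling of vaso-occlusive crisis prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree cost-effectiveness modelling of vaso-occlusive crisis prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voctree)
```

## The model

`voctree` evaluates treatments that prevent the first sickle-cell-disease
vaso-occlusive pain crisis (VOC) with a one-year decision tree. Each
treatment arm is a tree rooted in a success/failure chance node:

* **Success** — the patient finishes the year without a first pain crisis —
  splits into pathways with and without adverse events (AEs). Both carry
  effectiveness 1; the effectiveness endpoint is the probability of avoiding
  a first crisis, so an AE under success does not negate success.
* **Failure** splits into a first pain crisis (possibly followed by a second
  and then an additional crisis), acute chest syndrome (ACS), death, and an
  explicit *residual* branch. All failure terminals carry effectiveness 0.

Every terminal carries a total annual cost (QAR per patient). For a
validated tree the expected cost and effectiveness of an arm are

$$E[X] = \sum_{\text{pathways } i} \Big(\prod_{b \in i} p_b\Big) \, x_i ,$$

computed by leaf-to-root rollback; `enumerate_pathways()` exposes the joint
probabilities themselves, which is how the per-pathway tables of published
models arise. Comparisons between arms use the incremental
cost-effectiveness ratio $\mathrm{ICER} = \Delta C / \Delta E$ (QAR per pain
crisis averted), dominance classification when the differences disagree in
sign, and net monetary benefit $\mathrm{NMB}(\lambda) = \lambda E - C$ at a
willingness-to-pay threshold $\lambda$ (default 547,500 QAR ≈ 150,000 USD
per crisis averted). No discounting is applied anywhere: the horizon is a
single year.

### The residual failure branch

The packaged parameterization's published failure sub-events do not complete
a probability space (for crizanlizumab 5 mg/kg they sum to
$0.92 + 0 + 0.016 = 0.936$). Rather than silently rescaling the published
conditionals, the tree carries an explicit `other_failure` branch with the
complementary mass. Its terminal cost is set to the arm's crisis-free
no-AE cost — the least-assumption choice: a patient who fails for an
unrecorded reason still accrues the year of treatment, but no crisis
management. This branch is a modelling choice of this package, not a claim
of the source tables; sensitivity of results to its cost is bounded by the
branch's small probability (0.02–0.064 across arms).

### What reproduces and what does not

`reproduce_base_case()` recomputes every joint pathway probability from the
conditional inputs and compares it, at the published 4-decimal display
precision, with the printed joint values. Seven cells reproduce exactly
(five crizanlizumab 5 mg/kg pathways and both 2.5 mg/kg success pathways);
the remainder — including all printed death joints and the published
headline ICERs — are *not* derivable from any product of the printed
conditionals. The report therefore carries per-cell agreement flags and a
`headline_check` table instead of reconciling the numbers: the engine's
arithmetic is the authority on what the inputs imply, and the discrepancies
are surfaced, not tuned away. The recomputed incremental results
(ICER ≈ 4.67M QAR for 5 mg/kg vs l-glutamine, ≈ 0.60M QAR for 2.5 mg/kg vs
l-glutamine, and a ≈ 236k QAR saving for 2.5 over 5 mg/kg) follow from the
printed pathway costs and recomputed probabilities; the qualitative
conclusions — the effectiveness ordering
$0.4503 < 0.5152 < 0.5625$ and the dominance of the 2.5 mg/kg dose over
5 mg/kg — do reproduce and are asserted in the test suite.

## Uncertainty machinery

### Triangular and Trigen distributions

One-way ranges are symmetric triangulars: $\pm f$ around the point estimate
(default $f = 0.15$ as applied to medication unit costs, e.g.
$6678 \to (5676.3,\, 6678,\, 7679.7)$, reported to the nearest riyal).
Clinical-event uncertainty uses the *Trigen* convention of risk-analysis
spreadsheet tools: a triangular described by its most-likely value and two
values anchored at the 5th and 95th percentiles rather than by its support.
`trigen_to_triangular()` recovers the support by nested bisection on the
triangular CDF (outer root in the lower endpoint, inner root in the upper
endpoint, `uniroot` tolerance $10^{-10}$), and refuses fits that do not
reproduce the anchor percentiles to $10^{-9}$. Anchors at a natural
boundary — a probability with 5% of mass below 0, as in the ACS range
$(0, 0, 0.05)$ — necessarily yield supports spilling past the boundary;
this is a property of the convention, and the sampler deals with it (below).

Sampling is inverse-CDF on seeded uniforms (`qtri(runif(n))`), so every
analysis is bit-reproducible from its seed. Degenerate specs
(`min == mode == max`) are point masses, which is how a probabilistic run is
collapsed onto the base case for verification.

### Probabilistic sensitivity analysis

`run_psa()` draws all parameters independently each iteration (the source
tables state no correlation structure), re-evaluates every arm through the
tree engine, and records $(\Delta C, \Delta E, \mathrm{NMB})$ per
comparison. The packaged model samples the seven conditional clinical
events per arm (21 parameters); complementary sibling branches are never
sampled separately — they are renormalized as complements so each chance
node remains a probability space. Two boundary situations arise from the
published ranges themselves:

* an individual draw outside $[0, 1]$ (boundary-anchored Trigen supports):
  the iteration is rejected and redrawn, with the count reported. The abort
  cap is configurable (`max_reject_frac`, default 0.5); with the packaged
  ranges roughly 10–15% of iterations redraw, so a materially smaller cap
  would abort on the model's own inputs.
* failure sub-events jointly exceeding probability 1 (their published modes
  already sum to ≈0.99 for the 2.5 mg/kg arm): the three sampled siblings
  are rescaled to sum to one and the residual branch carries no mass —
  the same renormalization rule applied to the full sibling set.

The acceptability curve reports, per threshold $\lambda$, the fraction of
iterations with $\lambda \Delta E - \Delta C > 0$ and the fraction with
strict dominance ($\Delta E > 0$, $\Delta C < 0$); the default grid spans
0–1,000,000 QAR in 10,000-QAR steps and always contains the 547,500 QAR
threshold. Tornado analysis regresses the standardized output on all
standardized inputs by ordinary least squares (`stats::lm`) and ranks
parameters by coefficient magnitude, ties broken alphabetically; constant
or collinear columns are dropped with a warning. Published acceptability
fractions for this model (around 80–90% at the threshold) inherit the
irreproducible headline ICER scale and are treated as qualitative.

### One-way sensitivity analysis

`run_owsa()` varies the two medication unit costs over their triangular
ranges while holding clinical inputs fixed, and summarizes each comparison
as a mean with a 2.5/97.5 percentile interval over Monte Carlo draws. A
unit-cost multiplier $m$ rescales the arm's annual medication cost, which
enters every pathway of the arm equally, so by linearity the arm's expected
cost shifts by exactly $\text{(annual medication cost)} \times (m - 1)$;
the identity is verified against full tree re-evaluation in the tests. The
reported quantity is whatever the engine's arithmetic produces from the
inputs — an ICER where the comparison admits one, the cost saving where the
base case is a dominance.

## Synthetic models and what the tests show

`generate_synthetic_params()` and `random_tree()` generate random valid
model instances: branch probabilities drawn uniformly and normalized per
node (so trees validate at $10^{-9}$ by construction), terminal costs
log-uniform on $[0.1, 10] \times 10^5$ QAR — the order of magnitude of the
packaged model's annual costs — and seeded determinism throughout. They
emulate the *structure* of the study inputs (complete probability spaces,
positive costs, a binary effectiveness endpoint), not clinical reality: no
correlation between probabilities and costs, no skewed cost tails, no
parameter uncertainty. Green property tests on synthetic models therefore
certify the engine's arithmetic (rollback = enumeration to $10^{-9}$ on
1000 random trees; NMB maximization = frontier walking on 500 random arm
sets; Trigen fits round-trip their anchors), not the external validity of
any particular parameterization.

## Numerical choices

* Probabilities are stored at full precision; 4-decimal rounding is applied
  only in reports, matching the published display convention (QAR to the
  nearest riyal, USD to the nearest dollar).
* Validation tolerance defaults to $10^{-9}$ per chance node; pathway
  probabilities of a validated tree sum to 1 within `n_nodes` × tolerance.
* ICERs are reported per whole pain crisis averted (probability scale);
  when $\Delta E = 0$ but costs differ the ratio is undefined and the
  comparison is classified by cost, never as ±infinity.
* The exchange rate defaults to 3.641 QAR/USD, implied by the published
  cost pairs (79,424/21,813 and 73,226/20,111 both give ≈3.6411); the
  published WTP pair (547,500/150,000) implies 3.65. The discrepancy is
  noted here, the rate is configurable, and ICERs are invariant to joint
  conversion of both arms.
* Frontier ties at equal NMB break toward lower cost.
* Problem sizes: Monte Carlo analyses default to 5000 iterations; the
  distribution-level checks in the test suite use $10^5$ draws per fitted
  distribution, sizes at which Monte Carlo error is well below every
  tolerance asserted.

## Known limitations

* One-year horizon, binary effectiveness endpoint: no quality-of-life
  weighting, no chronic complications, no Markov extension, no discounting.
* Only triangular/Trigen uncertainty is implemented — the conventions of
  the source analysis — not the beta/gamma/Dirichlet families otherwise
  common in health-economic PSA.
* Parameters are sampled independently; renormalization induces the only
  dependence between siblings.
* The residual failure branch's cost assignment is an assumption (see
  above); the published tables leave it undefined.
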