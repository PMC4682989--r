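---
title: "Estimating the sampling variance of respondent-driven samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the sampling variance of respondent-driven samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdsvar)
```

## The estimation problem

Respondent-driven sampling (RDS) recruits a hidden population through its
own social ties: respondents pass coupons to peers, and the chain of
referrals is modeled as a random walk on the unobserved population network
`G`. Under the idealized model (undirected connected simple graph, random
referral, with-replacement sampling), the walk's stationary law is
degree-proportional, `pi_i = d_i/2m`, and the RDS-2 estimator
`sum(Y_j/d_j)/sum(1/d_j)` undoes the unequal inclusion probabilities.

The variance of that estimator over repeated samples is driven by the
autocorrelation of the outcome along the walk. Consecutive respondents are
network neighbors; if connected people resemble each other (homophily), the
effective information in `S` interviews is much less than `S` independent
draws, and design effects well above one result. This package computes that
variance exactly when the network is known, implements the estimators used
when it is not, and provides the simulation machinery to measure how far
those estimators fall short.

## Exact spectral variance on a known chain

For the walk's transition matrix `P` (rows `G_ij/d_i`), the symmetrized
matrix `G_ij/sqrt(d_i d_j)` shares its eigenvalues `lambda_k` and has an
orthonormal eigenbasis. Writing `Y*` for the outcome centered at its
`pi`-weighted mean and `alpha_k` for the loadings of `sqrt(pi) Y*` on that
basis, two stationary draws `t` steps apart covary as

    cov(t) = sum_{k >= 2} alpha_k^2 lambda_k^t,

with `cov(0) = sigma^2 = sum_i pi_i (Y*_i)^2`. The variance of the mean of
an `S`-step stationary walk is the average of all pairwise covariances:

    Var(ybar) = S^-2 [ S sigma^2 + 2 sum_{t=1}^{S-1} (S - t) cov(t) ].

This is the form implemented in `exact_rw_variance()`. One sometimes sees
the double sum written with an extra `1/(S-1)` prefactor; that normalization
does not reproduce the standard worked values for this quantity (and is
dimensionally inconsistent with `Var(ybar) -> sigma^2 Var`-scale behavior),
so the stationary-chain form above is used throughout. The walk is assumed
to start from `pi`, matching a seed drawn from the equilibrium
distribution; `design_effect` divides by the variance `sigma^2/S` of `S`
independent draws from `pi`. A constant outcome returns variance 0 with an
undefined design effect rather than an error. For non-reversible chains
(which arise for estimated higher-order transition matrices) the same
covariances are computed by matrix powers, `cov(t) = (pi Y*)' P^t Y*`,
which coincides with the spectral sum whenever the latter is defined.

## A two-block model of hidden mixing heterogeneity

The failure mode of interest is homophily on an *unobserved* variable. The
package ships a minimal population exhibiting it: four equal cells crossed
by the observed outcome `Y` and a hidden binary `Z`, where `Z = 0` people
befriend only their own `Y` group and `Z = 1` people carry all cross-group
ties. Friendship-end counts per cell pair are `D` (within each `Z = 0`
cell), `E` (between the two cells of a `Y` group), `F` (within each
`Z = 1` cell) and `H` (across `Y` groups); equal total degree per cell
forces `D = F + H`. With `a = E/(E+F+H)` and `b = H/(E+F+H)` the cell chain
is

    M = | 1-a   a    0    0  |
        |  a  1-a-b  b    0  |
        |  0    b  1-a-b  a  |
        |  0    0    a   1-a |

with uniform stationary law and closed-form eigenvalues
`(1, 1-b-a+sqrt(a^2+b^2), 1-2a, 1-b-a-sqrt(a^2+b^2))`
(`table1_eigenvalues()`, verified against the numeric eigendecomposition to
1e-10 in the tests). A first-order analysis sees only the dyadic collapse
`C` with off-diagonal `i = b/2`, whose second eigenvalue is `1 - b`. Since
`1-b-a+sqrt(a^2+b^2) > 1-b` for all positive `a`, `b`, the true chain always
mixes more slowly than its collapse, so a variance estimator built on `C`
*always* underestimates on this family — by a factor the tests measure
directly (design effects 7.64 vs 4.88 at `a = b = 1/3`, and 19.12 vs 3.15
at `a = 1/21, b = 10/21`, for 100-step walks). Note that the defining
mixing parameter `a` is the share of a cell's friendship ends crossing `Z`
within the same `Y` group (`E`-ties); renderings of this algebra that put
`F` in that role are inconsistent with the matrix above and with the
closed-form eigenvalues whenever `E != F`, which is why `block_spec()`
computes `a = E/(E+F+H)`.

`realize_block_network()` turns a spec into a node-level network by placing
the exact number of edges uniformly at random within each cell pair
(`D/2` and `F/2` undirected edges inside cells, since the counts are
friendship ends; `E` and `H` across). The mechanism is deliberately the
simplest one consistent with the cell counts: aggregated back to cells with
stationary weights, any realization reproduces `M` exactly, which the tests
assert. What it does **not** emulate: degree heterogeneity within cells,
triadic closure, or any community structure beyond the four blocks — so
passing tests on these fixtures say nothing about those features of real
networks. Cell sizes default to 30 per cell and are equal by construction.

## The branching sampler

`rds_sample()` implements coupon-style recruitment with the recruit-count
distribution (1/3, 1/6, 1/6, 1/3) for 0-3 recruits — the standard design in
simulation studies of school and college networks, and the default here.
Seeds are drawn from the degree-proportional equilibrium; recruitment
proceeds breadth-first (wave order, matching coupon rounds in the field);
each recruit is a uniformly chosen neighbor — any neighbor with
replacement, an uninterviewed one without. Two edge policies needed a
decision the model itself does not supply:

* **Die-out.** With a 1/3 chance of zero recruits, single-seed chains can
  die before reaching the target size; when the queue empties a fresh seed
  is drawn from the equilibrium distribution (restricted to unsampled nodes
  without replacement), so the requested `S` is always attained. Samples
  may therefore contain several trees.
* **Truncation.** Sampling halts at exactly `S` records; overflow recruits
  of the final batch are dropped in draw order.

Recorded degrees are true network degrees — no degree misreporting model.
With-replacement draws may return to the recruiter (pure random-walk
semantics). `chain_distances()` returns interview-order distances or
recruitment-tree path lengths; pairs in different trees have no tree
distance (returned `NA`).

## The estimators

`vhe_variance()` assembles the algebraic estimate from the sample alone:

1. a degree-weighted analog of the population variance,
   `vhat = sum_i (d_i / sum d) (Y_i - muhat)^2` with `muhat` the RDS-2
   mean (the sample must stand in for both `pi` and `Y*`; weights
   proportional to degree mirror the stationary law);
2. pairwise covariances from the eigensystem of the estimated category
   transition chain, evaluated at each pair's chain distance, summed over
   all ordered pairs;
3. combined as `S^-2 (S vhat + covariance sum)`, clamped at zero.

For order 1 the chain is the 2x2 row-normalized tally `C` with its own
stationary law as weights. `distance_mode = "tree"` (the branching
correction) replaces interview-order distances by recruitment-tree path
lengths; unlinked cross-tree pairs contribute zero covariance, a choice
that keeps the estimate defined for multi-seed forests (the alternative,
dropping those pairs, would rescale the sum arbitrarily). Orders 2 and 3
lift the state space to the most recent 2 or 3 outcomes (structural zeros
where history suffixes disagree); the lifted chain advances one respondent
per step, its state weights are the empirical history frequencies (the
lifted tally's stationary law is unreliable in the sparse cells that
motivate the order trade-off), and rows never observed as histories are
imputed by splitting mass evenly over their two structurally reachable
successors, with a flag. Tallies are raw; an optional reciprocity
symmetrization of the order-1 counts is available but off by default.

Two properties of the assembled estimator are worth knowing. On
non-branching chains, tree and sequence distances coincide, so the
branching correction changes nothing (asserted to 1e-12). And even in the
regime where the category chain *is* the true process — chains simulated
directly from a 2x2 `C` — the estimator is only asymptotically unbiased:
both `vhat` and the plug-in `alpha^2` are short of their targets by exactly
`Var(ybar)`, and the geometric sum is convex in the estimated eigenvalue,
leaving a net downward bias of a few percent at `S = 100`. The test suite
measures this directly (2,000 simulated chains): the mean estimate sits
about 4% below the exact chain variance, far outside the Monte Carlo error
of the mean. This is a property of any plug-in estimator of this form, not
of the implementation, and it is an order of magnitude smaller than the
structural bias the package exists to study.

`sbe_variance()` draws `b` synthetic chains of the observed length from
`C` (default `b = 1000`; initial category from observed frequencies — the
model is silent on both), resampling each synthetic respondent's degree
uniformly from observed respondents of that category, and reports the
variance of the replicate RDS-2 means. Single-category samples return
variance 0, flagged; a category never observed recruiting falls back to the
marginal category distribution, flagged. Degrees of zero are rejected
everywhere, never imputed.

## The first-order-Markov diagnostic

Whether a first-order summary suffices is testable. The diagnostic
regresses, over one observation per ordered adjacent pair (ego, alter),
the proportion of alter's neighbors with `Y = 1` — ego counted among them —
on alter's `Y`, ego's `Y` and their product, and rejects the first-order
hypothesis when the ego terms are jointly significant (Wald F on 2 and
`n - 4` df, HC1 robust covariance; the choice of
heteroskedasticity-consistent rather than cluster-robust errors follows the
test's standard form). At the sample level the pairs are referrals and
alter's neighborhood is its recruits plus its recruiter, which also keeps
pendant recruits in the table. Ordered pairs are used (two observations per
undirected edge) because the ego and alter roles are asymmetric; a
one-per-edge random orientation is available for sensitivity, as are both
readings of the ego-inclusion rule (`union`, the default, versus
`multiset`, which double-counts ego when already a neighbor). Incomputable
regressions — constant response, single-category data, fewer than five
observations — return an `undefined` verdict, which downstream summaries
count as "may be FOM".

One consequence of the ego-inclusion rule deserves emphasis, because the
test suite measures it: the response for pair (ego, alter) contains ego's
own outcome with weight `1/d(alter)`. The with-replacement walk can step
back to ego, so this is faithful to the process — but it means the
regression's null is essentially never exactly true on a finite-degree
graph, *whatever* the attribute structure. On 500 generated networks with
i.i.d. attributes (150 nodes, mean degree 8), the network-level test
rejects essentially always at the 5% level rather than at the nominal
rate; sample-level tests on small forests reject far less often purely for
power reasons. The diagnostic is therefore informative as a one-sided
screen — failure to reject on a sample says little — and its network-level
rejection rate should not be read as a calibrated error rate.

## Replicated studies and their metrics

`run_study()` draws `r` independent samples (sub-seeds derived from one
master seed, so studies are reproducible bit for bit) and reports:

* **population sampling variance** — the mean squared deviation of
  replicate RDS-2 means around the *true* mean (an MSE; a central-variance
  variant is available via `empirical_sampling_variance(central = TRUE)`);
* per-method **bias** (mean estimated variance minus population sampling
  variance), **ratio**, and **95% coverage** (`mu` within
  `muhat +/- 1.96 sigmahat`);
* **design effects**: empirical (population sampling variance over
  `p(1-p)/S` with the population `p`) and estimated;
* a **panel split** of all aggregates by the per-sample FOM verdict.

`homophily_ratio()` is observed over expected cross-group referrals with
expectation `2 p-hat (1 - p-hat)` from the *sample* composition (it is a
sample-level quantity); single-category samples are undefined and dropped,
with counts, from `bias_homophily_regression()`, which fits the
XY-standardized slope of per-sample bias on homophily, optionally absorbing
network indicators (equivalently, within-network demeaning — the tests
assert the algebraic identity).

## Numerical choices and problem sizes

* Row-stochasticity is enforced to 1e-10; reversibility (detailed balance)
  is detected to a 1e-9 relative tolerance and selects the spectral versus
  matrix-power covariance path.
* Eigenvalues sort descending; the leading loading `alpha_1` is zero by
  mean-centering and `sum alpha_k^2` equals the population variance (both
  asserted to 1e-10).
* `largest_component()` breaks size ties toward the component containing
  the lexicographically smallest node identifier; node order is sorted
  lexicographic throughout.
* Degenerate inputs: constant outcomes give zero variance (flagged), not
  errors; reducible chains are flagged and refuse exact-variance
  computation; negative assembled variance estimates clamp to zero with a
  flag.
* The test suite's simulation design: 200,000 stationary walks per fixture
  chain for the Monte Carlo check of the spectral formula; 2,000 simulated
  chains for the FOM-regime check of the VHE; 500 replicates of size-200
  branching RDS on two 200-240-node block realizations for the
  underestimation direction; 500 i.i.d.-attribute networks for the
  diagnostic's null behavior; 2,000 walks on a 200-node complete graph for
  the coverage machinery. These sizes hold each check's Monte Carlo error
  comfortably below the effect it measures.

## Limitations

* Undirected simple networks only: no weights, multi-edges, or directed
  referral structure.
* The block generator emulates mixing heterogeneity, not realistic degree
  distributions or clustering; conclusions about real networks require real
  networks, which the loaders (`load_network()` for edge lists and GraphML)
  accept.
* VHEhom is data-hungry: 4-chains are scarce in size-200 samples, and the
  imputation of unobserved history rows adds noise precisely when the
  higher order would matter.
* The RDS-1 mean estimator, successive-sampling estimators and tree
  bootstraps other than the SBE are out of scope.
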