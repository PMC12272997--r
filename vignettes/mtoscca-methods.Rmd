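---
title: "Methods: orthogonality-penalized multi-task sparse CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthogonality-penalized multi-task sparse CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the model, the numerical policies, and — most
importantly — the design decisions that were genuinely open when the
package was written, with the reasoning behind each. It states no
empirical claim that the test suite does not itself compute.

## Model and estimation

Given a standardized imaging block $X \in \mathbb{R}^{n\times p}$ and
$M$ standardized genetic blocks $Y_m \in \mathbb{R}^{n\times q}$ over
the same $n$ subjects, the solver estimates weight matrices
$U \in \mathbb{R}^{p\times M}$ and $V \in \mathbb{R}^{q\times M}$ by
minimizing, subject to $\|Xu_m\|^2 = \|Y_m v_m\|^2 = 1$,

$$
\sum_{m=1}^{M}\Big(\|Xu_m - Y_m v_m\|^2
  + \lambda_{v3}\,\|v_m v_m^\top - I\|_F^2
  + \lambda_{u2}\,\|u_m u_m^\top - I\|_F^2\Big)
  + \lambda_{v1}\|V\|_{2,1} + \lambda_{v2}\|V\|_{1,1}
  + \lambda_{u1}\|U\|_{2,1}.
$$

The regression form $\|Xu_m - Y_m v_m\|^2$ with unit-norm scores is the
usual computable surrogate for maximizing $\mathrm{corr}(Xu_m, Y_mv_m)$:
under the constraints the residual equals $2 - 2\,u_m^\top X^\top Y_m
v_m$, so minimizing it maximizes the canonical correlation.

**Alternating updates.** Holding all but one column fixed, each
subproblem is quadratic once the nonsmooth penalties are replaced by
their half-quadratic surrogates. With $D_{v1} =
\mathrm{diag}\big(1/(2\max(\|V_{i,\cdot}\|_2,\varepsilon))\big)$,
$D_{v2} = \mathrm{diag}\big(1/(2\max(|v_{j}|,\varepsilon))\big)$ (and
$D_{u1}$ analogous on rows of $U$), the stationarity conditions give
the linear systems implemented in `update_v()` / `update_u()`:

$$
\big[(1+\gamma_v)\,Y_m^\top Y_m + \lambda_{v1} D_{v1} + \lambda_{v2} D_{v2}
 + 2\lambda_{v3}(v_m v_m^\top - I)\big]\,v_m^{+} = Y_m^\top X u_m,
$$

and symmetrically for $u_m^{+}$ with right-hand side $X^\top Y_m v_m$.
Quoted closed forms for this family of updates sometimes carry two
typographical slips — a double-counted Gram matrix and a
matrix-valued right-hand side — so the package re-derives the systems
from the stationarity condition; the loop-assembled oracle in the test
suite checks every term entry by entry. The orthogonality gradient is
linearized at the previous iterate (its $v_mv_m^\top - I$ factor is
held constant within a sweep) so the subproblem stays a single linear
solve, mirroring the closed-form character of the update equations.
The reweighting diagonals are refreshed from the current iterate each
sweep; $\varepsilon = 10^{-6}$ caps them at $1/(2\varepsilon)$.

**Constraints and scale.** $\gamma_u, \gamma_v$ (quadratic pulls on the
score norms inside the systems) default to 0 because the constraints
are enforced *exactly* by rescaling $w \mapsto w/\|Zw\|$ after every
update; the knobs remain exposed for completeness.

**Initialization.** The default start is the leading singular-vector
pair of each cross-covariance $X^\top Y_m$ — the standard warm start in
sparse-CCA practice (it is deterministic and lies in the basin of the
dominant shared factor). An all-ones start and a seeded random start
are available as options. The all-ones start was observed to land in
spurious basins on simulated data: when the initial score $Xu^{(0)}$ is
nearly orthogonal to the latent factor, the self-reinforcing
reweighting diagonals freeze the iteration where it started. That
observation is why "ones" is *not* the default despite being the
simpler convention.

**Stopping, signs, stabilization.** Iteration stops when the largest
absolute weight change in a sweep falls below `tol` ($10^{-5}$) or
after `max_iter` (100) sweeps. Each $(u_m, v_m)$ pair is sign-fixed at
return by making the largest-magnitude entry of $u_m$ positive; note
that flipping *both* vectors leaves the objective and the correlation
unchanged, so this is purely a reproducibility convention (the
correlation itself is driven nonnegative by the objective). Linear
systems are symmetrized and, if the factorization fails — unavoidable
when $q > n$ makes $Y^\top Y$ rank-deficient and the penalties vanish —
an escalating ridge of $10^{-8}\cdot\mathrm{tr}(A)/\dim$ is added
before giving up with a condition estimate.

**Baseline.** `fit_mtscca()` runs the identical machinery with
$\lambda_{v3} = \lambda_{u2} = 0$: the structured-sparsity multi-task
SCCA with its norm constraints realized in penalized (Lagrangian) form.
The test suite asserts bit-for-bit equality with `fit_mtoscca()` at
zeroed orthogonality penalties, so comparisons between the two isolate
exactly the orthogonality terms.

## Default hyperparameters

The package defaults $(\lambda_{v1}, \lambda_{v2}, \lambda_{v3},
\lambda_{u1}, \lambda_{u2}) = (0.001, 0.001, 0.01, 0.1, 0.1)$ are the
combination selected by exhaustive grid search over
$\{0.001, 0.01, 0.1, 1\}^5$ in the motivating imaging-genetics
application (structural-MRI ROIs against SNP dosages and gene
expression in a cognitive-impairment cohort). They are reasonable
starting values for data standardized to unit column variance, not
universal constants; `grid_search()` re-selects them for new data. The
grid is enumerated in fixed lexicographic order ($\lambda_{v1}$
slowest, $\lambda_{u2}$ fastest) so that "the $k$-th combination" is
reproducible across runs and platforms. By default the grid criterion
is the in-sample mean $|CCC|$ over tasks, which mirrors the standard
selection procedure for this model family; note the saturation caveat
below when $q > n$.

## The synthetic world

`simulate_block()` draws one standard-normal latent score vector $c$
and three sparse loading vectors with $\pm 1$ entries on uniformly
chosen supports (10% of features by default), and forms each block as
the rank-one signal $c\,w^\top$ plus i.i.d. Gaussian noise of standard
deviation $\sigma$, drawn independently per block. Labels are
$\mathbb{1}[c > 0]$, so classification evaluation has a planted signal.

Two generator decisions deserve their reasoning on record:

* **Loading scale.** Loadings keep their raw $\pm 1$ entries rather
  than being normalized to unit length. The benchmark sweeps noise
  levels $\sigma = 1,\dots,5$; with $\pm 1$ loadings the per-feature
  signal-to-noise ratio spans $1$ down to $0.2$ and the held-out
  canonical correlation degrades smoothly across the sweep. Had the
  loadings been unit-normalized (entries $\approx 0.12$ for a
  65-feature support), even $\sigma = 1$ would sit at per-feature SNR
  $\approx 0.12$ and every sweep cell would measure the same noise
  floor — the benchmark would be unable to show the graded degradation
  it exists to show.

* **Held-out evaluation.** `noise_sweep()` evaluates $|CCC|$ on an
  independently generated block that shares the planted loadings
  (fresh scores and noise). With $q = 650 > n = 100$ the *in-sample*
  correlation of any fitted weight pair saturates near 1 at every
  noise level, because the task block can reproduce an arbitrary
  score vector; an in-sample sweep is therefore flat and
  uninformative (an `eval = "insample"` mode is kept for
  completeness). For the same reason, a real-data canonical
  correlation materially below 1 at $q > n$ — the regime of the
  motivating application — is only meaningful as a held-out quantity.

What the generator does **not** emulate: linkage-disequilibrium-style
correlation among noise features, multiple latent factors, cross-task
shared supports (each task draws its own), non-Gaussian dosage scales,
and any redundant correlated-feature structure. The last point matters
for interpreting the solver comparison: the orthogonality penalties
target redundancy among selected features, and a single-factor
generator with independent noise columns offers no redundancy to
exploit, so this benchmark should not be over-read as measuring the
orthogonality penalty's raison d'être. A green monotonicity/ordering
test establishes graded noise robustness and parity-or-better at
two-Monte-Carlo-SE resolution — no more.

**Recovery harness.** The planted-support recovery check (noise
$\sigma = 0.1$, support = entries above 10% of the maximum absolute
weight) runs the solver with orthogonality penalties only and the
sparsity penalties at zero. The reason is structural: at low noise the
planted support columns are near-duplicates of one another (pairwise
correlation $\approx 0.99$), and any $L_1$-type penalty then —
correctly, per its own objective — selects a small representative
subset of a collinear group rather than the full support. Support
*containment* is therefore a property of the unpenalized factor
estimate; the sparsity penalties' representative-selection behavior is
a separate, expected phenomenon. The same collinearity limits the
imaging-side check: the nine near-duplicate imaging columns make the
division of weight among them unstable at $\sigma = 0.1$ (any split
fits equally well), so containment is asserted for the genetic-side
$v_m$ supports, where it is well-posed.

## Biomarker evaluation

* **Screening.** `rf_screen()` ranks features by random-forest
  impurity importance and keeps the top `n_keep`, shrinking an
  over-wide SNP block to the gene block's width before the multi-task
  fit; forest settings are chosen by a small exhaustive grid with
  stratified cross-validation, and screening runs on training samples
  only. The forest itself (bagged CART, Gini splits, `mtry`
  subsampling) is implemented in the package because the pinned
  dependency set ships no random-forest package; it is scoped to the
  screening task, not offered as a general learner. Permutation
  importance is not implemented; impurity importance is the default
  and only option.
* **Per-marker ROC.** AUCs use the rank statistic with ties counted
  one half, computed from raw feature values with no direction
  flipping — a marker whose high values indicate controls reports an
  AUC below 0.5, as is conventional in the tables this output mirrors.
* **Confidence intervals.** DeLong placement-value intervals are the
  default (deterministic, standard for per-marker AUC reporting);
  stratified-bootstrap percentile intervals are the alternative.
  Because the bootstrap resamples cases and controls separately, a
  degenerate single-class resample cannot occur. Both intervals clip
  to $[0, 1]$.
* **Combined panels.** The combiner behind multi-feature panels is a
  ridge-penalized logistic model (`glmnet`, $\alpha = 0$, fixed small
  $\lambda$), fitted on the training split only and scored on the test
  split — the minimal standard multivariate combiner consistent with
  split discipline. A single-feature "panel" is scored by the raw
  feature itself so that its panel AUC is exactly its marker AUC
  (a logistic transform of one feature is monotone, but its sign
  could silently flip the direction; using the raw feature keeps the
  no-flipping convention).
* **Cross-validated stability.** `cv_selection_frequency()` refits the
  solver per fold and tabulates how often each feature enters the
  top-$k$ lists, the dispersion summary for a cross-validated ranking
  procedure whose headline statistic would otherwise be unstated.

## Known limitations

* Monotone descent of the recorded objective is an empirical property
  (asserted over seeded replicates), not a theorem: the exact
  rescaling onto the constraint set and the linearized orthogonality
  gradient both step outside the majorize-minimize guarantee.
* The solver targets dense Gram matrices at $p, q \lesssim 10^3$;
  there is no out-of-core or GPU path.
* Supervised variants (embedding diagnosis labels in the CCA
  objective) are out of scope; labels enter only through screening,
  splitting and ROC evaluation.
* The simulator's labels derive deterministically from the latent
  score, so classification difficulty is controlled entirely by the
  noise level, not by label noise.
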