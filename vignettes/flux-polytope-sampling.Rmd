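---
title: "Uniform sampling of steady-state flux polytopes with ellipsoid rounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uniform sampling of steady-state flux polytopes with ellipsoid rounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxhr)
```

## The model and the problem

A metabolic network with $M$ metabolites and $N$ reactions, stoichiometry
$S \in \mathbb{R}^{M \times N}$, and flux bounds
$v_r \in [v_r^{\min}, v_r^{\max}]$ has the feasible steady-state set

$$P \;=\; \{\, v \in \mathbb{R}^N : S v = 0,\; v^{\min} \le v \le v^{\max} \,\},$$

a bounded convex polytope. Inference tasks on metabolism — credible flux
ranges, marginal flux distributions, correlations between pathways — require
*uniform* samples from $P$. Exhaustive vertex enumeration is exponential,
and i.i.d. rejection sampling dies beyond a handful of dimensions, so the
workhorse is the hit-and-run (HR) Markov chain: from $x_t$, draw a uniform
unit direction $\theta_t$, intersect the line $x_t + \lambda\theta_t$ with
$P$ to get the chord $[\lambda_{\min}, \lambda_{\max}]$, draw
$\lambda^\star$ uniformly on the chord, and move. HR leaves the uniform law
invariant on any convex body and mixes in polynomial time.

Two practical obstacles dominate:

1. **Degeneracy.** $P$ lives inside the null space of $S$ and has empty
   interior in $\mathbb{R}^N$; run HR there and almost every chord has zero
   length — the dynamics freezes. `build_polytope()` therefore
   re-parameterizes $P$ on an orthonormal basis $B$ of the null space
   (numerical rank from the SVD, threshold
   $\max(M,N)\,\varepsilon\,\sigma_{\max}$): sampling happens in the
   $D$-dimensional coordinates $p$, with $v = \text{anchor} + Bp$ and
   $D = N - \operatorname{rank} S$ after pruning.

2. **Ill-conditioning.** Flux scales in genome-scale models span several
   orders of magnitude. The mixing time scales like
   $\tau \simeq O(D^2 R^2 / r^2)$, where $R/r$ — the sandwiching ratio of
   circumscribed to inscribed balls — can reach $10^5$. The isotropic HR
   step is then limited by the thinnest directions and never traverses the
   long ones.

The cure for (2) is *rounding*: build an ellipsoid
$E = \{p : (p-c)^\top \Sigma^{-1} (p-c) \le 1\}$ that matches the shape of
$P$ and draw the HR direction as $\theta \propto A u$ with $A A^\top =
\Sigma$ and $u$ uniform on the sphere. This is equivalent to running plain
HR on the affinely transformed (rounded) body $A^{-1}P$; the Jacobian of an
affine map is constant, so uniformity is exactly preserved for any fixed
invertible $A$. Any factor $A$ of $\Sigma$ induces the same direction law
(the seed $u$ is spherically symmetric), so the Cholesky factor used here
is interchangeable with a symmetric square root.

## The three rounding constructions

**PCA** (`pca_ellipsoid`): center = sample mean, shape = connected
(mean-subtracted) covariance of a pilot chain. Even a far-from-equilibrium
pilot carries shape information, but covariance stationarity is exactly
what a poorly conditioned chain lacks — PCA alone inherits the problem it
is meant to fix. Its role is *refinement*: after LP or Lovász rounding, a
biased pilot mixes well and its covariance estimates the stationary
covariance accurately, which is why the combined schedules
(`"lp+pca"`, `"lem+pca"`) perform best.

**Iterative LP** (`lp_ellipsoid`): a greedy diameter approximation in the
spirit of flux variability analysis. Minimize and maximize every coordinate
direction by linear programming; take the longest vector joining a
minimizing and maximizing vertex as the first axis; repeat the variability
analysis restricted to the orthogonal complement of the axes found so far,
until $D$ axes exist. Alternate LP optima (every facet of a box ties) would
make "the" optimizing vertex ill-defined, so a fixed generic secondary
objective — a small pull applied identically to the min and the max
problems — selects a canonical vertex; on an axis-aligned box the recovered
axes are then exactly the coordinate axes with the exact side lengths. The
ellipsoid is centered at the midpoint of the first axis' endpoints (a
convention; the construction does not define a center).

**Lovász ellipsoid method** (`lovasz_ellipsoid`): computes a *weak
Loewner–John pair* $E' \subseteq P \subseteq E$ with $E'$ a
$1/D^{3/2}$-shrinkage of $E$. Start from the ball enclosing the
bounding box (center = box midpoint, radius = half the box diagonal
$\times\,1.01$). If the center of $E$ is outside $P$, cut $E$ with the
most-violated constraint (a hyperplane separating the center from $P$);
otherwise shrink $E$ by $1/D^{3/2}$ and test containment of the shrunken
copy in $P$ — on failure, cut through the violated constraint. Cuts use
the standard minimal-volume enclosing ellipsoid of a sliced ellipsoid
(`min_enclosing_halfellipsoid`) with depth
$\alpha = (g^\top c - \beta)/\sqrt{g^\top \Sigma g} \in (-1/D, 1)$; the
classical references give the guarantee but not the update formulas, so the
standard deep-cut update is used and verified against brute force in the
tests. Because every cutting hyperplane supports a half-space containing
$P$, the invariant $P \subseteq E$ holds throughout, the volume strictly
decreases at every cut, and termination certifies $E' \subseteq P$ by
*exact* per-constraint support-function evaluation
($g^\top c + s\sqrt{g^\top \Sigma g} \le h$), rather than spot-checking
axis endpoints; the endpoint variant remains available
(`check = "axis"`) for fidelity comparisons. The containment test being
exact changes which cut is chosen, not the guarantee.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `equality_tol` | `1e-9` | allowed $\|S v\|_\infty$ on reconstructed fluxes |
| `blocked_tol` | `1e-9` flux units | FVA width below which a reaction is removed |
| `boundary_tol` | `1e-9` (relative) | strict-interior margin for membership |
| `chord_floor` | `1e-12` × box diagonal | chord width below which the direction is resampled |
| `default_bound` | `1e6` flux units | substitute for a missing flux bound (the sampler needs a bounded body; unbounded rays are out of scope) |
| `shrink` | $1/D^{3/2}$ | Lovász shrink factor (0.5 at $D=1$, where the canonical value degenerates to 1) |
| `max_iter` | $50 D^2$ | Lovász iteration cap |
| `pilot_n` | `20000` | pilot-chain length for PCA stages |
| `bins` / pseudo-count | 100 / 0.5 | KLD histogram resolution and regularization |

The blocked-reaction and equality tolerances are engineering choices (the
methods literature rarely states them); both are configurable. The pilot
length matters: the PCA covariance must at least order the axes of the
body, and pilots much shorter than $10^3 D$ steps fail to do so on
heterogeneous shapes. $\lambda^\star$ is drawn strictly inside the chord
(endpoints nudged inward by the chord floor) so iterates never stick to a
facet.

## Diagnostics

*Integrated autocorrelation time* is estimated by binning (batch means):
$r(b) = b \cdot \mathrm{Var}(\text{bin means})/\mathrm{Var}(\text{series})$
for bin lengths $b$ in powers of two rises to the plateau $2\tau_{\rm int}$.
The plateau is declared at the first $b$ where $r(b)$ changes by less than
10% from $r(b/2)$, capped at $b = T/20$; hitting the cap flags the estimate
"not converged" (the honest outcome for an unrounded chain on a
heterogeneous body). A delete-one-bin jackknife gives a standard error, and
$\tau$ is reported in Monte Carlo steps with any thinning multiplied back
in. White noise gives $\tau \approx 1/2$; values below flag
anticorrelation. The estimator is calibrated in the tests against the
closed form $\tau = (1+\rho)/(2(1-\rho))$ for AR(1).

*Sampler agreement* uses per-coordinate two-sample Kolmogorov–Smirnov tests
(chains subsampled with stride $\lceil 2\hat\tau \rceil$ to approximate
independence) and the histogram Kullback–Leibler divergence in bits,
$\mathrm{KLD}(Q\|P) = \sum_b P_b \log_2 (P_b/Q_b)$, with a shared binning
and pseudo-count $1/2$ per bin. The divergence has an operational reading:
$N$ samples from $Q$ pass for samples of $P$ with probability
$2^{-N\,\mathrm{KLD}}$. Agreement verdicts use 0.05 and 0.5 bits as the
good / approximate / poor boundaries.

## The synthetic benchmark generators

The generators produce the controlled shapes the experiments need, all with
analytically known per-coordinate marginals when axis-aligned (flat on the
side length), exact KLD references, and seed-determinism:

* `make_hypercube(D)` — the homogeneous control;
* `make_hyperrectangle(D, log_range)` — geometrically spaced side lengths
  (default $10^{-2}$ to $10^{5}$, a $10^7$ scale span) emulating
  heterogeneous flux scales; optionally tilted by a seeded random rotation;
* `make_random_polytope(D, m, seed)` — random unit-normal half-spaces at
  offsets in $[0.5, 1.5]$, regenerated until bounded; the oracle-comparison
  fixture for rejection sampling.

What these emulate is exactly the two failure axes of HR — dimension and
scale heterogeneity. What they do **not** emulate: the combinatorial facet
structure of real stoichiometries (boxes have $2D$ facets; networks have
correlated, near-redundant constraints), degenerate optima from biological
irreversibility patterns, and flux-coupling-induced lower-dimensional
faces. Passing the synthetic suite therefore certifies the sampler and the
rounding machinery, not any biological conclusion about a particular
network.

### Experiment designs fixed in this package

The schedule-comparison experiment (no rounding, PCA-only, LP, LEM, and the
PCA-refined combinations at equal measurement budgets) runs on a **tilted**
hyper-rectangle, $D = 20$, axes spanning $10^{-1}$ to $10^{2}$, pilot
$2\times10^4$ steps, measurement $2\times10^5$ steps per schedule. Two
deliberate choices: the tilt makes the greedy LP diameters (and the Lovász
outer shape) genuinely approximate — on an axis-aligned box the LP
ellipsoid is *exact*, so a PCA refinement could only add noise and the
combined schedules would have nothing to improve; and three decades of
scale span keep the PCA-only schedule distinguishable from no rounding at
desk-scale pilots (with a $10^7$ span, no feasible unrounded pilot carries
any information about the longest axes, and the two schedules tie at the
estimator cap). The heterogeneity-removal experiment keeps the full
$10^{-2}$–$10^{5}$ axis-aligned design at $D = 50$ with a $2\times10^6$
step budget, where the exact flat marginals give KLD references per axis.

## Numerical choices

* **LP solver.** All feasibility, variability-analysis and ellipsoid LPs go
  through a self-contained dense two-phase simplex (C++): row equilibration
  by powers of two (exact in binary floating point), Dantzig pricing with a
  Bland's-rule fallback against cycling, artificials barred from
  re-entering. It is validated against exact brute-force vertex enumeration
  on random polytopes and is exact on boxes, which the axis-recovery
  guarantees rely on. Free variables are split ($p = p^+ - p^-$); the
  polytopes here are bounded, so the split is safe.
* **Degenerate chords** resample the direction (from the same RNG stream,
  so seeds stay reproducible) rather than erroring, up to a cap that
  signals genuinely frozen dynamics — the symptom of a representation that
  is not full-dimensional.
* **Anchor projection.** The LP anchor is projected onto the null space of
  $S$ (via the right singular vectors), so reconstructed fluxes satisfy
  mass balance at machine precision rather than LP-solver precision.
* **Ties in `lp_ellipsoid`** are broken by one composite objective
  (`tie_break = 1e-7`) rather than a second lexicographic LP; on exact-tie
  faces (boxes) the selected vertex is exact, and elsewhere the
  perturbation only selects among near-optimal vertices.
* **Thinning is recorded, never hidden**: `tau` estimates convert back to
  Monte Carlo steps, and a chain's metadata always carries seed, sampler id
  and thinning.

## Limitations

* The rejection oracle is guarded to $D \le 10$ and a $10^{-6}$ acceptance
  floor; beyond that there is no exact reference, only internal consistency.
* The Lovász implementation with the prescribed $1/D^{3/2}$ shrink
  certifies its sandwich but can leave a residual anisotropy of order
  $D^{3/2}$; on strongly heterogeneous bodies LEM-alone rounding is
  accordingly weaker than LP-alone, and the PCA refinement is where the
  combined schedules earn their keep.
* ACHR is provided as a comparison baseline only; its non-Markovian
  adaptation voids the uniformity guarantee, which is the package's reason
  to exist.
* SBML support covers Level 3 core plus FBC flux bounds (read only); gene
  rules, compartments and objectives are ignored. Models with missing
  bounds are boxed at $\pm 10^6$ flux units with a warning, because the
  sampler requires a bounded body.
* Thermodynamic loop-law constraints make the feasible set non-convex and
  are out of scope.
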