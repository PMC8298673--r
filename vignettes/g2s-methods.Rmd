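---
title: "Graph-To-Structure: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-To-Structure: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Generating a 3D structure for a molecular graph conventionally means
minimizing an energy — with a force field, a semiempirical method or ab
initio theory — which is either biased or expensive. `g2s` instead treats
structure prediction as supervised regression: a training set of relaxed
geometries, one per graph, implicitly encodes the outcome of those
minimizations, and kernel ridge regression (KRR) interpolates it across
compound space.

Internal degrees of freedom are the natural targets: pairwise distances are
invariant to rotation and translation, and a complete (if noisy) distance
matrix determines coordinates up to a rigid motion and a reflection. Each
heavy-atom pair (I, J) of the zero-padded, canonically sorted distance
matrix gets its own regression coefficient column,

$$y_{IJ}(\mathbf{x}) = \sum_i^N \alpha_i^{(IJ)}\,k(\mathbf{x}_i,\mathbf{x}),
\qquad
\boldsymbol\alpha^{(IJ)} = (\mathbf{K} + \lambda\mathbf{I})^{-1}\,
\mathbf{y}^{\mathrm{ref}}_{IJ},$$

but all columns share one kernel matrix, so training all
$n_{\max}(n_{\max}-1)/2$ machines costs a single symmetric factorization.
The kernel is Laplacian, $\exp(-\lVert\mathbf{x}_i-\mathbf{x}_j\rVert_1/\sigma)$,
or Gaussian, $\exp(-\lVert\mathbf{x}_i-\mathbf{x}_j\rVert_2^2/2\sigma^2)$.

A critical assumption is **functionality of the graph → structure map**:
training data must contain exactly one geometry per graph, generated in a
consistent way (constitutional isomers only, no conformer duplicates —
`g2s_train()` rejects duplicate graphs outright). Where distinct conformers
exist in reality, the model can only learn the convention its training set
followed.

## Representations

All molecular schemes derive from a symmetric heavy-atom matrix: the bond
order matrix itself (`bond_order`), shortest-path bond counts (`bond_hop`),
covalent-radius-weighted shortest-path lengths (`bond_length`), the graph
Coulomb matrix with $0.5\,Z^{2.4}$ diagonal and $Z_iZ_j/l_{ij}$
off-diagonal (`graph_cm`), and its element-pair-bagged form (`graph_bob`).
Crystals use `flla`: each representative Wyckoff site encoded as its
element's periodic-table row and valence-electron count.

Design choices made where the design was genuinely open:

* **Covalent radii.** One table is pinned — the Cordero et al. (2008)
  single-bond radii (sp³ value for carbon) — rather than mixing sources.
  Reproducibility beats nuance here: the radii enter both the `bond_length`
  metric and the fixture generator.
* **Path weight.** `bond_length` minimizes the *summed edge weight*
  $\sum (r_a + r_b)$ along the path, not the hop count; that makes
  $l_{ij}$ a true metric (symmetry, zero diagonal and triangle inequality
  are property-tested). Path sums are computed on integer centi-Angstrom
  weights so they are exact, which matters for bit-level reproducibility.
* **Canonical sorting.** Atoms are ordered by non-decreasing Euclidean row
  norm of the representation matrix, the conventional reading of the
  norm-sorting rule. Ties are resolved by nuclear charge and then by
  canonical labeling of the weighted matrix (colour refinement with
  individualization, keeping the lexicographically smallest sorted matrix).
  The refinement is exact: the output depends only on the matrix content,
  never on input order. Residual degeneracies are true matrix
  automorphisms, for which every choice yields the same sorted matrix; the
  paired distance labels may then still differ between automorphic
  assignments — an ambiguity no graph representation can resolve, and the
  one place where label noise is inherent rather than numerical.
* **Row norms** are accumulated over sorted entries so that the floating-
  point result — not just its mathematical value — is identical under any
  input permutation.
* **graph_bob bags** are fitted state: bag sizes are fixed by the training
  set, queries with unseen element pairs fail loudly, and overflowing bags
  are truncated (smallest entries) with a warning. Distance labels for this
  scheme are ordered element-first, mirroring the atom-wise binning.
* **Disconnected graphs** (transition-state-like inputs) are handled by
  pseudo-edges of order 1 between every detached-fragment atom and the
  reaction-center atoms, which must be supplied explicitly
  (`attr(g, "reaction_centers")`): nothing in a bare graph identifies a
  reaction center reliably, so guessing is worse than asking.

## Hyperparameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| σ | kernel width (feature-distance units) | 13 log-spaced values in [0.05, 20] × median nonzero pairwise feature distance | median anchoring makes the grid scale-free across schemes |
| λ | ridge regularization | decades 10⁻¹⁰ … 10⁻³ | spans interpolation to strong smoothing; matched to anticipated label noise by CV |
| kernel | Laplacian / Gaussian | both searched | no a-priori winner across schemes |
| n_max | padding size, atoms | largest training molecule | fixes the target count at training time |

Selection uses grid search with nested fivefold cross-validation
(`nested_cv_search()`): inner folds pick the (kernel, σ, λ) triple by mean
MAE over all targets, outer folds report an unbiased MAE, and the final
model is refit on all data with the triple that wins most inner contests
(ties by mean inner score — the aggregation across outer folds is a
package choice; any fixed rule works, this one is robust to a single odd
fold). One triple is shared by all distance targets, following the
single-kernel/multi-property reading; per-target hyperparameters are
deliberately not implemented. Inside learning curves the nested protocol
would multiply cost without changing the question being asked, so
hyperparameters are selected once on the full training pool by plain
fivefold CV and held fixed across sizes and repeats.

## Hydrogen machines

Scaffold and hydrogen learning are separated: heavy atoms first, then
valence saturation. Each hydrogen contributes one training row with four
targets — its distances to four anchor heavy atoms that must not be
coplanar (tetrahedron volume ≥ 0.1 Å³, else the farthest anchor is swapped;
if no non-coplanar quadruple exists, e.g. for planar scaffolds, the set is
kept and flagged). Anchor *identity* is derived from the bonded heavy atom
and its nearest scaffold neighbours rather than from the hydrogen's own
position: only that rule is available at prediction time too, so training
targets and query-time interpretation coincide.

Hydrogen features are the bonded atom's canonical representation row, its
canonical position (disambiguating graph-automorphic atoms), a within-atom
rank (siblings on one atom are otherwise identical to the model; at
training time ranks follow the sorted label tuples so the rank is a
function of the geometry), and the molecule vector. Placement maximizes
agreement with the predicted anchor distances over a deterministic
generalized-spiral grid (default 4096 points) on the sphere of the
predicted bond radius, refined continuously from the two best distinct
basins so near-coplanar anchor sets cannot trap the argmin on the wrong
mirror side; a quadratic clash penalty (onset 1.0 Å) orders siblings.
A spiral grid rather than a quadrature node set is intentional: placement
is an argmin over a dense covering, where quadrature optimality is
irrelevant; any fixed deterministic covering serves.

One consequence worth stating plainly: hydrogens on the same heavy atom are
chemically interchangeable, so the predicted structure can permute their
*indices* relative to a reference file even when the hydrogen shell is
geometrically exact. All evaluation metrics in the package are therefore
heavy-atom metrics.

## Distance geometry

`embed_distances()` is a native two-stage solver: classical metric
embedding (double-centering, top-3 spectral components) provides the start;
SMACOF stress majorization of
$\sum_{i<j}(\lVert r_i - r_j\rVert - D_{ij})^2$ refines it. The Guttman
transform never increases stress, which the tests assert on every trace.
Defaults: relative stress-change tolerance 1e-10, 500 iterations. The
tolerance is strict and SMACOF's tail convergence is linear, so noisy
distance matrices may report `converged = FALSE` at a long-flat plateau;
raising `max_iter` (the README example uses 2000) resolves it, and
non-convergence is always flagged, never silent. Exact Euclidean distance
matrices are recovered to RMSD < 1e-6 Å from the spectral stage alone.

A distance matrix cannot encode handedness. Reconstruction returns one
enantiomer arbitrarily; `kabsch_superpose(..., allow_reflection = TRUE)` is
the default in evaluation and reports which hand was used. Whether
published heavy-atom RMSDs of this model family minimize over reflection is
generally unstated; this package does, and says so in every report.

Full dense predicted matrices are embedded — all pairs are predicted, so no
sparse-completion machinery exists. Because the solver is a smooth
majorizer rather than a stochastic global solver, artifacts attributable to
solver noise in other implementations will not reproduce here.

## Crystals

Elpasolite (ABC₂D₆) structures share one site topology, so stoichiometry is
the entire input. Site-pair distances are learned in fractional-coordinate
space (they would otherwise conflate with cell size) and a separate
single-target machine on the identical FLLA features predicts the cubic
lattice constant; Cartesian coordinates follow from embedding the predicted
fractional distances, aligning onto the ideal elpasolite template
(reflection allowed) and scaling by the predicted cell length. Stoichiometries
placing one element in both anion and cation roles are rejected.

## The synthetic fixture generator

The generator emulates the *study conditions*: families of constitutional
isomers over a fixed heavy-atom stoichiometry, each graph mapped to exactly
one geometry, generated consistently. Connectivities are sampled as uniform
labeled trees (Prüfer sequences) with optional single-ring closures,
deduplicated by colored-graph canonical labeling, and emitted in canonical
order; all bonds are single, and hydrogen counts follow standard valences.
Geometries are built from idealized internal coordinates — bond lengths
equal to covalent-radius sums, tetrahedral/trigonal/linear angles by
hybridization, canonical anti torsions, rings as planar cyclic polygons,
hydrogens completing the coordination geometrically. Connectivities whose
idealized build leaves any two atoms closer than 0.7 Å are excluded as
sterically unrealizable, deterministically. Crystal fixtures draw distinct
ABC₂D₆ stoichiometries and set the lattice constant to a smooth, strictly
increasing function of the four covalent-radius size proxies
($a_0 = 2r_A + 2r_B + 0.4 r_C + 4 r_D$, matching the ~8–10 Å scale of real
elpasolites) plus Gaussian noise of 0.1 Å emulating relaxation scatter; the
halide-site coordinate follows the A–D bond length, $x_D = (r_A+r_D)/a_0$.

What the fixtures deliberately do **not** emulate: conformational
flexibility (torsions are fixed anti), multiple bonds, electronic effects
on bond lengths, crystal-site relaxations beyond one parameter, and
measurement noise on molecular geometries. Passing tests on fixtures
therefore demonstrate the *machinery* — invariances, interpolation,
systematic learning, error anisotropy, parameter recovery under known noise
— not chemical accuracy on real data, for which the benchmark protocol
(`run_qm9_benchmark()`, user-downloaded datasets) exists. On 256 training
isomers the held-out distance MAE is about 0.24 Å; the idealized torsion
rules make long-range distances a deliberately hard, conformer-like target,
so desk-scale numbers sit above what thousands of quantum-relaxed training
structures achieve.

## Numerical choices and degenerate inputs

* Cholesky solves escalate a diagonal jitter 1e-10 → 1e-6 before failing
  hard; λ = 0 with duplicate feature rows is the documented way to hit it.
* Predicted distances are floored (0.5 Å molecules, 1e-3 fractional) before
  embedding; a model bad enough to predict non-physical values still yields
  a finite, flagged result.
* Fold assignments, subset draws and generator sampling all flow from one
  user seed through an RNG-state-preserving scope, so identical calls are
  bit-identical and never perturb the caller's RNG.
* Molecules are internally sorted by canonical graph key before fold
  assignment, so training is invariant to the order the dataset arrived in.
* Anchor ordering rounds distances to 1e-6 Å before ranking: idealized
  geometries produce exact ties whose order must not flip under solver
  noise.
* Models persist to a single schema-versioned JSON container (features,
  coefficients, hyperparameters, bag sizes, provenance); version mismatch
  on load is an error, not a guess.

## Known limitations

* Graph-automorphic atom pairs carry irreducible label ambiguity (wrong
  torsion/diastereomer choices on symmetric scaffolds); a richer positional
  encoding cannot fix what the graph does not determine.
* Hydrogen indices may permute within an atom (see above).
* Reconstruction quality degrades for long flexible chains where distant
  pairs dominate the error — the tests assert exactly this anisotropy
  (bonded pairs ~0.09 Å vs ≥4-hop pairs ~0.48 Å on fixtures).
* Crystal support assumes the cubic elpasolite template; periodic-image
  effects are not modelled in the embedding.
* KRR scales as N³ in training molecules; kernel approximations are out of
  scope.
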