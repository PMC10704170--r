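---
title: "Spring-model stiffness and the latent geometry of interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spring-model stiffness and the latent geometry of interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Interaction networks of genes or proteins are usually analysed as purely
combinatorial objects, yet many biological networks behave as if their nodes
lived in a metric space: hubs sit "centrally", communities occupy regions, and
tree-like hierarchy is the signature of negative curvature.  `springgeo`
implements a pipeline that (i) converts a network into an all-pairs
dissimilarity matrix through a physical spring model, (ii) embeds that matrix
into the three isotropic model geometries — Euclidean space, the hyperbolic
Poincaré ball, and the sphere — (iii) selects the geometry whose embedding
distorts the dissimilarities least, and (iv) when the winning geometry is
hyperbolic, clusters nodes by their radial coordinate to nominate a cluster of
candidate *driver* nodes of the network dynamics.

# The spring model

The network is a system of masses and springs: node $i$ carries mass $m_i$
equal to its total degree, edges are springs.  The mass-weighted incidence
matrix is $C = M A$, with $A$ the oriented incidence matrix (one $+1$/$-1$
pair per edge column; the orientation is bookkeeping only) and $M =
\mathrm{diag}(m)$.  At mechanical equilibrium the generalized Hooke law forces
node-space displacement patterns $v$ to satisfy $C^\top v = 0$, i.e. $m_i v_i
= m_j v_j$ across every edge.  We compute an orthonormal basis $N$ of
$\ker C^\top$ by SVD (singular values below $10^{-10}\sigma_{\max}$ treated as
zero) and define the all-pairs stiffness as the projector

$$K = N N^\top .$$

The kernel-as-matrix step deserves a note: "the stiffness is the nullspace of
$C^\top$" does not by itself name a matrix, and the Gram/projector form is the
canonical symmetric, basis-independent choice.  For a connected graph the
kernel is one-dimensional, spanned by $v_i \propto 1/m_i$, so

$$k_{ij} = \frac{1/(m_i m_j)}{\sum_l 1/m_l^2},$$

a closed form the test suite checks to $10^{-12}$ on dozens of random graphs.
$K$ is then rank one; the pipeline does not rely on its rank anywhere.  Key
invariants, all tested: $K$ is positive semidefinite with trace equal to the
number of connected components, block-diagonal across components, and
invariant to the arbitrary edge orientation.

Off-diagonal stiffness values are min–max rescaled to $[0,1]$ (a rescale is
declared degenerate when $\max-\min \le 10^{-12}$ relative — exact equality
would amplify $10^{-16}$ symmetry noise into the full $[0,1]$ range) and
converted to dissimilarities

$$d_{ij} = \frac{1}{1+\tilde k_{ij}} \in [0.5, 1], \qquad d_{ii} = 0 ,$$

so stiff (efficiently interacting) pairs are close.  The diagonal is forced to
zero because no embedding method accepts a nonzero self-dissimilarity.

Vibrational centrality — the thermal displacement amplitude
$\Delta x_i = \sqrt{(T/k_0)\,L^+_{ii}}$ with $L^+$ the Laplacian
pseudoinverse — is provided with defaults $T = k_0 = 1$.  The non-equilibrium
stiffness deserves a caveat: the printed relation $K = (C^\top)^{-1} F
\Delta x^{-1}$ cannot hold literally because $C^\top$ has rank at most $n-1$
and the force vector produced by $F = -C^\top K \Delta x$ is edge-dimensional.
We implement the minimal-norm least-squares solution
$K = \mathrm{pinv}(C^\top)\, F_E\, \mathrm{diag}(\Delta x)^{-1}$, where row
$e$ of $F_E$ restricts the node forces to the endpoints of edge $e$, warn that
a pseudoinverse was used, and symmetrize.  It reproduces the analytic
single-edge solution and returns $K = 0$ for zero forces.

# The three embeddings

**Stress.**  All model comparison uses the raw residual sum of squares over
unordered pairs, $\sum_{i<j}(d^{\mathrm{in}}_{ij}-d^{\mathrm{emb}}_{ij})^2$
— no square root, no normalization (a normalized diagnostic is attached to
the result but never used for selection).  Summing unordered rather than
ordered pairs differs by an exact factor 2 and cannot change any argmin.

**Euclidean.**  Classical (Torgerson) MDS: double-center $-\tfrac12 D^2$,
eigendecompose, keep the top $p$ non-negative eigenvalues (negatives clamped
and counted).  An exactly Euclidean input is recovered to machine precision
whenever $p \ge p_{\mathrm{true}}$.

**Hyperbolic (Poincaré ball, curvature $-\kappa$, default $\kappa = 1$).**
Distances are
$d(u,v) = \kappa^{-1/2}\operatorname{acosh}\!\bigl(1 +
2\lVert u-v\rVert^2 / ((1-\lVert u\rVert^2)(1-\lVert v\rVert^2))\bigr)$; the
2-D complex-disk closed form and the special case
$d(0,z) = \log\frac{1+|z|}{1-|z|}$ serve as independent cross-checks at
$10^{-12}$.  The embedding uses the strain-minimizing ("hydra") eigensolver
initialization — $Y = \cosh(\sqrt\kappa D)$, leading eigenpair giving the
time-like hyperboloid coordinate (entrywise absolute value, clamped $\ge 1$),
most-negative eigenpairs giving spatial directions, hyperboloid-to-ball
conversion $r_i = \sqrt{(x^0_i-1)/(x^0_i+1)}$ — followed by quasi-Newton
(L-BFGS-B, up to 500 iterations) minimization of the stress with an analytic
gradient.  Instead of clamping coordinates at the ball boundary we optimize an
unconstrained parametrization $x = \tanh(\lVert y\rVert)\,y/\lVert y\rVert$,
which is smooth, surjective onto the open ball, and keeps every iterate
feasible.  Two points are always embedded exactly (tested to $10^{-6}$);
planted 2-D disk configurations are recovered with median relative distance
error far below 5%.  Embedding at curvature $\kappa$ is exactly equivalent to
embedding $\sqrt\kappa D$ at curvature 1 (tested), so $\kappa$ is a
convenience knob, not a second degree of freedom.

**Spherical (radius $r$).**  Following the Gram-matrix construction
$Z(r) = r^2\cos(D/r)$, the radius is chosen to minimize
$|\lambda_{\min}(Z(r))|$ over $r \in [\max(D)/\pi\,(1+\varepsilon),\,
10\max(D)]$ — a log-spaced grid scan (120 points) with local refinement,
which is robust to the non-unimodality of the objective.  The lower bracket
keeps $D/r \le \pi$ so no arccos wrap-around can occur; if the optimum lands
on a bracket boundary a warning reports that no sphere in range fits.  At
$r^\*$ the top-$p$ non-negative eigenpairs give coordinates, each projected
exactly onto the radius-$r^\*$ sphere.  Planted unit-sphere distances recover
$r^\* = 1$ within 1%, and the search is scale-equivariant.

**Geometry selection** embeds at every (model, dimension) combination
(default dimensions 3–10: the paper-style analysis starts at 3 because the
network is non-planar; the upper end is our choice, exposed as
configuration), tabulates stresses, and flags the argmin.  A failed
combination becomes a missing row with a warning, never an abort.  On exact
planted configurations ($n = 60$, intrinsic dimension 2) the true geometry
wins in at least 19 of 20 seeds for each of the three geometries — this is
an acceptance criterion, rerun verbatim in the test suite.

# Radial clustering and the driver cluster

In a hyperbolic embedding the radial coordinate $r_i = \lVert x_i\rVert$
encodes popularity (expected degree decays with radius), so nodes are
clustered on this single coordinate.

*Exact 1-D k-means.*  The number of clusters comes from the elbow of the
WSS curve (maximum perpendicular distance to the chord from $k=1$ to
$k=k_{\max}$, default $k_{\max} = 25$; a collinear curve falls back to the
smallest $k$ explaining essentially all variance).  For the k-means fit
itself we depart from the stochastic Lloyd/k-means++ recipe: in one
dimension the optimum is attained on a contiguous partition of the sorted
values and is computable exactly by dynamic programming (the
`Ckmeans.1d.dp` idea).  Measured on 300 random instances, k-means++ with 25
restarts misses that optimum in about 2.7% of cases, which is incompatible
with the requirement that the 1-D solver match a DP oracle exactly;
exactness won.  The stochastic k-means++/Lloyd solver (25 restarts, seeded)
remains in use for the multi-dimensional spectral baseline, where no exact
algorithm exists.  A consequence worth stating: repeated-run stability
distributions of the 1-D fit are constant by construction; they are still
emitted so the output format matches repeated-run protocols, and the
BSS/WSS $\ge 100$ stability criterion is evaluated on them unchanged.

*Driver cluster.*  The driver conjecture is that the cluster whose internal
stiffness distribution best recapitulates the whole network's carries the
dynamics.  "Best reflects the density plot" is quantified as the minimum
two-sample Kolmogorov–Smirnov statistic between a cluster's intra-pair
rescaled stiffness values and the global off-diagonal distribution, over
clusters with at least `min_pairs = 30` intra pairs (KS validity);
empirical distributions are exported for the visual density-plot
confirmation.  Intra-cluster "edges" are **all node pairs** of the dense
stiffness matrix — matching the all-pairs count $\binom{2080}{2} =
2{,}162{,}160$ reported for the reference network — with graph-edge
restricted counts available separately.

*Spectral baseline.*  Symmetric normalized Laplacian
$L = I - D^{-1/2} W D^{-1/2}$; the eigengap heuristic picks $k$ maximizing
$\lambda_{k+1}-\lambda_k$ (eigenvalues ascending); clustering runs on the
row-normalized first $k$ eigenvectors, and WSS/BSS are defined in that
spectral-coordinate space (the reference analysis does not disclose its
script's internals, so the space is documented explicitly).  Zero-degree
nodes are removed with a warning before the Laplacian.

# Synthetic data: what it emulates and what it does not

The generator plants configurations with *known* geometry: uniform points in
a box (flat), normalized Gaussians on a radius-$r$ sphere (positive
curvature), and, for the hyperbolic disk, angle uniform with native radius
density $\propto \sinh r$ on $[0,R]$ (quasi-uniform in hyperbolic area,
default $R = 3$), converted to ball coordinates.  Exact model-space
distances — optionally perturbed by multiplicative log-normal noise —
validate the embeddings; threshold graphs on those points validate the full
pipeline.  Two regimes matter:

- *Pipeline end-to-end runs* use disk radius $R = 3$ with threshold 2
  ($n = 120$–150), which yields connected, moderately dense graphs whose
  stiffness dissimilarities are reliably recognized as hyperbolic.
- *Heavy-tailed degree checks* use the canonical hyperbolic random-graph
  regime, threshold $=$ disk radius ($R = 5$, $n = 300$), where the
  power-law degree tail is an established property.  At small thresholds
  degrees are quasi-homogeneous and no heavy tail exists to detect.

What a green synthetic test does **not** establish: that a real
Pathway-Commons-derived network is hyperbolic, that the rescaled-stiffness
mixture of real data has two modes, or anything about biological function of
driver genes.  The reference CML network (2,080 nodes, 3,464 edges after
multi-edge collapse, radial range $[0.7036, 0.7709]$, 12 radial clusters,
eigengap 2) lives behind an external download and is deliberately outside
the test suite; the pipeline accepts its SIF export directly.

# Numerical choices and degenerate inputs

- Nullspace threshold $10^{-10}\sigma_{\max}$; kernel-certificate residual
  bound $10^{-10}\max(m)$.
- Dissimilarity validation enforces symmetry at $10^{-8}$ and a zero
  diagonal; hyperbolic inputs must be strictly inside the unit ball,
  spherical points on the sphere within $10^{-6} r$.
- All arccos/acosh arguments are clamped to their domains; the hyperbolic
  gradient guards $1/\sqrt{g^2-1}$ with an $10^{-18}$ floor at coincident
  points.
- Isolated nodes: warned about, mass 0, excluded before the spring model
  (and removed before the normalized Laplacian).
- Degenerate rescale (all off-diagonal stiffness equal, e.g. any
  vertex-transitive graph): all rescaled values set to 1 with a warning, so
  the dissimilarity is the constant 0.5.
- Determinism: a single master seed fans out to per-stage seeds via a fixed
  integer recurrence (always below $2^{31}$); rerunning a pipeline with the
  same configuration reproduces every CSV byte for byte, and the manifest
  records an md5 for each output.
- Dense all-pairs matrices cap the pipeline at 5,000 nodes with a hard
  error (the reference network's 2,080 fits comfortably).

# Known limitations

- With the node-space reading of the weighted incidence, the equilibrium
  stiffness of a connected graph is rank one and a function of degrees
  only; the source analysis does not disclose its computation in enough
  detail to confirm the same form, and the pipeline is agnostic to $K$'s
  rank.  The Open-Question status is recorded rather than resolved.
- Hyperbolic sampling is 2-D only; higher-dimensional hyperbolic *sampling*
  is out of scope (embedding in any dimension is supported).
- The stress refinement is a local method; with curvature $\kappa \ne 1$ or
  adversarial inputs it can settle in local minima (the equivariance
  property in the test suite quantifies this honestly rather than hiding
  it).
- No GO/pathway enrichment and no interpretation of driver genes: outputs
  stop at identifiers and statistics.
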