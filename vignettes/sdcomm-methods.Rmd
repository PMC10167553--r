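---
title: "Latent-space random graphs on D-spheres: model, distance laws, and community diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space random graphs on D-spheres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(sdcomm)
```

## The model

`sdcomm` implements the S^D latent-space random-graph model, the spherical
formulation of hyperbolic random graphs in D+1 dimensions. Each of N nodes
carries two latent variables:

* an angular position on a D-sphere of radius $\hat R$ — the *similarity*
  coordinates; and
* a *latent degree* $\kappa \ge \kappa_0$ — the popularity variable,
  proportional to the node's expected degree once the model is calibrated.

A pair at angular (great-circle) distance $\theta$ with latent degrees
$\kappa, \kappa'$ is connected independently with probability

$$p(\theta, \eta) = \frac{1}{1 + (\theta/\eta)^\beta},
\qquad
\eta = \frac{(\hat\mu\,\kappa\kappa')^{1/D}}{\hat R},$$

so $\eta$ is a pair-specific angular threshold: below it connection is
likely, and in the $\beta \to \infty$ limit the probability becomes a hard
step at $\eta$. The inverse temperature $\beta$ controls how sharply
similarity binds connectivity; the package enforces the cold regime
$\beta/D > 1$, where graphs are sparse, clustered and heterogeneous. Because
the natural comparison across dimensions holds $\beta/D$ fixed, the user
interface takes `beta_over_d` (default 3.5) rather than $\beta$ itself.

The equivalent hyperboloid formulation (radial coordinate
$r$, Fermi–Dirac connection probability in hyperbolic distance) is provided
for cross-validation through `hyperbolic_distance()` and
`kappa_radial_map()`; the change of variables
$\kappa = \kappa_0 e^{\zeta D (R - r)/2}$ preserves connection
probabilities wherever the large-radius distance approximation
$d_h \approx r + r' + (2/\zeta)\log(\theta/2)$ holds. The spherical form is
the production path throughout. Matching the two probability expressions
through this change of variables fixes the hyperboloid's threshold
parameter to $\mu = 2R + (2/\zeta)\log[(\hat\mu\kappa_0^2)^{1/D}/(2\hat R)]$,
which the test suite verifies at the probability level (agreement to
$10^{-3}$ for far-out nodes at small angles).

### Conventions and defaults

| parameter | meaning | default |
|---|---|---|
| `D` | similarity dimension | — |
| `N` | nodes | — |
| `beta_over_d` | $\beta/D$, sharpness of the connection probability | 3.5 |
| `gamma` | Pareto exponent of latent degrees | 2.5 |
| `mean_kappa` | mean latent degree $\bar\kappa$ | 10 |
| `mean_degree` | target mean degree (drives $\hat\mu$ calibration) | 4 |
| `sigma` | angular dispersion of soft communities, in $[0,1]$ | — |

$\hat R$ follows the unit-density convention: the sphere's D-volume equals
N, under which $\eta \sim (\kappa\kappa'/N)^{1/D}$. Latent degrees are
Pareto with lower bound $\kappa_0 = \bar\kappa(\gamma-2)/(\gamma-1)$ so
that their mean is $\bar\kappa$; $\gamma \le 2$ is refused (infinite mean).
Node ids are 0-based in all files. One master seed drives everything;
sub-streams for centroids, coordinates, degree targets, calibration and
edges are derived deterministically from it by hashing the master seed with
a stream label, so any component can be reproduced in isolation.

### Calibrating the connection scale

The model guarantees that $\hat\mu$ *can be tuned* so that expected
degrees are proportional to latent degrees, but no convenient closed form
exists for general D, so `calibrate_mu_hat()` inverts the analytic mean
degree numerically: the expected mean degree of a uniformly random pair is
$(N-1) f_A(1)$ with

$$f_A(1) = \int_{\eta_0}^\infty f_Y(\eta)\, f_{A|Y}(1|\eta)\, d\eta,$$

and this quantity is monotone in $\hat\mu$, so bisection on
$\log\hat\mu$ converges reliably (relative tolerance $10^{-3}$). The test
suite closes the loop by Monte Carlo: sampled graphs at the calibrated
$\hat\mu$ hit the target mean degree within 5% over 10 seeds, and binned
$E[k|\kappa]/\kappa$ is flat within 10%.

## Distance laws

For uniform points on S^D the pairwise angular distance has density
$f_X(\theta) = \sin^{D-1}\theta / I_D$ with
$I_D = \sqrt{\pi}\,\Gamma(D/2)/\Gamma((D+1)/2)$: constant on the circle,
unimodal at $\pi/2$ for $D \ge 2$, and concentrating there as D grows.
Conditioning on a connected pair with threshold $\eta$ gives

$$f_{X|Y,A}(\theta|\eta,1) =
\frac{\sin^{D-1}\theta}{Z(\eta)\,[1 + (\theta/\eta)^\beta]},$$

the product of the geometric factor and the connection probability. On the
circle this is proportional to the connection probability itself — strictly
decreasing, maximum at $\theta = 0$ — while for $D > 1$ the mode detaches
from zero and moves right with dimension. Setting the log-derivative to
zero gives the stationarity condition

$$(D-1)\left[(\eta/\theta^*)^\beta + 1\right] =
\beta\,\frac{\tan\theta^*}{\theta^*},$$

solved by bracketed root finding on $(0, \pi/2)$ (the right-hand side
diverges at $\pi/2$, so the root is always interior; a dense grid scan of
the density is the fallback if bracketing fails). When
$\tan\theta^* \approx \theta^*$ this collapses to the closed form
$\theta^* \approx \eta\,(\beta/(D-1) - 1)^{-1/\beta}$, valid for $D > 1$
and $\beta > D - 1$; the package verifies it against the exact root within
2% at small thresholds.

### Marginalizing the degrees

With Pareto latent degrees, $\log(\kappa/\kappa_0)$ is exponential with
rate $\gamma - 1$, so for an i.i.d. pair
$t = \log(\eta/\eta_0) = \frac{1}{D}\left[\log(\kappa/\kappa_0) +
\log(\kappa'/\kappa_0)\right]$ is Gamma-distributed with shape 2 and rate
$D(\gamma-1)$, where $\eta_0 = (\hat\mu\kappa_0^2)^{1/D}/\hat R$ is the
smallest attainable threshold. Equivalently

$$f_Y(\eta) = \frac{D^2(\gamma-1)^2}{\eta}
\log\!\frac{\eta}{\eta_0}\left(\frac{\eta_0}{\eta}\right)^{D(\gamma-1)},
\qquad \eta \ge \eta_0.$$

This closed form was derived in-package and is gated on a Monte-Carlo
oracle (KS distance to $10^5$ transformed Pareto pairs below 0.01) rather
than trusted on its own. All $\eta$-integrals — $f_A(1)$ and the
degree-marginalized edge-distance law

$$f_{X|A}(\theta|1) = \frac{f_X(\theta)}{f_A(1)}
\int_{\eta_0}^\infty \frac{f_Y(\eta)}{1 + (\theta/\eta)^\beta}\, d\eta$$

— are computed in the Gamma variable $t$ with the heavy Pareto tail
truncated at the $1 - 10^{-8}$ quantile (`qgamma` makes the truncation
point exact). Quadrature uses adaptive integration at relative tolerance
$10^{-8}$/absolute $10^{-10}$; integrands with a boundary layer at the
threshold are split on a geometric sequence of cut points
$\eta, 3\eta, 9\eta, \dots$ because the tail decays like
$(\theta/\eta)^{-\beta}$ over many decades.

```{r laws, eval = FALSE}
curves <- tabulate_analytic_curves("marginal", dimensions = 1:3,
                                   grid = 256, N = 1000)
plot_analytic_curves(curves)
```

## Neighborhoods on spheres

Dividing the sphere into n regions of equal volume defines a
characteristic angular radius $\phi_n$
(`characteristic_angle()`), and the number of nearest neighbors as the
ratio of the tripled ball to the unit ball,
$n_{nn} = \mathrm{Vol}(B(3\phi_n))/\mathrm{Vol}(B(\phi_n)) - 1$. On the
circle this is exactly 2 for every $n > 2$; on S² the cap-area formula
gives the closed form $8 - 24/n + 16/n^2$ (derived via the triple-angle
identity and verified against quadrature to machine precision); in general
the count rises to $3^D - 1$, the Euclidean grid-neighbor count, as
$n \to \infty$. When $3\phi_n \ge \pi$ the tripled ball is the whole
sphere and the count saturates at its ceiling $n - 1$.

## Soft communities

`community_layout()` places n centroids homogeneously (equally spaced
angles on the circle, a Fibonacci lattice on the sphere, greedy max–min
selection from $10^4$ uniform candidates for $D \ge 3$) and splits N
nodes as evenly as possible. Cluster members are drawn from a von
Mises–Fisher distribution around their centroid with concentration

$$c(\sigma) = D\left(\frac{1}{\sigma^2} - 1\right),$$

chosen so that $\sigma = 0$ is an exact point mass, $\sigma = 1$ is exactly
uniform on the sphere, and the angular spread at small $\sigma$ is
approximately $\sigma$ itself, comparable across dimensions like a normal
standard deviation. The vMF draws use the Wood (1994) rejection scheme for
the cosine component. Labels are then *reassigned* to the nearest centroid,
so communities partition the sphere (no overlap) but need not coincide with
the generating cluster once dispersion is high. The exact cluster-sampling
recipe behind the published figures is not available to us; any
rotationally symmetric family satisfying the two endpoints is admissible
under this package's contract, and the endpoint properties (point mass,
uniformity, monotone spread in $\sigma$) are what the tests pin down.

### Degree calibration on clustered coordinates

Clustered coordinates break the uniform-case proportionality between
$\kappa$ and expected degree, so latent degrees are optimized directly
against per-node Pareto targets $k_i$ (drawn independently of the
community labels, reflecting the assumption that similarity structure and
degrees are decoupled): iterate
$\kappa_i \leftarrow |\kappa_i + u_i\,(k_i - E[k_i])|$, $u_i \sim U(0,1)$,
until $\max_i |E[k_i] - k_i| < 0.2$ (absolute tolerance). Three numerical
choices matter in practice, all documented because the naive iteration
fails on exactly the configurations of interest:

1. **Sequential updates with incremental bookkeeping.** Expected degrees
   are refreshed after every single-node move (only row/column i of the
   probability matrix changes), not once per sweep; synchronous sweeps
   oscillate indefinitely on clustered coordinates.
2. **Relative step cap.** $E[k_i]$ scales like $\kappa_i^{\beta/D}$
   through saturating pairwise probabilities, so a full step can overshoot
   by orders of magnitude; steps are capped at $\kappa_i/2$.
3. **Root-solve refinement.** Nodes still off target after 50 stochastic
   sweeps are finished by an exact one-dimensional root solve of their own
   (monotone) expected-degree equation, Gauss–Seidel style. Only nodes
   outside half the tolerance are touched, so settled regions stop
   perturbing each other.

These choices leave the fixed points and the 0.2 tolerance untouched; they
only make the iteration reach them. A Pareto target can still exceed the
structural ceiling $N - 1$ (probability $\approx 5\times10^{-5}$ per node
at the default parameters) — such cells cannot converge, are reported with
their residual vector, and the sweep machinery records them as failed
rather than aborting.

## Block-matrix diagnostics

A graph (probabilistic by default — the matrix $p_{ij}$ itself — or a
realized adjacency for user-supplied edge lists) is coarse-grained into the
community block matrix

$$B_{uv} = \frac{1}{m}\sum_{i,j} p_{ij}\,
\delta(c_i, u)\,\delta(c_j, v)\,(1 - \delta(c_i, c_j)),$$

with $m = \sum_{i<j} p_{ij} (1 - \delta(c_i, c_j))$ the expected number of
inter-community edges. The diagonal is zero and the upper triangle sums to
one, so $B$ is the probability mass function of a uniformly drawn
inter-community edge over community pairs. Three diagnostics summarize it:

* **Stable rank** $\mathrm{srank}(B) = \sum_i s_i^2 / s_1^2$ over singular
  values, reported as the ratio $r(B) = \mathrm{srank}(B)/n \in [0, 1]$ —
  near 1 when mass could be permuted onto a diagonal band (the circle's
  signature), lower under richer mixing. The null matrix maps to 0 by
  convention.
* **Shannon entropy** $S(B) = -\sum_{u<v} B_{uv}\log_2 B_{uv}$ bits, with
  $0\log 0 = 0$: zero when one pair carries all mass, maximal
  ($\log_2 \binom{n}{2}$) when mass is uniform.
* **Community degrees**: binarize at the one-expected-edge threshold
  ($C_{uv} = 1$ iff $B_{uv} > 1/m$, strict, so exactly one expected edge
  maps to 0; other thresholds can be passed), then count row sums and
  their average — the community-level analogue of the nearest-neighbor
  count.

Singular values are computed on the dense matrix; block orders here are at
most a few hundred, so no sparse path is needed.

## The dispersion sweep

`run_sigma_sweep()` drives the headline experiment: for every cell of
(dimension, community count, dispersion, replicate) it generates a
clustered network at $\beta/D = 3.5$, Pareto expected degrees with mean
4.0 and $\gamma = 2.5$, calibrates latent degrees, and records the three
block diagnostics in a long-format tibble — a pure function of
(config, master seed). The acceptance suite runs the full grid
$(n, \sigma) \in \{5,15,25\}\times\{0.2,0.5,0.8\}$, $D \in \{1,2\}$,
N = 1000, 10 replicate seeds (about 1.5 minutes on one CPU) and checks
the circle-vs-sphere contrast: the stable-rank ratio ordering
$r_{D=1} > r_{D=2}$, entropy rising with dispersion on the sphere while
near-stagnant on the circle, and higher average community degree on the
sphere at high dispersion.

```{r sweep, eval = FALSE}
cfg <- sweep_config(dimensions = c(1, 2), community_counts = c(5, 15, 25),
                    sigma_grid = c(0.2, 0.5, 0.8), replicates = 10)
res <- run_sigma_sweep(cfg, seed = 42)
plot_sweep(res, "entropy_bits")
```

In our runs the sphere-side statements and the community-degree contrast
hold throughout, and the stable-rank ordering holds across most of the
grid; the two places it does not are informative about the model rather
than bugs. At (n = 5, $\sigma$ = 0.2) — few, highly concentrated
communities, where the extra dimension has the least room to act — the
two dimensions' stable-rank ratios are within about 0.01 of each other
and their ordering flips; at (n = 15, $\sigma$ = 0.8) the gap is within
one standard error of the 10-seed mean. Likewise the circle's entropy is
not literally constant: it drifts upward by roughly 0.2 bits across the
dispersion grid (on a 6-bit scale) because high-latent-degree hubs carry
genuinely long-range inter-community probability mass — the same mechanism
that lifts the circle's average community degree above the geometric
bound of 2. These behaviors are reported as measured; the corresponding
assertions in the acceptance suite are stated at their original strictness
and fail where reality disagrees.

## What the generator does and does not emulate

The synthetic data reproduce the mechanisms the model is about: heavy-tailed
popularity, similarity-driven connection probabilities, soft angular
communities of similar sizes, and the dimension-dependence of both. They do
not emulate features of real networked data such as degree-degree
correlations beyond those induced by geometry, overlapping or hierarchical
communities, weighted or multilayer structure, or noise in community
labels. Passing tests therefore validate the model's internal consistency
and its analytic laws, not the claim that any particular real network is
well described by a given dimension.

## Known limitations

* The hot regime $\beta \le D$ is out of scope and refused at
  construction.
* Embedding (inference of coordinates from an observed graph) is not
  provided; community labels are inputs to the block diagnostics, never
  detected.
* The probability matrix is dense ($O(N^2)$ memory): practical to a few
  thousand nodes, which covers the study conditions.
* For $D \ge 3$ centroid placement is a greedy heuristic; it guarantees
  determinism and good spread, not optimal packing.
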