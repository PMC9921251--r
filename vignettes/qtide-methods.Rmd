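---
title: "Estimation and acquisition design for the diffusion tensor distribution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimation and acquisition design for the diffusion tensor distribution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtide)
```

## The signal model

Tensor-valued diffusion encoding probes a voxel with a full symmetric
b-tensor $B$ rather than a single direction.  When the voxel content is
modeled as a distribution $P(D)$ over microscopic Gaussian diffusion
tensors, the measured signal is the mixture average
$S(B) = S_0 \langle e^{-B:D} \rangle$, and its two-term cumulant expansion
is

$$ S(B) \approx S_0 \exp\!\big(-B:\langle D\rangle +
\tfrac12\, B^{\otimes 2}:\mathbb{C}\big), $$

where $\langle D \rangle$ is the mean diffusion tensor and
$\mathbb{C} = \langle D^{\otimes 2}\rangle - \langle D\rangle^{\otimes 2}$
its fourth-order covariance.  Taking logs makes the model linear in the 28
parameters $\theta = (\log S_0, \mathbf d, \mathbf c)$, with $\mathbf d$
the 6 independent components of $\langle D\rangle$ and $\mathbf c$ the 21
independent components of $\mathbb{C}$; `forward_signal()` evaluates
$\exp(A\theta)$ with the $N \times 28$ model matrix built by
`design_matrix()` from an acquisition scheme (directions, b-values in
ms/μm², b-tensor anisotropies $b_\Delta \in [-0.5, 1]$).

Units are fixed package-wide: $b$ in ms/μm² and diffusivities in μm²/ms,
so $b\,D$ is dimensionless.  The exponent of the forward model is clipped
at $\pm 700$; that bound is orders of magnitude outside any physical
regime and exists purely to prevent floating-point overflow on absurd
iterates.

### Voigt conventions

Second-order symmetric tensors are carried as 6-vectors
$(xx, yy, zz, \sqrt2\,yz, \sqrt2\,xz, \sqrt2\,xy)$ and fourth-order
tensors with major and minor symmetry as symmetric $6\times6$ matrices in
the same basis, flattened to 21-vectors (diagonal first, then the
$\sqrt2$-scaled upper triangle).  The normalization is *defined* by the
requirement that vector inner products equal full tensor contractions:
$\langle v_6(T), v_6(U)\rangle = T:U$ and
$\langle v_{21}(T^{\otimes 2}), v_{21}(U^{\otimes 2})\rangle = (T:U)^2$.
Every downstream formula (model matrix, constraints, metrics) is therefore
basis-independent and checkable against brute-force index contraction,
which is exactly how the test suite pins it.  Component ordering beyond
this property is a documented internal convention; only inner products
matter.

### Scalar metrics

With $V_{bulk} = \langle \mathbf d^{\otimes 2}, E_{bulk}\rangle = MD^2$,
$V_{shear} = \langle \mathbf d^{\otimes 2}, E_{shear}\rangle$ and the
second moments $\langle D^{\otimes 2}\rangle = \mathbf d^{\otimes 2} +
\mathbf c$, `scalar_metrics()` derives

* mean diffusivity $MD$, fractional anisotropy
  $FA = \sqrt{3/2}\sqrt{V_{shear}/(V_{bulk}+V_{shear})}$,
* microscopic FA ($\mu FA$, the same form on the second moments, hence
  insensitive to orientation dispersion),
* isotropic kurtosis $MK_i = 3\,\langle\mathbf c, E_{bulk}\rangle/MD^2$
  (variance of isotropic diffusivities),
* anisotropic kurtosis $MK_a = \tfrac{6}{5}\,\langle\mathbf c,
  E_{shear}\rangle/MD^2$, with $MK = MK_i + MK_a$ exactly,
* the order parameter $OP = \sqrt{V_{shear}/V_{shear,2}}$ and the
  coherence index $C_c = FA^2/\mu FA^2$.

The kurtosis denominators use the *mean-tensor* bulk variance $MD^2$;
this choice reproduces the classical isotropic-kurtosis definition (for a
mixture of isotropic pools, $MK_i = 3\,\mathrm{Var}(D_{iso})/MD^2$) and
preserves the additive decomposition $MK = MK_i + MK_a$.  These
closed forms are pinned by limit tests: a coherent axisymmetric tensor
gives $FA = \mu FA$ (the textbook eigenvalue formula) and $OP = 1$; an
isotropically dispersed population gives $FA \to 0$ with $\mu FA$
unchanged; a two-pool isotropic mixture gives $\mu FA = 0$ and
$MK_i = 3\,\mathrm{Var}(D_{iso})/MD^2$.

Degenerate inputs are handled explicitly rather than left to floating
point: non-positive $MD$ (possible in noisy fits) returns `NaN` metrics
with a warning, and shear variances below $10^{-12} MD^2$ are treated as
exactly zero so that isotropic voxels report $\mu FA = OP = 0$ instead of
amplified rounding noise (square roots are not Lipschitz at zero).

## Estimators

The log-linearized model $\log s = A\theta + \varepsilon$ has
heteroscedastic errors: $\mathrm{var}(\varepsilon_i) \propto 1/\tilde
s_i^2$ with $\tilde s$ the noise-free signal.  The package implements

* `lls_fit()` — ordinary least squares on $\log s$ (QR factorization, not
  normal equations);
* `wlls_fit()` — inverse-variance weighting with the *observed* signal,
  squared residual weights $s_i^2$;
* `iwlls_fit()` — iteration 1 is WLLS, afterwards the weights are rebuilt
  from the model prediction $\hat s = \exp(A\hat\theta)$.  Two weighted
  solves are the default: further reweighting changes the weights only
  marginally.  Observed-signal weights correlate with the noise and bias
  the fit (most visibly as an overestimated $MK_i$); predicted-signal
  weights remove most of that bias while keeping the precision advantage
  of weighting — the Monte-Carlo harness reproduces this ordering;
* `nls_fit()` — unweighted nonlinear least squares on the raw signal,
  damped Gauss–Newton/Levenberg–Marquardt with the analytic Jacobian
  $\mathrm{diag}(e^{A\theta})A$, LLS-initialized, converged at gradient
  norm $<10^{-8}$ or step $<10^{-10}$ (at most 200 iterations).

Non-positive samples (possible under Gaussian noise) are dropped from
log-domain fits with a warning rather than clamped, which would create
infinite weights.

### Constrained estimation

Physicality of $(\mathbf d, \mathbf c)$ is enforced by stacked linear
inequalities (`build_constraints()`), discretized over an antipodally
symmetric direction set (60 electrostatic directions plus the scheme's
own axes by default):

1. variant 1: non-negative directional diffusivity *and* non-negative
   directional covariance;
2. variant 2: directional diffusivity plus monotonic signal decay at
   $b_{max}$, $\langle (uu')^{\otimes2}, \mathbf c\rangle - b_{max}
   \langle uu', \mathbf d\rangle \le 0$ (covariance positivity is then
   implied along each direction and is not stacked twice);
3. variant 3: variant 2 plus $MK_i \ge 0$ and $MK_a \ge 0$, imposed on
   the numerators $\langle E_{bulk},\mathbf c\rangle$ and $\langle
   E_{shear},\mathbf c\rangle$ (valid because $MD^2 > 0$ for any
   physical fit).

The monotonic-decay rows are imposed at $b_{max}$ only: the signal model
is log-quadratic in $b$ along any fixed direction and shape, so a
non-positive derivative at both $b = 0$ (guaranteed by diffusivity
positivity) and $b = b_{max}$ controls the whole interval of interest.
A finite direction set keeps each weighted solve a convex quadratic
program, the standard discretization; an exact semidefinite formulation
is out of scope.  Residual violations between grid directions can be
audited post hoc via the eigenvalues of the fitted tensors.

`ciwlls_fit()` keeps the IWLLS iteration structure but replaces each
weighted solve with the QP $\min \|W^{1/2}(\log s - A\theta)\|^2$ s.t.
$G\theta \le h$; when the unconstrained iterate is already feasible it is
returned unchanged.  The QP solver is a primal active-set method (working
set grown by most-violated row, shrunk on negative multipliers, all
linear algebra through one Cholesky of $A'WA$); degenerate working sets
divert to an accelerated projected-gradient method on the dual, which is
globally convergent for convex problems.  The tests cross-check the
solver against an independent, deliberately naive projected-gradient
oracle and against feasibility certificates.  Infeasible or failed solves
fall back to the unconstrained iterate and are flagged
(`infeasible-fallback`), never silently accepted.

## Precision bounds and experimental design

For homoscedastic Gaussian noise the Fisher information of the model is
$I(\theta) = \sigma^{-2} A' \mathrm{diag}(s)^2 A$, and the delta-method
bound for derived metrics is $J = M' I^{-1} M$ with $M$ the matrix of
metric gradients (central differences, relative step $10^{-5}$, floor
$10^{-8}$; the metric formulas are smooth rational/root functions so this
is accurate far beyond the bound's own uncertainty).  Two design criteria
are exposed:

* `criterion_f2()` — D-optimality on the raw parameters, computed as
  $-\log\det I$ via Cholesky.  The log transform is a monotone surrogate
  for the determinant of the covariance bound that cannot underflow in 28
  dimensions; reported values are comparable only under this transform.
* `criterion_f3()` — weighted trace of the metric CRLB over
  $\{MD, \mu FA, MK_i, MK_a\}$ with weights $1/m_j^2$, so every metric
  gains equally in *relative* precision.  A vanishing metric would give an
  infinite weight; such weights are capped at $10^6$ and logged.

Both are averaged over a prior voxel population (`population_objective()`),
each prior randomly reoriented once (seeded quaternion rotations) so the
design cannot tailor itself to one fiber orientation.

`optimize_scheme()` fixes the directions to an electrostatic-repulsion
set — the same choice keeps the scheme nearly rotation invariant and
halves the search space — and minimizes the population criterion over the
$2N$ vector of b-values and shapes with derivative-free coordinate
polling: steps start at 0.4 of each box width and halve on stalled sweeps
down to $10^{-3}$, within the box $0.1 < b < 2$ ms/μm²,
$-0.5 \le b_\Delta \le 1$.  Any monotone derivative-free descent method
satisfies the design contract (optimized objective below both the random
initialization and the naive reference scheme); the default evaluation
budget of 6000 reaches that contract with a wide margin at $N = 120$,
$M = 50$ priors in under a minute.  Metric gradients and weights do not
depend on the scheme, so they are precomputed once per prior set.

`cluster_scheme()` converts the free-form optimum into an acquisition
that a scanner can run shell-wise: b-tensor shapes are k-means-clustered
(at most 4 clusters) and centres within 0.15 of the canonical shapes
$\{-0.5, 0, 1\}$ snap onto them; b-values take the smallest number of
shells ($\le 4$) whose within-cluster sum of squares is below 1% of
total; per-shell directions are regenerated by electrostatic repulsion.
The k-means-plus-snap rule is a documented choice — the grouping
criterion is otherwise underdetermined — and the clustered scheme's
objective stays within a few percent of the raw optimum.  In practice the
optimizer itself concentrates the shapes near linear, planar and
spherical encoding, which is why snapping is near-lossless.

Three reference schemes ship with the package (`packaged_scheme()`):
a naive 120-sample scheme `q1` spreading planar/spherical/linear
encoding over four b-values, and the two precision-optimized layouts
`q2hat` (D-optimal for raw parameters; linear + planar, most samples at
the outer shell) and `q3hat` (metric-optimized; keeps spherical encoding
at the outer shell and loads the intermediate shell).  Their per-shell
sample counts are fixed; the within-shell directions are generated by
electrostatic repulsion with fixed seeds, so the schemes are exactly
reproducible.  `precision_gain()` compares schemes as ratios of inverse
variance bounds, $p_{gain} = \mathrm{CRLB}_{ref}/\mathrm{CRLB}_i$
(variance-based as printed in the source material, not standard-deviation
based); the noise level cancels in the ratio.

## The synthetic voxel generator

Design and simulation need a prior population of plausible voxels.  The
generator (`synth_population()`) emulates brain-like tissue as discrete
mixtures of Gaussian micro-tensors:

* an anisotropic pool of `K = 50` axisymmetric micro-tensors whose axes
  follow a Watson distribution (density $\propto e^{\kappa\cos^2\psi}$,
  rejection-sampled) about a random mean axis, with axial and radial
  diffusivities drawn per micro-tensor so every voxel carries
  isotropic-diffusivity heterogeneity as well as orientation dispersion;
* an isotropic pool with gamma-distributed diffusivity.

The default classes are WM-like (axial 1.8–2.6, radial 0.2–0.7 μm²/ms,
$\kappa$ log-uniform 4–64, isotropic fraction up to 0.15), GM-like
(axial 0.9–1.5, radial 0.4–0.9, $\kappa$ 0.5–4, isotropic fraction
0.1–0.3) and CSF-like (free water at 3 μm²/ms), mixed 0.5/0.4/0.1; the
ranges were set once to land the derived metrics in the windows reported
for healthy human brain (WM $\mu FA \approx 0.7$–0.8, GM $MD \approx 1$,
$MD$ globally within 0.5–3.2 μm²/ms) and are asserted by the tests.
With `K = 50` the diffusivity and orientation metrics (MD, FA, μFA, OP)
are stable to about 1% across independent draws of the anisotropic pool;
the pool's kurtosis contributions fluctuate more in relative terms but
are small in absolute value.  Design optimization uses the WM+GM mixture
only
(`default_recipes(csf = FALSE)`): the design criteria weight metrics by
$1/m_j^2$ and pure-fluid voxels with vanishing anisotropy metrics are not
meaningful design targets.

What the generator does *not* emulate: the package's population is
parametric and noise-free, whereas in-vivo priors are themselves
estimates from noisy data.  Passing population-level comparisons on the
synthetic population therefore demonstrates the mechanisms (bias
directions, precision orderings, design improvements), not the specific
percentage values attainable on scanner data; absolute magnitudes of
population medians differ from any in-vivo cohort.  Spatially correlated
noise, multi-coil statistics beyond Rician, exchange and time-dependent
diffusion are likewise out of scope.

## The Monte-Carlo harness

`monte_carlo_evaluate()` generates the noise-free signal per voxel, adds
Rician noise $s' = \sqrt{(s+\epsilon_1)^2 + \epsilon_2^2}$ (SNR defined
as $S_0/\sigma$ at $b = 0$), fits every realization with each requested
estimator — all estimators see identical realizations — and reports
per-voxel bias, standard deviation and RMSE of the scalar metrics against
the ground truth, with population medians on top.  The per-voxel variance
uses the $1/n$ divisor so $RMSE^2 = bias^2 + sd^2$ holds exactly.
Relative statistics are reported only where the truth is bounded away
from zero ($|m| > 10^{-9}$); orientation metrics are 0/0-undefined on
isotropic voxels.  Runs are bit-for-bit reproducible given the seed, and
fit failures abort the run when they exceed 5% of realizations.

Problem sizes used by the validation suite were chosen to make the
qualitative surfaces stable at desk scale: 200 voxels × 400 realizations
at SNR 25 for the estimator comparison (per-voxel bias standard error
about $sd/20$, small against the WLLS bias signal), 200 voxels × 200
realizations at SNR 200 for consistency, $M = 50$ rotated priors for
design optimization, and 2000 Gaussian realizations at SNR 50 for the
efficiency check of NLS against the CRLB (variance estimate standard
error ≈ 3%, comfortably inside the 15% acceptance band).

## Known limitations

* The cumulant model truncates at the second cumulant: it is exact only
  at low $b$.  The tests assert the $O(b^3)$ error scaling, a ≤5% of
  $S_0$ mismatch against exact mixture signals at $b \le 1$ for every
  tissue voxel, and the same bound at $b \le 2$ for the *median* voxel —
  voxels with extreme isotropic heterogeneity (large $MK_i$) genuinely
  exceed it at $b = 2$, which is the known validity boundary of the
  truncation.  The model also carries no intra-compartment (microscopic)
  kurtosis, which the underlying multi-Gaussian picture assumes away.
* Positivity constraints are enforced on a direction grid, not as exact
  semidefinite constraints; violations between grid points are possible
  though rare with ≥60 directions.
* The estimator-comparison orderings that involve ratio-type orientation
  metrics ($\mu FA$, $OP$) are sensitive to the anisotropy composition of
  the population: on this synthetic population WLLS's shrinkage makes its
  RMSE for those two metrics competitive even though its bias is largest,
  while the kurtosis metrics reproduce the expected WLLS-worst ordering.
  The bias orderings and the constrained-estimator precision orderings
  are stable across the populations we generate.
* The design engine optimizes b-values and shapes only; directions are
  fixed by construction, and hardware constraints (TE/TR, gradient
  slewing, waveform design) are outside the model.
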