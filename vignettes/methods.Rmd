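---
title: "Methods: pairwise landscape models of genetic distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise landscape models of genetic distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscape)
```

`pairscape` compares six ways of summarising the landscape between pairs
of sampling sites — gradient surface metrics (GSM), two patch-mosaic
metric schemes (PMM3, PMM2), least-cost-path (LCP) and commute-distance
(CD) resistance models, and an isolation-by-distance null (IBD) — as
fixed-effect predictors of pairwise genetic distance in a
maximum-likelihood population-effects (MLPE) mixed model. This vignette
is the package's account of the statistical machinery, the synthetic
data that exercises it, and the design decisions taken where the
methodology was genuinely open.

## The MLPE model

Pairwise distances are not independent: all distances involving site
*k* share whatever makes *k* peculiar. The MLPE model absorbs this with
one random effect per site, entering every pair that contains it:

$$y_{ij} = \mathbf{x}_{ij}^\top\beta + u_i + u_j + \varepsilon_{ij},
\qquad u_k \sim N(0, \sigma_u^2), \quad
\varepsilon_{ij} \sim N(0, \sigma_e^2).$$

With $Z$ the pairs-by-sites incidence matrix (two unit entries per
row), the marginal covariance is $\sigma_e^2 (I + \theta Z Z^\top)$
with $\theta = \sigma_u^2/\sigma_e^2$. `fit_mlpe()` eigendecomposes
$ZZ^\top$ once per site set, so that for any fixed $\theta$ the
covariance is diagonal in the eigenbasis, $\beta$ has a closed
generalised-least-squares form and $\sigma_e^2$ a closed profile
estimate; a one-dimensional search over $\log\theta$ (plus an explicit
comparison with the $\theta = 0$ boundary, where the model collapses to
ordinary least squares) completes the fit. The test suite verifies the
profiled likelihood against a direct dense multivariate-normal
computation and checks that the optimum beats random parameter
perturbations; a multi-membership structure of this form cannot be
expressed directly in the usual mixed-model formula interfaces, which
is why the likelihood is implemented here rather than delegated.

Conventions fixed by this package:

* **AIC** uses the maximum-likelihood log-likelihood with
  $k = \#\beta + 2$ (two variance parameters). Model selection is done
  under ML; variance components for reporting (R², $\rho$) come from a
  REML refit, the usual convention.
* **R²** (marginal/conditional) uses the variance-component
  decomposition with a per-observation random-effect variance of
  $2\sigma_u^2$, because every row of $Z$ carries two unit loadings:
  marginal $= \sigma_f^2/(\sigma_f^2 + 2\sigma_u^2 + \sigma_e^2)$,
  conditional $= (\sigma_f^2 + 2\sigma_u^2)/(\cdot)$, with $\sigma_f^2$
  the variance of the fitted fixed-effect predictor.
* **$\rho$** is reported as the model-implied correlation between two
  pairwise observations sharing exactly one site,
  $\rho = \sigma_u^2/(2\sigma_u^2+\sigma_e^2) \in [0, 0.5)$. This is a
  deliberate design decision: "pairwise dependency" is exactly what
  this quantity measures, and the simulation tests confirm it matches
  the empirical shared-site correlation of simulated responses. An
  empirical rank-correlation variant would estimate the same target
  less directly; no equivalence with any particular external estimator
  is claimed.
* **Box–Cox**: the response is shifted strictly positive
  ($\varepsilon = 10^{-6}$) and $\lambda$ is chosen on the grid
  $[-2, 2]$ in steps of $0.01$ by profile likelihood — a grid rather
  than an analytic optimum for reproducibility and boundary safety.
* **VIF pruning** drops the single worst predictor (ties: the later
  column) while any VIF $\ge 10$; infinite VIFs (perfect collinearity)
  sort first. Pruning happens before standardisation; dredging then
  enumerates all subsets of the survivors, discarding subsets
  containing any pair with $|r| \ge 0.6$, and includes the
  intercept-only model so the null has a seat in every candidate set.
* **Residual spatial autocorrelation** is checked with Moran's *I* on
  site-averaged residuals of the full model, inverse-distance weights
  (zero diagonal, row-standardised), and a one-sided permutation
  p-value (999 permutations by default). The statistic matches the
  `ape` implementation; calibration (empirical size 2–9% at
  $\alpha = 0.05$) is part of the test suite.

## Landscape summaries

**Ellipse clipping.** Each pair's "local landscape" is an ellipse
centred midway between the sites, major axis on the inter-site bearing.
The default is deterministic: $a = (d/2)(1 + 0.1)$ and $b = a \cdot
\text{axis ratio}$ (default 0.5). A correlated-random-walk envelope
(`crw_ellipse()`) is the stochastic alternative: wrapped-normal turning
angles (concentration `kappa`), lognormal step lengths, and envelope
axes set to coverage quantiles of successful-walk positions. All CRW
distribution parameters are exposed rather than fixed, because the
envelope construction admits no canonical parameter values; the
deterministic ellipse is the pipeline default precisely so results do
not hinge on them. Cells are kept by a cell-centre test (the common GIS
convention), and thin crops are padded with masked cells to a 16×16
minimum window so the spectral metrics below stay defined for close
pairs.

**Gradient surface metrics.** Heights are referenced to the valid-cell
mean. Spatial-domain metrics (`Sa`, `S10`, `Ssk`, `Sdr`, `Sbi`) use
valid cells only; spectral metrics fill masked cells with the mean
(adding no power), apply a Hann taper against clip-boundary leakage
(toggleable), and use the 2-D FFT amplitude spectrum with DC excluded.
Two numerical choices deserve note:

* The angular spectrum for `Std`/`Stdi` and the radial spectrum for
  `Srwi` use the **mean** amplitude per 1° bin / unit annulus, not the
  sum. Lattice frequencies populate bins unevenly (whole frequency
  lines fall in the axis bins; annulus population grows with radius),
  so sums would show structure even for isotropic noise; means keep
  both spectra flat under isotropy, which is the property the indices
  are meant to measure. Ties in `Std` resolve to the smallest angle.
* `Sfd` is fixed to the convention $S_{fd} = 4 + s/2$, where $s$ is the
  least-squares slope of log radially-averaged power against log radius
  over rings $[2, \text{Nyquist}/2]$. Under this convention a
  fractional-Brownian surface with roughness exponent $H$ has
  $S_{fd} = 3 - H$, which is the identity the acceptance tests anchor
  to (recovery within ±0.15 at 256×256).

`Sbi` is $S_q / z_{05}$ with $z_{05}$ the mean-referenced height at
bearing fraction 0.05 of the Abbott curve (linear interpolation); for
Gaussian heights this approaches $1/1.6449 \approx 0.608$, another
anchored test.

**Patch-mosaic metrics.** Patches are connected components per class,
8-adjacency by default (the common landscape-metrics default;
4-adjacency by flag). Core cells are same-class cells whose full
8-neighbourhood is same-class and valid, eroded to `edge_depth` cells
(default 1). Edge length counts rook faces between differing valid
classes; faces against the landscape boundary or masked cells are
excluded by default (toggleable), the usual convention for clipped
landscapes. `split` and `mesh` satisfy `mesh * split = A` identically —
an algebraic identity the tests exercise on random mosaics. `iji` is
undefined below three classes and therefore omitted under PMM2; in
batch use a degenerate clip yields `NA` rather than aborting the run,
and the pipeline drops predictors undefined on any pair with a warning.

**Resistance models.** Conductance is $C = 1 + H^3$, which compresses
contrast among good habitat and spreads it among poor habitat while
keeping $C \ge 1$ everywhere. The raster graph joins 8-neighbours
(default) with edge conductance equal to the mean of the two cell
conductances divided by the centre-to-centre distance in cell units
($\sqrt 2$ for diagonals — the standard geo-correction). "Least-cost"
is operationalised as minimal cumulative resistance $\sum 1/g_e$ (the
most conductive corridor); a literal maximum of summed conductances
would be unbounded by detours. Commute distance is
$\mathrm{Vol}(G)\,R_{\mathrm{eff}}(i,j)$, computed from the dense
Laplacian pseudoinverse up to 3000 nodes and from one sparse Cholesky
factorisation with per-pair solves above that (identical to within
1e-6; both routes are tested against a Markov-chain expected-commute
oracle). LCP and CD are computed on the full raster by default — the
resistance surface is a global object — with per-ellipse computation
available by clipping first.

## The synthetic scene

The generator stands in for the study inputs a field campaign would
provide, with defaults chosen once to emulate that setting:

* **Suitability surface**: spectral-synthesis fractional-Brownian field
  with PSD exponent $2H + 2$, min–max rescaled to [0, 1]. Default
  $H = 0.6$ on a 128×128 grid of 30 m cells — moderately smooth
  autocorrelated habitat at the cell size of the land-cover products
  this emulates. Desk-scale grids keep the full test suite under a
  minute for this module; the fractal-dimension recovery tests use
  256×256, where periodogram regression is stable.
* **Land cover**: the surface thresholded at (1/3, 2/3) into
  non-habitat / complementary habitat / forest habitat — three classes
  with roughly equal prior mass, so most pairwise clips contain all
  three.
* **Sites**: rejection-sampled on valid cells with a minimum separation
  (default 10 cells), mirroring a design of well-separated sampling
  locations; 17 sites give the canonical 136-pair universe.
* **Genotypes**: a forward-in-time finite-island model, 10 loci,
  founder alleles at sizes {10, 12, 14, 16, 18} (a dinucleotide
  ladder), stepwise ±1 mutation at rate 5e-4, 100 generations, 25
  diploid individuals per site by default. Each offspring draws its
  source population with weight $e^{-d/\text{scale}}$ (self weight 1
  since $d = 0$), so one parameter moves the system continuously from
  panmixia (scale → ∞, differentiation near zero) to isolation
  (scale → 0, drift-dominated divergence), with
  isolation-by-distance structure in between. The default scale is a
  quarter of the raster diagonal. Forward simulation was chosen over
  coalescent machinery deliberately: it gives direct control of
  migration-by-distance at desk-scale runtime.
* **Responses with planted structure**: `simulate_mlpe_response()`
  draws from the MLPE generative model itself, which is what the
  parameter- and selection-recovery harnesses need.

What the generator does **not** emulate: linkage, null alleles and
genotyping error, temporally varying landscapes, anisotropic dispersal,
and real land-cover geometry (roads, fields, riparian strips have
structure a thresholded fBm field lacks). Passing tests therefore show
that the estimators recover what they target under the stated
generative model — not that any particular real landscape satisfies
that model.

## Degenerate inputs and numerical edges

Constant surfaces make `Ssk`, the texture metrics and `Sbi` undefined;
`gsm_vector()` converts these to `NA` with a warning so batch tables
stay rectangular. Negative per-locus among-population variance
components in `R_ST` are floored at zero by default (flag to disable)
so distances stay non-negative for the Box–Cox step; the final ratio is
clamped to [0, 1]. A site pair with no co-typed locus yields `NA` with
a warning. Distance-matrix symmetry is enforced to 1e-9 on input.
`theta` at the likelihood boundary 0 is accepted (the model degrades to
OLS, which the tests verify coefficient-for-coefficient). Sampling
variability of the boundary estimate is worth knowing: with a true
$\sigma_u^2 = 0$ at 136 pairs, roughly half the replicates estimate
exactly zero and most of the rest fall within a few percent of
$\sigma_e^2$, but outliers occur — the tests assert the distribution,
not a point.

## Scope and limitations

Pair order is fixed by site order throughout; all tables join on it.
Coordinate systems are assumed projected metres with square cells; no
reprojection is attempted, and raster I/O is the plain-text ESRI ASCII
grid. The dredge enumerates at most $2^{12}$ subsets; larger predictor
sets should be pruned first. Akaike weights are normalised over
whatever candidate set is supplied — per-approach dredges report
weights over the full dredged set, and the cross-approach table over
the six best models; the choice is explicit in the output rather than
hidden, since the two normalisations answer different questions.
Problem sizes used by the test-suite harnesses: 136-pair designs for
parameter recovery (200 replicates), a 10-site/45-pair scene for
selection recovery (50 response draws), 100–200 replicates for the
calibration checks — sizes at which the recovery properties are sharp
while the whole suite stays desk-scale.
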