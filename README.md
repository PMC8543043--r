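# InSpect: integrated spectral component estimation and mapping for quantitative MRI

Quantitative MRI spectroscopy models the signal of each voxel as coming
from a *spectrum* of MR properties — for combined diffusion–relaxometry
imaging, a two-dimensional T2\*–ADC correlation spectrum F(ω) linked to
the measured signal by a Fredholm integral with the separable
exponential kernel

    S(b, TE) = ∬ F(ADC, T2*) · exp(−TE/T2*) · exp(−b·ADC) dADC dT2*

Discretised on a grid this is `S = K F`, a severely ill-posed inverse
Laplace transform. The standard approach inverts it voxel by voxel with
Tikhonov-regularised non-negative least squares,

    F̂ = argmin_{F ≥ 0} ‖K F − S‖² + α‖F‖²,

and then integrates each voxel's spectrum over manually chosen spectral
regions of interest (sROIs) to obtain scalar maps. At realistic SNR the
per-voxel inversions — and hence the maps — are noisy.

**InSpect** replaces the voxelwise inversion with a joint, data-driven
model: a small number M of *canonical spectral components* F₁…F_M shared
by the whole image, mixed in each voxel n with non-negative weights
z_n on the probability simplex,

    S_n ~ N( K Σ_m z_nm F_m , σ_n² I ).

Components and weight maps are estimated together by block-coordinate
ascent on the Gaussian log-likelihood: components by non-negative least
squares on the stacked per-voxel residuals, weights by exact
simplex-constrained least squares per voxel, iterated until the weight
maps converge. The number of components is chosen by BIC,
`k·log(n) − 2·logL` with `k = (M−1)N + M·P`. Because information is
shared across all N voxels, the method tolerates far lower SNR than
voxelwise inversion and needs no manual sROIs.

The package implements, in this order of interest:

* `runInspect()` — the joint estimation algorithm (plus `selectM()` /
  `computeBIC()` for model selection);
* `fitVoxelSpectrum()`, `mapVoxelwise()`, `selectAlphaLcurve()`,
  `integrateSROI()` — the voxelwise baseline it is compared against;
* `makePhantom()`, `simulatePhantomData()`, `perturbComponents()` — a
  synthetic diffusion–relaxometry phantom (four canonical T2\*–ADC
  components, a 330-encoding placental-style protocol, Rician noise)
  providing ground truth for every claim the package makes;
* NIfTI/TSV/JSON I/O (`readImageData()`, `writeFitOutputs()`) and a CLI
  (`inst/cli/inspect.R`) with `simulate`, `fit-voxelwise`,
  `fit-inspect` and `select-m` subcommands.

## Worked example

```r
library(InSpect)

grid <- makeDefaultGrid(16)                      # 16 x 16 log grid, ADC x T2*
ph   <- makePhantom(shape = c(30, 30), grid = grid)
img  <- simulatePhantomData(ph, snr = 200, seed = 1)

sel <- selectM(img, grid, MRange = 2:6)
sel$scores[, c("M", "k", "bic")]
#>   M    k        bic
#> 1 2 1412  5780903.8
#> 2 3 2568   785228.1
#> 3 4 3724 -2145100.2
#> 4 5 4880 -2133816.3
#> 5 6 6036 -2120875.3
sel$bestM
#> [1] 4

img400 <- simulatePhantomData(ph, snr = 400, seed = 1)
fit <- runInspect(img400, grid, M = 4)
fit
#> InspectFit: M = 4, 900 voxels
#>   converged after 5 iteration(s); final max |dz| = 7.85e-04
#>   log-likelihood: 1.30043e+06
componentModes(canonicalComponents(fit))
#>             ADC     T2star
#> F1 0.0030170882 0.06134766
#> F2 0.0001764404 0.04890162
#> F3 0.0515914820 0.07696136
#> F4 0.1606105258 0.07696136
```

The BIC table bottoms out at M = 4, the true number of simulated
components. At SNR 400 the fitted component modes coincide with the
grid points nearest the four ground-truth (T2\*, ADC) locations —
(0.05 s, 2·10⁻⁴), (0.06 s, 3·10⁻³), (0.07 s, 5·10⁻²) and
(0.08 s, 0.2 mm²/s) — and `spectralWeights(fit)` holds the
corresponding 900 × 4 weight maps, within a mean absolute error of
0.003–0.009 per component of the ground truth after matching
components by mode.

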