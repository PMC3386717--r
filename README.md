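# nsctfuse

Pixel-level fusion of pairs of registered single-channel images — two focal
settings of one scene, a CT and an MR slice, a visible and an infrared
band — into one image that keeps the informative content of both. The
package is aimed at people evaluating fusion rules: it ships the full
pipeline, a seven-statistic quality suite, four comparison fusers, and
seeded synthetic scene generators, so every experiment is reproducible
from a seed.

## Method

Sources `A` and `B` are decomposed with a shift-invariant non-subsampled
contourlet transform (NSCT): an à trous pyramid (B3-spline kernel
`[1,4,6,4,1]/16`, sampling matrix `2I`) splits scales, and smooth
frequency-domain fan windows forming an exact partition of unity split
each band-pass scale into `2^l` directional bands. All bands are
image-sized and synthesis is a plain sum, so reconstruction is exact.

The two low-pass bands, vectorized as the columns of a nonnegative
`n x 2` matrix `V`, are fused by a rank-1 **accelerated NMF**: Lee–Seung
scaled-gradient updates whose per-column/per-row step lengths

    alpha = min( p'q / p'A'Ap ,  tau * max{ a : x + a p >= 0 } ),
    q = A'(b - Ax),  p = (x ./ A'Ax) o q,  tau = 0.99

come from the totally nonnegative least-squares line search, with a
fallback to step length 1 whenever a sub-objective would rise (so the
objective trace is non-increasing by construction). The fused low-pass
band is `W * mean(H)`.

Each band-pass directional pair is fused by the **neighborhood
homogeneity measurement**

    NHM(m,n) = 2 * sum_{N(m,n)} |C_A||C_B| / (E_A(m,n) + E_B(m,n))  in [0,1]

over 3x3 windows: where `NHM < T` (default `T = 0.75`) the coefficient
with larger neighborhood energy is selected; where `NHM >= T` the fused
coefficient is `NHM * c_max + (1-NHM) * c_min` by absolute value. The
inverse transform returns the fused image.

The quality suite reports information entropy, standard deviation,
average gradient, PSNR against both sources, the Xydeas–Petrović
`Q^{AB/F}` edge-transfer index, mutual information, and the windowed
spectral-angle average (16/32/64 tiles, per source). Baseline fusers:
PCA weighting, classic Lee–Seung NMF, CDF 9/7 wavelet (max-abs details /
mean approximation), and the contourlet pipeline with conventional rules.

## Worked example

```r
library(nsctfuse)

# a seeded multi-focus pair with known all-in-focus ground truth
pair  <- make_multifocus_pair(scene_spec(seed = 42))
fused <- fuse_images(pair$A, pair$B, fusion_config(seed = 42))

psnr <- function(F, X) 10 * log10(255^2 / mean((F - X)^2))
cat(sprintf("PSNR to truth:  A %.2f dB   B %.2f dB   fused %.2f dB\n",
            psnr(pair$A, pair$G), psnr(pair$B, pair$G), psnr(fused, pair$G)))
#> PSNR to truth:  A 23.65 dB   B 20.98 dB   fused 33.05 dB

fusion_metrics(pair$A, pair$B, fused)[, 1:6]
#> # A tibble: 1 × 6
#>      ie    sd    ag  psnr q_index    mi
#>   <dbl> <dbl> <dbl> <dbl>   <dbl> <dbl>
#> 1  7.60  62.8  11.5  23.2   0.645  7.96
```

The fused image is ~10 dB closer to the all-in-focus truth than either
half-blurred source; the metrics row is one column of the usual
methods-by-metrics comparison table (entropy in bits, SD and AG in
intensity units, PSNR in dB against the two *sources*, Q and MI
dimensionless/bits).

The accelerated factorization against plain Lee–Seung, same
initialization and iteration count:

```r
set.seed(42)
V   <- matrix(runif(100 * 80), 100, 80)
cfg <- anmf_config(max_iter = 100, tol = 0, seed = 42)
rbind(glance(anmf_factorize(V, 10, cfg)),
      glance(lee_seung_factorize(V, 10, cfg)))
#> # A tibble: 2 × 5
#>   method     rank iterations objective_initial objective_final
#>   <chr>     <dbl>      <int>             <dbl>           <dbl>
#> 1 anmf         10        100         19312392.            497.
#> 2 lee-seung    10        100         19312392.            499.
```

`run_benchmark()` scales this up (all fusers x seeded scenes, plus paired
factorization traces), `threshold_sweep()` reproduces the `T`-selection
experiment, and `inst/cli/nsctfuse.R` exposes `fuse`, `metrics`,
`benchmark`, `generate` and `decompose` subcommands for shell use:

```sh
Rscript inst/cli/nsctfuse.R generate -o fixtures --regime multifocus --seed 4
Rscript inst/cli/nsctfuse.R fuse -a fixtures/A.png -b fixtures/B.png -o fused.png --seed 4
Rscript inst/cli/nsctfuse.R metrics -a fixtures/A.png -b fixtures/B.png -f fused.png
```

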