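# iltnmr

Relaxation-time distributions from time-domain NMR signals by regularized
non-negative inversion — the analysis usually called the inverse Laplace
transform (ILT) in the NMR community.

Time-domain / low-field NMR instruments characterize biological and
agro-industrial materials (seeds, foods, oils, meat, plant tissue) through
relaxation decays rather than frequency spectra. A CPMG echo train, an
inversion-recovery or a saturation-recovery curve from a heterogeneous
sample is a superposition of exponentials,

    c(t_n) = Σ_i g(T_i) · K(t_n, T_i) + ε(t_n)

with kernel `K(t,T) = exp(−t/T)` (CPMG), `1 − 2·exp(−t/T)` (IR) or
`1 − exp(−t/T)` (SR). The positions and areas of the peaks of the
non-negative distribution `g(T)` reflect water/oil compartments, pore
structure and molecular mobility. Recovering `g` is an ill-posed Fredholm
inversion; **iltnmr** solves it by

1. SVD compression of the kernel system (numerical rank only),
2. Tikhonov penalty `α‖Lg‖²` (curvature operator by default; identity
   available), and
3. non-negative least squares (Lawson–Hanson) on the stacked system,

minimizing `‖Kg − c‖² + α‖Lg‖²` subject to `g ≥ 0`. The regularization
parameter α is the user-facing resolution/stability knob (typical values
0.01, 0.1, 1, 10); there is deliberately no automatic α selection.

The package also provides the standard preprocessing steps (start-point
removal, kernel-matched baseline offset correction, first-value
normalization), a synthetic-signal generator for validation (log-Gaussian
distributions + Gaussian rms noise), peak detection and ground-truth
comparison metrics, plain-text table I/O, and a CLI for batch processing.

## Worked example

A small synthetic two-component CPMG table ships with the package (two
signals sharing one time axis, the batch layout the reader accepts):

```r
library(iltnmr)

path <- system.file("extdata", "synthetic_cpmg_two_component.txt",
                    package = "iltnmr")
sig  <- read_signal_table(path, timescale = "ms")
grid <- make_t_grid(1, 10000, 200, "ms")   # log-uniform T axis
res  <- run_ilt_batch(sig, "cpmg", grid, alpha = 0.1)
res
#> <ilt_result_set> 2 inversion(s)
#> <ilt_result> CPMG inversion of `wet`: 250 time points -> 200 grid points (milliseconds)
#>   alpha = 0.1 (second_difference operator), rank kept = 31, chi^2 = 0.003559
#>   2 peak(s) at T = 46.6, 357.1 milliseconds
#> <ilt_result> CPMG inversion of `dry`: 250 time points -> 200 grid points (milliseconds)
#>   alpha = 0.1 (second_difference operator), rank kept = 31, chi^2 = 0.00398037
#>   2 peak(s) at T = 42.48, 340.9 milliseconds

find_peaks(res$wet$g, grid)
#> # A tibble: 2 × 6
#>   center height fwhm_log  area idx_lo idx_hi
#>    <dbl>  <dbl>    <dbl> <dbl>  <int>  <int>
#> 1   46.6 0.0682    0.176 0.603      1     93
#> 2  357.  0.0549    0.144 0.397     93    135
```

The `wet` signal was generated as 0.6·exp(−t/45) + 0.4·exp(−t/350) plus
0.4 % noise: the inversion finds two peaks at 46.6 and 357 ms whose areas
(0.60 / 0.40 of the total) recover the component amplitudes. `tidy(res)`
returns the distributions as a tibble, `augment(res)` the fits and
residuals, `glance(res)` one-row diagnostics per signal, and
`autoplot(res)` the relaxogram.

The same pipeline from a shell (the `ilt` subcommand mirrors every
processing parameter; `simulate` writes the two-component validation
signal):

```sh
Rscript inst/cli/nmr-ilt simulate --noise 1 --seed 7 signal.txt
Rscript inst/cli/nmr-ilt ilt --kernel cpmg --alpha 1 --t-start 1 \
  --t-end 10000 --n-points 200 --timescale ms signal.txt out/
```

which logs `signal=… alpha=1 rank_kept=… chi2=…` per column and writes
`distribution.csv`, `fit.csv`, `residuals.csv`, `peaks.csv` and
`run_config.json` into `out/`.

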