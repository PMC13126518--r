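---
title: "Regularized inversion of time-domain NMR relaxation signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized inversion of time-domain NMR relaxation signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iltnmr)
```

## The inverse problem

Time-domain NMR relaxometry measures a signal $c(t_n)$ that, for a
heterogeneous sample, is a superposition of exponential components with a
continuous distribution of relaxation times. Discretized on a grid of $N$
candidate relaxation times $T_i$, the forward model is

$$ c(t_n) \;=\; \sum_{i=1}^{N} g(T_i)\, K(t_n, T_i) \;+\; \epsilon(t_n), $$

with kernel $K$ depending on the pulse sequence:

| sequence | kernel $K(t, T)$ | asymptotes |
|---|---|---|
| CPMG (T2) | $e^{-t/T}$ | $1 \to 0$ |
| inversion recovery (T1) | $1 - 2e^{-t/T}$ | $-1 \to 1$ |
| saturation recovery (T1) | $1 - e^{-t/T}$ | $0 \to 1$ |

Recovering the non-negative amplitude distribution $g(T)$ from the measured
decay — often called the inverse Laplace transform in the NMR community,
although it is really the regularized inversion of a Fredholm integral of
the first kind — is severely ill-posed: the kernel's singular values decay
geometrically, so unregularized least squares amplifies noise into wild,
oscillatory solutions. `run_ilt()` therefore minimizes

$$ \| K g - c \|^2 + \alpha \| L g \|^2 \quad \text{subject to } g \ge 0, $$

by (1) projecting the system onto the numerically non-null singular
subspace of $K$, (2) stacking $\sqrt{\alpha} L$ below the projected design,
and (3) solving the stacked problem with non-negative least squares.

## The relaxation-time grid

`make_t_grid()` places `n_points` values uniformly in $\log_{10} T$ between
`t_start` and `t_end`, both endpoints included. Log-uniform spacing is the
community convention (distributions are plotted on a log axis, and peaks of
physically distinct origin are separated by ratios, not differences); it
also lets positional tolerances be expressed in grid steps. The window must
bracket all expected relaxation times — a window of 0.001 to 10 s covers
most biological samples — and should not be grossly wider than needed,
since far-outlying columns of $K$ are nearly degenerate. 100 or 200 points
are typical; the tests and validation protocols here use 200 points over
1–10000 ms (one step = 0.0201 decades ≈ 4.7 % in $T$).

No unit conversion is ever applied: a `timescale` tag (seconds /
milliseconds / microseconds) travels with signals and grids, inversions
require the tags to agree, and the output $T$ axis inherits the input unit.

## Regularization: $\alpha$ and the operator $L$

$\alpha$ is the single resolution/stability knob, chosen by the user
(typical ladder: 0.01, 0.1, 1, 10). Increasing $\alpha$ broadens peaks and
lowers their maxima while the total spectral area $\sum_i g_i$ is conserved
to within a few percent; decreasing $\alpha$ sharpens peaks but, below the
noise-supported resolution, manufactures spurious ones. No automatic
selection (L-curve, GCV) is attempted: with typical TD-NMR signal-to-noise
ratios the choice genuinely benefits from prior knowledge of the sample,
and an automatic optimum can be misleading. Pick the smallest $\alpha$
that yields a stable, physically sensible distribution.

Two penalty operators are available:

* `second_difference` (default): $L$ is the $(N-2) \times N$ discrete
  curvature operator with rows $(1, -2, 1)$. It penalizes roughness of
  $g$ — the natural reading of a penalty that "smooths the distribution" —
  and is indifferent to where mass sits on the grid.
* `identity`: classical Tikhonov damping of the amplitudes themselves.

The curvature operator is the default for a measured reason. The columns of
a CPMG kernel have norms that grow with $T$ (slow components persist
through more of the record), so a penalty on amplitude magnitude can
explain the same signal energy more cheaply by moving mass toward longer
$T$, where less amplitude is needed. On the noiseless two-component
validation signal below, the identity operator at $\alpha = 1$ displaces
the 500 ms peak by two grid steps (≈ 8 %), while the curvature operator
keeps both recovered centers within one grid step of the generating values
at every $\alpha$ in the ladder. The identity operator remains available
(`reg_operator = "identity"`) for comparison with amplitude-damped
implementations; the $\alpha \to \infty$ shrinkage limit
$\|g\| \to 0$ holds only for it.

At $\alpha = 0$ no rows are stacked and the problem reduces to plain NNLS
on the (compressed) system.

## SVD compression

`svd_compress()` replaces the $n \times N$ system with its projection onto
the singular directions with $\sigma_i \ge$ `rel_tol` $\cdot\,\sigma_\max$
(default `rel_tol` $= 10^{-12}$). At that threshold this is numerical
hygiene, not resolution control: least-squares objectives of the projected
and full systems differ only in directions that are null to machine
precision, and the test suite verifies that compressed and uncompressed
NNLS solutions agree to better than $10^{-6}$ in max-norm. The benefit is
speed — a 15000-echo CPMG record compresses to a design with a few tens of
rows before the (comparatively expensive) active-set iteration starts.
Truncation is *not* exposed as a smoothing device; resolution is
controlled by $\alpha$ alone.

## Non-negative least squares

`solve_nnls()` implements the Lawson–Hanson active-set algorithm with an
iteration cap of $10N$ (an `abort` with diagnostics on non-convergence,
which we have not observed on well-posed stacked systems). At return the
KKT conditions hold to $10^{-8}$: the gradient of the stacked objective is
numerically zero on positive coordinates and non-negative on zero
coordinates. The implementation is verified three ways: exhaustive
enumeration of all active sets on small random systems, the KKT
post-condition on random rectangular systems, and agreement with an
independently implemented solver (`pracma::lsqnonneg`) to $10^{-8}$.

Rank-deficient passive sets (possible at $\alpha = 0$ on compressed
systems) are handled by zeroing the null-direction coefficients of the QR
solve; degenerate zero-step cycles are caught by the iteration cap rather
than special-cased.

## Preprocessing

Three per-column operations run in a fixed order — remove start points,
offset correction, first-value normalization — so that batch runs over
compared signals are always processed identically:

* **Remove start points** discards the first $k$ rows (spectrometer
  dead-time artifacts; a discontinuous first point injects a spurious
  fast component).
* **Offset correction** subtracts a constant baseline estimated where each
  kernel's asymptote is known: the tail mean for CPMG (decays to 0), the
  head mean for saturation recovery (starts at 0), and the midpoint of
  head and tail means for inversion recovery (runs from $-A$ to $+A$).
  The averaging window is `m` points, defaulting to max(5, 2 % of the
  record), bounded by $n/4$ so the anchor stays inside the asymptotic
  region.
* **Normalization** divides each column by its own first value. A column
  starting at (near) zero — the saturation-recovery case — is rejected
  with advice rather than silently producing huge amplitudes.

## The synthetic validation generator

`simulate_two_peak_signal()` builds the canonical validation input: two
log-Gaussian components in $\log_{10} T$ centered at 100 and 500 ms with
equal areas, integrated through the CPMG kernel on an axis of 15000 echoes
0.2 ms apart (0.2–3000 ms), plus optional Gaussian white noise whose
standard deviation is a stated percentage of the maximum (initial)
amplitude — the usual rms-noise convention in TD-NMR. Component widths are
0.08 decades and each component's area is 1; widths, areas, centers and
the time axis are all parameters. The 3000 ms record gives both components
a long fully-decayed baseline (T = 500 ms decays to $e^{-6}$), which the
inversion needs to anchor the slow edge of the window; the defaults were
fixed once, from these physical considerations, before the validation
suites were run.

What the generator emulates: broad heterogeneous relaxation-time
distributions, realistic echo spacing, white detection noise, constant
baseline offsets (via the preprocessing tests). What it does not emulate:
dead-time corruption of early echoes, phase errors, baseline drift,
temperature instability, or $B_1$ miscalibration. Passing the validation
suites therefore demonstrates correctness of the inversion machinery under
the stated noise model, not robustness to every instrumental artifact;
the preprocessing options exist precisely because real records violate
the clean model in these known ways.

Seeds are mandatory arguments wherever randomness enters
(`add_gaussian_noise()`); the global RNG state is never consumed.

## Peak analysis

`find_peaks()` reports local maxima at or above 5 % of the global maximum
(a threshold that, on the validation fixtures, separates genuine
components from regularization ripple), with plateau maxima resolved to
the smallest index — the deterministic tie-break — and extents delimited
by flanking local minima. Width is the full width at half maximum in
decades, interpolated linearly in $\log_{10} T$; the area of a peak is the
plain sum of $g$ over its extent, matching the summation form of the
forward model so that area bookkeeping is exact algebra, not quadrature.
`compare_to_truth()` matches recovered to true peaks greedily by
$|\Delta \log_{10} T|$ and reports relative center deviations (in %),
unmatched recovered peaks (spurious), and the $L_2$ distance between
sum-normalized distributions.

## Validation protocols and problem sizes

The test suite regenerates everything from code; sizes were chosen to
exercise the full pipeline at the fidelity of the validation design:

* noiseless two-component fixture (15000 × 200 system), $\alpha = 1$:
  both recovered centers within one grid step of 100 and 500 ms;
* noise ladder 1 % and 2 % rms, ten seeds each: exactly two peaks in at
  least 9/10 runs and mean absolute center deviation below 5 %; at 5 %
  rms the inversion must complete, and spurious peaks are counted but not
  asserted away — they are the documented failure mode of the method at
  low signal-to-noise;
* $\alpha$ ladder {0.01, 0.1, 1, 10}: per-peak FWHM non-decreasing,
  heights non-increasing, total area varying by less than 5 %;
* solver cross-checks at small scale (exhaustive active sets, KKT,
  independent NNLS, compression equivalence on 200 × 50 CPMG systems).

## Known limitations

* $\alpha$ is manual; no L-curve/GCV/Bayesian selection is provided.
* One-dimensional kernels only; no $T_1$–$T_2$ or diffusion maps.
* The distribution is reported as discrete amplitude per grid point, not
  a density in $\log T$; divide by the (constant) log-step if a density
  is needed.
* Peak centers are grid values; sub-grid interpolation of maxima is not
  attempted, so positional accuracy is inherently one grid step.
* Very wide grids (many decades beyond the data's support) degrade
  conditioning and can produce edge artifacts — choose the window to
  bracket, not dwarf, the expected relaxation times.
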