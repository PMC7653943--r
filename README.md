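# gateopt

Choosing how many gates to use is the central trade-off of gated cardiac PET:
more respiratory or cardiac gates capture more motion (sharper hot spots,
thinner-looking myocardial walls) but leave fewer counts per gate (noisier
images). `gateopt` implements a respiratory–cardiac motion model that turns a
handful of motion measurements from gated images into the optimal number of
respiratory, cardiac and dual gates, together with everything needed to
exercise the method end to end without scanner data: amplitude/phase gate
assignment, a moving heart-phantom simulator, hot-spot and centre-of-mass
motion measurement, and SNR/FWHM image-quality metrics.

## The model

If a cyclic motion of amplitude *c* (mm) is divided into *n* gates, the
motion visible between the extreme gates is

```
f(n) = c (n − 1) / n
```

so `f(1) = 0` and `f(n) → c`. Respiratory and cardiac contributions add, and
dual gating with *r* respiratory and *p* cardiac gates captures

```
g(r, p) = a (r − 1) / r + b (p − 1) / p
```

where *a* and *b* are the respiratory and cardiac amplitudes obtained by
least squares from measured motion. The asymptotic motion estimate is
`m_est = c` (single mode) or `a + b` (dual). Motion is considered compensated
once captured to within half the scanner resolution *s*, which inverts to the
optimal gate counts `r_opt = ⌈2a/s⌉` and `p_opt = ⌈2b/s⌉` (1 gate when an
amplitude does not exceed `s/2`), or to a minimal-product search over a
measured motion grid. Published general linear models
(`n_r = 0.350 m + 1.005`, `n_p = 0.356 m + 0.718`,
`n_total = 1.717 m − 18.730` for `m ≥ 12` mm) map a motion amplitude straight
to a gate count; the exponential respiratory model of Dawood et al.
(`a + b e^{c/r}`) is included for comparison.

## Worked example

Desk-scale reproduction of the reference analysis (a 5.2 mm-resolution
scanner, 14.1 mm respiratory and 3.8 mm cardiac motion):

```r
library(gateopt)

threshold_from_motion(14.1, 3.8)
#> [1] 12.7

optimal_from_grid(phantom_motion_grid(), 12.7)
#> <gate_scheme> 5 respiratory x 4 cardiac = 20 dual gates

optimize_gates(c(12, 10), mode = "general")$scheme
#> <gate_scheme> 5 respiratory x 4 cardiac = 20 dual gates
```

The threshold is the motion gating must remove (each amplitude less half the
resolution, summed); the grid search finds the cheapest scheme capturing it;
and the general linear models give the same 20-gate, (5, 4) answer from the
patient-average 12 mm + 10 mm motion alone.

Fitting the single-mode model to the measured respiratory motions of the
shipped grid's cardiac-ungated row:

```r
fit <- fit_single_model(data.frame(n = 2:6, motion_mm = c(7.5, 10.4, 10.6, 11.1, 12.0)))
fit
#> <motion_model_fit> kind: single_resp
#>   coefficients: c = 14.476
#>   asymptotic motion m_est = 14.476 mm (n = 5 samples)
optimal_gates(fit, scanner_spec())
#> [1] 6
```

The full synthetic pipeline — simulate a 10-minute dual-gated acquisition of
the moving phantom (20 mm respiratory translation, 7 mm cardiac diameter
change, 10^7 counts), measure motion per scheme, fit, optimise and evaluate
image quality:

```r
cfg <- phantom_config(seed = 1)
sc <- scanner_spec(volume_shape = c(64, 64, 47))
study <- run_phantom_study(cfg, sc, duration_s = 600)
study
#> <phantom_study>
#>   fitted amplitudes: a = 19.62 mm respiratory, b = 7.66 mm cardiac
#>   threshold 22.08 mm; optimal scheme (8,3) (model), (5,6) (grid)
#>   SNR(n) = 14.3 -1.50 log10(n) dB (rmse 0.07 dB)
#>   hot-spot FWHM 23.3 -> 7.7 mm (-67%)
```

The fitted amplitudes recover the configured 20 mm / 7 mm truth to well
within the noise, per-scheme SNR decays log-linearly with the total gate
count (the 3 dB loss bound holds at the optimum), and dual gating sharpens
the hot spot substantially relative to the non-gated image.

`tidy()`, `glance()` and `autoplot()` methods are available for fits, and
`exec/gateopt` exposes `optimize`, `simulate` and `pipeline` verbs for shell
use.

## Package layout

- `R/` — motion models and fitting; gate assignment; phantom simulator;
  motion measurement; image quality; pipeline and I/O (CSV motion tables,
  gate-grid CSV, NIfTI volumes, JSON reports).
- `inst/extdata/phantom_motion_grid.csv` — measured phantom motion grid
  (total motion vs respiratory and cardiac gate counts).
- `vignettes/gateopt-methods.Rmd` — the model, its assumptions, simulator
  design and numerical choices.
- `tests/testthat/` — unit, property and acceptance tests.
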