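---
title: "Methods: primary-tail PDD modelling, beam quality and lateral scatter equilibrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primary-tail PDD modelling, beam quality and lateral scatter equilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epdd)
```

## The model and its assumptions

A clinical electron beam deposits a characteristic central-axis percent
depth dose (PDD): a shallow build-up to a maximum within a few cm of the
surface, a steep, nearly linear distal falloff, and a flat low-level
plateau beyond the electron range produced by bremsstrahlung photons.
`epdd` describes a sampled PDD as the product of two dimensionless
factors of depth $x$ (mm):

$$\mathrm{PDD}(x) \propto \underbrace{\frac{x^{0.1}}{N + x^{0.2}}\,
e^{-\mu x}}_{\text{primary}} \times \underbrace{\mathrm{tail}(x)}_{\text{distal}}$$

The primary factor rises from exactly 0 at the surface (the $x^{0.1}$
numerator vanishes) at a rate set by the hardening factor $N$, and is
slowly attenuated by $e^{-\mu x}$ with $\mu$ stored positive in
mm$^{-1}$. The curve is always renormalized so its maximum over the
evaluation grid — not an analytic maximum — equals exactly 100, because
that is the convention of tabulated modelled PDDs.

Two consequences of the surface zero are baked into the design: model
evaluation happens only at the supplied grid points, and the fitter
excludes depth-0 samples by default (`include_surface = FALSE`) rather
than inventing a surface offset. Measured scans report 75–90% at the
surface where the model gives 0; a depth-0 residual would otherwise
dominate any fit.

### Two tail shapes

The package ships two selectable tail forms:

* **printed** (default): $1 - x/(\sqrt{n} + x^2) + t$, with spreading
  factor $n$ and bremsstrahlung offset $t$. This form equals $1+t$ at
  the surface, dips shallowly near $x = n^{1/4}$, and returns to $1+t$
  at depth.
* **sigmoid**: $1 - x^p/(k + x^p) + t$, a logistic-like falloff. It is
  parameterized internally by the half-value depth $x_0 = k^{1/p}$ (mm)
  rather than $k$ itself, because $k \approx x_0^p$ overflows any
  interpretable scale for sharp falloffs ($x_0 = 48$ mm, $p = 9$ gives
  $k \sim 10^{15}$).

Why two? Evaluated at the tabulated per-energy parameters (e.g.
$N = 8.9$, $n = 290$, $\mu = 5\times10^{-4}$ for 12 MeV), the printed
form is monotone *increasing* over all clinical depths:

```{r printed-shape}
round(pdd_model(seq(0, 120, 20),
                primary_tail_params(8.9, 290, 5e-4))$dose_percent, 1)
```

No choice of $N$, $n$, $\mu$, $t$ lets the printed form both build up
over 0–25 mm and collapse from 100% to a few percent over the next
40 mm — the attenuation needed for the falloff ($\mu \approx 0.04$)
destroys the build-up, whose own $\mu$ must be two orders of magnitude
smaller. The best attainable printed-form fit to the bundled 12 MeV
measured scan has an rms percent deviation around 50%. A descending
tail is therefore required for any realistic scan, and a sigmoid is the
natural shape for a falloff with a position and a steepness; the
package keeps the printed form as the default for parameter work (it is
the form the per-energy parameter tables refer to) and uses the sigmoid
form when fitting measured data. Tests of the printed form are
parameter-level (evaluation, derivatives' signs, self-consistent
generate-and-refit); tests against measured scans use the sigmoid form.

## Fitting

`fit_pdd()` minimizes the sum of squared residuals between the
normalized model and the normalized measurement (both scaled to peak at
100) with bounded Levenberg–Marquardt (`minpack.lm`). Free
parameters are $N, n, \mu, t$ (plus the sharpness $p$ for the sigmoid
tail), with bounds $N \in (0, 100]$, $n > 0$, $\mu \in [0, 1]$,
$|t| < 1$. Options that matter:

* **Weighting.** Unweighted residuals (default) reproduce the loss most
  users expect from a least-squares curve fit; `weighting = "relative"`
  divides each residual by the measured dose, so the optimizer
  minimizes exactly the per-point percent deviation that commissioning
  tables report. When the quality metric of interest is relative rms
  deviation, the relative loss is the coherent choice, and it is what
  the package uses when judging fits to measured scans.
* **Multi-start.** A deterministic ladder: the initialization itself,
  then doubling/halving perturbations of $N$ and of $n$. The best
  objective wins, and the returned parameters never score worse than
  the initialization (checked explicitly; `converged` is set `FALSE`
  if the optimizer cannot improve on the start).
* **Initialization.** An explicit `init`, or `energy` (via the
  energy regressions below), or — failing both — a data-driven start:
  R50 of the scan converts to a mean energy ($2.33 \cdot R_{50}$ in
  cm), which seeds the regressions; for the sigmoid tail the half-value
  depth starts at the scan's R50.
* **Convergence.** Objective and parameter tolerances of $10^{-10}$;
  the iteration cap is 1024 (the hard ceiling of the underlying
  implementation). Non-convergence is flagged, never silent.

### What parameter recovery can and cannot show

With noiseless synthetic data, fits recover the generating parameters
essentially exactly (the unit suite asserts $<1\%$ relative, observed
$\sim 10^{-14}$). With realistic scanning noise the picture changes
qualitatively for the *printed* form: after max-100 normalization the
printed-form curve is a featureless slow rise, and $N$, $n$, $\mu$
become near-collinear. At 0.5% Gaussian noise on a 1 mm grid to 80 mm,
even fits initialized at the true parameters — an upper bound on what
any estimator can do — typically land 5–40% away from the truth while
fitting the *curve* to well within the noise. Parameter identifiability
is a property of the model-noise pair, not of the optimizer. The
package's tests therefore distinguish curve recovery (the fitted curve
matches the generating curve within noise — asserted, and what matters
for dosimetry) from parameter recovery at realistic noise (asserted
only in the noiseless limit). The sigmoid tail is much better
identified — its half-value depth is pinned by the falloff position to
a couple of percent at the same noise.

## Beam-quality extraction

All depth metrics interpolate linearly between samples; no spline
smoothing is applied by default because the bundled fixtures are
5 mm-sampled and smoothing would move the crossings.

* `depth_at_dose_level()` walks the distal limb from the curve maximum
  and solves the bracketing segment; R90 and R50 are `level = 90` and
  `50`. Exactness on piecewise-linear curves is tested against an
  independent closed-form segment solver to $10^{-9}$ mm.
* `falloff_line()` is the operational "tangent at the inflection": the
  least-squares line through all samples in the 80–20%-of-maximum
  window on the distal limb, with both endpoints included by
  interpolation. `slope_80_20()` is its slope (%/mm, negative);
  reported angles are `atan(slope)` in radians.
* `practical_range()` intersects that line with the horizontal
  bremsstrahlung background.
* `xray_contamination()` estimates the background as the median over
  the *flat* part of the tail: candidates beyond the distal
  10%-of-maximum crossing, trimmed to the longest terminal run whose
  consecutive slopes stay within 0.1 %/mm. The trimming matters:
  samples at 3–8% of maximum beyond the 10% crossing are usually still
  on the falloff, and a plain median over them biases the plateau high.
* `mean_energy_from_r50()` applies $E_0 = 2.33\,\mathrm{MeV/cm} \cdot
  R_{50}$; `most_probable_energy()` the NACP quadratic
  $0.22 + 1.98 R_p + 0.0025 R_p^2$ (Rp in cm).

`beam_quality()` assembles all of these, reporting `NA` for any metric
whose extraction fails on the given curve (e.g. R50 on a scan that
never descends through 50%), never a silent zero. It exposes both
`r_max_mm` (maximum *reading* depth) and `d_max_mm` (maximum *dose*
depth) as fields, but populates both with the argmax of the supplied
curve: separating them requires the ionization-to-dose conversion chain
applied to the same scan, and the conversion tables behind published
r_max/d_max pairs are not available to reproduce them.

## Dose physics

The per-energy regressions default to the published coefficients
($n = 31.667 E_0 - 88$, $N = 0.9975 E_0 - 2.8535$,
$\ln\mu = -0.1355 E_0 - 6.0986$). Two caveats are deliberate:

* The $n$ and $\ln\mu$ coefficients are exactly reproduced by ordinary
  least squares on the bundled per-energy parameter table against
  nominal energies; the published $N$ coefficients are *not* (OLS gives
  $\approx 1.003 E_0 - 2.92$). The published values are kept as
  defaults; `refit_energy_regressions()` recomputes all three from any
  table.
* The sign convention is $\mu > 0$ applied as $e^{-\mu x}$; the
  occasionally-seen "$\ln(-\mu)$" notation is read as $\ln\mu$, the
  only reading consistent with the tabulated $\ln\mu$ column.

`stopping_power()` implements the empirical ratio
$(-0.042 \ln N + 1.072)\, e^{(-n \cdot 5\times10^{-5} + 0.0381)\,x}$.
The depth unit defaults to **cm**: with mm the 12 MeV ratio would reach
$\sim 3.2$ at 50 mm depth, far outside the physically possible range of
water/air stopping-power ratios, while with cm it stays in the
plausible 0.98–1.10 band. A `depth_unit = "mm"` flag forces the literal
mm reading for anyone who wants the formula as typeset. The exponent
coefficient $-n \cdot 5\times10^{-5} + 0.0381$ changes sign at
$n = 762$, so the ratio grows with depth for all tabulated beams
($n \le 470$) — the unit tests assert the sign flip explicitly.

`convert_reading_dose()` multiplies (reading→dose) or divides
(dose→reading) by the stopping power at each depth and renormalizes.
The direction argument has **no default**: the source material states
the conversion in both directions in different places, so the user must
choose consciously. The round trip is the identity to $10^{-9}$.

`slope_mu_relation()` evaluates the published
$\tan^{-1}(\mathrm{slope}) = -6.6729 \ln\mu - 16.623$ but warns on
every call: at $\mu = 5\times10^{-4}$ it returns 34.10 where the
directly measured $\mathrm{atan}(\mathrm{slope})$ is $-1.35473$ rad,
under any unit or sign convention we tried — the constants appear
misprinted. `refit_slope_mu()` re-estimates a usable relation from a
slope table instead. No correctness claim is attached to the printed
formula anywhere in the package.

## Lateral scatter equilibrium

`lse_min_side()` evaluates
$S_{eq} = (n - N)^{0.288} / (E_0/n)^{0.0195}$ and declares the result
**cm**. The expression is dimensionless as printed; the cm reading is
the only one consistent with the tabulated values, which are exactly
10× the formula's output. The comparator `lse_sqrt_rule()` implements
$1.58\sqrt{E_0}$ cm: the rule is sometimes typeset without the square
root, but every tabulated comparator value matches the square-root form
to 0.01 mm (e.g. $E_0 = 5.41 \Rightarrow 36.75$ mm), so the root is
restored as a typographic correction. The mean energy (not the nominal
energy) enters both formulas — that is the only reading that reproduces
the tabulated rows.

`check_lse()` judges a cutout: a field side exactly equal to $S_{eq}$
counts as adequate (equilibrium is *reached* at that size), and an
inadequate verdict carries an explicit warning string that PDD and
output become field-size dependent below $S_{eq}$. Output-factor
correction for sub-equilibrium fields is out of scope.

## Synthetic scans

`synth_scan()` emulates a water-phantom scan: the normalized model on a
regular grid, floored at a flat bremsstrahlung level beyond the depth
where the model first drops below it, plus additive i.i.d. Gaussian
noise, deterministic for a fixed seed. Defaults are a 1 mm grid from 0
to 80 mm and 0.5% noise — typical scanning resolution and
reproducibility for commissioning-grade measurements. What it does
*not* emulate: depth-correlated noise from scanning direction and
dwell, detector volume averaging over the steep gradient, the
effective-point-of-measurement shift of plane-parallel chambers (a
measurement-time correction, out of software scope), and beam output
drift. Passing tests on synthetic scans therefore demonstrate the
correctness of the algorithms under the stated noise model, not
robustness to every artefact of real scan data.

## Numerical choices

* Normalization reference is the grid maximum; all-zero raw curves
  (e.g. a surface-only grid) raise a normalization error.
* CSV doses are written at 2 decimals with decimal-true round-half-even
  (83.335 → 83.34 even though the nearest double sits fractionally
  below the half); depths are written at full precision.
* Curves must have strictly increasing depths; duplicate depths are
  parse errors naming the row, not silently averaged.
* Optimizer: tolerances $10^{-10}$, iteration cap 1024, deterministic
  multi-start order; ties between equally good fits are resolved by
  that fixed order.
* Fixture-facing tests use the bundled 5 mm tables as-is; synthetic
  property tests use 1 mm grids to 80–120 mm (a few hundred points),
  100 random tuples for model-assembly checks and 20 seeded draws for
  recovery experiments — sizes chosen so the whole suite exercises
  every property in a couple of minutes.

## Known limitations

* The printed tail form cannot descend through a realistic distal
  falloff; fits to measured scans must use the sigmoid form.
* The published modelled-PDD columns are not bit-reproducible from the
  published per-energy parameters (the tail grouping and $t$ are
  under-determined in the source); the package treats them as
  fit-quality references only.
* Printed-form parameter values are not statistically identifiable
  from single noisy scans at realistic noise (see fitting section);
  report curves, not parameters, unless scans are averaged.
* The bundled tables contain internal inconsistencies at sub-3% tail
  doses (deviation cells that do not match their own modelled/standard
  pairs, and one scan whose 5 mm-grid R50 sits 3.5 mm deep of the
  finer-scan value); they are shipped verbatim, never corrected.
* No 2-D/3-D dose, beam profiles, pencil-beam or Monte Carlo transport,
  film-dosimetry workflow, or output-factor corrections.
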