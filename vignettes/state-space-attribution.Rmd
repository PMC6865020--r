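---
title: "Ecohydrological state-space change attribution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecohydrological state-space change attribution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrostate)
```

## The state space

On climatological timescales the land-surface water and energy
balances read `P = E + Ro` and `N = E + H`, with all fluxes in water
equivalents (m yr⁻¹): precipitation `P`, net radiation `N`,
evapotranspiration `E`, runoff `Ro`, sensible heat `H`. The package
works in the state space of the two excess ratios

\[
U = \frac{H}{N} = 1 - \frac{E}{N}, \qquad
W = \frac{Ro}{P} = 1 - \frac{E}{P},
\]

the fractions of the energy and water supplies *not* consumed by
evapotranspiration. Physically meaningful states occupy the unit
square; because `1 − U = E/N` and `1 − W = E/P`, the dryness index
satisfies the identity

\[
D = \frac{N}{P} = \frac{1 - W}{1 - U},
\]

so lines of constant `D` are straight rays ending at `(1, 1)` whose
slope magnitude in a `U`-over-`W` plot is the inverse aridity `1/D`.
The `D = 1` ray is the 45° diagonal and separates energy-limited
(`D < 1`) from water-limited (`D > 1`) surfaces; the biome ladder
(tundra `D < 0.3`, forest to 1, steppe/savanna to 2, semidesert to 3,
desert beyond) rides on the same index. `dryness()` returns `Inf`
for the dry limit `U = 1, W < 1` rather than erroring, and all
classification intervals are closed on the left (so `D = 1` is
steppe/savanna and water-limited) — the boundaries are conventions
that had to be fixed once; nothing downstream is sensitive to them
because continuous data hit them with probability zero.

The empirical runoff closure `Ro = P\,e^{-N/P}` (the Schreiber
relation, the simplest of the Budyko-family curves) maps to the
balanced-state curve

\[
U = 1 + \frac{1 - W}{\ln W},
\]

implemented with its removable limits `U(0) = 1`, `U(1) = 0` filled
in by continuity so that curve plotting and on-curve consistency
checks can touch the endpoints. On this curve `W = e^{-D}`, which the
test-suite uses as an exact oracle: states generated from the closure
must satisfy the curve equation to ≤ 1e−12 and return their `D`
through the state-space identity to ≤ 1e−10 relative.

Out-of-range ratios (`E > N` or `E > P` in imperfect inputs) are
*flagged invalid, never clipped*: clipping would silently pile mass
onto the `U = 0` / `W = 0` edges and distort every density
diagnostic downstream.

## Change, significance, attribution

Annual states are averaged over two periods (defaults 1982–1998 and
1999–2015) and compared per pixel. Three choices here were genuinely
open and are fixed as follows:

- **Variability reference.** `std_U`, `std_W` are *population*
  standard deviations (divide by `n`) of the annual values pooled
  across the whole record — one spread about the full-record mean,
  not per-period spreads. The `n` vs `n − 1` choice is irrelevant at
  34 years but must be pinned down for reproducibility.
- **Strictness.** A pixel is significant iff `|ΔU| > std_U` *or*
  `|ΔW| > std_W` with strict inequality, so constant pixels
  (`Δ = 0`, `std = 0`) can never flood the mask.
- **Period dryness** is recomputed from the period-mean state, not
  averaged over annual `D` (the two differ whenever the state moves;
  a counterexample is in the tests).

Attribution rests on the two canonical directions of the space: a
partitioning change at fixed forcing (`dE ≠ 0`) displaces a state by
`(dW, dU) = (-dE/P, -dE/N)` — both components share a sign, the
*positive diagonal* — while a forcing change at fixed `E` moves it
along the *negative diagonal* (aridity axis). The displacement is
projected onto an orthonormal axis pair:

- `mode = "diagonal"` (default): fixed ±45° axes,
  `c_int = (dU + dW)/\sqrt 2`, `c_ext = (dU - dW)/\sqrt 2`;
- `mode = "local_D"`: internal axis along the constant-`D` ray
  through the period-1 state toward `(1, 1)`, external axis its
  perpendicular oriented toward drying.

The description of the attribution coordinates admits both readings
("the `D = 1` line" vs "the initial slope at the origin point"), so
both are implemented and the Pythagoras identity
`c_int² + c_ext² = dU² + dW²` holds in each; they coincide exactly
on the `D = 1` line. The diagonal mode is the default because the
quadrant semantics (pink/yellow/light-blue/dark-blue) are themselves
defined by the fixed diagonals. Note that the internal direction is
exactly diagonal only where `N = P` (`D = 1`); elsewhere a pure-`dE`
displacement has `|dW/dU| = N/P ≠ 1`, which is why the local mode
exists for sensitivity analysis.

Axis-aligned displacements get a deterministic rule: `dW = 0` is
purely external (quadrant by `sign(dU)`), `dU = 0` purely internal
(quadrant by `sign(dW)`); an exactly zero displacement goes to its
own `no_change` bin so no quadrant is inflated, and `|c_int| =
|c_ext|` is reported as a dominance *tie* rather than broken
arbitrarily.

## Urban detection and greenness split

Cities are spatially contiguous nighttime-brightness pixels with
digital number `DN ≥ 12` (the standard overglow-suppressing
threshold for 6-bit stable-lights composites). "Contiguous" defaults
to 8-connectivity — the conservative, merging reading — with
4-connectivity as an option; labels are deterministic (row-major
first encounter), and city size is the sum of member-pixel spherical
areas `R²ΔλΔφ cos(lat)` with `R = 6371` km (no ellipsoid: relative
sizes are insensitive to the geodesy). The implementation is checked
against an independent brute-force flood-fill oracle on random
masks.

The coarse urban *stratum* follows the resample-everything-first
convention: the fine DN field is bilinearly interpolated to the
coarse pixel centers, then thresholded. Whether thresholding should
precede resampling is not decidable from the method description
alone, so a threshold-then-majority mode is provided behind a
switch; with the synthetic geometry (clusters centered on coarse
cells) both agree.

Greenness is split by the sign of the period-2 minus period-1 mean
of the annual series (no seasonal compositing — annual values are
all the generator produces, and the compositing rule of the original
satellite product is not part of the method); exact ties belong to
neither category.

## The synthetic landscape

The generator replaces the reanalysis/satellite inputs with a
controlled landscape whose statistical structure matches what the
analysis assumes, plus ground-truth labels. Its defaults *are* the
study conditions used throughout the tests and the acceptance
script:

- 60 × 80 pixels at 0.75° (4800 pixels — same order as a continental
  domain, desk-fast), years 1982–2015 split at 1999;
- base dryness spanning 0.1–5 log-linearly west→east with a mild
  north–south harmonic, so all biome bands are populated; `P` a
  smooth field near 1 m yr⁻¹;
- interannual noise: multiplicative lognormal (unit mean, cv
  `noise_sd = 0.05` — a typical interannual coefficient of variation
  for annual precipitation) on `P` and `N`, with `E` re-closed
  through the Schreiber relation each year. This keeps every year
  physically valid (`0 ≤ E ≤ min(P, N)`) *by construction*, with no
  ad-hoc clipping that would distort variances;
- perturbations as step changes over all period-2 years (the
  analysis compares period means, so a step is the minimal
  sufficient structure): internal patches `dE = ±0.1` m yr⁻¹ at
  fixed forcing, external patches `dN = +0.2, dP = −0.2` (drying)
  and the negated pair (wetting) at fixed `E`. Patch rectangles sit
  in the moderate-dryness belt where these magnitudes keep all
  pixel-years physically valid even under noise (the generator
  *rejects* any configuration that drives `E` outside
  `[0, min(P, N)]`);
- greenness: a dryness-dependent base level plus a signed two-period
  step of 0.05 NDVI units — greening on afforestation-like and
  wetting patches, browning on deforestation-like and drying
  patches, background signs drawn with `P(increase) = 0.7` to
  emulate the prevailing greening of recent decades;
- nightlights: a 5× finer grid with 12 compact 3 × 3 bright clusters
  (`DN = 40`) snapped to centers of pairwise non-adjacent coarse
  cells, on a random dim background (`DN ≤ 6`). Snapping makes the
  coarse-detection truth exact; non-adjacency keeps clusters
  disjoint under either connectivity.

What the generator does *not* emulate: reanalysis physics and its
spatially correlated errors, satellite compositing artifacts, sensor
saturation and overglow beyond a uniform background, spatial
autocorrelation of interannual noise, and trends *within* periods.
Green tests on this landscape therefore demonstrate the
correctness of the *machinery* — equations, masks, labeling,
bookkeeping — not the robustness of the diagnostic against real
observational error structure.

## Numerical and I/O choices

- Densities are raw 50 × 50 left-closed histograms on the unit
  square (no kernel smoothing — the diagnostic is literally pixel
  frequencies); values exactly 1 go to the top bin, finite states
  outside the square go to an explicit overflow bucket so mass is
  always conserved. Dryness-band masses classify bins by their
  centers, which keeps the rule refinement-stable (checked to ±2%
  under bin doubling).
- Bilinear resampling reproduces constants and bilinear fields to
  round-off and returns missing (never extrapolates) outside the
  source hull; grids are pixel-center registered, latitude
  descending, longitude ascending.
- Gridded layers are serialized as plain-text ESRI ASCII grids and
  long CSV series with JSON sidecars, written at 17 significant
  digits so write-then-read round trips are exact.
- Every random draw derives from the scenario seed (separate fixed
  offsets per generator stage), so a full pipeline run is
  reproducible byte for byte; the run report echoes every
  configurable choice.

The problem sizes used by the test-suite and acceptance script — the
4800-pixel default landscape, 10⁴-point curve-consistency grids,
10⁵ random attribution vectors, 200 random 20 × 20 labeling masks,
ten noisy-recovery seeds — were chosen as the smallest sizes at
which the checked properties are sharp (exact identities at machine
precision; recovery rates with two-digit resolution).

## Known limitations

- The Schreiber closure is the only Budyko-family relation
  implemented; the framework's other members (Ol'dekop, Turc–Pike,
  Fu) would change the balanced curve but not the state mapping.
- Net radiation must already be supplied in water-flux equivalents;
  no latent-heat conversion is applied.
- The significance rule is a two-period mean comparison against
  pooled interannual spread — deliberately simple, with no trend
  test and no multiple-comparison control across pixels.
- With fewer years per period the population-`std` rule becomes
  conservative (a half-record step of size `s` yields `|Δ| = 2·std`
  at best); the default 17 + 17 years is comfortably away from that
  edge.
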