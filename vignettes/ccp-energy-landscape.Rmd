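---
title: "The CCP energy landscape and its AFM morphometry pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CCP energy landscape and its AFM morphometry pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitscape)
```

## The model

A clathrin-coated pit (CCP) is idealized as a spherical cap on a flat plasma
membrane, parameterized by its coat area $A$ (nm²) and radius of curvature
$R$ (nm). Physically accessible states satisfy $A \le 4\pi R^2$; the
equality locus is the closed coated vesicle. The pit energy is the sum of
four terms:

$$E(A,R) = A\frac{\kappa_m}{2}\Big(\frac{2}{R}\Big)^2
 + \gamma\frac{A^2}{4\pi R^2}
 + A\frac{\kappa_c}{2}\Big(\frac{2}{R}-\frac{2}{R_c}\Big)^2
 - a\frac{A}{A_c}.$$

The first term is Helfrich bending of the membrane patch (spontaneous
curvature zero by default; a finite intrinsic membrane radius `R_memb` is
supported). The second is the work done against lateral tension: pulling a
cap of area $A$ out of the plane removes in-plane area
$\Delta A = A^2/(4\pi R^2)$, which for every valid cap equals $\pi h^2$
with $h$ the cap height — one of the exact identities the test suite
checks on $10^4$ random caps. The third term penalizes bending the clathrin
lattice away from its intrinsic curvature, and the fourth rewards
polymerized arm-arm contacts. A boundary correction of
$+a\,N_\mathrm{open}$ for unpolymerized edge arms is available in
`clath_poly_energy()` but negligible for lattices larger than a few cells.

### Parameters, units and defaults

All energies are in units of $k_BT$, lengths in nm, tension in
$k_BT/\mathrm{nm}^2$; SI conversion happens only inside
`kappa_from_stiffness()` with $k_BT = 4.11\times10^{-21}$ J (298 K).

| parameter | default | meaning |
|---|---|---|
| `kappa_memb` | 15 $k_BT$ | membrane bending rigidity |
| `R_memb` | $\infty$ | intrinsic membrane curvature radius (flat) |
| `gamma` | 0.01 $k_BT$/nm² | lateral membrane tension (mid-cellular range) |
| `kappa_clath` | 373 $k_BT$ | coat bending rigidity |
| `R_clath` | 40 nm | intrinsic coat curvature radius (cage radius) |
| `a` | 30 $k_BT$ | polymerization energy per arm-arm interaction |
| `A_clath` | 218 nm² | lattice area per arm-arm interaction |

The coat rigidity derives from an AFM point-load stiffness
$k \approx 0.08$ N/m measured on reconstituted cages. The exact thin-shell
relation behind that conversion is not independently constrained, so
`kappa_from_stiffness()` exposes its formula explicitly — the Reissner
point-load stiffness $k = 4Et^2/(R\sqrt{3(1-\nu^2)})$ combined with the
plate rigidity $\kappa = Et^3/(12(1-\nu^2))$ — and its default thickness
$t = 11.4977$ nm is a calibration chosen so that the default inputs return
373 $k_BT$. Only the linearity in $k$ and the functional form are
substantive; users with a preferred shell relation should pass their own
$t$ and $\nu$.

The per-arm polymerization energy `a` is an upper-bound estimate: at the
population mean radius $R_\mathrm{mean} = 92$ nm the per-arm bending cost
(`per_arm_bend_energy()`) is ≈ 32 $k_BT$, and marginal stability of those
lattices — bending cost balancing polymerization gain, so lattices can
still grow from a nearly flat geometry — gives $a \sim 30\,k_BT$. Lattice
defects can only lower the bending cost, hence "upper bound". The
evaluation is made exactly at $R_\mathrm{mean}$; this reproduces the
printed estimate and avoids an arbitrary reference-state choice.

### Minimization

At fixed $R$ the energy is quadratic in $A$ with positive curvature
(for $\gamma > 0$), so the inner minimization over
$A \in (0, 4\pi R^2]$ is closed-form. The default minimizer profiles out
$A$ and optimizes the resulting one-dimensional function of $R$ on a log
grid (600 points over 5–2000 nm) followed by `stats::optimize()`
refinement. An independent 2D log-grid search with six rounds of local
refinement (`method = "grid"`) is retained purely as a cross-check; the two
agree to well under 0.5 nm, and on the boundary both match the stationary
condition

$$R^* = \frac{4\kappa_c/R_c}{2\gamma + 4\kappa_c/R_c^2 - 2a/A_c} = 55.07\ \mathrm{nm}$$

at defaults. The minimizer reports which branch is active: `"boundary"`
(closed sphere), `"interior"` ($A < 4\pi R^2$ strictly), `"empty"` (no
coated state below zero energy, e.g. $a = 0$), or `"unbounded"` when the
large-$R$ energy density $2\kappa_c/R_c^2 - a/A_c$ is negative and the
energy has no minimum — reported explicitly rather than producing a
spurious number. The branch flag makes the critical-tension definition
operational: `critical_tension()` sweeps $\gamma$ (default grid 0.005 to
0.2 in steps of 0.005) and returns the smallest tension whose constrained
minimizer is interior, 0.06 $k_BT$/nm² at defaults, with a bracketing
check on both sides.

`relax_at_constant_area()` is the same minimization at fixed $A$: the
closed form $1/R = (4\kappa_c/R_c)/(4\kappa_m + 4\kappa_c + \gamma A/2\pi)$
clamped at the sphere bound $R \ge \sqrt{A/4\pi}$. It is the end state of a
nanodissected lattice fragment and the basis of `simulate_nanodissection()`.

## The morphometry chain

`level_background()` sets the zero level to the median of the
lowest-quartile heights. This estimator sits near the 12.5th percentile of
the background distribution, i.e. about $1.15\sigma$ *below* the true
membrane level for pixel noise $\sigma$ — a deliberate, documented bias of
order 0.1 nm that is negligible against cap heights of tens of nm and
robust against arbitrarily large protrusion coverage.

`fit_sphere()` fits the algebraic sphere equation
$x^2+y^2+z^2+Dx+Ey+Fz+G=0$ by linear least squares, then refits twice using
only points within 45° polar angle of the current apex. The apex cone is
measured from the fitted sphere center's vertical axis: tip dilation
corrupts the steep flanks of a pit, while the apex region is tracked
faithfully, so apex-centered restriction is the reading that serves the
stated purpose of the restriction. Cap height is taken from the fitted
sphere ($h = c_z + R$ above the zero level) rather than the raw maximum
pixel, which would inherit the full ridge corrugation and noise.

`detect_lattice()` high-pass filters (subtraction of a Gaussian blur,
default $\sigma = 4$ px), then marks strict 1D local maxima along either
image axis — a separable ridge test; diagonal axes are excluded. A minimum
peak prominence of 0.5 nm (5× the default pixel noise, a quarter of the
ridge corrugation) suppresses noise peaks. The test runs at samplings 1,
0.5 and 0.25 (block-mean down-sampling) to catch the tops of wide flat
ridges, and the OR-combined mask is closed with two rounds of 3×3
dilation followed by two erosions — the smallest count that bridges
single-pixel gaps.

`build_skeleton()` thins the mask (Zhang–Suen, implemented in-package),
peels up to 3 endpoint pixels to suppress noise spurs, and finds junctions
by crossing number (number of distinct arcs of skeleton neighbors ≥ 3)
rather than raw neighbor count, which misfires on the staircase pixels of
digitized diagonal lines. Junction pixels within 2 px merge into one hub —
AFM hub blobs span more than one pixel. Arms are extracted as connected
branch components between hubs; adjacency is severed where two branch
pixels flank a common junction pixel so arms cannot leak around a junction.
Two geometric repairs follow: arm paths deviating more than 2.2 px from
their chord are split at the deviation maximum (recovering lattice corners
whose third arm is missing, which leave no junction), and nearly collinear
(> 150°) degree-2 pass-through nodes are spliced out. Faces are the
interior cycles of the planar rotation system; the outer face is identified
by its opposite orientation. On the 19-hexagon benchmark this chain
recovers all 19 faces with ≥ 90% classified as hexagons and the full hub
set; recovered vertex counts fluctuate by up to ~10% because sharp boundary
corners are occasionally represented by two nearby bends or merged into an
adjacent hub.

`section_profile()` interpolates heights bilinearly at 1 px spacing and
attaches a local radius from sliding-window algebraic circle fits
(default window 15 samples), signed positive for crests.

## The synthetic generator

The generator emulates HS-AFM topographs of unroofed membranes: a flat
background at 0 nm, a spherical-cap protrusion, a polygonal ridge texture 2
nm proud of the local surface, grayscale dilation with a spherical tip
(radius 2 nm — the image is the maximum of surface minus tip sagitta over
the tip footprint), and additive Gaussian pixel noise of 0.1 nm, on
300 × 300 px frames at 2 nm/px. These defaults are the package's standard
imaging conditions and are used unchanged by the benchmarks.

Cap lattices are built by icosahedral geodesic subdivision and polyhedral
dualization rather than by stochastic point sampling: the dual mesh is
hexagon-dominant with *exactly* 12 pentagons on the closed sphere, so the
Euler-formula invariant is exact rather than approximate, the construction
is deterministic given the seed (which sets a uniform random rotation of
the sphere before the cap is cut), and edge lengths are uniform at the
clathrin arm scale (default 18 nm; the subdivision frequency is rounded,
so the realized mean edge can deviate from the request, most visibly for
small closed cages). Partial caps carry on average
$12\,\Omega/4\pi$ pentagons for cap solid angle $\Omega$.

`sample_population()` draws $(A,R)$ pairs from
$\propto \exp(-E/T_\mathrm{eff})$ on the landscape grid. The effective
temperature (default 300 $k_BT$) is a spread parameter for generating
plausible synthetic populations, not a physical claim; as
$T_\mathrm{eff}\to 0$ samples collapse onto the constrained minimum up to
grid discretization (the landscape grid is log-spaced, 200 cells per axis,
so the zero-temperature cloud sits within ~2% of the exact minimizer).

`simulate_nanodissection()` removes arm-arm interactions (edges) from a
mesh, takes connected components, assigns each component an area of
$3 A_c$ per face (three interactions per unit cell), and relaxes it at
constant area. Components whose face set is untouched keep their radius: a
severed terminal open arm releases no constraint and only costs $+a$ of
polymerization energy. Tying component area to face counts, rather than
integrating mesh area, keeps the dissection energetics in the same
bookkeeping as the polymerization term.

### What the generator does not emulate

Real lattices are disordered — variable polygon sizes, vacancies, partial
coats — whereas geodesic duals are maximally regular; real ridges have
finite width and height variation, whereas rendered ridges are hairline
(one pixel) and uniform; scanner drift, line noise, feedback ringing and
asymmetric tips are absent; and the Boltzmann population is a sampling
device, not a generative model of observed pit ensembles. Passing the
recovery benchmarks therefore demonstrates the correctness of the
measurement chain on clean, known-truth geometry, not its performance on
real micrographs.

## Numerical choices and degenerate inputs

- Caps validate $0 < h \le 2R$ ($A \le 4\pi R^2$) with $10^{-9}$ relative
  slack; constructors from any two of $(R,h,A)$ agree to $10^{-9}$.
- Landscape grids are log-spaced, default 400 × 400 over
  $R \in [10, 400]$ nm, $A \in [10^2, 10^5]$ nm², with the inaccessible
  region masked `NA`.
- Topograph TIFFs store float32 samples normalized to $[0,1]$; the offset
  and scale (nm) live in the JSON sidecar alongside the pixel size and zero
  level, because float TIFF samples outside $[0,1]$ are not portable. CSV
  grids store raw nm.
- `register_frames()` aligns by integer-pixel FFT cross-correlation only;
  featureless frames trigger a warning and an identity shift.
- Fit failures (seed outside a protrusion, < 12 usable points, fitted
  radius outside 5–2000 nm) return a structured failure record, never an
  error, so batch drivers can tally them.

## Problem sizes

The shipped tests exercise: $10^4$ random caps per analytic identity; a
600-point profile grid and 200 × 200 × 6-round grid search per
minimization; 50 rendered 300 × 300 px topographs for the radius/area
recovery benchmark (median errors well under the 5%/10% acceptance
bounds); one 19-hexagon lattice fixture; and draped lattices at
$R \in \{50, 100, 200\}$ nm for the angle-sum trend. The full suite runs
in well under a minute on one CPU.

## Known limitations

- The skeleton chain assumes ridges at least ~4 px apart (arm length
  ≥ 8 nm at 2 nm/px); denser lattices need finer pixels.
- Sharp lattice corners (≈ 60°) are rounded by thinning; they are recovered
  as positions but may appear as two bends, so exact vertex counts on
  synthetic polygons with acute corners are not preserved.
- `hub_angles()` uses straight 3D chords between adjacent hubs; intra-arm
  curvature is below skeleton resolution by construction.
- Faces of size ≤ 4 or ≥ 8 are tallied but excluded from the
  pentagon/hexagon/heptagon angle fits.
- The flat-conformation tolerance (±5° on the 360° angle sum) reflects AFM
  angular noise and is configurable.
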