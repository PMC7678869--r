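---
title: "QURT: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QURT: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `qurt`: the discrete
reconstruction model, the constraint system, the optimisation procedure, the
numerical conventions, and the design decisions that were genuinely open.
It states no empirical numbers beyond those the test suite and
`scripts/acceptance.R` compute themselves.

## The problem

A single-axis tilt series samples the Fourier transform of each
cross-section only along the radial lines perpendicular to the acquired
tilt directions (projection slice theorem). A tilt range narrower than
±90° therefore leaves a wedge around the z\* axis empty, and linear
reconstructions — filtered back projection (FBP) and iterative
least-squares methods such as SIRT — produce elongated, blurred structures
with streak and cloud artefacts. Regularised discrete methods (DART and
relatives, compressed sensing) counter this with prior knowledge about the
specimen (few grey levels, sparsity); QURT instead changes the image model
itself and needs only the tilt series and the angles.

## The discrete image model and its constraints

A digital image is a quantisation of an analogue one: with a quantisation
unit (QU) of grey value $q$, the pixel value is the number of QU pieces
stacked there, and the cross-section is a finite arrangement of
$N$ identical pieces in (x, z, grey) space. Because the line-projection
integral is the same for every tilt angle when the object projects fully
into the field of view,

$$\int p_\theta(x')\,dx' = \iint f(x,z)\,dx\,dz = \text{const},$$

one chosen *base angle* $\Theta$ fixes

$$N \approx \frac{\sum_j p_\Theta(x'_j)}{q}, \qquad
  n_\Theta(x'_j) \approx \frac{p_\Theta(x'_j)}{q},$$

the total piece count and its split over the detector columns of the base
angle. `qu_constraints()` rounds each column half-to-even and *defines*
$N$ as the sum of the rounded column counts, so the bookkeeping identity
$\sum_j n_\Theta(x'_j) = N$ holds exactly throughout the algorithm (the
alternative — rounding $N$ independently — creates an unfillable or
overfull budget).

## The error map and the placement rules

For a candidate image $g$, per-angle residuals and their simple (unfiltered)
back projection form the error map

$$E_{\theta_i}(x') = \mathrm{FP}[g](x') - p_{\theta_i}(x'), \qquad
  E_{\mathrm{map}} = \mathrm{BP}[E_{\theta_i}].$$

Negative map values mark a deficiency of pieces, positive values an excess;
the correct arrangement has an identically zero map. The solver applies
three rules:

* **placement** — add pieces one by one at the most negative map pixel
  whose column budget is not yet met, updating the map incrementally after
  each placement, until every column holds exactly $n_\Theta(x'_j)$ pieces;
* **erasure** — remove pieces where the map exceeds a positive margin
  (default $+q/2$; with the back projector normalised by the number of
  angles this threshold provably makes every erasure reduce the squared
  residual, since a piece's own map contribution is at most $q$ times its
  squared weight norm over angles);
* **refinement** — repeatedly execute the single intra-column move (take a
  piece from one pixel, stack it on another pixel of the same base-angle
  column) with the largest decrease of $\sum_{i,x'} E_{\theta_i}(x')^2$;
  column counts are conserved by construction and the squared residual is
  non-increasing because only strictly improving moves are executed.

Refinement stops when no move improves the residual or when the change
rate of the image, measured every `check_interval` (default 100)
iterations, drops below `convergence_tol` (default $10^{-6}$).

## Multiresolution schedule and base-angle averaging

Placing single-pixel pieces from a null image falls into fine-grained local
minima (an artificial granular image). The schedule therefore anneals the
QU piece *size* from 32 pixels down to 1 (halving), visiting each size with
the QU *values* in `q_values` (default 8 then 1; the last size only
$q = 1$). A piece of size $s$ is one pixel of a working grid binned by
$s$; binned projections are divided by $s^2$ so the grey scale is preserved
across levels and the budget $N$ grows exactly fourfold per doubling of the
linear image definition. Each level is solved for several base angles
(default $-\theta_{\max}, 0, +\theta_{\max}$; for step angles above 5° also
±50°, which trades off constraint diversity against per-column statistics)
and the per-angle results are averaged pixelwise — averaging removes the
square-piece mosaic pattern a single base angle leaves behind. The next
level starts from the previous average, interpolated and re-quantised.

## Design decisions in the open gaps

* **Projector pair.** The projection operator is a strip integral: the
  shadow of a square pixel at angle θ is the convolution of two boxes of
  widths |cos θ| and |sin θ| — a unit-area trapezoid — integrated over each
  detector bin in closed form. This conserves mass exactly for objects
  inside the inscribed circle and matches a subpixel point-mass oracle to
  well under 2% per bin. The back projector is the exact transpose divided
  by the number of angles, so residuals back-project precisely onto the
  pixels that caused them — the property the error map logic relies on.
  (A ray-driven interpolating projector was the alternative; the strip
  integral is both closer to the physical line integral of a pixelated
  object and self-adjoint by construction.)
* **Detector equals grid.** With one detector bin per pixel column, mass
  conservation cannot hold for sources outside the inscribed circle (their
  shadows leave the detector at oblique angles); both phantoms keep all
  structure inside that circle, matching the ideal-case assumption that the
  object projects fully into the imaging plane.
* **Inter-level warm start.** Block replication of the coarse average
  plants mosaic edges that the next level's intra-column moves must undo;
  bilinear interpolation (then re-quantisation to multiples of $q$,
  relieving over-budget columns from their most excessive pixels and
  placing the deficit) gives a measurably better starting point and is the
  default (`control = list(upsample = "block")` restores replication).
* **Tie-breaks.** Equal error-map minima are resolved in a fixed
  column-major scan order, making every reconstruction bit-reproducible.
* **Refinement at scale.** On grids up to 12×12 the best move is found by
  exhaustive enumeration of all legal moves (this exact path is what the
  unit tests check against brute force). On larger grids candidates are
  screened in O(1) by the exact second-order expansion of the residual
  change — using per-pixel squared weight norms and a precomputed overlap
  profile between column neighbours — and a shortlist is evaluated
  exactly; moves are applied in batches against an error map refreshed
  once per batch, while each accepted move is validated against exactly
  maintained residuals, so monotonicity is preserved bit-for-bit. The
  batch ranking is the one approximation made for speed; the endgame
  always falls back to one-move-at-a-time with a fresh map.
* **Erasure scheduling.** The erase rule has no stated schedule; it runs
  as a sweep before each refinement round, freeing budget that placement
  immediately refills. A safety cap of `move_cap` × N moves per level
  (default 50) exists but is not reached in the shipped studies.
* **Amplification.** Experimental intensities are mapped to integers with
  `amplify_projections()`: scale = `target_peak` / max(bin value). The
  reconstruction is divided by the same scale on output, so grey levels
  return to the data units.

## The synthetic phantoms

The reference layouts are package conventions (the original models are not
published pixel-exactly): the binary model is an annulus plus a horizontal
bar (long edges perpendicular to the 0° beam — maximally susceptible to
the missing wedge); the general model is a thick annulus with a smooth
radial grey gradient, a rectangle whose interior rises monotonically from
dark to bright, three punched holes and two cone-shaped ramps, peak grey
exactly 255. Shapes are rasterised with 4×4 subpixel area sampling so
edges are steep (about one pixel) yet not jagged; the binary model is then
binarised by majority coverage. Simulated tilt series are noiseless by
default; Poisson shot noise with a dose parameter is available. What
passing tests on these phantoms do *not* show: robustness to alignment
errors, background estimation errors, detector gain variation, or
structured (non-Poisson) noise — experimental data must be aligned and
background-subtracted before reconstruction (`subtract_background()`,
`amplify_projections()`).

## Problem sizes and baselines

The simulation studies in the tests and in `scripts/acceptance.R` run at
128×128 (the package's chosen working size for the full six-condition
comparison; single runs behave the same way at 256 and 512, only slower).
SIRT uses 150 iterations, relaxation 1.0 and a non-negativity clamp —
chosen once to plateau on the phantom suite — which makes it a strong
baseline; FBP uses the standard discrete Ram-Lak kernel with the angular
step as quadrature weight. The quality ordering QURT < SIRT < FBP in
normalized average error holds for every tilt condition tested, and the
QURT and FBP magnitudes track the reference values within a factor of two
(exact agreement is not expected, since the phantom geometry is a
reimplemented convention and the baseline parameters of the original
programs are unpublished).

## Known limitations

* Reconstruction is slice-wise 2D; no coupling between adjacent slices.
* The greedy search is deterministic; there is no stochastic restart, so a
  pathological tie structure could in principle bias a solution (not
  observed on the shipped phantoms).
* Runtime grows roughly with N × (angles) at the finest level; 512²
  cross-sections take minutes per slice on one CPU.
* Tilt-series alignment and background estimation are out of scope; inputs
  are assumed aligned and background-corrected.
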