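---
title: "Active contours with a semi-dynamic GVF field and magnetostatic correction"
author: "MagSnake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active contours with a semi-dynamic GVF field and magnetostatic correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(MagSnake)
```

## The model

A snake is a closed parametric curve $X(s) = [x(s), y(s)]$, $s \in [0,1]$,
that minimizes

$$E = \int_0^1 \tfrac12\big(\alpha |X'(s)|^2 + \beta |X''(s)|^2\big) +
E_\mathrm{ext}(X(s))\, ds,$$

whose Euler equation balances the internal force $\alpha X'' - \beta X''''$
against the external force. We evolve the curve in time with the standard
semi-implicit scheme: internal terms through the periodic pentadiagonal
system $(I + \gamma A)^{-1}$ (applied per coordinate via the circulant
eigendecomposition, i.e. an FFT — exact, unconditionally stable, $O(N\log
N)$), the external force explicitly:

$$X_{t+1} = (I + \gamma A)^{-1}\big(X_t + \gamma\kappa\, V(X_t)\big).$$

The external field is the **gradient vector flow** (GVF) of an edge map
$f(x,y)$ ($f = |\nabla I|^2$ or $|\nabla (G_\sigma * I)|^2$, normalized to
max 1): the minimizer of

$$\varepsilon = \iint \mu\,(u_x^2+u_y^2+v_x^2+v_y^2) +
|\nabla f|^2\,|V - \nabla f|^2\; dx\, dy ,$$

computed by explicit Euler iteration of the Euler–Lagrange diffusion
equations from $V = \nabla f$ with a 5-point Laplacian and replicate
padding. Near strong edges $V \approx \nabla f$ (the approximation is
asymptotic in $|\nabla f|^2/\mu$); elsewhere diffusion spreads the edge
information across the grid, which is what gives the snake its large
capture range — and also what makes forces from the two walls of a deep,
narrow concavity compete and cancel at its mouth, stalling the snake there.

## False-contour detection

On a *stopped* contour, a point is **false** when the external forces
around it run along the contour instead of across it. For each point we
take the 3×3 block of grid nodes centered on the nearest node and compute
the acute angle $\arccos|t\cdot\hat v| \in [0^\circ, 90^\circ]$ between the
undirected tangent line and each force vector; the point is flagged iff the
*maximum* of the nine angles is $\le \theta$. Using the maximum makes a
single irregular force direction near a real contour rescue the point —
the advantage over judging by one angle. Forces with magnitude below
`minForce` are skipped, and if all nine are skipped the angle is defined as
$0^\circ$: a null field cannot drive the contour, so a contour stalled in
one is false.

Flags are aggregated over $l = \max(1, \mathrm{round}(N/\texttt{pointsPerSegment}))$
contiguous equal-as-possible segments starting at point 1; segment $L_i$ is
false iff $(\sum_{X(s)\in L_i} FP)\cdot l/U > \eta$ with $U = N$, i.e. iff
the within-segment false fraction strictly exceeds $\eta$. Adjacent false
segments are merged (cyclically) into maximal runs before the correction
step. Fixed blocks anchored at point 1 were chosen over data-dependent
division points for determinism; the within-segment fraction is the only
reading of the $l/U$ normalization that is independent of the number of
segments.

## Magnetostatic correction

Hypothetical electric currents flow along the object boundary: at every
pixel whose gradient magnitude reaches `edgeFrac` of the maximum, the
current is the rotated gradient $\Gamma = (-1)^\lambda(-I_y, I_x)$, with
$\lambda$ selecting counter-clockwise ($\lambda = 1$) or clockwise
($\lambda = 2$) circulation. The out-of-plane magnetic field at $p$ is the
Biot–Savart style sum

$$B(p) = \sum_c \frac{[\Gamma(c)\times \hat R_{p,c}]_z}{|p-c|^2 + \epsilon^2},$$

with all physical constants and per-point current magnitudes folded to 1
(only the product with the update weight $k$ matters) and a softening
$\epsilon = 1$ px removing the $R \to 0$ singularity. The false contour
carries current $I_s = 1$ along its tangent $\Upsilon(s)$, so the in-plane
force at point $i$ is $F_i = (t_{iy} B_i, -t_{ix} B_i)$ — perpendicular to
the contour by construction, pointing into the concavity when the two
current directions agree. $B$ is evaluated only at false-segment points,
not on the whole grid; that locality is the method's efficiency advantage
over a fully dynamic magnetostatic field.

The field update $V_\mathrm{new} = V + kF$ is realized as a local splat:
every grid node within a tent-shaped halo (radius `halo`, default 3 px) of
a false-segment point receives $k$ times the force of its nearest segment
point, weighted by $(1-|dx|/h)(1-|dy|/h)$ (bilinear weights when $h = 1$).
Nodes outside the halos are untouched — the field is **semi-dynamic**:
static while the snake moves, modified only where and when a false part is
found.

### Circulation bookkeeping

Contours store an orientation label equal to the sign of the shoelace area
in the image's y-down pixel frame. A positively-oriented ("ccw") contour is
*visually* clockwise on screen, so the matching boundary-current enum for a
non-intersecting initialization is the opposite label; the driver's
automatic $\lambda$ rule applies that mapping. The convention is pinned by
a test asserting that the mean corrective force over a false run points
into the concavity; if an implementation change flips a sign, that test —
not the convention — decides. Initial contours that cross the object
boundary require an explicit `lambdaDir`.

## The outer loop

`runSegmentation()` computes the edge map and GVF once, then alternates:
evolve until the contour stops; classify points and segments; if false
segments exist, add the magnetostatic forces near them and evolve again —
up to `maxOuterRounds` (default 20). Detection only runs on a stopped
contour; a round that exhausts its step budget (`maxSteps`, default 200)
keeps evolving in the next round, because tangent-versus-force angles on a
still-moving contour mean nothing. A contour whose perimeter falls below
8 px aborts the run with an error.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| $\alpha$, $\beta$ | 0.6, 0.3 | elasticity / rigidity weights |
| $\mu$ | 0.2 | GVF smoothness; raise for noisier images (keep < 0.25) |
| $k$ | 0.6 | weight of the magnetic force in the field update |
| $\theta$ | 20° | false-point angle threshold |
| `pointsPerSegment` | 50 | nominal segment length for the fraction rule |
| $\eta$ | 0.8 | within-segment false-fraction threshold (strict) |
| $\lambda$ | auto | boundary-current circulation (from init orientation) |
| $\gamma$, $\kappa$ | 1, 1 | step size / external-force weight |
| `spacing` | 1 px | contour resampling interval (allowed 0.5–2) |
| `stopEps`, `stopWindow` | 0.03 px, 10 | stop when the max *normal* displacement stays below `stopEps` this many steps |
| `halo` | 3 px | field-update radius |
| `edgeFrac` | 0.3 | boundary-point gradient threshold |

## Numerical choices

* **GVF time step.** The explicit scheme is stable for
  $dt\,(8\mu + 2\max b) \le 2$ with $b = f_x^2 + f_y^2$; the classic pure
  diffusion bound $1/(4\mu)$ ignores the data term and diverges on sharp
  normalized edge maps. The default $dt = 1/(4\mu + 1)$ guarantees a
  monotone energy descent for any normalized edge map ($b \le 1$).
* **GVF stopping.** Mean absolute per-pixel update < `tol` (default
  `1e-5`). On large, mostly flat grids the mean dilutes edge-local updates,
  so a loose tolerance would freeze the diffusion long before the field
  spreads; `1e-5` gives a capture range of several tens of pixels on a
  256² grid in ~1300 iterations.
* **Snake stopping.** The stop criterion measures the *normal* component
  of each point's displacement. Tangential sliding is pure
  reparameterization (it is absorbed by the per-step arc-length
  resampling) and, precisely on false segments, forces run along the
  contour and would otherwise keep the stop criterion from ever firing.
  `stopEps = 0.03` px sits above the residual corner jitter of the
  discretized evolution and below typical approach speeds.
* **Resampling.** Arc-length uniform with the first point fixed;
  orientation is recomputed from the signed area after every resample.
  Chords spanning sharp polygon corners are shorter than their arcs, so
  chord spacing is uniform only up to the corner sagitta.
* **Interpolation of markers.** Piecewise linear, so marker polygons are
  reproduced exactly; smooth shapes marked sparsely deviate by the chord
  sagitta (0.68 px for 12 markers on a radius-20 circle).
* **Edge-map variants.** Only the two gradient forms ($|\nabla I|^2$,
  $|\nabla(G_\sigma * I)|^2$) are exposed; binary images go through the
  same formulas.
* **Degenerate inputs.** Coincident contour neighbors fall back to
  one-sided tangents (with a warning); an all-zero edge map yields the zero
  field and an elastic collapse guarded by the perimeter check; an empty
  magnetic source yields zero forces with a warning.

## The synthetic generator

`makeShape()` renders binary objects — a disc (convex control), a square
with one deep rectangular slot (`"ushape"`), a square with up to four slots
(`"multi_concave"`), an annulus (`"ring"`) — optionally blurred and with
seeded additive Gaussian intensity noise, and traces the ground-truth
boundary from the clean mask as the 0.5 iso-contour at subpixel precision.
`enclosingInit()` offsets the convex hull of the truth outward to emulate a
loosely drawn initial contour. These fixtures emulate sharp-edged,
noise-free (by default) objects; they do not reproduce the texture,
intensity inhomogeneity or weak edges of real MRI/ultrasound data, so
passing tests demonstrate the mechanics of the method, not clinical
accuracy. Test and script problem sizes (96–256² grids, concavities 9–24 px
wide and 30–50 px deep) were chosen as the smallest scales at which the
GVF stall is clearly expressed.

## Known limitations

* **Detectability depends on concavity width.** The angle test compares
  tangents with forces in a 3×3 *pixel* neighborhood. When the concavity
  mouth is only a few pixels wide, the stalled bridge sits so close to the
  slot-wall edge fields that every neighborhood contains near-perpendicular
  forces, and no point is flagged; the segment rule additionally needs the
  false run to fill more than $\eta$ of a `pointsPerSegment` block (> 40
  contiguous false points at the defaults), while a narrow mouth spans only
  10–20 points at 1 px spacing. On such geometries the pipeline returns
  the plain-GVF result. Matching the detector scale to the geometry
  (e.g. $\theta = 45$, 5-point segments for a 24 px mouth on a 256² grid)
  engages the correction, which then converges the contour to the slot
  bottom; the driver tests and the acceptance script demonstrate both
  regimes.
* Single closed contour only — no topology changes, no multi-object
  segmentation from one initialization.
* 2-D single-channel images only; isotropic Gaussian smoothing only.
* The magnetic field of the false contour itself is ignored (only the
  object-boundary currents act), as in the underlying model.
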