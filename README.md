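# MagSnake

Parametric active contours (snakes) with a semi-dynamic gradient-vector-flow
external force field and a magnetostatic corrective force for deep boundary
concavities.

## The problem

Snakes extract an object boundary from a grayscale image by deforming a
closed curve X(s) to minimize

    E = ∫ ½(α|X′(s)|² + β|X″(s)|²) + E_ext(X(s)) ds,

where α and β weight elasticity and rigidity and E_ext is derived from the
image. The classic gradient vector flow (GVF) external field V(x,y) =
(u, v) is obtained by diffusing the gradient of an edge map f(x,y) over the
whole image, minimizing

    ε = ∬ μ(u_x² + u_y² + v_x² + v_y²) + |∇f|² |V − ∇f|² dx dy,

which gives the snake a large capture range. But inside a deep, narrow
concavity the diffused forces from the two walls compete and cancel, and
the snake stalls across the concavity mouth. This package implements a
corrected pipeline aimed at exactly that failure, for people segmenting
objects with deep indentations (medical MRI/ultrasound boundaries,
irregular biological shapes):

1. **False-contour detection.** On a stopped snake, the acute angle between
   each point's tangent line and the nine force vectors in its local 3×3
   pixel neighborhood is computed. If the *maximum* angle is ≤ θ the point
   is a false (stalled) contour point — forces run along the contour
   instead of across it. The contour is split into `l = round(N/50)` equal
   segments and segment `L_i` is false iff `(Σ_{X(s)∈L_i} FP) · l/U > η`
   (U = N, strict inequality). Taking the maximum over nine forces makes
   the test robust to single irregular force directions near a real
   contour.
2. **Magnetostatic correction.** Hypothetical electric currents
   Γ = (−1)^λ(−I_y, I_x) flow along the object boundary (the image
   gradient rotated by 90°; λ selects the circulation direction). Their
   Biot–Savart style out-of-plane field
   `B(p) = Σ_c [Γ(c) × R̂_{p,c}]_z / (|p−c|² + ε²)` exerts an in-plane force
   `F = I_s Υ(s) × B` on the current-carrying false contour — always
   perpendicular to it, pointing into the concavity.
3. **Semi-dynamic field update.** `V_new = V + kF` is applied only in a
   small halo around the false segments; elsewhere the field stays static.
   The snake then evolves again, and the loop repeats until a stopped
   contour has no false part.

## Worked example

```r
library(MagSnake)

## a 256x256 binary object with a deep concavity (mouth 24 px, depth 40 px)
shp  <- makeShape(shapeSpec("ushape", size = 256L, mouthWidth = 24, depth = 40))
init <- enclosingInit(shp$truth, margin = 10)

det <- detectorParams(theta = 45, pointsPerSegment = 5L)

## plain GVF snake (correction disabled)
plain <- runSegmentation(shp$image, init,
  runConfig(detector = det, magnet = magnetParams(k = 0), maxOuterRounds = 30L))
boundaryDistance(plain@finalContour, shp$truth)[c("mean", "max")]
#> $mean  [1] 1.783091
#> $max   [1] 30.63847          # stalled: the slot is never entered

## full method
full <- runSegmentation(shp$image, init,
  runConfig(detector = det, magnet = magnetParams(k = 0.6), maxOuterRounds = 30L))
full
#> RunResult: 11 round(s), 8 field update(s), convergedClean = TRUE
boundaryDistance(full@finalContour, shp$truth)[c("mean", "max")]
#> $mean  [1] 0.1456005
#> $max   [1] 2.323693          # the contour followed the slot to its bottom
```

The mean/max values are symmetric surface distances (in px) between the
segmented contour and the known ground-truth boundary: after eight local
field updates the corrected snake traces the whole concavity (max error
2.3 px) where plain GVF leaves a 30 px gap.

A thin command-line interface wraps the same functions:

```sh
Rscript exec/magsnake fixture --shape ushape --out-image u.png --out-contour truth.csv
Rscript exec/magsnake segment --image u.png --init init.csv \
    --out-contour out.csv --out-mask mask.png --out-report report.json
```

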