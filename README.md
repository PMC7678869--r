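# qurt — Quantisation Units Reconstruction Technique for limited-angle tomography

Electron tomography reconstructs a 3D volume from projection images acquired
while tilting the specimen, but mechanical limits keep the tilt range below
±90°. The unsampled, wedge-shaped region of Fourier space — the *missing
wedge* — elongates and blurs every cross-section reconstructed by the
conventional linear methods (filtered/weighted back projection, SIRT).

`qurt` implements the **quantisation units reconstruction technique (QURT)**,
a nonlinear discrete method that suppresses missing-wedge artefacts without
prior knowledge about the specimen. It treats a digital cross-section as a
stack of grey-level quanta: with a quantisation unit (QU) of value *q*, a
pixel's grey level is the number of QU pieces stacked there. Because the
projection integral is tilt-invariant,

$$\int p_{0^\circ}(x)\,dx=\int p_\theta(x')\,dx' = \iint f(x,z)\,dx\,dz,$$

a base-angle projection $p_\Theta$ fixes both the total number of pieces,
$N \approx \sum_j p_\Theta(x'_j)/q$, and their distribution over detector
columns, $n_\Theta(x'_j) \approx p_\Theta(x'_j)/q$. QURT places these N
pieces one by one at the most piece-deficient pixel of the **error map**

$$E_{\mathrm{map}}(x,z) = \mathrm{BP}\!\left[\,\mathrm{FP}[g](x') - p_{\theta}(x')\,\right],$$

the simple back projection of the residuals of the current image *g*; pieces
under positive map values are erased, and placed pieces are then rearranged
inside their column (preserving $n_\Theta$) by always executing the move
that most reduces the squared residual. A coarse-to-fine schedule over the
QU piece size (32 → 1 pixels) and value (8 → 1), and averaging over several
base angles Θ, steer this combinatorial search away from local minima.

The package also provides:

* an exact strip-integral forward/back projector pair (mass-preserving,
  exact adjoint),
* FBP (Ram-Lak / Hann) and SIRT baselines,
* the two reference phantoms of the simulation study (binary doughnut+bar;
  grey-gradient doughnut+rectangle with holes and cones, peak grey 255) and
  tilt-series simulation with optional Poisson noise,
* evaluation metrics: normalized average error, Fourier missing-wedge energy,
  QU accounting,
* MRC / TIFF input-output, a slice-wise volume driver, and a small CLI
  (`exec/qurt`).

## Worked example

```r
library(qurt)

model <- phantom_general(128)                       # grey-gradient phantom
ts    <- simulate_tilt_series(model, tilt_angles(70, 2))   # 71 projections
print(ts)
#> Tilt series: 71 projections of 128 bins, angles -70..70 deg (step ~2)

fit  <- qurt(ts)        # multiresolution QURT, base angles -70/0/+70
sirt <- sirt(ts)        # 150-iteration SIRT baseline
fbp  <- fbp(ts)         # ramp-filtered back projection

normalized_error(fit,  model)   #> 0.02041012
normalized_error(sirt, model)   #> 0.03011554
normalized_error(fbp,  model)   #> 0.1215224

wedge_energy(fit,  70)$in_wedge   #> 2738.994
wedge_energy(sirt, 70)$in_wedge   #> 1131.189
```

The three errors are mean absolute deviations from the phantom divided by
its peak grey value: QURT beats both baselines under a ±70° tilt range, and
its Fourier spectrum carries about 2.4× more energy inside the missing wedge
than SIRT's (the phantom itself measures 3047 there), i.e. the wedge is
substantially recovered rather than left empty. `plot(fit)` shows the
reconstruction; `summary(fit)` prints the per-level QU accounting (budget N,
pieces placed, moved and erased — N quadruples each time the image
definition doubles).

## CLI

```sh
exec/qurt simulate    --model general --size 256 --range 70 --step 2 --out-prefix sim
exec/qurt reconstruct --stack sim_stack.mrc --angles sim_angles.txt --method qurt --out rec.mrc
exec/qurt evaluate    --recon rec.mrc --model-kind general --max-tilt 70
```
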