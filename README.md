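# tomomorph

Sparse-view iterative CT reconstruction and trabecular bone morphometry in R.

Micro-CT is the reference method for quantifying trabecular bone structure,
but a full short-scan protocol (260 views over 181.3 degrees at a 0.7 degree
step) costs scan time and radiation dose. `tomomorph` evaluates whether
iterative reconstruction preserves quantitative bone morphometry when the
projection data are cut to one half, one quarter, or one sixth: it generates
synthetic three-material bone phantoms (background, soft tissue, bone)
calibrated to published group statistics of a surgically destabilized (ACLT)
vs control animal model, simulates short-scan fan/cone-beam projections with
Poisson photon noise, reconstructs with

* **FBP/FDK** — Hamming-apodized (alpha = 0.54) filtered backprojection with
  Parker short-scan weighting; the full-data reference,
* **CGLS** — conjugate gradients on the least-squares normal equations,
* **TV** — total-variation regularization minimized with safeguarded
  Barzilai-Borwein steps, the weight chosen by the L-curve method,
* **DART** — the discrete algebraic reconstruction technique, alternating
  CGLS updates with segmentation against a three-value gray prior and
  fixation of interior voxels,

segments bone with a median/unsharp/Otsu/despeckle chain, and computes the
six morphometric parameters: BV/TV (%), Tb.Th (um), Tb.S (um),
Tb.N = (BV/TV)/Tb.Th (1/mm), the ellipsoid factor EF = a/b − b/c of maximal
inscribed ellipsoids (rod-like positive, plate-like negative), and
subchondral plate thickness Pl.Th (um). Group differences use the exact
(tie-aware permutation) Mann-Whitney U test; algorithms are compared through
per-sample relative errors against the full-data reference and
contrast-to-noise ratios.

Who it is for: imaging scientists weighing dose/time reductions in
quantitative bone studies, and developers of reconstruction methods who need
a reproducible, fully synthetic end-to-end benchmark with oracle-tested
operators (exact adjoint projector pair, brute-force-verified local
thickness and Otsu, enumeration-verified exact Mann-Whitney).

## Worked example

Analytic rod-lattice phantom (100 um radius rods on a 500 um pitch, 25 um
voxels) pushed through the morphometry module:

```r
library(tomomorph)
spec <- PhantomSpec(c(40L, 40L, 48L), structure = "rod_lattice")
ph   <- makeRodPhantom(100, 500, 3L, spec)
bone <- phantomLabels(ph$truth) == 2L
computeMorphometry(bone, array(FALSE, dim(bone)),
                   voi = array(TRUE, dim(bone)), voxelSize = 25)
#> MorphometryResult: BV/TV 12.25%, Tb.Th 181.2 um, Tb.S 485.1 um,
#>                    Tb.N 0.676 1/mm, EF 0.732, Pl.Th NA um
```

The voxelized BV/TV (12.25%) sits next to the analytic
pi r^2 / pitch^2 = 12.57%; Tb.Th recovers the 200 um rod diameter within one
voxel; the strongly positive EF (+0.73) reads the rods as prolate. The
direct-model trabecular-number identity reproduces published reference
columns exactly:

```r
round(trabecularNumber(51.9, 214.7), 2)   # BV/TV %, Tb.Th um
#> [1] 2.42
```

A fast end-to-end study (2 + 2 samples, 96 x 96 slices, 120 views) runs the
whole grid — full-data FBP reference plus CGLS/TV/DART at 1/2, 1/4, 1/6 of
the views, ten reconstructions per sample — and tabulates relative errors
against the reference:

```r
st <- runStudy(studyConfig("smoke", masterSeed = 1L))
aggregate(meanRelErr ~ algorithm + level, st$relerr, mean)
#>   algorithm level meanRelErr
#> 1      cgls   1/2   7.263141
#> 2      dart   1/2   7.589928
#> 3        tv   1/2   6.216713
#> 4      cgls   1/4   8.943216
#> 5      dart   1/4   6.374259
#> 6        tv   1/4   7.799103
#> 7      cgls   1/6  10.231078
#> 8      dart   1/6  10.400473
#> 9        tv   1/6  11.268711
```

(Each number is the mean over the six parameters and all samples of
|value − reference| / reference in percent; at this tiny smoke scale the
algorithms are close, while the desk-scale `"demo"` preset — 6 + 6 samples
at 256 x 256 with the full 260-view protocol — separates them, with DART
staying in the low single digits at every reduction level.)
`reportStudy(st, "results/")` writes the descriptive tables (p-values
formatted "one-tailed (two-tailed)"), relative errors, CNR summaries and a
run manifest.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/tomomorph.R simulate --group aclt --n 2 --seed 1 --out sim/
Rscript inst/cli/tomomorph.R study --preset smoke --seed 1 --out results/
```

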