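---
title: "Band selection for intraoperative hyperspectral tissue classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band selection methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiband)
```

## The problem

Visible/near-infrared hyperspectral cameras capture hundreds of narrow
wavelength bands per pixel. For in-vivo brain tissue classification
(normal parenchyma, glioblastoma tumor, hypervascularized tissue,
surgical background) most of that spectral dimension is redundant or
noisy. Identifying a small subset of informative bands matters twice
over: it speeds up intraoperative classification, and it tells sensor
designers which wavelengths a cheaper, faster custom camera would need.

`hsiband` implements a wrapper band-selection pipeline around a support
vector machine: the candidate band subsets proposed by a metaheuristic
optimizer are scored by actually training and evaluating the classifier
on them, with a fitness that penalizes large subsets. Because no
clinical data ships with the package, a synthetic scene generator
provides labeled data with the statistical structure the pipeline
assumes, making every stage testable end to end.

## Preprocessing chain

1. **Radiometric calibration.** Raw counts become percent reflectance
   via `calibrate()`: $C = 100\,(R - D)/(W - D)$ with a white-tile
   reference $W$ captured under the operating illumination and a
   closed-shutter dark frame $D$. A zero $W - D$ anywhere is an error —
   it means the reference pair is unusable, not that the pixel is.
2. **Extreme-band removal.** The sensor's first and last bands are
   noise-dominated; `removeExtremeBands()` keeps the 440–902 nm
   operating window by default.
3. **Smoothing.** The spectral noise filter is a centered moving
   average (`smoothSpectra()`, default window 5 bands). Edge bands use
   shrinking windows so the band count is preserved. A moving average
   is the simplest order-preserving smoother; nothing in the method
   depends on the exact kernel.
4. **Per-pixel normalization.** `normalizePixels()` maps each pixel's
   spectrum onto $[0,1]$ by min–max scaling. This removes the
   brightness differences caused by the non-uniform tissue surface;
   classification then depends on spectral shape only. Constant
   (zero-range) pixels — dead sensors, saturated glare — are set to all
   zeros with a warning rather than erroring, since they occur in real
   cubes and should not abort a surgical pipeline.

**Sampling-interval decimation.** `decimateBands()` emulates a coarser
camera: `n` target wavelengths are placed at the midpoints of equal
intervals spanning the grid, and for each target the nearest existing
band is kept (ties toward the lower index, no band kept twice). We
decimate by wavelength spacing, not index stride, so the result is
well-defined on irregular grids; and we subsample rather than
block-average because the point is to emulate a sensor with fewer
bands, not to denoise.

## Training-set reduction

Wrapper selection retrains the SVM thousands of times, so the training
set is first reduced to balanced prototypes (`reduceTrainingSet()`):

* per class, seeded k-means with `kPerClass = 100` clusters (Euclidean
  distance);
* per centroid, the `pixelsPerCentroid = 10` class pixels with the
  smallest *spectral angle* to the centroid are kept.

With four classes this yields 4 × 100 × 10 = 4000 prototype pixels,
balanced across classes. The spectral angle (`spectralAngle()`) is
brightness-insensitive, which complements the min–max normalization.

Design choices worth recording:

* **Selection is without replacement** across centroids of a class
  (centroids processed in index order, nearest-angle-first). This
  guarantees the 1000-per-class quota consists of distinct pixels.
* **Candidates are drawn from the whole class**, not only a centroid's
  own cluster members — the aim is the most representative pixels of
  each class, and the angle ranking decides.
* **k-means initialization** uses 10 seeded random restarts
  (`stats::kmeans`, Hartigan–Wong). Restarts give the stability that
  matters here — determinism under the seed and insensitivity to a bad
  initialization; the specific initialization scheme does not.
* **Deficient classes** (fewer pixels than the quota) shrink their
  cluster count to `floor(n / pixelsPerCentroid)` with a warning, so
  the procedure stays total on small synthetic sets.
* The reduction runs inside each cross-validation fold, on the training
  patients only; the held-out patient never influences the prototypes.

## Metrics

All metrics derive from one-vs-rest confusion counts
(`confusionCounts()`, `classCounts()`):

* overall accuracy `overallAccuracy()`;
* per-class `sensitivity()` = TP/(TP+FN) and `specificity()` =
  TN/(TN+FP). Undefined ratios (empty denominators) are reported as
  `NA`, never coerced to 0;
* per-class Matthews correlation `mcc()` with the convention that a
  zero factor in the denominator gives 0, and its rescaling
  `mccNorm()` = (MCC+1)/2;
* the figure of merit `fom()`, a pairwise balanced accuracy:
  $$\mathrm{FoM} = \frac{1}{2}\left(\sum_{i<j}
  \frac{ACC_i + ACC_j}{|ACC_i - ACC_j| + 1}\right)\binom{n}{2}^{-1}$$
  Equal per-class accuracies give their mean; imbalance between any
  pair shrinks that pair's contribution. This is the fitness component
  that protects the clinically critical tumor class from being traded
  away for bulk accuracy;
* the penalized fitness `penalizedFitness()`:
  $(1-\mathrm{base})\,(1+\lambda/\lambda_{\max})$, minimized by the
  optimizers. The *product* form is the only reading under which the
  size term is a penalty — a quotient would reward more bands. With a
  perfect base metric the value is 0 for any subset size; exact ties
  are therefore broken toward the smaller subset wherever the
  optimizers compare candidates, which is the penalty's intent carried
  into comparisons.

## Optimizers

All three optimizers treat a candidate as a binary mask over the grid
and minimize the penalized wrapper fitness; fitness values are cached
by mask, and all-zero masks are repaired by activating one random band.

**Genetic algorithm** (`gaSelect()`): size-2 tournament selection,
k-point crossover (default 1 cut), single-bit mutation per child with
probability `mutationRate`, generational replacement with elitism, and
a stagnation stopping rule (`stoppingRule()`: stop when the best
fitness improved by less than `epsilon` over the last `patience`
generations). Initialization draws each band with probability
`initProb = 0.3`: the object of the search is a small subset, and a
sparse-biased start searches that region of the lattice first.

**Binary particle swarm** (`psoSelect()`): velocities follow
$v \leftarrow \alpha v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)$
with the conventional $c_1 = c_2 = 2$, inertia $\alpha = 0.72$ and a
velocity clamp at $\pm 4$. Positions are re-binarized every iteration
by the sigmoid-threshold rule: bit $b$ is set when a uniform draw falls
below $\sigma(v_b)$. This is the classical binary-swarm transfer; note
that under it a zero velocity means a *random* bit, not a frozen one,
so a fully degenerate configuration ($\alpha = c_1 = c_2 = 0$) performs
random search rather than freezing the swarm.

**Ant colony** (`acoRank()`) produces a full band *ranking* rather than
a subset. The published description of this stage is a sketch, so the
instantiation here is an ordinary pheromone model made explicit, not a
reproduction: ants build fixed-size subsets with selection probability
proportional to $\tau^{a} (\eta \cdot \rho)^{b}$, where $\tau$ is
pheromone, $\eta$ a per-band Fisher-ratio class-separability score
(normalized between-class over within-class variance), and $\rho$ a
redundancy discount, $1$ minus the mean absolute correlation with the
bands already chosen. Each subset is scored by the SVM wrapper on a
stratified 70/30 validation split of the training set and deposits
pheromone proportional to its accuracy; pheromone evaporates at a fixed
rate per iteration. The final ranking sorts bands by terminal pheromone
(ties by $\eta$, then index); `acoTopkEvaluate()` then evaluates the
top 20/40/60/80/100 ranked bands.

## Validation protocol

Everything is evaluated leave-one-patient-out (`makeFolds()`,
`evaluateLOPO()`): each fold trains on all patients but one and tests
on the held-out patient, so the reported numbers measure inter-patient
generalization. The SVM is linear with cost 1 by default — fast enough
to sit inside the wrapper loop, with no further feature scaling since
spectra are already in $[0,1]$. Kernel and cost are configurable; no
claim is made that these defaults reproduce any particular published
absolute accuracy.

One protocol point deserves emphasis. Read literally, the wrapper
procedure scores candidate subsets on the *test* patient, which leaks
test data into band selection. `runPF2()` therefore defaults to an
inner validation split: one training patient is held out of the
reduction and serves as the validation set for the fitness, and the
test patient is touched only once, by the final model. The literal
protocol remains available as `paperLiteral = TRUE` for comparison
studies.

Per-fold band subsets are aggregated by `computeLevels()` into
coincidence levels ($L_i$ = bands selected in at least $i$ folds;
nested by construction), re-evaluated with `evaluateLevels()`, and
summarized as contiguous wavelength ranges by `contiguousRanges()`
(gap tolerance 0 by default: only adjacent bands merge, which is what
printed range tables imply).

## The synthetic scene generator

`buildDefaultSignatures()` constructs class signatures over a grid
(default 440–902 nm, 128 bands — the pipeline's operating point) as
smooth logistic-ramp base curves minus Gaussian absorption dips at
540/560/580 nm: the oxygenated-hemoglobin double valley (540/580) and
the deoxygenated single valley (560). Hypervascularized tissue gets the
deepest valleys and tumor a distinct ramp and dip profile; the
background is a mixture of three distinct material spectra (drape,
metal, marker), which gives it the largest standard deviation — as one
observes for the heterogeneous background class in real operating-field
data.

Two dials control separability:

* `contrast` shrinks all class means *and* stdevs toward their common
  mean. At 1 a linear classifier generalizes across patients at ≥ 95%
  accuracy; at 0 the classes are exchangeable by construction and
  accuracy sits at chance (25% for four balanced classes). The stdevs
  must participate: with means collapsed but variances distinct, the
  nonlinear per-pixel normalization would turn variance differences
  into mean differences and the scene would not reach chance.
* `tumorContrast` interpolates the tumor mean between the normal curve
  and its own, for targeted tumor-detectability experiments.
  `generateDataset(..., zeroContrastPatient = p)` additionally draws
  one patient's tumor pixels from the normal signature and offset,
  emulating an acquisition in which the tumor is spectrally indistinct
  — useful for robustness tests of the selection stage.

Inter-patient variability is a smooth low-frequency offset per patient
and class (a random constant plus a half-period sinusoid, magnitude
`patientOffsetSd = 1.5` reflectance units on the 0–100 scale): enough
to make leave-one-patient-out genuinely harder than a random split,
small enough that max-contrast scenes remain separable. Pixels are the
class mean plus offset plus per-band Gaussian noise scaled by the class
stdev spectrum, clipped at zero.

`generateCube()` adds spatial structure (background border, rectangular
tumor blob with an unlabeled separation ring, vessel strips, optional
near-saturated glare pixels marked unlabeled) for map rendering and
I/O tests.

What the generator deliberately does **not** model: radiative transfer
or any optical physics, realistic spatial texture, wavelength-dependent
sensor noise, label noise at region boundaries. Passing tests on these
scenes therefore demonstrate that the pipeline's machinery is correct
and that its selection pressure works when informative bands exist —
not that any particular accuracy will transfer to clinical data.

## Numerical choices and problem sizes

* Default study conditions: 4 synthetic patients, 500 labeled pixels
  per class per patient, 128 bands, 2% glare in cubes.
* Stagnation: `patience = 20` iterations, `epsilon = 1e-6` (strict
  inequality: an improvement of exactly `epsilon` counts as progress).
* Optimizer defaults: GA population 50 over up to 100 generations; PSO
  30 particles over up to 100 iterations. The test-suite and
  demonstration runs use smaller budgets chosen to keep a full run on a
  single CPU interactive (e.g. GA population 24, up to 40 generations,
  with reduction at 25 clusters per class); on the default max-contrast
  scene these budgets already reach subsets of ~20% of the bands within
  half a point of full-band accuracy, so larger budgets buy nothing on
  synthetic data.
* Ties: k-point crossover cuts are drawn uniformly; decimation ties go
  to the lower band index; fitness ties to the smaller subset.
* Degenerate inputs: empty band masks are repaired, not rejected;
  constant pixels normalize to zeros with a warning; classes below the
  reduction quota shrink their cluster count with a warning; a
  singleton band subset is a legal (if weak) classifier input.

## Known limitations

* The ant-colony internals are an explicit, documented interpretation;
  published descriptions of this stage are too thin to reproduce
  exactly.
* The specificity formula as printed in the source literature for this
  family of metrics contains a known repetition of the accuracy
  formula; the standard TN/(TN+FP) definition is implemented.
* Linear-SVM defaults make no attempt to match unpublished classifier
  configurations; absolute accuracies on clinical data are out of
  scope.
* ENVI I/O supports the fields this pipeline writes (BIL, float32,
  wavelength list), not the full format zoo.
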