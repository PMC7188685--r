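# canalmorph

Ecological and auditory inference from the fossil inner ear.

The endosseous labyrinth is one of the few neurosensory structures that
survives fossilization in a quantitatively usable form. `canalmorph`
implements, as a tested R package plus a numbered analysis workflow, the
full inference chain used to read it:

1. **Hearing capability.** The pars inferior length (PI) is scaled to
   basicranium length (BC) and log-transformed,
   `x = log10(PI / BC)`, then mean best hearing frequency and best
   hearing range (Hz) are predicted from OLS regressions of extant
   hearing data on `x`.
2. **Ecology from canal shape.** Semicircular-canal centerlines are
   resampled into a 60-landmark scheme (20 per canal; endpoints fixed,
   interior semilandmarks slid along the curve to minimize
   thin-plate-spline bending energy), aligned by generalized Procrustes
   analysis, and projected into tangent-space principal components.
   Phylogenetic signal is measured with multivariate Blomberg's K on a
   consensus of occurrence-calibrated time trees; shape ~ ecology + size
   models are fit by permutation ANCOVA and phylogenetic generalized
   least squares (RRPP); and fossils are classified by canonical
   variates analysis with Mahalanobis typicality probabilities and
   log-likelihood group assignment.

A synthetic-data module generates labyrinth samples with controlled
Brownian-motion phylogenetic covariance and planted ecology effects, a
birth–death time tree with fossil occurrence records, and a
reference hearing table — so every stage runs and is tested without any
external data.

## Worked example

The hearing prediction for the champsosaur specimen CMN 8920, from the
published regression equations evaluated at its scaled log pars-inferior
length `x = -0.65698`:

```r
library(canalmorph)
freq  <- hearing_model(3391.3, 4026.8,  "mean_best_frequency")
range <- hearing_model(6190,   7003.193, "best_range")
bf <- predict(freq,  -0.65698)   # 1798.784
br <- predict(range, -0.65698)   # 2936.487
summarize_hearing(round(bf, 1), round(br, 1))
#> best hearing frequency 1798.8 Hz, range 2936.5 Hz (330.5-3267.1 Hz)
```

(The interval endpoints are 330.55 and 3267.05 Hz; the display rounds
each to 0.1 Hz.)

A best hearing frequency near 1.8 kHz with a range topping out near
3.3 kHz is a low-frequency hearing profile, consistent with an animal
lacking a tympanic ear and listening underwater.

## The analysis workflow

`analysis/` contains the pipeline as numbered scripts, run from the
repository root after installing the package:

```sh
Rscript analysis/01_simulate.R            # synthetic 61-specimen dataset
Rscript analysis/02_align.R               # slide, GPA, tangent-space PCA
Rscript analysis/03_phylogenetic_signal.R # time calibration + Blomberg's K
Rscript analysis/04_ecology_models.R      # permutation ANCOVA + PGLS
Rscript analysis/05_classify_fossils.R    # CVA, typicality, assignment
Rscript analysis/06_hearing.R             # hearing regression + prediction
```

Each stage prints what it found and writes tables under `results/`. On
the default synthetic dataset (seed 20) the run reports, among other
things: 33 PCs needed for 95% of shape variation; significant
phylogenetic signal in both centroid size and canal shape (K ≈ 0.7,
p ≈ 0.001 at 1000 permutations); a significant size term in the ANCOVA
and a significant ecology term in the PGLS; and assignment of the
held-out fossil to a specific ecology group with its typicality
probabilities against all groups.

Alternatively `run_pipeline()` executes every stage in one call on a set
of input files and is byte-reproducible for a fixed seed.

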