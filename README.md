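# fcmkl

Individualized prediction of motor (ALSFRS-R) and cognitive (MoCA) scores
from seed-based resting-state functional connectivity, for researchers
studying amyotrophic lateral sclerosis as a multi-network disorder.  The
package implements the full analysis chain around a sparse multiple kernel
learning (MKL) regressor: nuisance regression (realignment parameters +
derivatives, aCompCor tissue components, linear trend), ideal band-pass
filtering (0.01–0.1 Hz), spherical-ROI extraction, Fisher-z seed
connectivity (MPFC and PCC seeds to the SMN/DMN/FPN/SN nodes, 31 edges),
per-edge linear kernels plus one combined age/gender/mean-FD confound
kernel, nested leave-one-out / 5-fold cross-validation over the cost grid
`c(1e-4, …, 100)`, permutation significance tests, Meng's Z comparison of
dependent correlations, computational kernel-lesion analysis, and a
network-specificity comparison against a visual/auditory-extended node set.

The core estimator minimises the block-L1 MKL objective

    min_{f_1..f_M, b}  Σ_m ‖f_m‖_{H_m} + C Σ_i L_ε(y_i − Σ_m f_m(x_i) − b)

with the ε-insensitive loss, so that entire kernels — i.e. entire
connections — receive exactly zero weight and the surviving weights name
the predictive circuitry.  A synthetic-cohort generator with known
connectivity→behavior ground truth (n, T = 240, TR = 2 s, realistic score
scales, true measured-feature R² = 0.5) backs every statistical claim in
the test suite; see the methods vignette
(`vignettes/connectivity-mkl.Rmd`) for the model, the solver, all design
decisions and known limitations.

## Worked example

```r
library(fcmkl)

coh   <- generate_cohort(cohort_config(n_subjects = 40, rng_seed = 1))
fc    <- cohort_fc(coh)                      # denoise → band-pass → Fisher z
stack <- build_kernel_stack(fc, coh$confounds[, c("age","gender","mean_fd")])
print(stack)
#> kernel stack: 32 kernels, 40 subjects
#> CONFOUND:1  DMN:5  FPN:10  SMN:6  SN:10

loo  <- loo_fcmkl(stack, coh$scores$ALSFRS_R, rng_seed = 1, refit = TRUE)
print(loo)
#> nested LOO prediction (n = 40): r = 0.462, rMSE = 4.502
#> selected C per outer fold: 1 x 32, 10 x 7, 100 x 1

perm <- permutation_test(stack, coh$scores$ALSFRS_R, loo,
                         n_perm = 199, rng_seed = 1)
print(perm)
#> permutation test (199 permutations):
#>   r    = 0.462, p = 0.0150
#>   rMSE = 4.502, p = 0.0200

kc <- kernel_contributions(loo$model)
head(kc$kernel[order(-kc$kernel$weight), ], 4)
#>               label group    weight contribution
#> 21       PCC->dmPFC   FPN 15.624621   0.36001226
#> 1         MPFC->SMA   SMN  7.432466   0.17125400
#> 4  MPFC->L_parietal   DMN  5.264607   0.12130363
#> 6       MPFC->dmPFC   FPN  3.780301   0.08710322
```

The printed LOO `r` is the Pearson correlation between actual and
out-of-sample predicted scores, `rMSE` the root-mean-squared error in score
units, and the permutation p-values count (with add-one smoothing) how many
score-shuffled re-runs of the *entire* nested pipeline match the observed
performance.  In this cohort two of the three generatively informative edges
(`PCC->dmPFC`, `MPFC->SMA`) top the kernel-weight ranking, with chance-
correlated neighbours sharing the remainder -- at true R-squared 0.5 and
n = 40 this is the expected regime (see the vignette's discussion of the
statistical frontier).
`lesion_run()` removes whole kernel groups and quantifies the drop with
Meng's Z; `specificity_run()` compares the 31-edge model against the
39-edge visual/auditory-extended one; `holdout_fcmkl()` gives the single
train/test-split check.

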