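# microgen

Generative adversarial imputation of missing samples in longitudinal
microbiome studies.

Longitudinal cohorts sample each subject's microbiome at a series of
planned timepoints, but missed visits leave holes in the subject x
timepoint grid, and incomplete subjects are usually discarded. `microgen`
imputes the missing samples so the whole cohort stays usable. The imputer
is a phylum-aware bidirectional recurrent GAN:

* relative-abundance profiles are pseudo-counted (half the global minimum
  nonzero abundance) and centered-log-ratio (clr) transformed;
* taxa are grouped by phylum and ordered within each group by the
  geometric mean of absolute Spearman correlations, so a per-cluster 1-D
  CNN (kernel 3; 16 and 8 filters; LeakyReLU; max-pooling) can extract
  local features from correlated neighbours;
* a one-layer bidirectional tanh RNN predicts each timepoint from its
  past (forward) and future (backward) context; the two predictions are
  blended with trainable temporal-decay factors
  `lambda = exp(-ReLU(W delta + b))` computed from the forward/backward
  time gaps `delta`, and observed values always pass through exactly:
  `x_bar = x (*) e + x_tilde (*) (1 - e)`;
* an LSTM discriminator with a real/fake head and a timepoint-prediction
  head trains adversarially against the generator
  (`loss_G = lossG + lossR + lossC`, `loss_D = lossD + lossT`, Adam at
  1e-3, five discriminator iterations per generator update, early
  stopping on the generator-loss plateau).

The package also ships seven classical baseline imputers (mean, median,
linear, cubic, moving window, deterministic MICE, LOCF), a synthetic
longitudinal cohort simulator with MCAR/MAR/MNAR amputation, and an
evaluation suite (clr-scale MAE, Shannon/Bray-Curtis diversity
comparison, zero-preservation metrics, 10-fold benchmarking). The
numerical core (forward passes, backpropagation, Adam) is hand-written
RcppArmadillo; training a 30-subject cohort takes seconds.

## Worked example

```r
library(microgen)

# a synthetic infant-style cohort: 20 subjects, 8 timepoints, 40 taxa in
# 4 phyla, smooth AR trajectories with a shared cohort trend
spec     <- simulation_spec(n_taxa = 40, n_phyla = 4, n_timepoints = 8,
                            n_template_subjects = 20, seed = 42)
truth    <- generate_base_cohort(spec)
observed <- ampute(truth, missingness_spec("MCAR", rate = 0.25, seed = 42))
observed
#> microgen_dataset: 20 subjects x 8 timepoints x 40 taxa
#>   observed samples: 121 / 160 (24.4% missing)
#>   timepoints: 4, 7, 10, 13, 16, 19, 22, 25
#>   phyla: P1, P2, P3, P4

clr   <- clr_transform(add_pseudocount(observed))
model <- train_microgen(clr, tcfg = training_config(patience_epochs = 300,
                                                    max_epochs = 2000,
                                                    seed = 42))
model
#> microgen_model (variant 'full'): 12724 generator + 2139 discriminator parameters
#>   trained 386 epochs, best generator loss 14.0034 at epoch 86

imputed   <- impute_microgen(model, clr)
truth_clr <- clr_transform(add_pseudocount(truth))
mae_clr(truth_clr$clr_values, imputed$clr, observed$mask)
#> [1] 1.029
```

The clr-scale MAE of 1.03 over the 39 missing samples beats carrying the
last observation forward (1.17) and the within-subject mean (1.17) on the
same cohort, and sits level with linear interpolation (1.02). The
post-processed output is again compositional and preserves structural
zeros:

```r
ra <- postprocess_to_ra(imputed$clr, clr$pseudo_count)
zero_metrics(truth$abundances, ra, observed$mask)
#> $symdiff  [1] 266
#> $recall   [1] 0.354
```

A command-line front end wraps the same functions
(`Rscript $(Rscript -e 'cat(system.file("cli", "microgen.R", package="microgen"))')
simulate|train|impute|evaluate|benchmark ...`), writing TSV/JSON outputs
and a run manifest; every subcommand honours `--seed`.

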