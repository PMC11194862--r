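# dmtresponse

Personalized treatment-response prediction for relapsing-remitting multiple
sclerosis (RRMS) from registry-style longitudinal data.

Patients switching disease-modifying treatment (DMT) face a choice among
several drugs with heterogeneous individual benefit. Given registry tables
of EDSS assessments, relapse events and therapy episodes, this package
builds the full modelling pipeline around a treatment switch: it constructs
therapy cycles (including no-therapy gaps and overlapping-treatment
periods), derives the two effectiveness outcomes measured during the index
therapy — the on-therapy relapse count and confirmed disability progression
(CDP) — encodes eleven baseline predictors, and fits

* a **negative-binomial** model (log link, log-duration offset) for relapse
  counts, and
* a **binomial** model (logit link, log-duration covariate) for CDP,

each with a clinical-centre random intercept and treatment-by-covariate
interactions, so that predictions can be produced for every one of six
index DMTs (dimethyl fumarate, fingolimod, glatiramer acetate, interferon
beta1, natalizumab, teriflunomide) per patient:

```
relapse_count ~ NegBin( exp(x'B + u_centre + log d), phi ),   u_centre ~ N(0, sigma^2)
P(CDP)        ~ Bernoulli( logit^-1(x'B' + gamma log d + u'_centre) )
```

Evaluation follows the clinical-prediction-model playbook: a temporal
train/test split on the index start date (with training follow-up censored
at the last EDSS before the split to prevent leakage), 10-fold
cross-validation with out-of-sample predictions, 20-bin calibration curves
with recalibration intercept/slope, C-index with bootstrap CI, MSE and
RMSE%. A two-tier synthetic-registry generator with known ground truth
(analysis-ready cycles, and raw longitudinal tables with planted
progression trajectories) makes every stage testable without access to a
real registry. A Hanley–McNeil sample-size solver for C-index tests is
included.

The hierarchical fits use a Laplace approximation with Gaussian posterior
draws (no MCMC backend required); see the methods vignette
(`vignettes/methods.Rmd`) for the model, conventions, and limitations.

## Worked example

Simulate a registry, run the whole pipeline with the fixed-effects engine,
and rank the six DMTs for one test patient:

```r
library(dmtresponse)
cfg <- sim_config(n_patients = 2000, seed = 3)
res <- run_pipeline(pipeline_config(sim = cfg, cindex_B = 200, run_cv = FALSE))

m <- res$metrics$relapse_temporal
sprintf("relapse temporal: C %.3f MSE %.3f mean pred %.2f mean obs %.2f",
        m$c_index$estimate, m$mse, m$predicted$mean, m$observed$mean)
#> "relapse temporal: C 0.745 MSE 1.218 mean pred 0.64 mean obs 0.62"

predict_all_dmts(res$fits$relapse, res$test[1, ])[, c("index_dmt", "mean", "outcome_free", "rank")]
#>            index_dmt  mean outcome_free rank
#> 1  dimethyl fumarate 0.220        0.813    1
#> 2      teriflunomide 0.263        0.783    2
#> 3         fingolimod 0.272        0.777    3
#> 4        natalizumab 0.282        0.770    4
#> 5 glatiramer acetate 0.286        0.767    5
#> 6   interferon beta1 0.313        0.750    6
```

For this patient the model expects 0.22 relapses under dimethyl fumarate
over the observed follow-up, with an 81% chance of staying relapse-free —
the best-ranked option; interferon beta1 ranks last at 75%. The temporal
C-index of 0.745 says that of two random test patients with different
relapse counts, the model gives the higher prediction to the worse outcome
about three times in four. (Numbers are from the synthetic registry above
and will track the seed.)

The pipeline result also carries the participant flow log (`res$flowlog`,
one row per named filter with exact counts), calibration tables
(`res$metrics$*$calibration_bins`), and both fitted models.

## Command line

```sh
Rscript inst/cli/dmtresponse.R simulate   --out data/ --seed 7 --n-patients 2000
Rscript inst/cli/dmtresponse.R run-all    --out artifacts/ --seed 7
Rscript inst/cli/dmtresponse.R samplesize --c0 0.6 --c1 0.65 --prevalence 0.25
```

Subcommands: `simulate`, `preprocess`, `derive-outcomes`, `build-features`,
`fit`, `predict`, `validate`, `samplesize`, `run-all`.

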