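# qsarprofiler

Transparent application of QSA(P)R models — quantitative
structure–activity (property) relationships — to target chemicals, with
the reliability analysis that regulatory practice expects: prediction
intervals, structural and endpoint applicability domains (AD),
inverse-variance consensus averaging, Shannon-entropy uncertainty for
classifiers, and fingerprint-based neighbor detection. Models are
user-defined, exchanged as XML documents carrying their training data, and
organized into a group/subgroup registry; results are exported as
report-ready CSV tables suitable for compiling QSAR prediction reporting
format (QPRF) documentation.

The package is aimed at computational toxicologists and environmental
chemists who need to batch-apply many regression (MLR) and linear
discriminant (LDA) models and audit every number in the output.

## The statistics at the core

For an MLR model fitted on `n` training chemicals and `p` descriptors:

* prediction-interval halfwidth
  `σ = t(1−α/2, n−p−1) · s · √(1+h)` with
  `s = √(Σ(yₙ−ŷₙ)²/(n−p−1))` and leverage
  `h = x̃(X̃ᵀX̃)⁻¹x̃ᵀ` (intercept-augmented);
* structural AD: out when `h ≥ 3(p+1)/n`;
* endpoint AD: standardized residual `r′ = (y−ŷ)/(s√(1−h))` with a 2.5 SD
  rule, the training experimental range, and the training
  prediction-interval halfwidth range;
* consensus of N predictions: weights `wᵢ = 1/σᵢ²`, combined value
  `Σwᵢŷᵢ/Σwᵢ`, combined uncertainty `√(1/Σw)`.

For LDA classifiers: pooled-covariance posteriors, uncertainty
`−Σ pₖ log₂ pₖ` (bits), a cosine-similarity percentile rule for the
structural AD, and a posterior band (0.25, 0.75) for the endpoint AD.
Neighbor similarity uses Tanimoto, Dice or cosine indices over binary or
count fingerprints. The methods vignette
(`vignettes/qsar-profiling.Rmd`) documents every convention, boundary rule
and design decision.

## Worked example

Three synthetic example models ship with the package (two MLR, one LDA;
see `inst/extdata/`). Profile three target chemicals against all of them:

```r
library(qsarprofiler)
ext <- system.file("extdata", package = "qsarprofiler")
reg <- load_registry(file.path(ext, "registry.cfg"), quiet = TRUE)
targets <- read_smi_file(file.path(ext, "targets.smi"))
prof <- profile_chemicals(targets, reg, consensus = "all")
subset(prof$predictions, status == "ok")[, c("target_id", "model_id",
  "prediction", "uncertainty", "uncertainty_type", "in_ad")]
#>      target_id          model_id         prediction uncertainty uncertainty_type in_ad
#>  ethyl_acetate example-class-lda              light  0.53610394     entropy_bits  TRUE
#>  ethyl_acetate  example-logk-mlr 1.6896186485176969  0.32098086            sigma  TRUE
#>       p_cresol example-class-lda              heavy  0.01308711     entropy_bits  TRUE
#>       p_cresol  example-logk-mlr 2.0196574435242152  0.29209110            sigma  TRUE
#>         hexane example-class-lda              light  0.42341282     entropy_bits  TRUE
#>         hexane  example-logk-mlr 1.6570813796859698  0.32206072            sigma  TRUE
```

Each row is one (target, model) pair. MLR rows report the predicted
endpoint with its 95% prediction-interval halfwidth (`sigma`, model
units); LDA rows report the predicted class with its Shannon entropy in
bits (0 = certain, 1 = coin toss — ethyl acetate's 0.536 bits says the
weight-class call is genuinely uncertain, p-cresol's 0.013 bits is
near-certain). `in_ad` combines the structural and endpoint domain
verdicts; the third shipped model requires an externally supplied
descriptor and is reported as skipped with a machine-readable reason
rather than dropped. `prof$ad_details` holds the per-criterion numeric
evidence (leverage, cutoff, standardized residual, ranges), and
`prof$neighbors` the most similar training chemicals:

```r
m <- reg$models[["example-logk-mlr"]]
x <- as.data.frame(as.list(compute_descriptors(parse_smiles("CCCCCC"), m$specs)))
predict(m, x)
#>      value halfwidth      lwr      upr  leverage in_ad endpoint_in_ad structural_in_ad reasons
#> 1 1.657081 0.3220607 1.335021 1.979142 0.4341987  TRUE           TRUE             TRUE

head(subset(prof$neighbors, model_id == "example-logk-mlr" &
                            target_id == "hexane"), 3)
#>  target_id         model_id rank training_id training_smiles similarity y_experimental      y_predicted
#>     hexane example-logk-mlr    1 cyclohexane        C1CCCCC1  1.0000000         1.7409 1.52920110196768
#>     hexane example-logk-mlr    2     pentane           CCCCC  0.8333333         1.3421 1.37750087655008
#>     hexane example-logk-mlr    3      butane            CCCC  0.6666667         0.9874 1.09792037341419
```

Hexane sits well inside the model's structural domain (leverage 0.434
below the 0.571 cutoff) and its interval halfwidth lies inside the
training halfwidth range, so the prediction of 1.66 ± 0.32 log units is
reported as reliable; the nearest training neighbors with their measured
endpoints let an assessor sanity-check it against experiment.
`export_report(prof, "outdir", registry = reg)` writes the four CSV report
tables. A command-line front end with `profile`, `validate-model`, `fit`,
`neighbors`, `consensus` and `make-fixture` subcommands lives at
`inst/cli/qsarprofiler.R`.

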