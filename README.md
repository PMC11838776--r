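# tspoquant

Blood-free, reference-free quantification of dynamic TSPO PET.

TSPO (the 18 kDa translocator protein) is the workhorse PET target for
imaging neuroinflammation, and it is notoriously hard to quantify:
arterial blood sampling is invasive and fragile, no brain region is free
of specific binding (so there is no clean reference region), the rs6971
polymorphism splits subjects into high- and mixed-affinity binders, and
the signal carries large unexplained inter-individual variability.
`tspoquant` implements an analytical framework that avoids both blood and
reference-tissue modelling: a logistic regression model is trained to
separate brain regions with constitutively **low** TSPO expression from
regions with constitutively **high** expression, and the fitted
probability that a region belongs to the high class,

```
ln( p / (1 - p) ) = b0 + sum_j b_j X_j        ->   p_TSPO in [0, 1]
```

becomes the regional index of neuroinflammatory load. The features `X_j`
are the regional SUV time-activity curve sampled on a sparse grid
(1.25, 4.5, 13.5, 30, 50, 75 min), the regional delivery rate `K1`
(mL/cm^3/min) estimated non-invasively from an image-derived input
function with a single irreversible compartment, and subject covariates
(age, sex, binding class, dose over weight), all min-max normalized with
persisted bounds. A per-dataset random intercept (hierarchical logistic
regression, Laplace ML) absorbs scanner/protocol batch effects;
bootstrap-stabilised stepwise selection (100 subject-level resamples,
features kept above 80% selection frequency) prunes the predictor set.

The package is aimed at PET methodologists: it covers TAC and NIfTI ROI
extraction I/O, IDIF selection and tri-exponential fitting, forward
compartmental simulation, the K1 stage, model fitting/prediction,
selection, a full evaluation battery (ROC/AUC, relative-probability
histograms and `Delta_P`, Wilcoxon tests, test-retest ICC(A,1),
expression-map concordance, BH-FDR), a rat LPS variant with a hemispheric
TAC-AUC screen, and synthetic cohort generators so that the entire
pipeline is testable without clinical data.

## Worked example

Train on a synthetic three-dataset healthy-control cohort (72 + 27 + 26
subjects, 25 regions), quantify the cortex-and-cerebellum (CC) domain,
and contrast a "disease" cohort generated with +30% binding:

```r
library(tspoquant)

coh <- generateCohort(cohortConfig(seed = 11))
k1  <- estimateCohortK1(coh$tacs, coh$inputs, window = 4)
tr  <- trainTspoModel(coh$tacs, k1, coh$expressionMap, seed = 42)

tr$selection
#> SelectionReport: 100 bootstrap iterations, threshold > 0.8
#>           tac_50           tac_75         genotype              sex
#>             1.00             1.00             1.00             0.95
#>              age         tac_13.5 dose_over_weight          tac_4.5
#>             0.79             0.75             0.20             0.16
#>           tac_30         tac_1.25               K1
#>             0.08             0.06             0.06
#> retained: tac_50, tac_75, sex, genotype

tr$model
#> Hierarchical logistic model for p_TSPO
#>      (Intercept)  tac_50  tac_75    sex genotype
#> coef    -18.4707 35.2891 27.4854 2.0854  -7.0932
#> se        3.6346  8.6071  7.5041 0.7548   1.2892
#> z        -5.0819  4.1000  3.6627 2.7628  -5.5022
#> deviance: 70.9058  null: 1346.02  converged: TRUE
#> random intercept sd: 4.432 over 3 datasets

auc(tr$roc)                       # held-out low/high classification
#> [1] 0.9997333
```

Late TAC samples carry positive weight (high late uptake marks the
high-expression class), and the mixed-affinity (MAB = 0) genotype
coefficient is strongly negative, as binding-affinity biology dictates.
Mean CC `p_TSPO` tracks the generating regional expression pattern, and
the +30% binding cohort shifts probability mass above 0.5:

```r
cc  <- coh$roster$roi_id[coh$roster$cc]
pHC <- predictPtspo(tr$model, tr$design[tr$design$roi_id %in% cc, ])
expressionConcordance(pHC, coh$expressionMap)$rho
#> [1] 0.8077922

dis <- generateCohort(cohortConfig(nSubjects = c(ds1 = 20L),
                                   datasetOffsets = c(ds1 = 0),
                                   bindingScale = 1.3, seed = 12))
ctl <- generateCohort(cohortConfig(nSubjects = c(ds1 = 20L),
                                   datasetOffsets = c(ds1 = 0), seed = 14))
pOf <- function(x) {
  k <- estimateCohortK1(x$tacs, x$inputs, window = 4)
  d <- buildDesign(x$tacs, k, labels = coh$expressionMap,
                   bounds = tr$bounds)
  predictPtspo(tr$model, d[d$roi_id %in% cc, ])
}
deltaP(pOf(dis)$p_tspo, pOf(ctl)$p_tspo)
#> GroupComparison (rank-sum): n_case=420 n_control=420
#>   Delta_P = +11.7%  p = 2.52e-05
```

`Delta_P` is the percent excess relative probability of `p_TSPO > 0.5`
in the case cohort versus controls; its sign flips exactly under cohort
swap, so a blocking scan (reduced binding) yields a negative value.

A thin command-line front end over the same functions ships in
`inst/cli/tspoquant.R` (subcommands `simulate`, `train`, `predict`,
`rat`), and the methods vignette
(`vignettes/tspo-quantification-methods.Rmd`) documents the model,
parameter choices and the synthetic generator's scope.

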