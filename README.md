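# confmet

Confidence scoring and false discovery rate estimation for small-molecule
structure annotation from tandem mass spectrometry.

## The problem

Untargeted metabolomics annotates compounds by searching fragmentation
spectra against structure databases with in-silico scorers. The raw score
of the best candidate (the *hit*) ranks candidates within one query well,
but it cannot tell *across* queries which hits are correct: incorrect hits
can score high and correct hits low, and for many queries the true
structure is not in the database at all. `confmet` is for computational
metabolomics researchers and tool builders who need to order annotations
by trustworthiness, report how many hits survive at a given false
discovery rate, and evaluate such confidence measures rigorously.

## The method

The confidence score combines two layers:

1. **Kernel-density E values.** For a hit with log-score $y$ and proxy-decoy
   log-scores $y_1,\dots,y_n$ (candidates from a very large background
   database, the hit excluded), with Silverman bandwidth
   $h = 1.059223841\,\hat\sigma\,n^{-1/5}$,

   $$E = \frac{m}{n}\sum_{i=1}^n\Big[\tfrac12 -
     \tfrac12\,\mathrm{erf}\Big(\frac{y-y_i}{\sqrt2\,h}\Big)\Big],$$

   the expected number of the $m$ target-database candidates scoring at
   least as high by chance; $P = E/m$.

2. **A sign-constrained linear SVM with Platt scaling.** Standardized,
   capped hit features (raw score, calibrated score $-\log_{10}E$, score
   gap to the runner-up, log candidate count, explained intensity, ...)
   enter an $\ell_2$-regularized squared-hinge linear SVM whose weights are
   forced to respect pre-declared directions (a high hit score may only
   increase confidence). The constraint is imposed by augmenting one
   synthetic positive sample per feature with value $\pm\beta$
   ($\beta = 10^7$). Decision values are mapped to $(0,1)$ by the Platt
   sigmoid $1/(1+\exp(Af+B))$. Separate models serve each collision energy
   (10/20/40 eV, merged) and the single-candidate regime.

Ordering hits by confidence and treating one minus the confidence as a
posterior error probability $p_j$ gives the FDR/q-value estimate
$\widehat{\mathrm{FDR}}_k = \frac1k\sum_{j\le k}p_j$. Evaluation utilities
include exact FDR, ROC curves, and hop plots (TP/N vs FP/N, endpoint on
$x+y=1$), plus a spectral noise model for emulating biological-quality
spectra and exact maximum-common-edge-subgraph (MCES) and Tanimoto
structure comparison. See `vignette("confidence-scoring")` for the full
account.

## Worked example

```r
library(confmet)
set.seed(1)

# synthetic labeled training data standing in for reference measurements
train <- gen_hit_dataset(1500, seed = 11)
tr <- train[train$n_candidates > 1, ]
model <- train_directional_svm(tr[, default_feature_schema()$name],
                               tr$correct, collision_energy = 20)
print(model)
#> confidence_model (multi regime, CE 20): C = 0.001, A = -5.641, B = -0.04307
#>               hit_score        calibrated_score     score_gap_runner_up
#>                 0.30171                 0.30606                 0.18364
#>      log_num_candidates     explained_intensity fingerprint_cardinality
#>                -0.16173                 0.16825                 0.06518
#>              tree_score     fingerprint_quality
#>                 0.04107                 0.02177
```

Every weight obeys its declared direction — note the negative weight on
the candidate count (more candidates mean a harder query) and positive
weights everywhere else. Scoring fresh data and asking how many
annotations survive at 5% and 10% exact FDR:

```r
test <- gen_hit_dataset(500, seed = 22)
te <- test[test$n_candidates > 1, ]
conf <- confidence_score(model, te[, default_feature_schema()$name])
hits <- ranked_hits(conf, correct = te$correct, posterior_error = 1 - conf)
round(roc_curve(hits)$auc, 3)
#> [1] 0.973
fdr_threshold_report(hits, c(5, 10))
#>   fdr_level n_hits n_correct threshold
#> 1         5    231       220 0.6290945
#> 2        10    264       238 0.3423121
```

So at 10% exact FDR, 264 of the 451 multi-candidate queries are reported
(238 of them correct) above a confidence threshold of 0.34. The
calibration layer on its own:

```r
ss <- score_sample(hit_score = 210, decoy_scores = rlnorm(50, 4, 0.6),
                   m = 391855)
c(E = e_value(ss), P = p_value(ss))
#> E = 3198   P = 0.008162
```

A hit score of 210 against these 50 proxy-decoy scores corresponds to
about 3,198 of the 391,855 target-database candidates expected to reach it
by chance — an unremarkable hit despite the seemingly large raw score.

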