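# draphnet

Bilinear affinity regression linking drug molecular profiles to disease
genetics, to predict and explain binary drug–phenotype associations.

## The problem

Drugs have unexpected effects on disease — harmful side effects, but also
repurposing opportunities — and these effects plausibly arise from the
drug's molecular activities propagating to the genes that drive disease
risk. Three data sources describe the pieces: in-vitro assay panels score
each drug against hundreds of biological endpoints (a drugs × endpoints
matrix **D** of hit fractions, with many untested cells); transcriptome-wide
association studies score each gene's regulated expression against each
phenotype (a genes × phenotypes matrix **G** of signed z-scores); and
pharmacovigilance catalogues record known drug–phenotype associations (a
binary drugs × phenotypes matrix **Y**, side effects or indications).

draphnet ties the three together with a supervised bilinear model

```
logit P(Y[i, j] = 1) = b0 + D[i, ] %*% W %*% G[, j]
```

where **W** (endpoints × genes) is the interaction network of interest.
Both feature spaces are compressed — `D ≈ U_D S_D V_D'` by soft-thresholded
iterative SVD with missing data (SoftImpute), `G = U_P S_P V_P'` by
truncated SVD — and the reduced interaction matrix
`W_DP = V_D' W U_P S_P` is estimated by lasso logistic regression using
the Kronecker/vec trick: `logit P(Y=1) = b0 + (U_D S_D) W_DP V_P'`.

Fitted models are interpreted through the **phenome effect matrix**
`U_D S_D W_DP` and the **disease genome matrix**
`(U_D S_D W_DP) S_P^-1 U_P'`, with per-entry significance from a
permutation null (refit on shuffled Y, same inputs) with
Benjamini–Yekutieli correction, hypergeometric target–gene enrichment,
and a drug–drug network connecting pairs whose significant disease genes
overlap more than a weighted-sampling null expects, categorised by
maximal cliques.

The package is for computational drug-repurposing / pharmacogenomics
researchers who have matrices shaped like the above (ToxCast-, PhenomeXcan-
and SIDER-style) or want to study the method itself; a planted-truth
simulator makes every step testable without external downloads.

## Worked example

```r
library(draphnet)

sim <- simulateData(simConfig(seed = 1))   # 120 drugs, 400 genes, 40 phenotypes
dec <- softImpute(sim$endpoints, rank = 4, lambda = 0.1)
gd  <- decomposeGeneMatrix(sim$genes, rP = 4)
fit <- fitAffinity(drugFactors(dec), gd, sim$assoc, l1Strength = 0.005)
fit
#> AffinityModel (side_effects): 120 drugs, 40 phenotypes, 400 genes; r_D = 4,
#> r_P = 4, l1 = 0.005, 7/16 nonzero in W_DP

ev <- cvEvaluate(dec, sim$genes, sim$assoc, rD = 4, rP = 4,
                 l1Strength = 0.005, nFolds = 20, binarize = "topk", seed = 2)
round(ev$auc, 3)
#> [1] 0.841
signif(ev$rankSumP, 3)
#> [1] 8.5e-06
```

The held-out AUC of 0.841 says the model ranks true drug–phenotype pairs
above negatives for drugs it never saw during fitting; the rank-sum p-value
says its predicted association sets sit closer (in Jaccard distance) to the
truth than the nearest-neighbour-in-factor-space baseline, so the learned
interaction matrix adds information beyond raw profile similarity. The
premise behind the model can be checked directly:

```r
ds <- drugPairSimilarity(sim$endpoints, sim$assoc, nPerm = 500, seed = 2)
round(ds$spearman, 3); signif(ds$permutationP, 3)
#> [1] 0.213
#> [1] 0.002
```

— drug pairs with more correlated endpoint profiles share more phenotype
associations. Downstream interpretation:

```r
res  <- diseaseGenomeTest(fit, sim$assoc, nPerm = 199, seed = 6)
sets <- significantGenes(res, alpha = 0.05)
net  <- buildNetwork(drugGeneSets(sets), pThreshold = 0.05,
                     nSim = 1000, seed = 7)
```

See the methods vignette (`vignettes/draphnet-methods.Rmd`) for the model,
its assumptions, parameter meanings, and known limitations — in
particular, how rank truncation limits per-gene resolution of the
disease-genome projection.

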