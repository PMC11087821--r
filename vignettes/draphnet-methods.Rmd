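---
title: "Methods: bilinear affinity regression from drug biology to disease genetics"
author: "draphnet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilinear affinity regression from drug biology to disease genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(draphnet)
```

## The model

draphnet links two molecular feature spaces through a supervised bilinear
model. The inputs are three matrices:

* **D** (drugs x assay endpoints): real-valued hit-fraction scores from
  in-vitro screening panels (ToxCast-style Level 5 summaries). Most drugs
  are assayed for only a fraction of the endpoints, so D carries an
  observation mask.
* **G** (genes x phenotypes): signed z-scores measuring the association of
  genetically regulated expression of each gene with each phenotype
  (PhenomeXcan-style S-MultiXcan statistics with the consensus per-tissue
  direction). G is complete.
* **Y** (drugs x phenotypes): binary known drug–phenotype associations
  (SIDER-style side effects or indications; one model per polarity).

The working hypothesis is that a drug's effect on a phenotype arises from
its molecular effects propagating to the phenotype's genetic drivers. The
model expresses this as a bilinear logistic regression

$$\operatorname{logit} P(Y_{ij} = 1) \;=\; \beta_0 + D_i \, W \, G_{\cdot j},$$

where \(W\) (endpoints x genes) is the interaction network of interest.
Because \(W\) is far too large to estimate directly, both feature spaces
are compressed: \(D \approx U_D S_D V_D^\top\) by soft-thresholded
iterative SVD (`softImpute()`, which handles the missing entries), and
\(G = U_P S_P V_P^\top\) by a plain truncated SVD
(`decomposeGeneMatrix()`). The model is then fitted in the reduced space,

$$\operatorname{logit} P(Y = 1) = \beta_0 + (U_D S_D)\, W_{DP}\, V_P^\top,
\qquad W_{DP} = V_D^\top W\, U_P S_P,$$

with \(W_{DP}\) (r_D x r_P) estimated by L1-penalised logistic regression.
The fit uses the vec/Kronecker identity
\((V_P \otimes U_D S_D)\,\mathrm{vec}(W_{DP}) =
\mathrm{vec}(U_D S_D\, W_{DP}\, V_P^\top)\): every (drug, phenotype) pair
becomes a row of an expanded design matrix (`buildDesign()`), the labels
are \(\mathrm{vec}(Y)\), and glmnet's lasso-logistic solver does the rest
(`fitAffinity()`). The vec convention is column-major throughout, with the
drug index varying fastest.

An orientation note: the gene-major matrix G (genes x phenotypes) is
decomposed with \(U_P\) on the gene side and \(V_P\) on the phenotype
side. This makes the gene-space projection below dimensionally consistent.

### Projections

Fitted models are interpreted through two projections:

* the **phenome effect matrix** \(U_D S_D W_{DP}\) (`phenomeEffect()`),
  each drug's compressed effect profile over the phenotype factor space;
* the **disease genome matrix**
  \((U_D S_D W_{DP})\, S_P^{-1} U_P^\top\) (`diseaseGenome()`), each
  drug's inferred effect on every disease-associated gene.

Under truncation \(U_P^\top U_P = I\) but \(U_P U_P^\top \neq I\), so the
gene-space matrix is the minimum-norm preimage of the phenome effect; the
package asserts consistency only in the composed direction
\(\text{genome} \cdot U_P \,\mathrm{diag}(S_P) = \text{phenome}\).

### Permutation significance

Whether a drug–gene connection is meaningful is judged against an
empirical null: the entries of \(\mathrm{vec}(Y)\) are shuffled (the
association density is preserved, all drug and phenotype structure is
broken), the model is refitted with the same configuration and the *same*
D and G, and the refit is projected to gene space (`nullEnsemble()`;
"rows" and "columns" permutation modes are available since the choice is
a design degree of freedom). Two-sided empirical p-values use an add-one
correction, \(p = (1 + \#\{|null| \ge |true|\})/(n_{perm} + 1)\), so they
are strictly positive, and are adjusted per drug across its genes with
the Benjamini–Yekutieli step-up (`byAdjust()`), which controls FDR under
the strong dependence the shared fitted model induces. The reference
analysis scale is 10,000 permutations; desk-scale runs here use 99–199,
which bounds the attainable p at 1/(n_perm+1).

### Enrichment and the drug–drug network

Given per-drug significant gene sets, `targetGeneEnrichment()` asks for
each drug target (shared by at least three drugs) whether the target's
drugs are enriched for drugs associated with each gene: an upper-tail
hypergeometric test with BH adjustment within target.
`permutedTargetCalibration()` repeats this with drugs randomly reassigned
to targets (sizes preserved) to show the true targets carry more signal
than chance. `buildNetwork()` connects drug pairs sharing more
significant genes than a weighted-sampling null expects — random gene
sets are drawn without replacement with probability proportional to how
many drugs a gene is associated with, resampling the drug of the pair
with the smaller set — and `findCliques()` retrieves all maximal cliques
of at least three drugs as the categorisation units.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rank`, `lambda` (`softImpute`) | data-driven via `cvSelect()` | truncation rank and soft-threshold of the endpoint decomposition; chosen by hiding 5% of observed cells and minimising imputation MSE. On the full-scale reference data the documented operating point is rank 246, lambda 0.34. |
| `rD`, `rP`, `l1Strength` (`fitAffinity`) | tuned via `tuneAffinity()` | truncation ranks of the two decompositions and the lasso penalty. `l1Strength` is glmnet's lambda (penalty on the mean log-loss). Documented full-scale operating points: indications r_P = 131, r_D = 95, penalty 1; side effects r_P = 197, r_D = 246, penalty 0.1. At the simulation scale used here, ranks 4/4 with `l1Strength = 0.005`. |
| `nFolds` | 10 (tuning), 20 (evaluation) | drug-held-out folds; tuning holds out 10% of drugs per fold, evaluation approximates leave-one-drug-out with 5% per fold. The two procedures are deliberately separate and separately configurable. |
| `nPerm` | 100 (API), 10,000 (reference scale) | permutation count for the disease-genome null. |
| `alpha` | 0.05 | per-drug q-value cutoff for significant gene sets (the target-enrichment display threshold is q < 0.01). |
| `pThreshold`, `nSim` | 0.05, 1000 | nominal edge significance and Monte-Carlo draws for the drug–drug network. |

Design choices where the method description leaves room:

* **Intercept**: included by default. Association matrices are ~10% dense;
  without an intercept the base rate would have to pass through
  \(W_{DP}\), distorting the interaction estimate.
* **Held-out drug factors** come from the SoftImpute decomposition of the
  *full* endpoint matrix. D is unsupervised input — only association rows
  are ever held out — so this leaks no label information.
* **Binarisation for the Jaccard comparison**: thresholding probabilities
  at 0.5 is the default, but at realistic association densities almost
  all probabilities sit below 0.5 and predicted sets degenerate to empty.
  The model-vs-baseline comparison therefore supports
  `binarize = "topk"`, taking each drug's top-k phenotypes with k the
  size of the nearest neighbour's association set, which makes the two
  predictions size-matched; this mode is used in the package's own
  evaluation runs.
* **Tie-breaks**: consensus tissue signs tie toward +1 (option:
  the most significant tissue's sign); variance filtering keeps
  `ceiling(f * n)` genes with SD ties broken by input order; nearest
  neighbour distance ties break by drug id. All for determinism.
* **p-value clipping**: gene p-values of exactly 1 would map to an
  infinite quantile; they are clipped to the largest double below 1
  (magnitudes are symmetric in p about 0.5, so this equals the magnitude
  at p = 1e-16). The lower clip is 1e-300.

## The synthetic-data generator

`simulateData()` emulates the statistical structure of the real inputs
from a planted ground truth: a low-rank drug factor matrix squashed
through the logistic map to hit-fraction scale (rank 4 + Gaussian assay
noise, sd 0.25, 20% of cells masked), a low-rank signed gene–phenotype
matrix scaled to z-score-like spread (sd 2), a sparse ±1 interaction
matrix W scaled so the association logits have sd 2, and
\(Y \sim \mathrm{Bernoulli}(\sigma(DWG + \beta_0))\) with \(\beta_0\)
bisected to a SIDER-like 10% density. Targets are groups of five drugs
sharing a latent endpoint component, with planted gene sets read off the
interaction rows of that component's endpoints. The defaults — 120 drugs,
200 endpoints, 400 genes, 40 phenotypes — are the package's reference
study conditions; all randomness flows from one master seed with
per-matrix sub-streams.

What the generator does **not** emulate: tissue-level structure behind
the consensus signs, realistic assay panel correlation structure,
reporting biases in the association catalogue, and the incompleteness of
the "negative" labels (a 0 means *not recorded*, not *absent* — true of
the real data too, but the generator's 0s are genuine absences). Passing
tests on synthetic data therefore demonstrate correctness of the
machinery and recoverability of planted structure, not performance on
real pharmacovigilance data.

## Numerical choices and known limitations

* `softImpute()` initialises missing cells at 0 (the scores are centred
  hit fractions; mean-initialisation is a flag), converges on the
  relative Frobenius change of the reconstruction (tol 1e-5), and tracks
  the penalised objective, which is non-increasing. Components shrunk to
  zero are dropped: downstream code must use the returned rank.
* glmnet is called with `standardize = FALSE` and a tight threshold
  (1e-10) so the factorized fit agrees with an explicitly expanded
  regression to 1e-6; rank-1 designs are padded with a zero column to
  meet glmnet's two-column minimum.
* Per-pair network seeds derive from the global seed and the sorted id
  pair via a small string hash, so the network is independent of drug
  input order and parallelisable.
* **Gene-identity resolution is limited by the truncation.** The
  disease-genome scores equal \((DW)\,U_P U_P^\top\): the planted sparse
  gene support is smeared through a rank-r_P projection, so individual
  support genes are only identifiable when r_P is an appreciable
  fraction of the gene count (the package's tests recover \(DW\) exactly
  when \(U_P\) is square). At reference scale (10,027 genes, r_P ~ 200)
  per-gene calls should be read as pointers into correlated gene
  neighbourhoods, not pinpoint identifications.
* **Permutation p-values within one analysis are strongly dependent**:
  all drug–gene entries are functions of the r_D x r_P fitted
  parameters. Calibration is therefore checked by pooling entries across
  independent global-null realisations; within one data set the
  empirical distribution of p-values need not look uniform even when the
  test is exact.
* The BY adjustment combined with the add-one p-value floor means small
  significant sets are unreachable at low permutation counts: at
  m genes per drug, q < alpha requires several jointly small p-values.
  Interpret desk-scale significance counts accordingly.

## Problem sizes used in the package's own runs

Unit tests run on 15–60 drug simulations; the evaluation and acceptance
runs use the 120-drug reference configuration with 20-fold drug-held-out
cross-validation, 199 permutations for the disease-genome null, 99
permutations x 4 independent realisations for the calibration check, and
1000 Monte-Carlo draws per network edge. These sizes were chosen so a
complete run is comfortable on a laptop while keeping every statistical
check well-powered.
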