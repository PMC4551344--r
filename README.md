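# PDACsig

Survival-signature discovery, hypoxia scoring and collagen texture analysis
for pancreatic cancer cohorts.

Resectable pancreatic ductal adenocarcinoma (PDAC) shows wide variation in
outcome that is partly encoded in the tumor transcriptome and in the
architecture of its collagen-rich stroma. PDACsig packages, as one tested
Bioconductor-style pipeline, the analysis machinery used to connect the
two: it discovers a PCA-metagene survival signature from a bulk expression
cohort, applies it as a per-sample risk score to new cohorts (including
cross-species, e.g. mouse tumors scored with a human signature), builds and
scores a hypoxia meta-signature from curated gene-set collections, tests
gene sets for over-representation, provides the supporting survival
statistics, and quantifies fibrillar collagen in second harmonic generation
(SHG) image stacks by gray-level co-occurrence (GLCM) texture decay. All
stages are exercisable on built-in synthetic data generators, so the entire
pipeline is testable without downloads.

It is intended for computational biologists analyzing survival-annotated
expression cohorts, and for imaging groups quantifying fibrillar matrix
texture.

## The methods in brief

**Screening.** Each transcript is scored with the FAST statistic — for
standardized expression $z_g$, the Cox partial-likelihood score at
$\beta = 0$ scaled by $1/n$:

$$ s_g = \frac{1}{n}\sum_{i:\,\delta_i=1}\big(z_{gi} -
   \bar z_{g,R(t_i)}\big), \qquad R(t) = \{j: t_j \ge t\}. $$

Two-sided significance comes from a permutation test that jointly permutes
(time, event) against samples, sharing one permutation stream across all
transcripts; transcripts are selected when the local false discovery rate
of their p-value — estimated by a Grenander (least-concave-majorant)
density with the null proportion taken from the flat tail — is below 0.15.

**Metagenes.** Selected transcripts are row-centered and decomposed by
PCA. Each component is oriented so that higher score means higher hazard
(positive FAST statistic of its sample scores), then split into a
*hazardous* set (oriented loading > 0) and a *protective* set. Components
are evaluated by leave-one-out cross-validation of the entire pipeline,
including re-screening in every fold.

**Scoring.** A cohort is risk-scored by standardizing each matched
signature transcript across samples, multiplying by the oriented loading
and summing per sample. The hypoxia meta-signature is the set of genes in
strictly more than 20% of the "HYPOXIA"-named sets of a collection, scored
per sample by the first principal axis with the sign anchored so the VEGFA
weight is positive.

**Enrichment and statistics.** Hypergeometric over-representation with
Benjamini–Yekutieli correction; Kaplan–Meier curves with median survival,
log-rank, Yates-corrected chi-square on 2×2 tables, Mann–Whitney U,
Spearman correlation.

**Collagen texture.** Maximum projection → Otsu mask → symmetric GLCMs
restricted to in-mask pixel pairs, over 4 directions and offset distances
1–100 px → five Haralick parameters per offset → double-exponential fit
$A_1 e^{-d/\lambda_1} + A_2 e^{-d/\lambda_2} + c$ of each
direction-averaged curve → the **weighted mean decay distance**
$(A_1\lambda_1 + A_2\lambda_2)/(A_1+A_2)$, a scalar fibrillar-texture
score, plus area percent and depth-resolved foreground profiles.

The methods vignette (`vignettes/pdac-signatures-methods.Rmd`) documents
the models, defaults, numerical choices and what the synthetic generators
do and do not emulate.

## Worked example

Discover a signature on a simulated 73-patient cohort with a planted
hazard factor, stratify the cohort by risk tertiles and compare survival:

```r
library(PDACsig)

cohort <- generateSurvivalCohort(nSamples = 73, nGenes = 2000,
                                 nSignatureGenes = 300,
                                 hazardCoefficient = 1, seed = 1)
cohort
#> ExpressionCohort: 2000 features x 73 samples
#>   survival: median time 9.8, 50 events / 73 samples

disc <- discoverSignature(cohort, keepFraction = 0.5, nPerm = 2000,
                          seed = 1)
disc$model
#> SignatureModel: component 1 with 152 transcripts
#>   hazardous: 66  protective: 86  orientation: 1
#>   training: nSelected=152  varianceExplained=0.6722  scoreStatistic=0.466

truth <- cohortTruth(cohort)
sel <- signatureLoadings(disc$model)
length(intersect(names(sel), truth$signatureGenes)) /
    length(union(names(sel), truth$signatureGenes))
#> [1] 0.4967

st <- stratifyScores(riskScore(cohort, disc$model), "tertile")
grp <- scoreStrata(st); keep <- grp != "mid"
logrankTest(survTime(cohort)[keep], survEvent(cohort)[keep], grp[keep])
#> $chisq 23.15   $df 1   $p 1.49e-06

kmEstimate(survTime(cohort)[grp == "high"],
           survEvent(cohort)[grp == "high"])$median   # 5.1 months
kmEstimate(survTime(cohort)[grp == "low"],
           survEvent(cohort)[grp == "low"])$median    # 86.1 months
```

The pipeline selected 152 transcripts, about half of them members of the
planted 300-gene signature (Jaccard 0.50 against the ground truth stored
in the cohort's metadata), and split them into hazardous and protective
sets. Risk-tertile stratification separates survival sharply (log-rank
p ≈ 1.5 × 10⁻⁶; median survival 5.1 vs 86.1 months in the high- vs
low-risk tertile of this simulation).

Texture analysis of a synthetic SHG-like stack:

```r
stack <- generateShgStack(width = 160, height = 160, depth = 1,
                          fiberCount = 25, correlationLengthPx = 6,
                          areaFractionTarget = 0.25, seed = 7004)
tp <- analyzeStack(stack, distances = 1:48, levels = 16, seed = 7004)
areaPercent(tp)                            # 25.0
meanDecayDistance(tp)[["correlation"]]     # 10.9 px
```

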