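---
title: "Methods: fuzzy rule matrices, collinearity collapse and network fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy rule matrices, collinearity collapse and network fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbfuse)
```

## The problem

Post-pipeline microbiome tables (samples × taxa, counts or processed
floats) resist ordinary regression modelling for three reasons: excess
zeros make likelihoods and log-ratio transforms fragile; taxonomic nesting
and ecological linkage make many columns (nearly or exactly) collinear, so
coefficients are unstable or aliased; and class effects are small relative
to between-sample dispersion. `mbfuse` addresses the three in sequence and
then anchors the data-driven result in literature-derived taxon
co-occurrence, producing per-taxon priority scores rather than hypothesis
tests.

## Stage 1: Takagi–Sugeno rule inference

The outcome labels are encoded `1..K` in lexicographic order (the order is
a convention; it only needs to be fixed) and appended to the abundance
matrix. For every column of the augmented matrix, `num_labels` Gaussian
membership functions are placed with means equally spaced over the
observed `[min, max]`; the shared standard deviation is
`spacing / (2 * sqrt(2 * log(2)))`, the unique width at which adjacent
Gaussians cross at membership 0.5 — a neutral choice that leaves no gaps
and no term dominance. Constant columns get a single degenerate always-on
term rather than failing, so downstream column indexing is stable.

Rules are generated one per training sample: each variable contributes its
maximum-membership term (a value exactly between two means resolves to the
lower index, deterministically), and the rule degree is the product of the
sample's memberships. Candidates sharing an antecedent — including those
that would disagree about the output term — collapse to the
highest-degree candidate. Rule count therefore never exceeds the sample
count, and duplicated samples strictly reduce it; this deduplication is
the mechanism by which "effective samples" can drop below the sample
count.

Consequents are first-order linear functions trained by hybrid learning:
a global linear least-squares solve over all rule consequents on the
row-normalised firing strengths, alternating with one damped gradient step
on the premise means and sigmas. The least-squares pass is optimal for the
current premise, and a premise step is only accepted when it does not
increase the training error (step halving, at most 8 times), so the error
recorded after successive least-squares passes is non-increasing by
construction. Firing strengths are normalised in log space (softmax
style), which makes predictions invariant to common rescaling and immune
to underflow with many input variables; if every rule's absolute strength
still falls below `1e-300`, prediction falls back to the nearest rule by
antecedent-mean distance with a warning. A singular consequent system —
the normal case when `rules × (features + 1)` exceeds the sample count —
falls back to a ridge-stabilised solve with regulariser
`1e-8 × mean(column sum of squares)`.

The product handed downstream is the integer rule matrix (term indices,
one row per rule, final *effective label* column) together with its
auto-scaled copy. The learned consequents matter for `predict()` but not
for the downstream stages. Whether the discretisation damages the
correlation structure is measured, not assumed:
`correlation_preservation()` reports the maximum absolute difference
between the two Pearson correlation matrices, and the acceptance suite
bounds it at 0.25 on a fixed-seed fixture with two latent-correlation-0.9
blocks of five features at n = 200 (observed values sit well below the
bound).

**Defaults.** `num_labels = 7`, `max_iter = 10`, `step_size = 0.01` — the
documented defaults of the fuzzy-rule learning tradition this follows,
exposed in `pipeline_config()`. The stage has no random element;
reproducibility comes from the deterministic least squares and fixed
iteration count.

## Stage 2: DBSCAN collapse with the aliased-coefficient stopping rule

Features — columns of the auto-scaled rule matrix — are the points,
under Euclidean distance, so that highly correlated features are near one
another (for unit-variance columns, `d² = 2(n−1)(1−r)`). With
`minpts = 2` DBSCAN reduces exactly to connected components of the
eps-neighbourhood graph on non-isolated points; the test suite checks this
equivalence against a union-find oracle on random instances.

Epsilon is not a free parameter: the grid `1, 1.5, …, max term index`
is walked upward, and each candidate clustering is accepted only when the
collapsed design (with intercept) has no *aliased* columns. Aliasing is
operationalised as sequential rank deficiency — column `j` is flagged when
its residual after projection on the preceding accepted columns falls
below `1e-7` times the largest column norm seen — which is precisely the
mechanism that yields `NA` coefficients in a GLM fit, made deterministic
and family-independent. The logistic regression itself (binomial for two
classes, multinomial otherwise) is fitted once at the accepted epsilon and
returned for diagnostics; fitting it at every grid point would not change
the decision, because the rank check alone determines it. If the grid is
exhausted without clearing the aliasing (for example, a constant feature
whose scaled column is identically zero), the final grid value is returned
with a warning rather than an error, so partial results remain usable.

Clusters collapse to `Σ loading_i × column_i` where the loading is the
first principal-component direction of the centred (not re-standardised —
the columns are already auto-scaled) cluster block, computed by SVD. The
loading has unit norm and its largest-magnitude entry is flipped positive;
this sign convention is arbitrary but fixed, and ties resolve to the first
entry. A zero-variance cluster falls back to the uniform loading
`1/√k` with a warning. Noise features pass through verbatim with loading
1, so provenance exactly partitions the original features.

## Stage 3: adaptive-LASSO scores

Cluster scores minimise
`‖y − Σ_j x_j β_j‖² + λ Σ_j w_j |β_j|`, with the quadratic term exactly
as written (no 1/2 factor — the soft-threshold constant in the orthonormal
closed form is therefore `λ w_j / 2`, and the analytic acceptance test is
written against that convention). The response is the auto-scaled
effective-label column treated as continuous, matching the squared-error
objective even for multi-class outcomes; the design is the auto-scaled
clustered matrix, and the model carries no intercept (both sides are
centred). Pilot weights are the absolute coefficients of an unpenalised
linear fit of `y` on the design — ridge-stabilised with a tiny regulariser
when the system is wide or singular — floored at `1e-6` so the rescaling
stays finite. The weighted problem is solved by the rescaling trick
(`x̃_j = x_j / w_j`, plain LASSO via glmnet with tight convergence
thresholds, `β_j = β̃_j / w_j`); λ comes from k-fold cross-validation
(`k = 10`, seeded fold assignment) at the minimum-CV-error value — the
1-SE rule is deliberately not used, as the score magnitudes themselves,
not a parsimonious support, are the product. Note a consequence of
defining the penalty weights as `|pilot coefficient|` (rather than its
inverse): when the outcome association is weak relative to the dimension,
cross-validation can legitimately settle on the null model and report
all-zero scores; the scores are then honest "nothing to prioritise"
output.

Feature scores are `cluster_score × loading`, so singletons inherit their
cluster score unchanged. Score distributions are summarised with
moment-based, non-excess estimators (`skewness = m₃/m₂^{3/2}`,
`kurtosis = m₄/m₂²`), the convention consistent with kurtosis values far
above 3 for a spiked score distribution; constant scores report 0 for both
with a warning.

## Stage 4: name conversion and network fusion

Mixed-level names strip the rank prefix and any qualifier after the base
clade token (`f__Myxococcales.0319.6G20` and `s__Myxococcales.sp` both
become `Myxococcales`). OTU ids resolve through a mothur-style taxonomy to
the deepest classified rank, unclassified ranks falling back to the
nearest classified ancestor. Species-level spellings that need database
normalisation are handled by a user-supplied synonym vector — the exact
normalisation used by enrichment databases is not derivable from first
principles, so it is left user-editable rather than guessed.

Enrichment results are consumed as a flat file (study id, disease,
semicolon-joined members) rather than a live web query, which keeps the
module deterministic and testable; the disease filter is a
case-insensitive substring match. Node size is the study-occurrence count,
edge weight the co-occurrence count, and the adjacency matrix carries
occurrences on its diagonal — so co-occurrence can never exceed either
occurrence. Cluster infusion adds nothing for clusters whose members all
map to one name, ignores clusters with no member in the network, and
otherwise adds missing members as size-1 nodes plus `cluster`-origin edges
of weight 1 (the display convention's "red" edges become a categorical
`edge_origin`/`in_cluster` attribute; an existing enrichment edge keeps
its weight and gains the mark). Infusion is idempotent. Node scores are
plain means of member feature scores; nodes with no scored members keep
`NA` and are flagged. GraphML export writes `NA` scores as `NaN` (GraphML
has no missing-value notion) and the importer maps them back.

## The synthetic fixtures

`simulate_abundance()` draws latent Gaussians, maps them through
`Poisson(exp(mu_log + sigma_log·z))` (defaults 3.5 and 0.8, i.e. median
counts ≈ 33 with roughly one-decade dispersion), and zero-inflates with a
detection-limit mechanism: the zero probability equals `sparsity`
(default 0.3) at the median latent abundance and rises as abundance falls,
`plogis(qlogis(sparsity) − z)`. This reflects how zeros arise in real
surveys — rare organisms drop below the detection limit — and means
presence/absence carries part of any abundance signal, as it does in real
data.

Collinear blocks come in two flavours. *Copy blocks* (the default three
blocks of five) are exact scaled replicates of one base count profile with
shared zeros. This emulates mixed-rank taxonomic nesting: when a clade is
tabulated at several ranks and is the only member of its parent, the
columns are exactly proportional — which is also the only collinearity
that survives term discretisation and can trigger the aliased-coefficient
rule, since approximate correlation is destroyed by binning. *Latent
blocks* (`copy = FALSE`) share a Gaussian factor at correlation `rho` and
are used where approximate collinearity is wanted, e.g. the
correlation-preservation fixture. The signal block's latent means are
shifted per class across `[−effect_size, +effect_size]`; the default
`effect_size = 2` latent standard deviations makes the designated block
genuinely drive the outcome, which is what a recovery fixture must
guarantee — with the penalty-weight convention above, a much weaker signal
is legitimately absorbed into the null model.

What the generator does **not** emulate: compositional closure (no
total-sum constraint), phylogenetic correlation beyond the blocks,
overdispersion beyond log-normal mixing, or batch structure. Passing the
recovery tests therefore shows the pipeline's mechanics work under the
assumed pathologies, not that it will rank taxa correctly in any given
real survey.

Problem sizes in the shipped tests and acceptance script — 200 × 60
end-to-end runs over ten seeds, 100-instance clustering oracles,
50-instance LASSO oracles — were chosen as the smallest sizes at which
the checked properties are stable.

## Known limitations

- The epsilon search reacts only to exact rank deficiency; features that
  are merely highly correlated (but not aliased) are clustered only if
  they fall within the selected epsilon, which with the default grid
  requires very high term-scale correlation.
- The anti-oracle penalty-weight convention (weights proportional to pilot
  coefficients) is kept because it is the displayed objective of the
  method this package implements; users wanting classical adaptive-LASSO
  behaviour can pass inverse pilot weights to `adaptive_lasso()`
  directly.
- Rule-matrix learning is O(rules × samples × features) per pass and the
  consequent solve is ridge-regularised whenever `rules × (features+1)`
  exceeds the sample count — normal for wide tables, but it means the
  fitted consequents are not unique there (the inferred matrix is
  unaffected).
- The fusion stage prioritises only among taxa present in the supplied
  enrichment results; it cannot surface associations absent from the
  literature input.
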