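# dtilink

Drug–target interaction (DTI) link prediction from similarity-network
embeddings, for computational chemogenomics and drug-repurposing work.

Experimentally mapping which small molecules bind which proteins is slow and
expensive; most of the drug × target matrix is simply unknown. `dtilink`
predicts the missing links from two cheap side-channels — chemical similarity
between drugs and sequence similarity between proteins — under the guilt-by-
association premise that similar drugs tend to hit similar targets.

## Method

The pipeline has four stages:

1. **Similarity networks.** Drugs are encoded as 166-bit structural-key
   (MACCS) fingerprints and compared with the Tanimoto coefficient
   `T(A,B) = |A∩B| / |A∪B|`, giving the weighted drug–drug network
   `M_DDS`. Proteins are compared by pairwise alignment (Smith–Waterman,
   BLOSUM62, affine gaps by default), normalised as
   `s(a,b) = S(a,b) / sqrt(S(a,a)·S(b,b))`, giving the protein–protein
   network `M_PPS`.
2. **Node embedding (node2vec).** Each network is explored with
   second-order biased random walks: from edge `(t, v)` the walk steps to
   `x` with probability proportional to `w(v,x)·α`, where `α = 1/p` if
   `x = t`, `α = 1` if `x` neighbours `t`, and `α = 1/q` otherwise. Walks
   are treated as sentences and node vectors `V ∈ R^n` (default `n = 100`)
   are learned by skip-gram with negative sampling (unigram^0.75 noise).
3. **Link classification.** A candidate pair `(d, t)` is represented by the
   `2n`-vector `[V_drug(d); V_protein(t)]` and classified by a
   gradient-boosted tree ensemble (max depth 4, subsample 1, min child
   weight 2, gamma 0.8; learning rate chosen by grid search). Evaluation
   follows a 90/10 internal/external split with 5-times-repeated stratified
   10-fold internal cross-validation: the best fold model (by internal-test
   f-beta) per repeat is applied once to the external set, and precision,
   recall, f-beta, AUPR and AUC are reported. f1 is used when negatives are
   experimentally validated inactives; f2 (recall-weighted) when negatives
   are sampled from unknown pairs.
4. **Repurposing.** The final model, refit on all labelled pairs, scores
   every unknown pair; candidates are pairs with probability ≥ 0.99 whose
   drug is approved (clinical phase 4).

A synthetic-data module generates fingerprint clusters, mutated sequence
families and a planted cluster-by-family interaction structure with label
noise, so the whole pipeline is testable without downloads.

## Worked example

```r
library(dtilink)

spec         <- fixture_spec(seed = 1)          # 60 drugs / 4 clusters, 50 proteins / 3 families
compounds    <- gen_compounds(spec)
proteins     <- gen_proteins(spec)
interactions <- gen_interactions(spec, compounds, proteins)

result <- run_dti_pipeline(
  compounds, proteins,
  interactions[c("drug_id", "target_id", "activity", "activity_flag", "label")],
  pipeline_config(seed = 1)
)
result$cv
#> <dti_cv> 5 repeat(s), 10 folds | beta = 1
#>   external auc       0.9409 (sd 0.0057)
#>   external aupr      0.9568 (sd 0.0040)
#>   external fbeta     0.9158 (sd 0.0114)
#>   external precision 0.9485 (sd 0.0237)
#>   external recall    0.8854 (sd 0.0043)
```

The external rows are the honest numbers: metrics on the 10% of pairs that
never took part in training, grid search or model selection. Here the
pipeline recovers the planted cluster-by-family interaction structure from
noisy fingerprints and mutated sequences with external AUC 0.94 and recall
0.89. `tidy(result$cv)` returns the per-repeat/fold metric tibble,
`glance(result$cv)` a one-row summary, and `autoplot(result$cv)` the metric
spread; `score_unknown_pairs()` + `filter_candidates()` turn the final
model into a ranked repurposing candidate table.

A command-line front end for the file-based workflow
(`similarity` / `embed` / `dataset` / `train` / `predict` / `simulate`) is
installed at `inst/cli/dtilink.R`.

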