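---
title: "Predicting drug-target interactions from similarity-network embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions from similarity-network embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dtilink` treats drug-target interaction (DTI) prediction as supervised
link prediction on a bipartite graph whose two node sets are described only
indirectly, through intra-set similarity networks. The working assumption
is the guilt-by-association principle of chemogenomics: structurally
similar drugs tend to bind similar proteins. The pipeline therefore never
looks at a drug-protein pair directly; it looks at where the drug sits in
the drug-drug similarity network, where the protein sits in the
protein-protein similarity network, and lets a classifier learn which
regions of that joint space interact.

Four stages, each exposed as ordinary functions over tibbles:

1. **Similarity networks.** Drugs are 166-bit structural-key (MACCS)
   fingerprints; pairwise similarity is the Tanimoto coefficient, so the
   drug network's weights are set-overlap fractions in [0, 1]. Proteins
   are compared by pairwise sequence alignment; the raw optimal score
   `S(a, b)` is normalised by the geometric mean of the self-scores,
   `S(a, b) / sqrt(S(a, a) * S(b, b))`, which maps it to [0, 1], makes it
   symmetric, and makes self-similarity exactly 1.
2. **node2vec embedding.** Second-order random walks with return bias `p`
   and in-out bias `q` sample neighbourhoods of each network; skip-gram
   with negative sampling turns co-visited nodes into nearby vectors.
3. **Gradient-boosted link classification** on the concatenated pair
   vector, under a repeated, stratified, externally held-out
   cross-validation protocol.
4. **Candidate extraction**: the refit final model scores all unknown
   pairs, and high-confidence pairs involving approved drugs are reported
   as repurposing candidates.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `embedding_dim` (n) | 100 | dimension of each node vector; pairs become `2n`-vectors. 100 is the standard choice for preserving network neighbourhoods at these graph sizes. |
| `p`, `q` | 1, 1 | walk biases; at 1/1 walks are first-order (weight-proportional). The reference defaults of the embedding literature; tune only with evidence. |
| `walks_per_node`, `walk_length` | 10, 80 | corpus budget per node (dimensionless); the word2vec-style trainer needs tens of visits per node for stable vectors. |
| `window`, `negatives`, `epochs`, `learning_rate` | 10, 5, 5, 0.025 | skip-gram hyperparameters, reference defaults; the learning rate decays linearly to 1e-4 of its start. |
| `activity_threshold` | 5.5 pChEMBL | pChEMBL is -log10 of molar activity, so 5.5 is about 3 uM; at or above it a measured pair is a positive. Strictly between 0 and the threshold the pair is "weak" and excluded from both training and the unknown set - weak binders are neither convincing positives nor negatives. |
| `external_fraction`, `folds`, `repeats` | 0.1, 10, 5 | evaluation geometry: one stratified external draw, then repeated stratified internal folds. |
| `max_depth`, `subsample`, `min_child_weight`, `gamma` | 4, 1, 2, 0.8 | boosted-tree settings. "gamma" is the split-regularisation penalty of the tree ensemble, not a learning rate; the learning rate is a grid dimension (default grid {0.1, 0.3}) because a shrinkage fixed at 0.8 would be far outside sensible boosting practice. |
| `probability_threshold` | 0.99 | candidate cutoff on the predicted probability. A cutoff of 0.0099 would pass essentially every pair and defeat ranking, so the package reads "0.99" as a probability, configurable. |
| `beta` | 1 or 2 | f-beta selection metric: 2 (recall-weighted) when negatives are randomly sampled unknowns - false positives are then unreliable, so precision is down-weighted; 1 when negatives are experimentally validated inactives. |

## Numerical and design choices

* **Tanimoto of two all-zero fingerprints is defined as 1** (both
  featureless, hence indistinguishable), avoiding 0/0; the case is logged
  because featureless compounds are usually an upstream problem.
* **Alignment defaults**: local (Smith-Waterman) mode, BLOSUM62, affine
  gap penalties -10 open / -0.5 extend, i.e. a gap of length L costs
  10 + 0.5·L score units - the long-standing defaults of R's pairwise
  alignment tooling. The ambiguity residue `X` scores 0 against
  everything, a neutral treatment that neither rewards nor punishes
  unknown residues. All of this sits behind `alignment_scoring()`.
* **Similarity graphs are kept complete** (no sparsification by default):
  the walk generator consumes edge weights directly, so weak edges are
  rarely walked anyway, and thresholding would add a parameter with no
  principled default. `sparsify()` is available when a cutoff is wanted.
* **The unit diagonal is not an edge.** Self-similarity is a normalisation
  convention, not connectivity; random walks that could rest in place
  would waste corpus budget, so walks ignore the diagonal.
* **Determinism**: every stochastic stage (walks, skip-gram, sampling,
  splitting, boosting) draws a named child seed from the master seed
  (`child_seed()`), is single-threaded, and reproduces bit-identical
  output under the same seed. The skip-gram trainer carries its own
  integer RNG rather than relying on C++ library distributions, whose
  stream is implementation-defined.
* **Node identity, not insertion order**: walk generation and vocabulary
  construction index nodes by sorted id, so permuting the input rows
  cannot change any node's vector.
* **Symmetry is exact by construction**: pairwise similarity is computed
  once per unordered pair and mirrored, so matrices are symmetric to zero
  error rather than to rounding error. On disk, similarity matrices carry
  six decimals; embeddings are written at full double precision.
* **Matrix read tolerance**: input similarity matrices may be asymmetric
  up to 1e-8 (they are symmetrised as `(M + t(M))/2`); larger asymmetry
  or entries outside [0, 1] abort with coordinates.
* **Replicate activity measurements** for the same pair are reduced to
  their median before labelling - robust to the occasional discordant
  assay; an explicit `inactive` flag always wins over an activity value,
  and the number of such conflicts is reported.
* **Cross-validation is over pairs** (warm start): a drug or protein may
  appear on both sides of a split, matching the evaluation protocol the
  pipeline implements. Cold-start splitting is a different question and
  out of scope.
* **Final model rounds**: the refit on all labelled pairs has no held-out
  set for early stopping, so it reuses the median early-stopped round
  count of the fold models.

## What the synthetic generator does and does not emulate

`fixture_spec()` plants exactly the structure the method assumes:
fingerprint clusters (a 166-bit prototype per cluster, members flipped
bitwise at 5%), sequence families (a random ancestor per family, sites
substituted at 5%), and an interaction probability that depends only on
the (cluster, family) block - 0.9 within a matched block, 0.05 elsewhere,
with 2% label noise. Every drug cluster is matched to one protein family
(wrapping around when there are more clusters than families): leaving a
cluster unmatched would make its drugs carry no recoverable signal and cap
the recall of *any* method on the planted structure, which would measure
the generator rather than the pipeline.

The defaults - 60 drugs in 4 clusters, 50 proteins in 3 families of
120-residue sequences - are the reference conditions for the package's
end-to-end validation; they are small enough for a complete repeated-CV
run in tens of seconds yet large enough that external test sets hold ~200
pairs. Positives receive a synthetic pChEMBL uniform in (5.5, 10) and
negatives an `inactive` flag, so the labelling rules are exercised on the
way through.

What passing on these fixtures shows: the full chain - similarity,
embedding, feature concatenation, classification, selection, external
evaluation - recovers block-structured association from noisy data,
end to end, deterministically. What it does not show: performance on real
chemistry. Real fingerprints are not independent bit flips around
prototypes, real protein families differ in length and domain structure,
real bioactivity is assay-dependent and biased toward studied targets, and
real interaction matrices are far sparser than 25% positive blocks.
Numbers on fixtures are evidence of correctness, not of field performance.

## Problem sizes in the test-suite and acceptance runs

The end-to-end checks run the default fixture (60 x 50, ~2,000 balanced
pairs after labelling, 100-dimensional embeddings, 5 x 10-fold CV) across
five seeds; oracle-equivalence checks run Tanimoto against bit-set
arithmetic (hundreds of random pairs), alignment against an independently
written affine-gap dynamic program (sequences up to length 12, both
modes), and the evaluation metrics against exhaustive confusion-matrix,
pair-counting and Riemann constructions (hundreds of random instances).
These sizes were chosen so the whole suite completes in minutes on one
core while keeping Monte-Carlo bands (3 sigma) tight enough to catch real
bias - the walk-frequency check, for instance, pools thousands of
conditioned transitions.

## Known limitations

* MACCS fingerprinting of SMILES requires Open Babel via
  ChemmineR/ChemmineOB; precomputed fingerprint tables avoid the
  dependency entirely.
* Dense similarity graphs make walk generation O(|V|) per step; the
  implementation is comfortable at hundreds to a few thousand nodes,
  which covers the datasets this method targets, but would need sparse
  neighbour lists beyond that.
* The probability scores of boosted trees are not calibrated; the 0.99
  candidate cutoff is a ranking device, not a calibrated confidence.
* Only pair-level (warm) generalisation is evaluated by default; claims
  about unseen drugs or unseen targets would need the cold-split option
  and different embeddings.
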