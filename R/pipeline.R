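#' Run the full DTI link-prediction pipeline
#'
#' Convenience wrapper over the whole method: build (or accept) the
#' drug-drug and protein-protein similarity graphs, embed each with
#' node2vec, label the interaction table, assemble the labelled pair set
#' (balancing classes either by down-sampling validated negatives or by
#' sampling negatives from unknown pairs), concatenate link features, split,
#' and run the repeated cross-validation protocol. All stage seeds are
#' children of `config$seed`.
#'
#' @param compounds Compound tibble with fingerprints (or structures —
#'   fingerprints are computed when missing), or `NULL` when `dds` is given.
#' @param proteins Protein tibble, or `NULL` when `pps` is given.
#' @param interactions Interaction tibble.
#' @param config A [pipeline_config()].
#' @param dds,pps Optional precomputed [similarity_graph()]s, bypassing the
#'   similarity stage.
#' @param negatives `"validated"` uses inactive-flagged records (balanced by
#'   down-sampling when `balance` is `TRUE`); `"sampled-unknown"` draws
#'   negatives uniformly from pairs with no known interaction, one per
#'   positive.
#' @param balance Balance classes 1:1, default `TRUE`.
#' @return A list of class `"dti_pipeline"`: `dds`, `pps`, `drug_embedding`,
#'   `protein_embedding`, `labelled`, `pairs`, `features`, `split`, `cv`
#'   (a `dti_cv`), and `config`.
#' @export
run_dti_pipeline <- function(compounds = NULL, proteins = NULL, interactions,
                             config = pipeline_config(),
                             dds = NULL, pps = NULL,
                             negatives = c("validated", "sampled-unknown"),
                             balance = TRUE) {
  negatives <- match.arg(negatives)
  if (is.null(dds)) {
    compounds <- fingerprint_compounds(compounds)
    dds <- drug_similarity_matrix(compounds)
  }
  if (is.null(pps)) {
    pps <- protein_similarity_matrix(proteins)
  }
  emb_d <- embed_graph(dds, config)
  emb_p <- embed_graph(pps, config)
  labelled <- assign_labels(interactions, config$activity_threshold)
  if (negatives == "validated") {
    pairs <- labelled_pairs(labelled, balance = balance,
                            seed = child_seed(config$seed, "balance"))
  } else {
    pos <- labelled[labelled$label == "positive", c("drug_id", "target_id")]
    pos$label <- 1L
    pos$provenance <- "positive"
    unknown <- enumerate_unknown_pairs(node_ids(dds), node_ids(pps), labelled)
    neg <- sample_negative_pairs(unknown, nrow(pos),
                                 seed = child_seed(config$seed, "negatives"))
    pairs <- dplyr::bind_rows(pos, neg)
  }
  features <- build_features(pairs, emb_d, emb_p)
  split <- make_cv_split(pairs$label,
                         external_fraction = config$external_fraction,
                         folds = config$folds, repeats = config$repeats,
                         seed = child_seed(config$seed, "split"))
  spec <- classifier_spec(max_depth = config$max_depth,
                          subsample = config$subsample,
                          min_child_weight = config$min_child_weight,
                          gamma = config$gamma,
                          n_estimators = config$n_estimators,
                          learning_rate = config$classifier_learning_rate,
                          seed = child_seed(config$seed, "classifier"),
                          grid = config$grid %||% list())
  beta <- config$beta
  if (is.null(beta) && negatives == "sampled-unknown") beta <- 2
  cv <- run_cv(features, split, spec, beta = beta)
  structure(list(dds = dds, pps = pps,
                 drug_embedding = emb_d, protein_embedding = emb_p,
                 labelled = labelled, pairs = pairs, features = features,
                 split = split, cv = cv, config = config),
            class = "dti_pipeline")
}

#' @export
print.dti_pipeline <- function(x, ...) {
  cat("<dti_pipeline>", nrow(x$dds), "drugs,", nrow(x$pps), "proteins,",
      nrow(x$pairs), "labelled pairs\n")
  print(x$cv)
  invisible(x)
}
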