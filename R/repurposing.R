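#' Score unknown drug-target pairs
#'
#' Applies the final model to every unknown pair and returns predictions
#' sorted by score descending, ties broken by (drug_id, target_id) so the
#' ranking is fully deterministic.
#'
#' @param model A `trained_link_model`.
#' @param unknown_pairs Tibble with `drug_id`, `target_id`.
#' @param drug_embeddings,protein_embeddings `node_embedding` matrices.
#' @param threshold Probability threshold for the hard `predicted_label`.
#' @return A tibble `rank`, `drug_id`, `target_id`, `score`,
#'   `predicted_label`.
#' @export
score_unknown_pairs <- function(model, unknown_pairs, drug_embeddings,
                                protein_embeddings, threshold = 0.5) {
  if (nrow(unknown_pairs) == 0) {
    return(tibble::tibble(rank = integer(), drug_id = character(),
                          target_id = character(), score = numeric(),
                          predicted_label = integer()))
  }
  fs <- build_features(unknown_pairs[c("drug_id", "target_id")],
                       drug_embeddings, protein_embeddings)
  p <- predict(model, fs)
  out <- tibble::tibble(drug_id = unknown_pairs$drug_id,
                        target_id = unknown_pairs$target_id,
                        score = as.numeric(p),
                        predicted_label = as.integer(p >= threshold))
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$drug_id,
                        .data$target_id)
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}

#' Filter ranked predictions into repurposing candidates
#'
#' Keeps predictions with probability at least `min_score` and, when
#' `require_phase` is set, whose drug has reached that clinical phase
#' (phase 4 = approved). Drugs without a phase annotation are treated as
#' unknown and excluded when a phase is required. The incoming ranking is
#' preserved.
#'
#' @param predictions Tibble from [score_unknown_pairs()].
#' @param annotations Tibble `drug_id`, `max_clinical_phase` (integer 0-4).
#' @param min_score Probability cutoff, default 0.99.
#' @param require_phase Required clinical phase (typically 4), or `NULL` for
#'   no phase filter.
#' @return The filtered candidate tibble with a `drug_phase` column.
#' @export
filter_candidates <- function(predictions, annotations = NULL,
                              min_score = 0.99, require_phase = 4) {
  stopifnot(min_score >= 0, min_score <= 1)
  out <- predictions[predictions$score >= min_score, , drop = FALSE]
  if (!is.null(annotations)) {
    stopifnot(all(c("drug_id", "max_clinical_phase") %in% names(annotations)))
    bad <- annotations$max_clinical_phase[!is.na(annotations$max_clinical_phase)]
    if (any(!bad %in% 0:4)) stop("max_clinical_phase must be in 0..4")
    out <- dplyr::left_join(out, annotations[c("drug_id", "max_clinical_phase")],
                            by = "drug_id")
    out <- dplyr::rename(out, drug_phase = "max_clinical_phase")
  } else {
    out$drug_phase <- NA_integer_
  }
  if (!is.null(require_phase)) {
    out <- out[!is.na(out$drug_phase) & out$drug_phase == require_phase, ,
               drop = FALSE]
    if (nrow(out) == 0) {
      warning("no candidate passes the phase-", require_phase, " filter")
    }
  }
  out
}

#' Targets lacking approved-drug interactions
#'
#' Splits the targets of a labelled interaction table into (a) targets with
#' at least one known positive interaction but none involving a phase-4
#' (approved) drug, and (b) targets with no known positive interaction at
#' all — the cases where a predicted repurposing candidate is most valuable.
#'
#' @param known_table Labelled interaction tibble.
#' @param annotations Tibble `drug_id`, `max_clinical_phase`.
#' @return A list with character vectors `no_approved_drug` (a) and
#'   `no_known_positive` (b), plus `with_approved_drug` for completeness.
#' @export
targets_without_approved_drugs <- function(known_table, annotations) {
  pos <- known_table[known_table$label == "positive", ]
  phase <- stats::setNames(annotations$max_clinical_phase, annotations$drug_id)
  all_targets <- unique(known_table$target_id)
  pos_targets <- unique(pos$target_id)
  has_approved <- unique(pos$target_id[
    !is.na(phase[pos$drug_id]) & phase[pos$drug_id] == 4
  ])
  list(
    with_approved_drug = sort(has_approved),
    no_approved_drug = sort(setdiff(pos_targets, has_approved)),
    no_known_positive = sort(setdiff(all_targets, pos_targets))
  )
}
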