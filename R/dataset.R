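#' Label interaction records from activity values and flags
#'
#' Applies the activity-threshold labelling rules to a drug-target
#' interaction table: a record flagged `inactive` is negative (an explicit
#' inactive flag wins over any activity value; conflicts are counted and
#' reported); otherwise an activity at or above `activity_threshold` (pChEMBL
#' scale) is positive; an activity strictly between 0 and the threshold is
#' `weak` (excluded from training and from the unknown set); records with no
#' usable activity evidence keep their existing label. Multiple measurements
#' of the same pair are reduced to their median activity before labelling.
#'
#' @param table Interaction tibble (see [read_interactions()]).
#' @param activity_threshold Positive pChEMBL threshold, default 5.5.
#' @return The table with one row per (drug, target) pair and labels in
#'   `positive` / `negative` / `weak` / `unknown`.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   drug_id = c("d1", "d2"), target_id = c("t1", "t1"),
#'   activity = c(6.1, 3.0), activity_flag = "none", label = "unknown"
#' )
#' assign_labels(tab)$label
assign_labels <- function(table, activity_threshold = 5.5) {
  stopifnot(activity_threshold > 0)
  if (any(!is.na(table$activity) & table$activity < 0)) {
    stop("negative activity value (pChEMBL scale is non-negative)")
  }
  if (!"activity_flag" %in% names(table)) table$activity_flag <- "none"
  if (!"label" %in% names(table)) table$label <- "unknown"
  if (anyDuplicated(table[c("drug_id", "target_id")])) {
    n0 <- nrow(table)
    table <- table |>
      dplyr::group_by(.data$drug_id, .data$target_id) |>
      dplyr::summarise(
        activity = if (all(is.na(.data$activity))) NA_real_ else
          stats::median(.data$activity, na.rm = TRUE),
        activity_flag = if (any(.data$activity_flag == "inactive")) "inactive"
          else if (any(.data$activity_flag == "active")) "active" else "none",
        label = .data$label[1],
        .groups = "drop"
      )
    message("assign_labels: ", n0 - nrow(table),
            " replicate measurement(s) reduced to per-pair medians")
  }
  inactive <- table$activity_flag == "inactive"
  has_act <- !is.na(table$activity)
  conflicts <- sum(inactive & has_act & table$activity >= activity_threshold)
  if (conflicts > 0) {
    message("assign_labels: ", conflicts,
            " record(s) flagged inactive despite activity >= threshold; flag wins")
  }
  label <- table$label
  label[has_act & table$activity > 0 & table$activity < activity_threshold] <- "weak"
  label[has_act & table$activity >= activity_threshold] <- "positive"
  label[inactive] <- "negative"
  table$label <- label
  table
}

#' Enumerate unknown drug-target pairs
#'
#' The full Cartesian product of the drug and target id lists minus every
#' pair known as positive, negative or weak — the "experimental" set that the
#' final model is applied to. The count always equals
#' `|drugs| * |targets| - |known|`.
#'
#' @param drug_ids,target_ids Character id vectors (unique).
#' @param known_table Labelled interaction tibble; rows with label
#'   `positive`, `negative` or `weak` are treated as known.
#' @return A tibble with columns `drug_id`, `target_id` (drug-major order).
#' @export
enumerate_unknown_pairs <- function(drug_ids, target_ids, known_table) {
  stopifnot(length(drug_ids) > 0, length(target_ids) > 0,
            !anyDuplicated(drug_ids), !anyDuplicated(target_ids))
  known <- known_table[known_table$label %in% c("positive", "negative", "weak"), ]
  bad_d <- setdiff(known$drug_id, drug_ids)
  bad_t <- setdiff(known$target_id, target_ids)
  if (length(bad_d) > 0) stop("known pair references drug outside the list: ", bad_d[1])
  if (length(bad_t) > 0) stop("known pair references target outside the list: ", bad_t[1])
  if (anyDuplicated(known[c("drug_id", "target_id")])) {
    stop("duplicate pair in known table")
  }
  all_pairs <- tidyr::expand_grid(drug_id = drug_ids, target_id = target_ids)
  dplyr::anti_join(all_pairs, known, by = c("drug_id", "target_id"))
}

#' Sample negative pairs from the unknown set
#'
#' Uniform sample without replacement from the unknown pairs, labelled 0.
#' This is the benchmark-dataset device for obtaining (putative) negatives
#' when validated inactives are unavailable; by default the sample is sized
#' to the positive count for a 1:1 class balance.
#'
#' @param unknown_pairs Tibble of unknown pairs (see
#'   [enumerate_unknown_pairs()]).
#' @param n_samples Number of pairs to draw (<= available).
#' @param seed Integer seed; identical seed gives an identical sample.
#' @return A tibble `drug_id`, `target_id`, `label` (0), `provenance`
#'   (`"sampled-unknown-negative"`).
#' @export
sample_negative_pairs <- function(unknown_pairs, n_samples, seed = 1L) {
  if (n_samples > nrow(unknown_pairs)) {
    stop("requested ", n_samples, " negatives but only ",
         nrow(unknown_pairs), " unknown pairs available")
  }
  old <- .Random.seed_guard(seed)
  on.exit(old())
  idx <- sample.int(nrow(unknown_pairs), n_samples)
  out <- unknown_pairs[idx, c("drug_id", "target_id")]
  out$label <- 0L
  out$provenance <- "sampled-unknown-negative"
  out
}

#' Build a labelled pair set from an interaction table
#'
#' Positive-labelled rows become label 1; negative-labelled rows become label
#' 0 with provenance `"validated-negative"`. Weak and unknown rows are
#' dropped. With `balance = TRUE` the majority class is down-sampled to the
#' minority count (seeded).
#'
#' @param table Labelled interaction tibble (after [assign_labels()]).
#' @param balance Down-sample the majority class to a 1:1 ratio?
#' @param seed Integer seed used only when balancing.
#' @return A tibble `drug_id`, `target_id`, `label`, `provenance`.
#' @export
labelled_pairs <- function(table, balance = FALSE, seed = 1L) {
  keep <- table$label %in% c("positive", "negative")
  out <- tibble::tibble(
    drug_id = table$drug_id[keep],
    target_id = table$target_id[keep],
    label = as.integer(table$label[keep] == "positive"),
    provenance = "validated-negative"
  )
  if (anyDuplicated(out[c("drug_id", "target_id")])) stop("duplicate labelled pair")
  if (balance) {
    n1 <- sum(out$label == 1L); n0 <- sum(out$label == 0L)
    if (n1 == 0 || n0 == 0) stop("both classes are required to balance")
    old <- .Random.seed_guard(seed)
    on.exit(old())
    maj <- if (n0 > n1) 0L else 1L
    keep_idx <- c(which(out$label != maj),
                  sample(which(out$label == maj), min(n0, n1)))
    out <- out[sort(keep_idx), ]
  }
  out
}

#' Concatenate node embeddings into link features
#'
#' Row i is the drug vector of pair i followed by its protein vector: a
#' `2n`-dimensional representation of the candidate link.
#'
#' @param pairs Tibble with `drug_id`, `target_id` and optionally `label`.
#' @param drug_embeddings,protein_embeddings `node_embedding` matrices.
#' @return An object of class `"link_feature_set"`: list with `pairs`
#'   (tibble), `features` (matrix with `2n` columns, drug block first) and
#'   `labels` (integer or `NULL`).
#' @export
build_features <- function(pairs, drug_embeddings, protein_embeddings) {
  miss_d <- setdiff(unique(pairs$drug_id), node_ids(drug_embeddings))
  miss_t <- setdiff(unique(pairs$target_id), node_ids(protein_embeddings))
  if (length(miss_d) + length(miss_t) > 0) {
    stop("missing embeddings for: ",
         paste(utils::head(c(miss_d, miss_t), 5), collapse = ", "))
  }
  nd <- ncol(drug_embeddings); np <- ncol(protein_embeddings)
  feats <- cbind(
    unclass(drug_embeddings)[pairs$drug_id, , drop = FALSE],
    unclass(protein_embeddings)[pairs$target_id, , drop = FALSE]
  )
  colnames(feats) <- c(paste0("d", seq_len(nd)), paste0("p", seq_len(np)))
  rownames(feats) <- NULL
  if (!all(is.finite(feats))) stop("non-finite link features")
  structure(
    list(pairs = tibble::as_tibble(pairs), features = feats,
         labels = if ("label" %in% names(pairs)) as.integer(pairs$label) else NULL),
    class = "link_feature_set"
  )
}

#' @export
print.link_feature_set <- function(x, ...) {
  cat("<link_feature_set>", nrow(x$features), "pairs x", ncol(x$features),
      "features")
  if (!is.null(x$labels)) {
    cat(" | ", sum(x$labels == 1L), "positive /", sum(x$labels == 0L), "negative")
  }
  cat("\n")
  invisible(x)
}

#' Tidy a link feature set
#' @param x A `link_feature_set`.
#' @param ... Unused.
#' @return A wide tibble: pair columns followed by the feature columns.
#' @export
tidy.link_feature_set <- function(x, ...) {
  dplyr::bind_cols(x$pairs, tibble::as_tibble(x$features))
}

#' Repeated stratified cross-validation split
#'
#' Draws the external test set once (stratified by label), then partitions
#' the remaining internal pairs into `folds` stratified folds, redrawn
#' independently for each of `repeats` repeats. With the defaults this is the
#' 90/10 internal/external split with 5-times-repeated 10-fold internal CV.
#'
#' @param labels Binary 0/1 label vector (one per pair), or a tibble with a
#'   `label` column.
#' @param external_fraction Fraction held out once as external test.
#' @param folds,repeats Internal CV geometry.
#' @param seed Integer seed.
#' @param groups Optional grouping vector (e.g. the drug ids for a
#'   cold-drug split): when given, the external set and every fold are
#'   unions of whole groups, so no group straddles a train/test boundary.
#'   The default pair-level split is the warm-start protocol.
#' @return An object of class `"cv_split"`: list with `external` (indices),
#'   `repeats` (list of fold-index lists partitioning the internal indices)
#'   and `labels`.
#' @export
make_cv_split <- function(labels, external_fraction = 0.1, folds = 10,
                          repeats = 5, seed = 1L, groups = NULL) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)),
            external_fraction > 0, external_fraction < 1,
            folds >= 2, repeats >= 1,
            is.null(groups) || length(groups) == length(labels))
  n <- length(labels)
  if (n < 2 * folds) stop("need at least ", 2 * folds, " pairs for ", folds, " folds")
  old <- .Random.seed_guard(seed)
  on.exit(old())
  check_folds <- function(fold_sets, r) {
    for (f in seq_along(fold_sets)) {
      test_lab <- labels[fold_sets[[f]]]
      if (length(unique(test_lab)) < length(unique(labels))) {
        stop("a class is absent from fold ", f, " of repeat ", r,
             "; use fewer folds or more data")
      }
    }
  }
  if (is.null(groups)) {
    # warm-start: stratified over pairs
    external <- integer(0)
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      k <- round(external_fraction * length(idx))
      external <- c(external, sample(idx, k))
    }
    external <- sort(external)
    internal <- setdiff(seq_len(n), external)
    rep_list <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      fold_of <- integer(n)
      for (cls in sort(unique(labels))) {
        idx <- which(labels == cls)
        idx <- idx[idx %in% internal]
        idx <- sample(idx)
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))
      }
      fold_sets <- lapply(seq_len(folds), function(f) sort(internal[fold_of[internal] == f]))
      check_folds(fold_sets, r)
      rep_list[[r]] <- fold_sets
    }
  } else {
    # cold split: whole groups move together (stratification is then only
    # approximate, so the class-presence check does the gatekeeping)
    groups <- as.character(groups)
    ug <- sort(unique(groups))
    ext_g <- sample(ug, max(1, round(external_fraction * length(ug))))
    external <- sort(which(groups %in% ext_g))
    int_g <- setdiff(ug, ext_g)
    rep_list <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      gf <- stats::setNames(rep_len(seq_len(folds), length(int_g)), sample(int_g))
      fold_sets <- lapply(seq_len(folds), function(f) {
        sort(which(groups %in% names(gf)[gf == f]))
      })
      check_folds(fold_sets, r)
      rep_list[[r]] <- fold_sets
    }
  }
  structure(list(external = external, repeats = rep_list,
                 labels = labels, folds = as.integer(folds)),
            class = "cv_split")
}

#' @export
print.cv_split <- function(x, ...) {
  cat("<cv_split>", length(x$labels), "pairs |", length(x$external),
      "external |", length(x$repeats), "repeat(s) x", x$folds, "folds\n")
  invisible(x)
}
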