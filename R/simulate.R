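#' Specification of a synthetic DTI study
#'
#' Defines a synthetic chemogenomic dataset with planted structure: drug
#' fingerprints fall into clusters (a random 166-bit prototype per cluster,
#' members perturbed by independent bit flips), protein sequences fall into
#' families (a random ancestor per family, members perturbed by per-site
#' substitutions), and a pair (d, t) interacts with a probability given by a
#' cluster-by-family block matrix, with independent label noise. The
#' defaults are the reference study conditions used throughout the package's
#' validation: 60 drugs in 4 clusters, 50 proteins in 3 families, 5% bit
#' flips and site mutations, within-block interaction probability 0.9
#' against 0.05 elsewhere, and 2% label noise.
#'
#' @param n_drugs,n_proteins Population sizes.
#' @param n_drug_clusters,n_protein_families Planted group counts.
#' @param fingerprint_flip_prob Per-bit flip probability in `[0, 0.5)`.
#' @param sequence_length Protein length (every sequence has this length).
#' @param mutation_rate Per-site substitution probability in `[0, 1)`.
#' @param block_interaction_matrix Cluster-by-family interaction
#'   probabilities; `NULL` builds the identity-like matrix with `p_in` on
#'   matched cluster/family indices (cluster k matched to family
#'   `((k-1) mod n_families) + 1`, so every cluster carries signal) and
#'   `p_out` elsewhere.
#' @param p_in,p_out Within- and between-block interaction probabilities used
#'   when `block_interaction_matrix` is `NULL`.
#' @param label_noise Probability of flipping a generated label, in
#'   `[0, 0.5)`.
#' @param seed Integer seed; all generators are deterministic under it.
#' @return A validated list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_drugs = 60, n_proteins = 50,
                         n_drug_clusters = 4, n_protein_families = 3,
                         fingerprint_flip_prob = 0.05,
                         sequence_length = 120, mutation_rate = 0.05,
                         block_interaction_matrix = NULL,
                         p_in = 0.9, p_out = 0.05,
                         label_noise = 0.02, seed = 1L) {
  if (is.null(block_interaction_matrix)) {
    # every drug cluster targets one protein family (wrapped when the group
    # counts differ), so no cluster is left without signal
    block_interaction_matrix <- matrix(p_out, n_drug_clusters, n_protein_families)
    for (k in seq_len(n_drug_clusters)) {
      block_interaction_matrix[k, ((k - 1L) %% n_protein_families) + 1L] <- p_in
    }
  }
  spec <- list(
    n_drugs = as.integer(n_drugs), n_proteins = as.integer(n_proteins),
    n_drug_clusters = as.integer(n_drug_clusters),
    n_protein_families = as.integer(n_protein_families),
    fingerprint_flip_prob = fingerprint_flip_prob,
    sequence_length = as.integer(sequence_length),
    mutation_rate = mutation_rate,
    block_interaction_matrix = block_interaction_matrix,
    label_noise = label_noise, seed = as.integer(seed)
  )
  stopifnot(
    spec$n_drug_clusters >= 1, spec$n_drug_clusters <= spec$n_drugs,
    spec$n_protein_families >= 1, spec$n_protein_families <= spec$n_proteins,
    spec$fingerprint_flip_prob >= 0, spec$fingerprint_flip_prob < 0.5,
    spec$sequence_length >= 2,
    spec$mutation_rate >= 0, spec$mutation_rate < 1,
    nrow(spec$block_interaction_matrix) == spec$n_drug_clusters,
    ncol(spec$block_interaction_matrix) == spec$n_protein_families,
    all(spec$block_interaction_matrix >= 0),
    all(spec$block_interaction_matrix <= 1),
    spec$label_noise >= 0, spec$label_noise < 0.5
  )
  structure(spec, class = "fixture_spec")
}

#' Generate clustered synthetic compounds
#'
#' One random 166-bit prototype per cluster (bit density 0.3, roughly the
#' occupancy of structural-key fingerprints of drug-like molecules); each
#' member is its cluster prototype with independent bit flips. Cluster
#' membership is recorded as ground truth in a `cluster` column.
#'
#' @param spec A [fixture_spec()].
#' @return A compound tibble with `compound_id`, `structure` (`NA`),
#'   `fingerprint` and ground-truth `cluster`.
#' @export
gen_compounds <- function(spec) {
  old <- .Random.seed_guard(child_seed(spec$seed, "gen:compounds"))
  on.exit(old())
  protos <- lapply(seq_len(spec$n_drug_clusters), function(k) {
    stats::rbinom(166, 1, 0.3)
  })
  cluster <- rep_len(seq_len(spec$n_drug_clusters), spec$n_drugs)
  fps <- lapply(seq_len(spec$n_drugs), function(i) {
    fp <- protos[[cluster[i]]]
    flip <- stats::rbinom(166, 1, spec$fingerprint_flip_prob) == 1
    fp[flip] <- 1L - fp[flip]
    as.integer(fp)
  })
  tibble::tibble(
    compound_id = sprintf("D%03d", seq_len(spec$n_drugs)),
    structure = NA_character_,
    fingerprint = fps,
    cluster = cluster
  )
}

#' Generate synthetic protein families
#'
#' One random ancestor sequence per family (uniform over the 20 amino
#' acids); each member substitutes every site independently with probability
#' `mutation_rate` (always to a different residue). Family membership is
#' recorded as ground truth in a `family` column.
#'
#' @param spec A [fixture_spec()].
#' @return A protein tibble with `protein_id`, `sequence` and ground-truth
#'   `family`.
#' @export
gen_proteins <- function(spec) {
  old <- .Random.seed_guard(child_seed(spec$seed, "gen:proteins"))
  on.exit(old())
  aa <- setdiff(protein_alphabet(), "X")
  ancestors <- lapply(seq_len(spec$n_protein_families), function(k) {
    sample(aa, spec$sequence_length, replace = TRUE)
  })
  family <- rep_len(seq_len(spec$n_protein_families), spec$n_proteins)
  seqs <- vapply(seq_len(spec$n_proteins), function(i) {
    s <- ancestors[[family[i]]]
    mut <- which(stats::runif(spec$sequence_length) < spec$mutation_rate)
    for (j in mut) s[j] <- sample(setdiff(aa, s[j]), 1)
    paste(s, collapse = "")
  }, "")
  tibble::tibble(
    protein_id = sprintf("P%03d", seq_len(spec$n_proteins)),
    sequence = seqs,
    family = family
  )
}

#' Generate a planted-block interaction table
#'
#' Every (drug, target) pair interacts with the probability of its
#' (cluster, family) block, labels are then flipped independently with
#' probability `label_noise`, and activity evidence is synthesised to
#' exercise the labelling rules: positives get a pChEMBL value uniform in
#' (5.5, 10), negatives an `inactive` flag. The returned table carries the
#' noisy ground truth in a `true_label` column (the pre-noise label is in
#' `planted_label`); its `label` column is `"unknown"` so that
#' [assign_labels()] reconstructs labels from the evidence.
#'
#' @param spec A [fixture_spec()].
#' @param compounds,proteins Outputs of [gen_compounds()] / [gen_proteins()]
#'   (must carry `cluster` / `family` ground truth).
#' @return An interaction tibble over all pairs.
#' @export
gen_interactions <- function(spec, compounds, proteins) {
  stopifnot("cluster" %in% names(compounds), "family" %in% names(proteins))
  old <- .Random.seed_guard(child_seed(spec$seed, "gen:interactions"))
  on.exit(old())
  grid <- tidyr::expand_grid(
    drug_id = compounds$compound_id,
    target_id = proteins$protein_id
  )
  cl <- compounds$cluster[match(grid$drug_id, compounds$compound_id)]
  fam <- proteins$family[match(grid$target_id, proteins$protein_id)]
  p_edge <- spec$block_interaction_matrix[cbind(cl, fam)]
  planted <- stats::runif(nrow(grid)) < p_edge
  flip <- stats::runif(nrow(grid)) < spec$label_noise
  truth <- xor(planted, flip)
  activity <- ifelse(truth, stats::runif(nrow(grid), 5.5, 10), NA_real_)
  tibble::tibble(
    drug_id = grid$drug_id,
    target_id = grid$target_id,
    activity = activity,
    activity_flag = ifelse(truth, "none", "inactive"),
    label = "unknown",
    planted_label = as.integer(planted),
    true_label = as.integer(truth)
  )
}

#' Write a complete synthetic fixture to disk
#'
#' Emits `fp.tsv` (fingerprints), `proteins.fasta`, `dti.tsv` (activity
#' evidence only) and `truth.tsv` (ground-truth clusters, families and
#' labels) into a directory.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The list of written paths, invisibly.
#' @export
simulate_fixture <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- gen_compounds(spec)
  proteins <- gen_proteins(spec)
  interactions <- gen_interactions(spec, compounds, proteins)
  paths <- list(
    fingerprints = file.path(out_dir, "fp.tsv"),
    proteins = file.path(out_dir, "proteins.fasta"),
    interactions = file.path(out_dir, "dti.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_fingerprints(compounds, paths$fingerprints)
  write_proteins(proteins, paths$proteins)
  write_interactions(
    interactions[c("drug_id", "target_id", "activity", "activity_flag")],
    paths$interactions
  )
  truth <- dplyr::bind_rows(
    tibble::tibble(id = compounds$compound_id, kind = "drug",
                   group = compounds$cluster),
    tibble::tibble(id = proteins$protein_id, kind = "protein",
                   group = proteins$family)
  )
  readr::write_tsv(truth, paths$truth, progress = FALSE)
  invisible(paths)
}
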