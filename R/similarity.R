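#' Populate MACCS structural-key fingerprints
#'
#' Computes the 166-bit structural-key fingerprint of every compound that has
#' a SMILES structure but no fingerprint yet, through Open Babel
#' (ChemmineR/ChemmineOB). Pre-existing fingerprints are left untouched.
#'
#' @param compounds Compound tibble (see [read_compounds()]).
#' @param permissive If `TRUE`, compounds whose structure cannot be parsed are
#'   dropped with a warning instead of aborting the run.
#' @return The compound tibble with all `fingerprint` entries populated
#'   (0/1 integer vectors of length 166).
#' @export
fingerprint_compounds <- function(compounds, permissive = FALSE) {
  need <- which(vapply(compounds$fingerprint, is.null, TRUE))
  if (length(need) == 0) return(compounds)
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fingerprinting SMILES requires ChemmineR and ChemmineOB")
  }
  failed <- character()
  for (i in need) {
    smi <- compounds$structure[i]
    fp <- tryCatch({
      if (is.na(smi) || !nzchar(smi)) stop("missing structure")
      sdf <- ChemmineR::smiles2sdf(smi)
      fpset <- ChemmineR::fingerprintOB(sdf, "MACCS")
      # FPset only defines an S4 as.matrix method; dispatch it explicitly so
      # the package works without ChemmineR attached
      fpm <- methods::getMethod("as.matrix", "FPset")(fpset)
      bits <- as.integer(fpm[1, 1:166])
      if (anyNA(bits)) stop("fingerprint failed")
      bits
    }, error = function(e) NULL)
    if (is.null(fp)) {
      failed <- c(failed, compounds$compound_id[i])
    } else {
      compounds$fingerprint[[i]] <- fp
    }
  }
  if (length(failed) > 0) {
    msg <- paste0(length(failed), " compound(s) could not be fingerprinted: ",
                  paste(utils::head(failed, 5), collapse = ", "))
    if (!permissive) stop(msg)
    warning(msg, "; dropped")
    compounds <- compounds[!compounds$compound_id %in% failed, ]
  }
  compounds
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' `|A n B| / (|A| + |B| - |A n B|)` over the bit sets. Two all-zero
#' fingerprints are defined as maximally similar (1) — both are featureless —
#' and flagged with a message.
#'
#' @param fp_a,fp_b Binary 0/1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(1, 1, 0, 1))
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    stop("fingerprint length mismatch: ", length(fp_a), " vs ", length(fp_b))
  }
  if (any(fp_a != 0 & fp_a != 1) || any(fp_b != 0 & fp_b != 1)) {
    stop("fingerprints must be binary")
  }
  a <- sum(fp_a); b <- sum(fp_b); ab <- sum(fp_a & fp_b)
  if (a + b == 0) {
    message("tanimoto: two all-zero fingerprints, similarity defined as 1")
    return(1)
  }
  ab / (a + b - ab)
}

#' Drug-drug similarity graph from fingerprints
#'
#' Pairwise Tanimoto similarity over all unordered compound pairs; each pair
#' is computed once, so the matrix is symmetric to exactly zero error.
#'
#' @param compounds Compound tibble with all fingerprints populated.
#' @return A [similarity_graph()] of kind `"drug"`.
#' @export
drug_similarity_matrix <- function(compounds) {
  if (any(vapply(compounds$fingerprint, is.null, TRUE))) {
    stop("all compounds need fingerprints; run fingerprint_compounds() first")
  }
  if (any(lengths(compounds$fingerprint) != 166L)) {
    stop("fingerprints must have length 166")
  }
  fp <- do.call(rbind, compounds$fingerprint)
  n_bits <- rowSums(fp)
  inter <- fp %*% t(fp)
  denom <- outer(n_bits, n_bits, `+`) - inter
  w <- ifelse(denom == 0, 1, inter / denom)
  # exact symmetry: copy the upper triangle down
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 1
  dimnames(w) <- list(compounds$compound_id, compounds$compound_id)
  if (any(n_bits == 0)) {
    message("drug_similarity_matrix: ", sum(n_bits == 0),
            " all-zero fingerprint(s); their similarities use the 0/0 := 1 convention")
  }
  similarity_graph(w, "drug")
}

#' Alignment scoring scheme
#'
#' @param submat Substitution matrix name shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`).
#' @param gap_open,gap_extend Gap penalties, non-positive; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param mode `"local"` (best-scoring sub-segment, score >= 0) or `"global"`
#'   (end-to-end with affine gaps).
#' @return A list of class `"alignment_scoring"`. The ambiguity residue `X`
#'   scores 0 against every residue.
#' @export
alignment_scoring <- function(submat = "BLOSUM62", gap_open = -10,
                              gap_extend = -0.5, mode = c("local", "global")) {
  mode <- match.arg(mode)
  stopifnot(gap_open <= 0, gap_extend <= 0)
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = submat, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(submat, envir = e)) {
    stop("unknown substitution matrix: ", submat)
  }
  sm <- get(submat, envir = e)
  alphabet <- protein_alphabet()
  if (!all(alphabet %in% rownames(sm))) {
    stop("substitution matrix ", submat, " does not cover the residue alphabet")
  }
  sm <- sm[alphabet, alphabet]
  sm["X", ] <- 0
  sm[, "X"] <- 0
  structure(list(submat = submat, matrix = sm, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode),
            class = "alignment_scoring")
}

check_sequence <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  bad <- gsub(sprintf("[%s]", paste(protein_alphabet(), collapse = "")), "", seq)
  if (nzchar(bad)) stop("invalid residue(s): ", substr(bad, 1, 5))
  invisible(seq)
}

#' Optimal pairwise alignment score
#'
#' Affine-gap dynamic programming (Smith-Waterman in local mode,
#' Needleman-Wunsch in global mode) via Biostrings.
#'
#' @param seq_a,seq_b Amino-acid strings over the 20-letter alphabet plus `X`.
#' @param scoring An [alignment_scoring()] scheme.
#' @return The raw optimal alignment score (>= 0 in local mode).
#' @export
align <- function(seq_a, seq_b, scoring = alignment_scoring()) {
  check_sequence(seq_a); check_sequence(seq_b)
  Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b,
    substitutionMatrix = scoring$matrix,
    gapOpening = -scoring$gap_open,
    gapExtension = -scoring$gap_extend,
    type = scoring$mode,
    scoreOnly = TRUE
  )
}

#' Normalised sequence similarity
#'
#' `align(a, b) / sqrt(align(a, a) * align(b, b))`, clamped to `[0, 1]`. The
#' geometric-mean normalisation makes self-similarity exactly 1 and is
#' symmetric in its arguments.
#'
#' @inheritParams align
#' @return Similarity in `[0, 1]`.
#' @export
sequence_similarity <- function(seq_a, seq_b, scoring = alignment_scoring()) {
  saa <- align(seq_a, seq_a, scoring)
  sbb <- align(seq_b, seq_b, scoring)
  if (saa <= 0 || sbb <= 0) {
    stop("degenerate sequence: non-positive self-alignment score")
  }
  s <- align(seq_a, seq_b, scoring) / sqrt(saa * sbb)
  min(max(s, 0), 1)
}

#' Protein-protein similarity graph from sequences
#'
#' Pairwise normalised alignment similarity over all unordered protein pairs,
#' each computed once (the matrix is symmetric to exactly zero error), with a
#' unit diagonal.
#'
#' @param proteins Protein tibble (see [read_proteins()]).
#' @param scoring An [alignment_scoring()] scheme.
#' @return A [similarity_graph()] of kind `"protein"`.
#' @export
protein_similarity_matrix <- function(proteins, scoring = alignment_scoring()) {
  n <- nrow(proteins)
  if (n < 2) stop("need at least 2 proteins")
  seqs <- proteins$sequence
  for (s in seqs) check_sequence(s)
  self <- vapply(seqs, function(s) {
    Biostrings::pairwiseAlignment(s, s, substitutionMatrix = scoring$matrix,
                                  gapOpening = -scoring$gap_open,
                                  gapExtension = -scoring$gap_extend,
                                  type = scoring$mode, scoreOnly = TRUE)
  }, 0, USE.NAMES = FALSE)
  if (any(self <= 0)) {
    stop("degenerate sequence (non-positive self-score): ",
         proteins$protein_id[self <= 0][1])
  }
  w <- diag(1, n)
  for (j in 2:n) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = seqs[seq_len(j - 1)], subject = seqs[j],
      substitutionMatrix = scoring$matrix,
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
      type = scoring$mode, scoreOnly = TRUE
    )
    val <- pmin(pmax(sc / sqrt(self[seq_len(j - 1)] * self[j]), 0), 1)
    w[seq_len(j - 1), j] <- val
    w[j, seq_len(j - 1)] <- val
  }
  dimnames(w) <- list(proteins$protein_id, proteins$protein_id)
  similarity_graph(w, "protein")
}
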