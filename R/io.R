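#' Read a compound table
#'
#' Reads compounds from one of three dialects: a headerless two-column
#' `id<TAB>SMILES` list, an SDF file, or a fingerprint TSV whose rows are a
#' compound id followed by 166 binary structural-key bits (optionally with a
#' header row). Input order is preserved.
#'
#' @param path File path.
#' @param format One of `"smiles-tsv"`, `"sdf"`, `"fingerprint-tsv"`.
#' @return A tibble with columns `compound_id`, `structure` (SMILES or `NA`)
#'   and `fingerprint` (list-column of 0/1 integer vectors of length 166, or
#'   `NULL`).
#' @export
read_compounds <- function(path, format = c("smiles-tsv", "sdf", "fingerprint-tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  out <- switch(format,
    "smiles-tsv" = read_compounds_smiles(path),
    "sdf" = read_compounds_sdf(path),
    "fingerprint-tsv" = read_compounds_fptsv(path)
  )
  dup <- out$compound_id[duplicated(out$compound_id)]
  if (length(dup) > 0) stop("duplicate compound_id: ", dup[1])
  if (nrow(out) == 0) warning("empty compound file: ", path)
  out
}

read_compounds_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(compound_id = character(), structure = character(),
                          fingerprint = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) stop("row ", bad[1], ": expected id<TAB>smiles")
  tibble::tibble(
    compound_id = vapply(parts, `[[`, "", 1L),
    structure = vapply(parts, `[[`, "", 2L),
    fingerprint = rep(list(NULL), length(parts))
  )
}

read_compounds_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF requires the ChemmineR package")
  }
  sdf <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdf)
  smi <- tryCatch(
    as.character(ChemmineR::sdf2smiles(sdf)),
    error = function(e) rep(NA_character_, length(sdf))
  )
  tibble::tibble(compound_id = ids, structure = smi,
                 fingerprint = rep(list(NULL), length(ids)))
}

read_compounds_fptsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(compound_id = character(), structure = character(),
                          fingerprint = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # header row detected when the second field is not a 0/1 bit
  if (length(parts[[1]]) >= 2 && !parts[[1]][2] %in% c("0", "1")) {
    parts <- parts[-1]
  }
  fps <- vector("list", length(parts))
  ids <- character(length(parts))
  for (i in seq_along(parts)) {
    row <- parts[[i]]
    if (length(row) - 1L != 166L) {
      stop("row ", i, " (", row[1], "): expected 166 fingerprint bits, got ",
           length(row) - 1L)
    }
    bits <- suppressWarnings(as.integer(row[-1]))
    if (anyNA(bits) || any(bits != 0L & bits != 1L)) {
      stop("row ", i, " (", row[1], "): fingerprint entries must be 0 or 1")
    }
    ids[i] <- row[1]
    fps[[i]] <- bits
  }
  tibble::tibble(compound_id = ids, structure = NA_character_, fingerprint = fps)
}

#' Write compounds as a fingerprint TSV
#' @param compounds Compound tibble with populated `fingerprint` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(compounds, path) {
  stopifnot(all(lengths(compounds$fingerprint) == 166L))
  lines <- vapply(seq_len(nrow(compounds)), function(i) {
    paste(c(compounds$compound_id[i], compounds$fingerprint[[i]]), collapse = "\t")
  }, "")
  writeLines(c(paste(c("compound_id", paste0("fp", 1:166)), collapse = "\t"), lines),
             path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' The token before the first whitespace in each header is the protein id.
#' Sequences are uppercased; residues outside the 20-letter amino-acid
#' alphabet plus `X` are rejected.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  if (any(seqs != as.character(aa))) {
    message("read_proteins: lowercase residues uppercased")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate protein_id: ", dup[1])
  if (any(!nzchar(seqs))) {
    stop("empty sequence for protein_id: ", ids[!nzchar(seqs)][1])
  }
  bad <- grepl(sprintf("[^%s]", paste(protein_alphabet(), collapse = "")), seqs)
  if (any(bad)) stop("invalid residue in protein_id: ", ids[bad][1])
  tibble::tibble(protein_id = unname(ids), sequence = unname(seqs))
}

protein_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
}

#' Write proteins as FASTA
#' @param proteins Protein tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- proteins$protein_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.interaction_columns <- c("drug_id", "target_id", "label", "activity", "activity_flag")

#' Read a drug-target interaction table
#'
#' TSV with a header; requires `drug_id` and `target_id` plus either a
#' `label` column (binary 0/1 or positive/negative text) or an `activity`
#' column (pChEMBL scale) with an optional `activity_flag` column
#' (active/inactive). When only activity data are present, labels are left
#' `"unknown"`; call [assign_labels()] to apply the labelling rules.
#'
#' @param path TSV path.
#' @return A tibble with columns `drug_id`, `target_id`, `activity`,
#'   `activity_flag`, `label`.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  unknown <- setdiff(names(tab), .interaction_columns)
  if (length(unknown) > 0) {
    stop("unknown interaction column(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(c("drug_id", "target_id") %in% names(tab))) {
    stop("interaction table needs drug_id and target_id columns")
  }
  if (!any(c("label", "activity") %in% names(tab))) {
    stop("interaction table needs a label or an activity column")
  }
  out <- tibble::tibble(
    drug_id = tab$drug_id,
    target_id = tab$target_id,
    activity = if ("activity" %in% names(tab)) as.numeric(tab$activity) else NA_real_,
    activity_flag = if ("activity_flag" %in% names(tab)) {
      flag <- tolower(tab$activity_flag)
      flag[is.na(flag) | flag == ""] <- "none"
      if (!all(flag %in% c("active", "inactive", "none"))) {
        stop("activity_flag must be active/inactive/none")
      }
      flag
    } else "none",
    label = if ("label" %in% names(tab)) parse_label(tab$label) else "unknown"
  )
  dup <- duplicated(out[c("drug_id", "target_id")])
  if (any(dup)) {
    stop("duplicate interaction pair: (", out$drug_id[dup][1], ", ",
         out$target_id[dup][1], ")")
  }
  out
}

parse_label <- function(x) {
  lab <- tolower(trimws(x))
  lab[lab %in% c("1", "positive", "active")] <- "positive"
  lab[lab %in% c("0", "negative", "inactive")] <- "negative"
  lab[is.na(lab) | lab == ""] <- "unknown"
  bad <- setdiff(unique(lab), c("positive", "negative", "weak", "unknown"))
  if (length(bad) > 0) stop("unrecognised label value: ", bad[1])
  lab
}

#' Write an interaction table as TSV
#' @param interactions Interaction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  readr::write_tsv(interactions, path, progress = FALSE)
  invisible(path)
}

#' Read a similarity matrix from TSV
#'
#' First row and first column carry the node ids. The matrix must be square
#' and symmetric up to `tol`; it is symmetrised as `(M + t(M)) / 2`, the
#' diagonal is forced to exactly 1, and entries must lie in `[0, 1]`.
#'
#' @param path TSV path.
#' @param kind `"drug"` or `"protein"`.
#' @param tol Symmetry / range tolerance, default `1e-8`.
#' @return A [similarity_graph()].
#' @export
read_similarity_matrix <- function(path, kind = c("drug", "protein"), tol = 1e-8) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) {
    stop("similarity matrix must be square, got ", nrow(m), " x ", ncol(m))
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column ids of similarity matrix disagree")
  }
  similarity_graph(m, kind, tol = tol)
}

#' Write a similarity graph as TSV
#'
#' Weights are written with six decimal places, ids in the first row and
#' column.
#'
#' @param graph A `similarity_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(graph, path) {
  m <- unclass(graph)
  ids <- rownames(m)
  header <- paste(c("", ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(ids[i], sprintf("%.6f", m[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read node embeddings from TSV
#' @param path TSV path (node id then the embedding coordinates, no header).
#' @return A `node_embedding` matrix with node ids as rownames.
#' @export
read_embedding <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric embedding entries in ", path)
  colnames(m) <- NULL
  node_embedding(m)
}

#' Write node embeddings as TSV
#' @param embedding A `node_embedding`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  m <- unclass(embedding)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}
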