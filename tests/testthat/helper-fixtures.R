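# Small in-code fixtures shared across test files.

# a tiny labelled interaction tibble exercising every labelling rule
tiny_interactions <- function() {
  tibble::tibble(
    drug_id = c("d1", "d1", "d2", "d2", "d3"),
    target_id = c("t1", "t2", "t1", "t2", "t1"),
    activity = c(6.2, 5.5, 3.0, NA, NA),
    activity_flag = c("none", "none", "none", "inactive", "none"),
    label = "unknown"
  )
}

# two 10-cliques joined by one bridge edge, as a similarity graph
two_clique_graph <- function(n_per = 10, w_in = 0.9, w_bridge = 0.3) {
  n <- 2 * n_per
  w <- matrix(0, n, n)
  w[1:n_per, 1:n_per] <- w_in
  w[(n_per + 1):n, (n_per + 1):n] <- w_in
  w[n_per, n_per + 1] <- w_bridge
  w[n_per + 1, n_per] <- w_bridge
  diag(w) <- 1
  ids <- sprintf("n%02d", 1:n)
  dimnames(w) <- list(ids, ids)
  similarity_graph(w, "drug")
}

# triangle a-b-c plus pendant d attached to b, unit weights
triangle_pendant_graph <- function() {
  ids <- c("a", "b", "c", "d")
  w <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w["a", "b"] <- w["b", "a"] <- 1
  w["b", "c"] <- w["c", "b"] <- 1
  w["a", "c"] <- w["c", "a"] <- 1
  w["b", "d"] <- w["d", "b"] <- 1
  diag(w) <- 1
  similarity_graph(w, "drug")
}

# small embeddings with controllable dimension
toy_embedding <- function(ids, dim = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(length(ids) * dim), length(ids), dim)
  rownames(m) <- ids
  node_embedding(m)
}

small_fixture_spec <- function(seed = 1L) {
  fixture_spec(n_drugs = 24, n_proteins = 18, n_drug_clusters = 3,
               n_protein_families = 3, sequence_length = 60, seed = seed)
}
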