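test_that("tanimoto matches hand set-counts and the bit-set oracle", {
  # |A| = 3, |B| = 3, |A n B| = 2 -> 2 / (3 + 3 - 2)
  a <- integer(166); a[c(1, 5, 9)] <- 1L
  b <- integer(166); b[c(1, 5, 20)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1.0)
  disjoint <- integer(166); disjoint[c(2, 3)] <- 1L
  expect_equal(tanimoto(a, disjoint), 0.0)
  expect_message(z <- tanimoto(integer(166), integer(166)), "all-zero")
  expect_equal(z, 1)
  expect_error(tanimoto(a, b[1:100]), "length mismatch")
  expect_error(tanimoto(c(a[-1], 2L), b), "binary")

  set.seed(11)
  for (i in 1:1000) {
    x <- random_fingerprint(stats::runif(1, 0.05, 0.6))
    y <- random_fingerprint(stats::runif(1, 0.05, 0.6))
    expect_equal(tanimoto(x, y), oracle_tanimoto(x, y))
  }
})

test_that("drug similarity matrix is symmetric, unit-diagonal, and oracle-exact", {
  set.seed(3)
  comp <- tibble::tibble(
    compound_id = sprintf("c%d", 1:8),
    structure = NA_character_,
    fingerprint = lapply(1:8, function(i) random_fingerprint())
  )
  g <- drug_similarity_matrix(comp)
  m <- unclass(g)
  expect_identical(m, t(m))  # exact, computed once per unordered pair
  expect_equal(unname(diag(m)), rep(1, 8))
  expect_true(all(m >= 0 & m <= 1))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(m[i, j], oracle_tanimoto(comp$fingerprint[[i]], comp$fingerprint[[j]]))
  }
  # identical compounds are maximally similar
  comp2 <- comp[c(1, 1), ]; comp2$compound_id <- c("a", "b")
  expect_equal(unclass(drug_similarity_matrix(comp2)), matrix(1, 2, 2),
               ignore_attr = TRUE)
})

test_that("alignment scores agree with an independent affine-gap DP oracle", {
  sc <- alignment_scoring()
  # identical sequences in global mode score the diagonal sum
  s <- "HEAGAWGHEE"
  diag_sum <- sum(sc$matrix[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])])
  expect_equal(align(s, s, alignment_scoring(mode = "global")), diag_sum)

  expect_equal(
    align("HEAGAWGHEE", "PAWHEAE", sc),
    oracle_align("HEAGAWGHEE", "PAWHEAE", sc$matrix, 10, 0.5, "local")
  )

  set.seed(21)
  for (mode in c("local", "global")) {
    scm <- alignment_scoring(mode = mode)
    for (i in 1:40) {
      a <- random_sequence(sample(3:12, 1))
      b <- random_sequence(sample(3:12, 1))
      expect_equal(align(a, b, scm),
                   oracle_align(a, b, scm$matrix, 10, 0.5, mode),
                   info = paste(mode, a, b))
    }
  }
})

test_that("local alignments floor at zero and X scores zero", {
  sc <- alignment_scoring()
  # no positive-scoring residue pair: glycine run vs tryptophan run
  expect_equal(align("GGGG", "WW", sc) <= 0, TRUE)
  expect_equal(align("GGGG", "WWWW", sc), max(0, oracle_align("GGGG", "WWWW", sc$matrix, 10, 0.5, "local")))
  # X contributes nothing anywhere
  expect_equal(align("MKVX", "MKVX", sc), align("MKV", "MKV", sc))
  expect_error(align("MKB", "MKV", sc), "invalid residue")
  expect_error(alignment_scoring("NOSUCHMATRIX"), "unknown substitution matrix")
})

test_that("sequence similarity is normalised, symmetric, and bounded", {
  sc <- alignment_scoring()
  s <- random_sequence(50)
  expect_equal(sequence_similarity(s, s, sc), 1.0)
  set.seed(4)
  sims <- replicate(20, {
    a <- random_sequence(50); b <- random_sequence(50)
    f <- sequence_similarity(a, b, sc)
    expect_identical(f, sequence_similarity(b, a, sc))
    expect_gte(f, 0); expect_lte(f, 1)
    f
  })
  # unrelated random sequences are dissimilar in expectation
  expect_lt(mean(sims), 0.5)
})

test_that("protein similarity matrix separates mutated families", {
  spec <- small_fixture_spec(seed = 5)
  prot <- gen_proteins(spec)
  g <- protein_similarity_matrix(prot)
  m <- unclass(g)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, nrow(prot)))
  same <- outer(prot$family, prot$family, `==`)
  ut <- upper.tri(m)
  expect_gt(mean(m[same & ut]), mean(m[!same & ut]))
  # identical sequences give an all-ones 2x2 graph
  twin <- tibble::tibble(protein_id = c("p1", "p2"),
                         sequence = rep(random_sequence(30), 2))
  expect_equal(unclass(protein_similarity_matrix(twin)), matrix(1, 2, 2),
               ignore_attr = TRUE)
  expect_error(protein_similarity_matrix(twin[1, ]), "at least 2")
})

test_that("sparsify thresholds edges and reports isolated nodes", {
  ids <- c("a", "b", "c")
  w <- matrix(c(1, .9, .2, .9, 1, .4, .2, .4, 1), 3, 3, dimnames = list(ids, ids))
  g <- similarity_graph(w, "drug")
  expect_equal(unclass(sparsify(g, 0)), unclass(g))
  s <- sparsify(g, 0.3)
  expect_equal(sum(unclass(s)[upper.tri(s)] > 0), 2)  # 0.9 and 0.4 survive
  expect_equal(unname(diag(unclass(s))), rep(1, 3))
  s1 <- sparsify(g, 1)
  expect_equal(sum(unclass(s1)[upper.tri(s1)] > 0), 0)
})

test_that("MACCS fingerprinting populates 166 binary bits deterministically", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  comp <- tibble::tibble(
    compound_id = c("ethanol", "aspirin", "ethanol2"),
    structure = c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "CCO"),
    fingerprint = list(NULL, NULL, NULL)
  )
  out <- fingerprint_compounds(comp)
  expect_true(all(lengths(out$fingerprint) == 166))
  expect_true(all(unlist(out$fingerprint) %in% 0:1))
  expect_identical(out$fingerprint[[1]], out$fingerprint[[3]])
  expect_gt(sum(out$fingerprint[[2]]), sum(out$fingerprint[[1]]))

  # precomputed fingerprints pass through untouched
  pre <- random_fingerprint()
  comp$fingerprint[[2]] <- pre
  out2 <- fingerprint_compounds(comp)
  expect_identical(out2$fingerprint[[2]], pre)

  # unparsable structures abort unless permissive
  bad <- tibble::tibble(compound_id = "junk", structure = "not-a-smiles(((",
                        fingerprint = list(NULL))
  expect_error(fingerprint_compounds(bad), "junk")
  expect_warning(out3 <- fingerprint_compounds(bad, permissive = TRUE), "junk")
  expect_equal(nrow(out3), 0)
})
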