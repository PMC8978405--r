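test_that("labelling rules follow the activity threshold and inactive flag", {
  lab <- assign_labels(tiny_interactions())
  expect_equal(lab$label,
               c("positive",  # 6.2 >= 5.5
                 "positive",  # boundary 5.5 is inclusive
                 "weak",      # 0 < 3.0 < 5.5
                 "negative",  # inactive flag, no activity
                 "unknown"))  # no evidence
  # idempotent and total
  expect_identical(assign_labels(lab), lab)
  expect_true(all(lab$label %in% c("positive", "negative", "weak", "unknown")))

  # the inactive flag wins over a positive-range activity, with a message
  conflict <- tibble::tibble(drug_id = "d", target_id = "t", activity = 7,
                             activity_flag = "inactive", label = "unknown")
  expect_message(out <- assign_labels(conflict), "flag wins")
  expect_equal(out$label, "negative")

  neg <- tibble::tibble(drug_id = "d", target_id = "t", activity = -1,
                        activity_flag = "none", label = "unknown")
  expect_error(assign_labels(neg), "negative activity")

  # replicate measurements reduce to the median before labelling
  reps <- tibble::tibble(drug_id = "d", target_id = "t",
                         activity = c(2, 6, 9), activity_flag = "none",
                         label = "unknown")
  expect_message(out <- assign_labels(reps), "median")
  expect_equal(nrow(out), 1)
  expect_equal(out$label, "positive")
})

test_that("unknown-pair enumeration satisfies the count identity", {
  known <- tibble::tibble(drug_id = c("d1", "d2"), target_id = c("t1", "t2"),
                          label = c("positive", "weak"))
  u <- enumerate_unknown_pairs(c("d1", "d2"), c("t1", "t2"), known)
  expect_equal(nrow(u), 2 * 2 - 2)
  expect_true(!any(paste(u$drug_id, u$target_id) %in% c("d1 t1", "d2 t2")))

  # randomized instances against brute-force set difference
  set.seed(8)
  for (i in 1:20) {
    nd <- sample(3:9, 1); nt <- sample(3:9, 1)
    drugs <- sprintf("d%d", 1:nd); targets <- sprintf("t%d", 1:nt)
    all_p <- expand.grid(drug_id = drugs, target_id = targets,
                         stringsAsFactors = FALSE)
    k <- sample(0:(nd * nt), 1)
    ki <- sample(nrow(all_p), k)
    known <- all_p[ki, ]
    known$label <- sample(c("positive", "negative", "weak"), k, replace = TRUE)
    u <- enumerate_unknown_pairs(drugs, targets, known)
    expect_equal(nrow(u), nd * nt - k)
    brute <- setdiff(paste(all_p$drug_id, all_p$target_id),
                     paste(known$drug_id, known$target_id))
    expect_setequal(paste(u$drug_id, u$target_id), brute)
  }

  # unknown-labelled rows are not "known"
  known$label <- "unknown"
  expect_equal(nrow(enumerate_unknown_pairs(drugs, targets, known)), nd * nt)

  expect_error(
    enumerate_unknown_pairs("d1", "t1",
                            tibble::tibble(drug_id = "dX", target_id = "t1",
                                           label = "positive")),
    "outside")
})

test_that("negative sampling is uniform, seeded, and bounded", {
  unknown <- tidyr::expand_grid(drug_id = sprintf("d%d", 1:10),
                                target_id = sprintf("t%d", 1:10))
  s1 <- sample_negative_pairs(unknown, 10, seed = 4)
  expect_equal(nrow(s1), 10)
  expect_equal(unique(s1$label), 0L)
  expect_equal(unique(s1$provenance), "sampled-unknown-negative")
  expect_identical(s1, sample_negative_pairs(unknown, 10, seed = 4))
  expect_error(sample_negative_pairs(unknown, 101, seed = 1), "only")

  all_s <- sample_negative_pairs(unknown, 100, seed = 2)
  expect_setequal(paste(all_s$drug_id, all_s$target_id),
                  paste(unknown$drug_id, unknown$target_id))

  # inclusion frequency of each pair ~ Binomial(n_draws, 0.1)
  n_draws <- 2000
  counts <- integer(100)
  for (i in seq_len(n_draws)) {
    s <- sample_negative_pairs(unknown, 10, seed = 10000 + i)
    idx <- match(paste(s$drug_id, s$target_id),
                 paste(unknown$drug_id, unknown$target_id))
    counts[idx] <- counts[idx] + 1L
  }
  se <- sqrt(0.1 * 0.9 / n_draws)
  expect_true(all(abs(counts / n_draws - 0.1) < 3 * se + 1e-12))
})

test_that("link features concatenate drug block then protein block", {
  emb_d <- node_embedding(matrix(c(1, 2), 1, 2, dimnames = list("d", NULL)))
  emb_p <- node_embedding(matrix(c(3, 4), 1, 2, dimnames = list("t", NULL)))
  fs <- build_features(tibble::tibble(drug_id = "d", target_id = "t", label = 1L),
                       emb_d, emb_p)
  expect_equal(unname(fs$features[1, ]), c(1, 2, 3, 4))
  expect_equal(colnames(fs$features), c("d1", "d2", "p1", "p2"))

  ids <- c("a", "b"); tds <- c("x", "y")
  emb_d2 <- toy_embedding(ids, dim = 100)
  emb_p2 <- toy_embedding(tds, dim = 100, seed = 2)
  pairs <- tidyr::expand_grid(drug_id = ids, target_id = tds)
  pairs$label <- c(1L, 0L, 1L, 0L)
  fs2 <- build_features(pairs, emb_d2, emb_p2)
  expect_equal(ncol(fs2$features), 200)
  # pairs sharing a drug share the first n columns
  expect_identical(fs2$features[1, 1:100], fs2$features[2, 1:100])
  expect_error(
    build_features(tibble::tibble(drug_id = "zz", target_id = "x"),
                   emb_d2, emb_p2),
    "zz")
})

test_that("cross-validation split is stratified, disjoint, and partitioning", {
  labels <- rep(c(1L, 0L), each = 500)
  sp <- make_cv_split(labels, external_fraction = 0.1, folds = 10,
                      repeats = 5, seed = 6)
  expect_equal(length(sp$external), 100)
  expect_equal(sum(labels[sp$external]), 50)  # stratified external draw
  internal <- setdiff(seq_along(labels), sp$external)
  global_pos <- mean(labels[internal])
  for (r in seq_along(sp$repeats)) {
    folds <- sp$repeats[[r]]
    expect_equal(sort(unlist(folds)), internal)  # exact partition
    expect_equal(length(unlist(folds)), length(unique(unlist(folds))))
    for (f in folds) {
      expect_equal(length(intersect(f, sp$external)), 0)
      expect_equal(length(f), 90, tolerance = 0.02)
      # label proportions within one pair of the global proportion
      expect_lte(abs(sum(labels[f]) - global_pos * length(f)), 1)
    }
  }
  expect_identical(sp, make_cv_split(labels, seed = 6))
  expect_error(make_cv_split(rep(1L, 15), folds = 10), "at least")
  expect_error(make_cv_split(c(rep(1L, 95), rep(0L, 5)), folds = 10,
                             repeats = 1, seed = 1),
               "absent")
})

test_that("cold splits keep whole groups on one side of every boundary", {
  set.seed(14)
  n <- 300
  drugs <- sample(sprintf("d%02d", 1:30), n, replace = TRUE)
  labels <- sample(0:1, n, replace = TRUE)
  sp <- make_cv_split(labels, external_fraction = 0.2, folds = 4, repeats = 2,
                      seed = 5, groups = drugs)
  ext_g <- unique(drugs[sp$external])
  int_idx <- setdiff(seq_len(n), sp$external)
  expect_equal(length(intersect(ext_g, drugs[int_idx])), 0)
  for (r in seq_along(sp$repeats)) {
    fold_groups <- lapply(sp$repeats[[r]], function(f) unique(drugs[f]))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(length(intersect(fold_groups[[i]], fold_groups[[j]])), 0)
    }
    expect_equal(sort(unlist(sp$repeats[[r]])), int_idx)
  }
})

test_that("balanced pair sets equalise classes by down-sampling", {
  lab <- tibble::tibble(
    drug_id = sprintf("d%d", 1:30), target_id = sprintf("t%d", 1:30),
    label = c(rep("positive", 10), rep("negative", 20))
  )
  p <- labelled_pairs(lab, balance = TRUE, seed = 3)
  expect_equal(sum(p$label == 1L), 10)
  expect_equal(sum(p$label == 0L), 10)
  expect_identical(p, labelled_pairs(lab, balance = TRUE, seed = 3))
  full <- labelled_pairs(lab)
  expect_equal(nrow(full), 30)
})
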