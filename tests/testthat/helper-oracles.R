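# Independent brute-force oracles, written directly from first principles and
# kept free of any package internals.

# Tanimoto as explicit set operations on bit positions
oracle_tanimoto <- function(a, b) {
  A <- which(a == 1)
  B <- which(b == 1)
  if (length(A) == 0 && length(B) == 0) return(1)
  length(intersect(A, B)) / length(union(A, B))
}

# Affine-gap pairwise alignment by Gotoh dynamic programming.
# A gap of length L costs open + L * ext (penalties passed as positives).
# mode "local" floors the match state at zero and takes the matrix maximum;
# mode "global" scores end-to-end.
oracle_align <- function(a, b, submat, open, ext, mode = "local") {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  M[1, 1] <- 0
  local <- mode == "local"
  if (!local) {
    for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
    for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      if (local && M[i, j] < 0) M[i, j] <- 0
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      if (local && M[i, j] > best) best <- M[i, j]
    }
  }
  if (local) best else max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# confusion-matrix metrics by explicit enumeration
oracle_precision_recall <- function(y, s, thr = 0.5) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y)) {
    pred <- s[i] >= thr
    if (pred && y[i] == 1) tp <- tp + 1
    if (pred && y[i] == 0) fp <- fp + 1
    if (!pred && y[i] == 1) fn <- fn + 1
    if (!pred && y[i] == 0) tn <- tn + 1
  }
  c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

# AUC by O(n^2) positive/negative pair counting, ties worth one half
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# AUPR as the Riemann sum of precision over recall increments at every
# distinct threshold, highest first
oracle_aupr <- function(y, s) {
  thr <- sort(unique(s), decreasing = TRUE)
  n_pos <- sum(y == 1)
  prev_r <- 0
  area <- 0
  for (t in thr) {
    keep <- s >= t
    tp <- sum(y == 1 & keep)
    p <- tp / sum(keep)
    r <- tp / n_pos
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

random_fingerprint <- function(density = 0.3) {
  as.integer(stats::runif(166) < density)
}

random_sequence <- function(len, alphabet = setdiff(dtilink:::protein_alphabet(), "X")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
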