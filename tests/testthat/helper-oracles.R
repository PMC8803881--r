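# Independent oracles used to cross-check the package implementations.

# Brute-force substitution scoring: plain loops over the PSSM, no shared
# code with scoreSubstitutions().
bruteScoreSubstitutions <- function(pssm, exclude_to_glycine = TRUE) {
  sc <- scoreMatrix(pssm)
  wt <- strsplit(wtSeq(pssm), "")[[1]]
  rows <- list()
  for (i in seq_along(wt)) {
    for (a in AA_ORDER) {
      if (a == wt[i]) next
      if (exclude_to_glycine && a == "G") next
      rows[[length(rows) + 1]] <- data.frame(
        position = i, wt_aa = wt[i], mut_aa = a,
        delta = sc[i, a] - sc[i, wt[i]])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta, out$position, match(out$mut_aa, AA_ORDER)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Naive average-linkage agglomerative clustering on a distance matrix:
# clusters as index sets, inter-cluster distance = mean of all pairwise
# original distances, repeatedly merge the closest pair (ties: smallest
# index pair) until k clusters remain.
naiveAverageLinkage <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- NULL
    m <- length(clusters)
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (is.null(best) || dij < best$d - 1e-12) best <- list(i = i, j = j, d = dij)
      }
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  lab <- integer(n)
  for (c in seq_along(clusters)) lab[clusters[[c]]] <- c
  lab
}

# Relabel a partition by order of first appearance so two labelings of
# the same partition compare equal.
canonicalPartition <- function(labels) {
  match(labels, unique(labels))
}

# Random symmetric distance matrix with zero diagonal and continuous
# entries (no ties almost surely).
randomDistanceMatrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 10)
  d + t(d)
}

# A PSSM built directly from a score matrix (bypasses buildPSSM) for
# tests that need exact control over the scores.
pssmFromScores <- function(wt_seq, scores) {
  colnames(scores) <- AA_ORDER
  rownames(scores) <- seq_len(nrow(scores))
  new("PSSM", wtSeq = wt_seq, scores = scores, alphabetOrder = AA_ORDER)
}

# Random PSSM over non-glycine wild-type residues.
randomPssm <- function(L, score_range = c(-8L, 8L)) {
  wt <- paste(sample(setdiff(AA_ORDER, "G"), L, replace = TRUE),
              collapse = "")
  sc <- matrix(sample(seq(score_range[1], score_range[2]), L * 20,
                      replace = TRUE), nrow = L)
  pssmFromScores(wt, sc)
}

# The PAM30 similarity matrix as shipped with Biostrings, fetched
# independently of the package's internal cache.
pam30ref <- local({
  e <- new.env()
  utils::data("PAM30", package = "Biostrings", envir = e)
  e$PAM30
})
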