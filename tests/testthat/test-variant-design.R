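test_that("single-column PSSM yields the expected top candidate", {
  sc <- matrix(-4L, nrow = 1, ncol = 20)
  sc[1, match("R", AA_ORDER)] <- 5L
  sc[1, match("A", AA_ORDER)] <- -2L
  p <- pssmFromScores("A", sc)
  cands <- scoreSubstitutions(p)
  expect_identical(cands$label[1], "A1R")
  expect_equal(cands$delta[1], 7)
})

test_that("a fully conserved protein still ranks totally and deterministically", {
  set.seed(21)
  L <- 8
  wt <- sample(setdiff(AA_ORDER, "G"), L, replace = TRUE)
  sc <- matrix(sample(-8:0, L * 20, replace = TRUE), nrow = L)
  for (i in seq_len(L)) sc[i, match(wt[i], AA_ORDER)] <- 5L  # strict row max
  p <- pssmFromScores(paste(wt, collapse = ""), sc)
  cands <- scoreSubstitutions(p)
  expect_true(all(cands$delta < 0))
  expect_identical(cands$rank, seq_len(nrow(cands)))
  expect_identical(cands, scoreSubstitutions(p))
})

test_that("scoring matches brute-force enumeration on random PSSMs", {
  set.seed(22)
  for (case in 1:25) {
    p <- randomPssm(10)
    for (flag in c(TRUE, FALSE)) {
      got <- scoreSubstitutions(p, exclude_to_glycine = flag)
      want <- bruteScoreSubstitutions(p, exclude_to_glycine = flag)
      expect_equal(got[names(want)], want)
      if (flag) expect_true(all(got$mut_aa != "G"))
      expect_lte(nrow(got), (if (flag) 18 else 19) * 10)
    }
  }
})

test_that("double pool enumeration honours the distinct-position rule", {
  top <- data.frame(position = 1:25,
                    wt_aa = rep(c("A", "K", "T", "F", "Y"), 5),
                    mut_aa = rep(c("R", "W", "M", "L", "N"), each = 5),
                    delta = 25:1, rank = 1:25)
  top$label <- paste0(top$wt_aa, top$position, top$mut_aa)
  pool <- enumerateDoublePool(top)
  expect_equal(nrow(pool), choose(25, 2))  # 300
  # same-position pairs are dropped
  top3 <- data.frame(position = c(5, 5, 9), wt_aa = c("A", "A", "K"),
                     mut_aa = c("R", "W", "M"), delta = 3:1, rank = 1:3)
  top3$label <- paste0(top3$wt_aa, top3$position, top3$mut_aa)
  expect_equal(nrow(enumerateDoublePool(top3)), 2)
  # canonical labels: position-sorted, unique
  expect_true(all(pool$position1 < pool$position2))
  expect_identical(pool$label,
                   paste0(pool$wt1, pool$position1, pool$mut1, "-",
                          pool$wt2, pool$position2, pool$mut2))
  expect_false(anyDuplicated(pool$label) > 0)
  expect_error(enumerateDoublePool(top3[1, ]), "at least 2")
})

test_that("PAM30 variant distance matches hand computation from the table", {
  expect_equal(pam30Distance("A1R", "A1R", "AKT"), 0)
  # two singles at one site, mutations R vs W:
  # (m(R,R) + m(W,W))/2 - m(R,W) from the published PAM30 entries
  expect_equal(pam30Distance("K2R", "K2W", "AKT"),
               (pam30ref["R", "R"] + pam30ref["W", "W"]) / 2 -
                 pam30ref["R", "W"])
})

test_that("distance is local: a shared substitution contributes nothing", {
  wt <- "AKTWYF"
  # both carry K2R; they differ only at the second site
  d_shared <- pam30Distance("K2R-W4M", "K2R-W4L", wt)
  d_site <- pam30Distance("W4M", "W4L", wt)
  expect_equal(d_shared, d_site)
})

test_that("distance matrices are symmetric, non-negative, zero-diagonal", {
  set.seed(23)
  wt <- paste(sample(setdiff(AA_ORDER, "G"), 30, replace = TRUE),
              collapse = "")
  wt_res <- strsplit(wt, "")[[1]]
  pos <- sample(30, 8)
  labels <- vapply(pos, function(i) {
    paste0(wt_res[i], i, sample(setdiff(AA_ORDER, wt_res[i]), 1))
  }, character(1))
  dm <- variantDistanceMatrix(labels, wt)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0))
  # consistent with the pairwise function
  expect_equal(dm[1, 2], pam30Distance(labels[1], labels[2], wt))
})

test_that("variant labels are validated against the wild type", {
  expect_error(pam30Distance("A9R", "A1R", "AKT"), "outside")
  expect_error(pam30Distance("K1R", "A1W", "AKT"), "does not match")
})

test_that("n_clusters = n puts every point in its own cluster", {
  d <- randomDistanceMatrix(6)
  dimnames(d) <- list(letters[1:6], letters[1:6])
  cl <- agglomerativeCluster(d, 6)
  expect_equal(sort(unique(cl)), 1:6)
})

test_that("two well-separated blobs are recovered exactly", {
  n <- 8
  d <- matrix(100, n, n)
  d[1:4, 1:4] <- 1; d[5:8, 5:8] <- 1
  diag(d) <- 0
  cl <- agglomerativeCluster(d, 2)
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:8])), 1)
  expect_false(cl[1] == cl[5])
})

test_that("clustering matches a naive average-linkage oracle", {
  set.seed(24)
  for (case in 1:100) {
    n <- sample(6:12, 1)
    k <- sample(2:(n - 1), 1)
    d <- randomDistanceMatrix(n)
    got <- canonicalPartition(agglomerativeCluster(d, k))
    want <- canonicalPartition(naiveAverageLinkage(d, k))
    expect_identical(got, want)
  }
})

test_that("invalid clustering inputs are rejected", {
  d <- randomDistanceMatrix(5)
  expect_error(agglomerativeCluster(d, 6), "n_clusters")
  bad <- d; bad[1, 2] <- -1
  expect_error(agglomerativeCluster(bad, 2), "symmetric")
})

test_that("the default pipeline emits a 25 + 25 library with full provenance", {
  set.seed(25)
  wt <- paste(sample(setdiff(AA_ORDER, "G"), 120, replace = TRUE),
              collapse = "")
  aln <- generateMsa(wt, 300, runif(120, 0.3, 0.9), seed = 31)
  pssm <- buildPSSM(aln)
  lib <- designLibrary(pssm, designParams(seed = 7))
  d <- designs(lib)
  expect_equal(nrow(d), 50)
  expect_equal(sum(d$kind == "double"), 25)
  expect_equal(sum(d$kind == "single"), 25)
  expect_false(anyDuplicated(d$label) > 0)
  # no glycine targets anywhere
  expect_true(all(d$mut1 != "G"))
  expect_true(all(is.na(d$mut2) | d$mut2 != "G"))
  # doubles' constituents come from ranks <= 25; one double per cluster
  dbl <- d[d$kind == "double", ]
  expect_true(all(dbl$rank1 <= 25 & dbl$rank2 <= 25))
  expect_identical(sort(dbl$cluster), 1:25)
  # singles are ranks 26..50 verbatim
  sng <- d[d$kind == "single", ]
  expect_identical(sort(sng$rank1), 26:50)
  cands <- scoreSubstitutions(pssm)
  expect_identical(sng$label, cands$label[26:50])
})

test_that("libraries are seed-deterministic; singles are seed-independent", {
  set.seed(26)
  wt <- paste(sample(setdiff(AA_ORDER, "G"), 100, replace = TRUE),
              collapse = "")
  aln <- generateMsa(wt, 250, 0.6, seed = 5)
  pssm <- buildPSSM(aln)
  l1 <- designLibrary(pssm, designParams(seed = 11))
  l2 <- designLibrary(pssm, designParams(seed = 11))
  l3 <- designLibrary(pssm, designParams(seed = 12))
  expect_identical(designs(l1), designs(l2))
  s1 <- designs(l1)[designs(l1)$kind == "single", ]
  s3 <- designs(l3)[designs(l3)$kind == "single", ]
  expect_identical(s1, s3)
})

test_that("a too-short protein raises an explicit sizing error", {
  sc <- matrix(0L, nrow = 2, ncol = 20)
  p <- pssmFromScores("AK", sc)
  expect_error(designLibrary(p, designParams(seed = 1)),
               "surviving substitution candidates")
})

test_that("library TSV output records designs and seed", {
  set.seed(27)
  wt <- paste(sample(setdiff(AA_ORDER, "G"), 100, replace = TRUE),
              collapse = "")
  pssm <- buildPSSM(generateMsa(wt, 200, 0.6, seed = 3))
  lib <- designLibrary(pssm, designParams(seed = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLibraryTsv(lib, path)
  lines <- readLines(path)
  expect_identical(lines[1], "# seed=4")
  tab <- read.delim(path, skip = 1)
  expect_equal(nrow(tab), 50)
  expect_identical(tab$label, designs(lib)$label)
})
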