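test_that("a fully conserved column gives its residue the strict row maximum", {
  aln <- Biostrings::AAStringSet(rep("W", 100))
  p <- buildPSSM(aln, pseudocount = 1)
  row <- scoreMatrix(p)[1, ]
  expect_true(all(row["W"] > row[setdiff(AA_ORDER, "W")]))
})

test_that("a uniform column scores zero for every residue", {
  aln <- Biostrings::AAStringSet(AA_ORDER)  # each residue once
  p <- buildPSSM(aln, pseudocount = 1)
  expect_true(all(scoreMatrix(p)[1, ] == 0L))
})

test_that("toy column {A,A,R} matches the hand-evaluated formula", {
  # c(A)=2: 2*log2((2+0.05)/(4*0.05)) = 2*log2(10.25) = 6.72 -> 7
  # c(R)=1: 2*log2((1+0.05)/(4*0.05)) = 2*log2(5.25)  = 4.79 -> 5
  # c=0:    2*log2(0.05/0.2)          = 2*log2(0.25)  = -4
  aln <- Biostrings::AAStringSet(c("A", "A", "R"))
  row <- scoreMatrix(buildPSSM(aln, pseudocount = 1))[1, ]
  expect_equal(unname(row["A"]), 7L)
  expect_equal(unname(row["R"]), 5L)
  expect_true(all(row[setdiff(AA_ORDER, c("A", "R"))] == -4L))
})

test_that("scores are invariant to the order of non-wild-type records", {
  set.seed(10)
  aln <- generateMsa("MKTAYIAKQR", 60, 0.6, seed = 2)
  shuffled <- aln[c(1, sample(2:60))]
  expect_identical(scoreMatrix(buildPSSM(aln)),
                   scoreMatrix(buildPSSM(shuffled)))
})

test_that("adding a residue to a column never decreases its score", {
  set.seed(11)
  for (rep in 1:20) {
    col <- sample(AA_ORDER, 30, replace = TRUE)
    a <- sample(AA_ORDER, 1)
    base <- buildPSSM(Biostrings::AAStringSet(c(col[1], col)))
    more <- buildPSSM(Biostrings::AAStringSet(c(col[1], col, a)))
    expect_gte(scoreMatrix(more)[1, a], scoreMatrix(base)[1, a])
  }
})

test_that("gaps are excluded from column counts (ungapped depth)", {
  aln <- Biostrings::AAStringSet(c("AW", "A-", "A-"))
  p <- buildPSSM(aln, pseudocount = 1)
  # column 2 sees only one W, same as a depth-1 conserved column
  single <- buildPSSM(Biostrings::AAStringSet("W"), pseudocount = 1)
  expect_identical(unname(scoreMatrix(p)[2, ]),
                   unname(scoreMatrix(single)[1, ]))
})

test_that("the wild-type record must be gap-free and match wt_seq", {
  expect_error(buildPSSM(Biostrings::AAStringSet(c("A-K", "AMK"))),
               "gap-free")
  expect_error(buildPSSM(Biostrings::AAStringSet(c("AMK", "AMK")),
                         wt_seq = "AMR"), "conflicts")
})

test_that("a handcrafted psiblast file parses to its exact integers", {
  lines <- c("Some description line",
             paste(AA_ORDER, collapse = "  "),
             "1 M  1  2  3  4  5  6  7  8  9 10 11 12 13 14 15 16 17 18 19 20",
             "2 K -1 -2 -3 -4 -5 -6 -7 -8 -9 -1 -2 -3 -4 -5 -6 -7 -8 -9 -1 -2",
             "3 T  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0  0")
  p <- readPSSM(text = lines)
  expect_identical(wtSeq(p), "MKT")
  expect_identical(unname(scoreMatrix(p)[1, ]), 1:20)
  expect_true(all(scoreMatrix(p)[3, ] == 0L))
})

test_that("the second 20-column block and trailing statistics are ignored", {
  # psiblast rows carry 20 log-odds + 20 percentages + 2 floats
  lines <- c("", "Last position-specific scoring matrix computed",
             paste(c(AA_ORDER, AA_ORDER), collapse = " "),
             paste("1 A", paste(rep("2", 20), collapse = " "),
                   paste(rep("5", 20), collapse = " "), "0.36 0.12"),
             "", "                      K         Lambda",
             "Standard Ungapped    0.1337     0.3114")
  p <- readPSSM(text = lines)
  expect_identical(wtSeq(p), "A")
  expect_true(all(scoreMatrix(p)[1, ] == 2L))
})

test_that("malformed PSSM rows raise errors naming the line", {
  hdr <- c("desc", paste(AA_ORDER, collapse = " "))
  short <- c(hdr, paste("1 A", paste(rep("1", 19), collapse = " ")))
  expect_error(readPSSM(text = short), "line 3")
  dup <- c(hdr,
           paste("1 A", paste(rep("1", 20), collapse = " ")),
           paste("1 R", paste(rep("1", 20), collapse = " ")))
  expect_error(readPSSM(text = dup), "duplicate")
  frac <- c(hdr, paste("1 A", paste(rep("1.5", 20), collapse = " ")))
  expect_error(readPSSM(text = frac), "non-integer")
})

test_that("write -> read is the identity on PSSM objects", {
  aln <- generateMsa("MKTAYIAKQRLW", 80, 0.7, seed = 9)
  p <- buildPSSM(aln)
  path <- withr::local_tempfile(fileext = ".pssm")
  writePSSM(p, path)
  q <- readPSSM(path)
  expect_identical(wtSeq(q), wtSeq(p))
  expect_equal(unname(scoreMatrix(q)), unname(scoreMatrix(p)))
})
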