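#' Read a protein multiple sequence alignment from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that enforces the
#' alignment contract: at least one record, all records the same length,
#' and an alphabet restricted to the 20 canonical residues plus the gap
#' character.
#'
#' @param path FASTA file path.
#' @return a [Biostrings::AAStringSet].
#' @export
readMsaFasta <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  validateAlignment(aln)
  aln
}

validateAlignment <- function(aln) {
  if (length(aln) < 1L) stop("alignment must contain at least one sequence")
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("alignment sequences must all have equal length")
  seqs <- as.character(aln)
  for (k in seq_along(seqs)) splitResidues(seqs[k], allow_gap = TRUE,
                                           what = sprintf("record %d", k))
  invisible(aln)
}

#' Build a PSSM from a protein alignment
#'
#' Computes per-column log-odds scores in the half-bit integer convention
#' of the psiblast ASCII dialect:
#' \deqn{s(i,a) = \mathrm{round}\!\left(2\log_2
#'   \frac{c(i,a) + \beta q_a}{(n_i + \beta)\, q_a}\right)}
#' where \eqn{c(i,a)} counts residue \eqn{a} in column \eqn{i} (gaps
#' excluded), \eqn{n_i} is the ungapped column depth, \eqn{\beta} the
#' pseudocount and \eqn{q_a} the background frequency. The first alignment
#' record anchors the wild-type sequence and must be gap-free.
#'
#' Columns consisting entirely of gaps fall back to the background alone
#' (all scores 0 under a uniform background) with a warning.
#'
#' @param aln a [Biostrings::AAStringSet] (or object coercible to one);
#'   first record = wild type.
#' @param pseudocount positive pseudocount \eqn{\beta} (default 1).
#' @param background length-20 positive vector of background frequencies
#'   summing to 1 (default uniform), in [AA_ORDER] order unless named.
#' @param wt_seq optional wild-type sequence; if supplied it must match the
#'   first alignment record.
#' @return a \linkS4class{PSSM}.
#' @examples
#' aln <- generateMsa("MKTAYIAK", n_seqs = 50, conservation = 0.8, seed = 3)
#' buildPSSM(aln)
#' @export
buildPSSM <- function(aln, pseudocount = 1, background = rep(1 / 20, 20),
                      wt_seq = NULL) {
  if (!is(aln, "AAStringSet")) aln <- Biostrings::AAStringSet(aln)
  validateAlignment(aln)
  if (length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  if (length(background) != 20L || any(background <= 0))
    stop("background must be 20 strictly positive frequencies")
  background <- background / sum(background)
  if (is.null(names(background))) names(background) <- AA_ORDER
  q <- background[AA_ORDER]

  wt <- as.character(aln[[1]])
  if (grepl("-", wt, fixed = TRUE))
    stop("the first alignment record (wild type) must be gap-free")
  if (!is.null(wt_seq) && !identical(wt_seq, wt))
    stop("supplied wt_seq conflicts with the first alignment record")

  mat <- do.call(rbind, strsplit(as.character(aln), ""))
  L <- ncol(mat)
  scores <- matrix(0L, nrow = L, ncol = 20L,
                   dimnames = list(seq_len(L), AA_ORDER))
  for (i in seq_len(L)) {
    col <- mat[, i]
    col <- col[col != "-"]
    n_i <- length(col)
    if (n_i == 0L)
      warning(sprintf("column %d is all gaps; scored from background alone", i))
    cnt <- table(factor(col, levels = AA_ORDER))
    odds <- (as.numeric(cnt) + pseudocount * q) /
      ((n_i + pseudocount) * q)
    scores[i, ] <- as.integer(round(2 * log2(odds)))
  }
  new("PSSM", wtSeq = wt, scores = scores, alphabetOrder = AA_ORDER)
}

#' Read a psiblast ASCII PSSM
#'
#' Parses the plain-text position-specific scoring matrix emitted by
#' psiblast (\code{-out_ascii_pssm}): header lines, then one row per
#' position carrying the position index, the query residue, and two
#' 20-column blocks of which the first holds the integer log-odds scores.
#' Only the first block is read; weighted-percentage columns and trailing
#' statistics lines are ignored. The residue column order is taken from
#' the header line when present.
#'
#' @param path path to the ASCII PSSM file (alternatively pass the file
#'   text via \code{text}).
#' @param text optional character vector of lines, used instead of
#'   \code{path}.
#' @return a \linkS4class{PSSM}.
#' @export
readPSSM <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  # header: first line whose tokens are >= 20 single residue letters
  alpha <- AA_ORDER
  data_start <- NULL
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) >= 20L && all(nchar(toks) == 1L) &&
        all(toks %in% AA_ORDER)) {
      alpha <- toks[1:20]
      if (!setequal(alpha, AA_ORDER))
        stop(sprintf("line %d: header is not a permutation of the 20 residues",
                     ln))
      data_start <- ln + 1L
      break
    }
  }
  if (is.null(data_start))
    stop("no PSSM header line (residue column labels) found")

  idx <- integer(); res <- character(); rows <- list()
  for (ln in seq(data_start, length(lines))) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    toks <- strsplit(line, "\\s+")[[1]]
    # data rows start "<pos> <residue> <20 ints> ..."; anything else ends
    # the matrix block (psiblast prints K/Lambda statistics afterwards)
    if (!grepl("^[0-9]+$", toks[1])) break
    if (length(toks) < 2L || !toks[2] %in% AA_ORDER)
      stop(sprintf("line %d: expected a residue in column 2", ln))
    sc <- toks[-(1:2)]
    if (length(sc) < 20L)
      stop(sprintf("line %d: expected 20 score columns, found %d",
                   ln, length(sc)))
    sc <- sc[1:20]
    if (!all(grepl("^-?[0-9]+$", sc)))
      stop(sprintf("line %d: non-integer score field", ln))
    i <- as.integer(toks[1])
    if (i %in% idx)
      stop(sprintf("line %d: duplicate position index %d", ln, i))
    idx <- c(idx, i); res <- c(res, toks[2])
    rows[[length(rows) + 1L]] <- as.integer(sc)
  }
  if (!length(rows)) stop("no PSSM data rows found")
  if (!identical(idx, seq_along(idx)))
    stop("position indices must run 1..L without gaps")
  scores <- do.call(rbind, rows)
  colnames(scores) <- alpha
  scores <- scores[, AA_ORDER, drop = FALSE]
  rownames(scores) <- idx
  new("PSSM", wtSeq = paste(res, collapse = ""), scores = scores,
      alphabetOrder = AA_ORDER)
}

#' Write a PSSM in the psiblast ASCII dialect
#'
#' Emits a file that [readPSSM()] parses back to an identical object:
#' a description line, a residue-order header, and one row per position.
#'
#' @param pssm a \linkS4class{PSSM}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePSSM <- function(pssm, path) {
  stopifnot(is(pssm, "PSSM"))
  sc <- pssm@scores[, AA_ORDER, drop = FALSE]
  res <- strsplit(pssm@wtSeq, "")[[1]]
  hdr <- c("Position-specific scoring matrix (half-bit integer log-odds)",
           paste(c("   ", sprintf("%3s", AA_ORDER)), collapse = " "))
  body <- vapply(seq_along(res), function(i) {
    paste(c(sprintf("%3d", i), sprintf("%1s", res[i]),
            sprintf("%3d", sc[i, ])), collapse = " ")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
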