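# PAM30 is shipped as a data object by Biostrings; cache it once.
pam30cache <- new.env(parent = emptyenv())
pam30matrix <- function() {
  if (is.null(pam30cache$m)) {
    e <- new.env()
    utils::data("PAM30", package = "Biostrings", envir = e)
    pam30cache$m <- e$PAM30
  }
  pam30cache$m
}

#' Parameters of the variant-design pipeline
#'
#' Defaults encode the screening procedure: the 25 top-ranked
#' substitutions feed the double-substitution pool, which is clustered
#' into 25 groups (one double drawn per group), while ranks 26-50 enter
#' the library verbatim as singles -- a 50-member library in total.
#'
#' @param n_top number of top-ranked substitutions combined into doubles.
#' @param n_single_lo,n_single_hi rank window taken as single variants.
#' @param n_clusters number of clusters for the double pool (= number of
#'   doubles in the library).
#' @param seed integer seed driving every random choice of the pipeline.
#' @param exclude_to_glycine drop substitutions whose target residue is
#'   glycine before ranking (glycine introduction is destabilising).
#' @param linkage agglomerative linkage criterion.
#' @param pool "exhaustive" enumerates all valid pairs of the top
#'   substitutions; "random" samples \code{pool_size} of them first.
#' @param pool_size pool size when \code{pool = "random"}.
#' @return a named list of validated parameters.
#' @export
designParams <- function(n_top = 25L, n_single_lo = 26L, n_single_hi = 50L,
                         n_clusters = 25L, seed = 1L,
                         exclude_to_glycine = TRUE,
                         linkage = c("average", "complete", "single"),
                         pool = c("exhaustive", "random"),
                         pool_size = 300L) {
  linkage <- match.arg(linkage)
  pool <- match.arg(pool)
  if (n_top < n_clusters)
    stop("n_top must be at least n_clusters")
  if (n_single_hi < n_single_lo)
    stop("n_single_hi must be >= n_single_lo")
  list(n_top = as.integer(n_top), n_single_lo = as.integer(n_single_lo),
       n_single_hi = as.integer(n_single_hi),
       n_clusters = as.integer(n_clusters), seed = as.integer(seed),
       exclude_to_glycine = isTRUE(exclude_to_glycine), linkage = linkage,
       pool = pool, pool_size = as.integer(pool_size))
}

#' Rank all point substitutions of a PSSM by conservation gain
#'
#' Enumerates every (position, residue) substitution of the wild-type
#' sequence and scores it by the PSSM delta
#' \eqn{\Delta = s(i, a_{mut}) - s(i, a_{wt})}: positive deltas mark
#' replacements by residues more conserved in the protein family than the
#' wild-type residue. Substitutions introducing glycine are removed when
#' \code{exclude_to_glycine} is on. The list is sorted by delta
#' (descending), with deterministic tie-breaking by position and then
#' residue alphabet order, and ranks assigned 1..n.
#'
#' @param pssm a \linkS4class{PSSM}.
#' @param exclude_to_glycine drop candidates whose target residue is G.
#' @return data.frame with columns \code{position}, \code{wt_aa},
#'   \code{mut_aa}, \code{delta}, \code{rank}, \code{label} (e.g. "Y27R").
#' @examples
#' aln <- generateMsa("MKTAYIAK", n_seqs = 100, conservation = 0.7, seed = 2)
#' head(scoreSubstitutions(buildPSSM(aln)))
#' @export
scoreSubstitutions <- function(pssm, exclude_to_glycine = TRUE) {
  stopifnot(is(pssm, "PSSM"))
  sc <- pssm@scores[, AA_ORDER, drop = FALSE]
  if (any(is.na(sc))) stop("PSSM contains NA scores")
  wt <- strsplit(pssm@wtSeq, "")[[1]]
  L <- length(wt)

  pos <- rep(seq_len(L), each = 20L)
  mut <- rep(AA_ORDER, times = L)
  wt_aa <- wt[pos]
  keep <- mut != wt_aa
  if (exclude_to_glycine) keep <- keep & mut != "G"
  pos <- pos[keep]; mut <- mut[keep]; wt_aa <- wt_aa[keep]
  delta <- sc[cbind(pos, match(mut, AA_ORDER))] -
    sc[cbind(pos, match(wt_aa, AA_ORDER))]

  ord <- order(-delta, pos, match(mut, AA_ORDER))
  out <- data.frame(position = pos[ord], wt_aa = wt_aa[ord],
                    mut_aa = mut[ord], delta = delta[ord],
                    rank = seq_along(ord))
  out$label <- paste0(out$wt_aa, out$position, out$mut_aa)
  out
}

#' Enumerate the double-substitution pool
#'
#' Forms all unordered pairs of the supplied top-ranked substitutions
#' whose positions differ (two substitutions at the same site cannot
#' coexist). Labels are canonical: constituent substitutions sorted by
#' position, joined with "-".
#'
#' @param top data.frame of candidates (rows of [scoreSubstitutions()]).
#' @return data.frame with one row per double: \code{label},
#'   \code{position1, wt1, mut1, delta1, rank1},
#'   \code{position2, wt2, mut2, delta2, rank2}.
#' @export
enumerateDoublePool <- function(top) {
  if (nrow(top) < 2L)
    stop("need at least 2 candidates to form double substitutions")
  pairs <- utils::combn(nrow(top), 2L)
  i <- pairs[1, ]; j <- pairs[2, ]
  ok <- top$position[i] != top$position[j]
  i <- i[ok]; j <- j[ok]
  if (!length(i))
    stop("no position-disjoint pairs available in the candidate set")
  # canonical order: first constituent at the smaller position
  swap <- top$position[i] > top$position[j]
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  out <- data.frame(
    position1 = top$position[a], wt1 = top$wt_aa[a], mut1 = top$mut_aa[a],
    delta1 = top$delta[a], rank1 = top$rank[a],
    position2 = top$position[b], wt2 = top$wt_aa[b], mut2 = top$mut_aa[b],
    delta2 = top$delta[b], rank2 = top$rank[b])
  out$label <- paste0(out$wt1, out$position1, out$mut1, "-",
                      out$wt2, out$position2, out$mut2)
  out[, c("label", names(out)[names(out) != "label"])]
}

# "Y27R" / "T31R-F92W" -> data.frame(position, wt_aa, mut_aa)
parseVariantLabel <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z])$", parts))
  if (any(lengths(m) != 4L))
    stop(sprintf("malformed variant label '%s'", label))
  data.frame(position = as.integer(vapply(m, `[`, "", 3)),
             wt_aa = vapply(m, `[`, "", 2),
             mut_aa = vapply(m, `[`, "", 4))
}

# residues of a variant at a set of positions (mutated where applicable)
variantResidues <- function(subs, positions, wt) {
  res <- wt[positions]
  hit <- match(positions, subs$position)
  res[!is.na(hit)] <- subs$mut_aa[hit[!is.na(hit)]]
  res
}

#' PAM30 distance between two sequence variants
#'
#' Converts PAM30 similarities into a distance between the two full
#' mutated sequences using the self-similarity-centred form
#' \deqn{d(x, y) = \sum_{k: x_k \ne y_k}
#'   \frac{m(x_k, x_k) + m(y_k, y_k)}{2} - m(x_k, y_k)}
#' so identical sequences are at distance 0 and only differing positions
#' contribute. Variants are given as labels ("Y27R", "T31R-F92W") applied
#' to a shared wild-type sequence.
#'
#' @param a,b variant labels.
#' @param wt_seq the common wild-type sequence.
#' @return a non-negative number; 0 iff the mutated sequences coincide.
#' @examples
#' pam30Distance("A1R", "A1W", "AKT")
#' @export
pam30Distance <- function(a, b, wt_seq) {
  wt <- splitResidues(wt_seq, what = "wt_seq")
  sa <- parseVariantLabel(a); sb <- parseVariantLabel(b)
  for (s in list(sa, sb)) {
    if (any(s$position < 1L | s$position > length(wt)))
      stop("substitution position outside the wild-type sequence")
    if (any(wt[s$position] != s$wt_aa))
      stop("variant label wild-type residue does not match wt_seq")
    if (!all(s$mut_aa %in% AA_ORDER))
      stop("unknown residue in variant label")
  }
  m <- pam30matrix()
  pos <- union(sa$position, sb$position)
  x <- variantResidues(sa, pos, wt)
  y <- variantResidues(sb, pos, wt)
  diff <- x != y
  if (!any(diff)) return(0)
  sum((m[cbind(x[diff], x[diff])] + m[cbind(y[diff], y[diff])]) / 2 -
        m[cbind(x[diff], y[diff])])
}

#' Pairwise PAM30 distance matrix over a variant set
#'
#' @param labels character vector of variant labels sharing \code{wt_seq}.
#' @param wt_seq the wild-type sequence.
#' @return a symmetric matrix with zero diagonal, dimnames = labels.
#' @export
variantDistanceMatrix <- function(labels, wt_seq) {
  wt <- splitResidues(wt_seq, what = "wt_seq")
  m <- pam30matrix()
  subs <- lapply(labels, parseVariantLabel)
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    si <- subs[[i]]
    for (j in seq(i + 1L, n)) {
      sj <- subs[[j]]
      pos <- union(si$position, sj$position)
      x <- variantResidues(si, pos, wt)
      y <- variantResidues(sj, pos, wt)
      k <- x != y
      dij <- if (any(k))
        sum((m[cbind(x[k], x[k])] + m[cbind(y[k], y[k])]) / 2 -
              m[cbind(x[k], y[k])])
      else 0
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Agglomerative clustering of a precomputed distance matrix
#'
#' Hierarchical agglomerative merging (via [stats::hclust()]) on the
#' supplied distances, cut at \code{n_clusters} groups. Deterministic for
#' a given matrix.
#'
#' @param dm symmetric distance matrix (or a [stats::dist] object).
#' @param n_clusters number of clusters, between 1 and n.
#' @param linkage linkage criterion: "average" (default), "complete" or
#'   "single".
#' @return integer vector of cluster labels in 1..n_clusters, named by the
#'   matrix dimnames; every cluster is non-empty.
#' @export
agglomerativeCluster <- function(dm, n_clusters,
                                 linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.matrix(dm)) {
    if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-9) ||
        any(diag(dm) != 0) || any(dm < 0))
      stop("dm must be a symmetric non-negative matrix with zero diagonal")
    dm <- as.dist(dm)
  }
  n <- attr(dm, "Size")
  if (n_clusters < 1L || n_clusters > n)
    stop(sprintf("n_clusters must be in 1..%d", n))
  if (n_clusters == n) {
    lab <- seq_len(n)
    names(lab) <- attr(dm, "Labels")
    return(lab)
  }
  cutree(hclust(dm, method = linkage), k = n_clusters)
}

#' Design the 50-variant substitution library
#'
#' Runs the full pipeline: PSSM delta-scoring of all substitutions (with
#' glycine-target removal), exhaustive pairing of the top \code{n_top}
#' into a double-substitution pool, PAM30 distance matrix over the pool,
#' agglomerative clustering into \code{n_clusters} groups, one seeded
#' random draw per cluster, and the rank window
#' \code{n_single_lo..n_single_hi} taken verbatim as singles. Default
#' parameters yield 25 doubles + 25 singles = 50 designs.
#'
#' @param pssm a \linkS4class{PSSM}.
#' @param params parameters from [designParams()].
#' @return a \linkS4class{VariantLibrary}.
#' @examples
#' aln <- generateMsa(paste(rep("MKTAYIAKQR", 8), collapse = ""),
#'                    n_seqs = 300, conservation = 0.6, seed = 11)
#' lib <- designLibrary(buildPSSM(aln), designParams(seed = 7))
#' lib
#' @export
designLibrary <- function(pssm, params = designParams()) {
  stopifnot(is(pssm, "PSSM"))
  cands <- scoreSubstitutions(pssm, params$exclude_to_glycine)
  if (nrow(cands) < params$n_single_hi)
    stop(sprintf(paste("only %d surviving substitution candidates;",
                       "the rank window requires at least %d"),
                 nrow(cands), params$n_single_hi))
  top <- cands[seq_len(params$n_top), ]
  if (length(unique(top$position)) < 2L)
    stop("top candidates occupy a single position; no doubles possible")

  pool <- enumerateDoublePool(top)
  if (params$pool == "random" && nrow(pool) > params$pool_size)
    pool <- withSeed(params$seed,
                     pool[sort(sample(nrow(pool), params$pool_size)), ])
  if (nrow(pool) < params$n_clusters)
    stop(sprintf("double pool has %d members; %d clusters requested",
                 nrow(pool), params$n_clusters))

  dm <- variantDistanceMatrix(pool$label, pssm@wtSeq)
  cl <- agglomerativeCluster(dm, params$n_clusters, params$linkage)
  picked <- withSeed(params$seed, vapply(seq_len(params$n_clusters),
    function(k) {
      members <- which(cl == k)
      members[sample.int(length(members), 1L)]
    }, integer(1)))

  doubles <- pool[picked, ]
  doubles$kind <- "double"
  doubles$cluster <- seq_len(params$n_clusters)

  singles <- cands[seq(params$n_single_lo, params$n_single_hi), ]
  singles <- data.frame(
    label = singles$label, position1 = singles$position,
    wt1 = singles$wt_aa, mut1 = singles$mut_aa, delta1 = singles$delta,
    rank1 = singles$rank,
    position2 = NA_integer_, wt2 = NA_character_, mut2 = NA_character_,
    delta2 = NA_real_, rank2 = NA_integer_,
    kind = "single", cluster = NA_integer_)

  cols <- c("label", "kind", "position1", "wt1", "mut1", "delta1", "rank1",
            "position2", "wt2", "mut2", "delta2", "rank2", "cluster")
  designs <- rbind(doubles[, cols], singles[, cols])
  rownames(designs) <- NULL
  new("VariantLibrary", designs = designs, wtSeq = pssm@wtSeq,
      params = params, seed = params$seed)
}

#' Write a variant library as TSV
#'
#' One row per design with constituent substitutions, deltas, ranks and
#' cluster ids; a comment header records the RNG seed for provenance.
#'
#' @param lib a \linkS4class{VariantLibrary}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLibraryTsv <- function(lib, path) {
  stopifnot(is(lib, "VariantLibrary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d", lib@seed), con)
  write.table(lib@designs, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
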