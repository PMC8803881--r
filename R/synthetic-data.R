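#' Generate a synthetic protein multiple sequence alignment
#'
#' Samples a fixed-length (gap-free) alignment around a wild-type sequence.
#' Each column draws the wild-type residue with probability
#' \code{conservation[i]}; the remaining mass is spread over the other 19
#' residues in proportion to \code{background}. The first record is the
#' wild-type sequence itself. This is a statistical stand-in for a
#' database-derived homolog alignment, tuned so downstream PSSMs have a
#' controllable conservation signal; it models neither phylogeny nor
#' indels.
#'
#' @param wt_seq wild-type protein sequence (string over the 20-letter
#'   alphabet).
#' @param n_seqs number of sequences in the alignment (including the
#'   wild-type record).
#' @param conservation per-position probability of the wild-type residue,
#'   in \[0, 1\]; recycled if a scalar.
#' @param seed integer seed; the same spec and seed yield a byte-identical
#'   alignment.
#' @param background length-20 non-negative vector of residue weights
#'   (named or in [AA_ORDER] order) used to spread the non-wild-type mass;
#'   default uniform.
#' @return a [Biostrings::AAStringSet] of \code{n_seqs} equal-length
#'   sequences; the first is \code{wt_seq}.
#' @examples
#' aln <- generateMsa("MKTAYIAK", n_seqs = 20, conservation = 0.9, seed = 1)
#' aln[1]
#' @export
generateMsa <- function(wt_seq, n_seqs, conservation, seed,
                        background = rep(1 / 20, 20)) {
  wt <- splitResidues(wt_seq, what = "wt_seq")
  L <- length(wt)
  if (length(n_seqs) != 1L || n_seqs < 1L)
    stop("n_seqs must be a positive integer")
  if (length(conservation) == 1L) conservation <- rep(conservation, L)
  if (length(conservation) != L)
    stop("conservation must have one value per position of wt_seq")
  if (any(conservation < 0 | conservation > 1))
    stop("conservation values must lie in [0, 1]")
  if (length(background) != 20L || any(background < 0) ||
      sum(background) <= 0)
    stop("background must be 20 non-negative weights")
  if (is.null(names(background))) names(background) <- AA_ORDER

  mat <- matrix(wt, nrow = n_seqs, ncol = L, byrow = TRUE)
  if (n_seqs > 1L) {
    withSeed(seed, {
      for (i in seq_len(L)) {
        p <- background[AA_ORDER]
        p[wt[i]] <- 0
        p <- if (sum(p) > 0) p / sum(p) * (1 - conservation[i])
             else rep(0, 20)
        p[wt[i]] <- p[wt[i]] + conservation[i]
        if (sum(p) == 0) p[wt[i]] <- 1  # conservation 0 with wt-only background
        mat[2:n_seqs, i] <- sample(AA_ORDER, n_seqs - 1L, replace = TRUE,
                                   prob = p / sum(p))
      }
    })
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- c("wild_type", sprintf("synth_%04d", seq_len(n_seqs - 1L)))[
    seq_len(n_seqs)]
  Biostrings::AAStringSet(seqs)
}

#' Generate a synthetic enzyme assay table
#'
#' Draws (substrate, activity) measurements from a substrate-inhibition (or
#' plain saturation) rate law with additive Gaussian noise truncated at
#' zero, emulating an in vitro relative-activity assay over a serial
#' substrate dilution. The default grid spans 50-350 umol/L.
#'
#' @param params a \linkS4class{KineticParams} object (the ground truth).
#' @param concentrations strictly positive, ascending substrate
#'   concentrations in umol/L.
#' @param noise_sd standard deviation of the additive noise, in
#'   relative-activity units (>= 0).
#' @param replicates number of replicate measurements per concentration.
#' @param seed integer seed for reproducible noise.
#' @return data.frame with columns \code{substrate_uM}, \code{activity},
#'   \code{replicate}; \code{replicates * length(concentrations)} rows.
#' @examples
#' tru <- kineticParams(Vmax = 100, Km = 80, Ki = 300)
#' head(generateAssay(tru, noise_sd = 2, replicates = 3, seed = 7))
#' @export
generateAssay <- function(params, concentrations = seq(50, 350, by = 50),
                          noise_sd = 0, replicates = 1L, seed = 1L) {
  stopifnot(is(params, "KineticParams"))
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be sorted strictly ascending")
  if (length(noise_sd) != 1L || noise_sd < 0)
    stop("noise_sd must be a single non-negative number")
  if (replicates < 1L) stop("replicates must be a positive integer")

  S <- rep(concentrations, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(concentrations))
  v0 <- haldaneRate(S, params)
  v <- if (noise_sd > 0)
    withSeed(seed, pmax(0, v0 + rnorm(length(S), sd = noise_sd)))
  else v0
  data.frame(substrate_uM = S, activity = v, replicate = rep_id)
}

#' Write an assay table to CSV
#'
#' @param assay data.frame as returned by [generateAssay()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeAssayCsv <- function(assay, path) {
  stopifnot(all(c("substrate_uM", "activity", "replicate") %in% names(assay)))
  write.csv(assay, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an assay table from CSV
#'
#' Expects the header \code{substrate_uM,activity,replicate}.
#'
#' @param path CSV file path.
#' @return data.frame of assay points.
#' @export
readAssayCsv <- function(path) {
  tab <- read.csv(path)
  need <- c("substrate_uM", "activity", "replicate")
  if (!all(need %in% names(tab)))
    stop("assay CSV must have header substrate_uM,activity,replicate")
  if (any(tab$substrate_uM <= 0)) stop("substrate concentrations must be > 0")
  if (any(tab$activity < 0)) stop("activities must be >= 0")
  tab
}
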