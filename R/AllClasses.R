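#' @import methods
#' @importFrom stats median coef optimize runif rnorm setNames as.dist hclust cutree
#' @importFrom utils read.csv write.csv write.table packageVersion head
NULL

#' Canonical residue ordering of the psiblast PSSM dialect
#'
#' The 20 standard amino acids in the column order used by psiblast ASCII
#' position-specific scoring matrices (and by the PAM/BLOSUM tables shipped
#' with Biostrings).
#'
#' @format A character vector of length 20.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' PSSM: position-specific scoring matrix
#'
#' An L x 20 integer matrix of log-odds scores (half-bit, rounded -- the
#' psiblast ASCII convention) anchored to a wild-type protein sequence.
#' Row i scores every residue at position i; positions are reported
#' 1-based throughout the user-facing API.
#'
#' @slot wtSeq single character string, the wild-type protein sequence
#'   (length L, no gaps).
#' @slot scores numeric L x 20 matrix; columns named by residue in
#'   \code{alphabetOrder}, rows by position.
#' @slot alphabetOrder character vector of 20 residues giving the column
#'   order (a permutation of the standard alphabet).
#'
#' @seealso [buildPSSM()], [readPSSM()], [writePSSM()], [scoreSubstitutions()]
#' @export
setClass("PSSM",
  slots = c(wtSeq = "character", scores = "matrix",
            alphabetOrder = "character"))

setValidity("PSSM", function(object) {
  L <- nchar(object@wtSeq)
  msgs <- character()
  if (length(object@wtSeq) != 1L || L < 1L)
    msgs <- c(msgs, "wtSeq must be a single non-empty string")
  if (!setequal(object@alphabetOrder, AA_ORDER) ||
      length(object@alphabetOrder) != 20L)
    msgs <- c(msgs, "alphabetOrder must be a permutation of the 20 residues")
  if (nrow(object@scores) != L)
    msgs <- c(msgs, sprintf("scores has %d rows but wtSeq has length %d",
                            nrow(object@scores), L))
  if (ncol(object@scores) != 20L)
    msgs <- c(msgs, "scores must have 20 columns")
  if (any(!is.finite(object@scores)))
    msgs <- c(msgs, "all scores must be finite")
  wt_res <- strsplit(object@wtSeq, "")[[1]]
  if (L >= 1L && !all(wt_res %in% AA_ORDER))
    msgs <- c(msgs, sprintf("wtSeq contains non-standard residue at position %d",
                            which(!wt_res %in% AA_ORDER)[1]))
  if (length(msgs)) msgs else TRUE
})

#' VariantLibrary: a designed set of substitution variants
#'
#' The output of [designLibrary()]: a table of single- and
#' double-substitution designs with their PSSM delta scores, ranks and
#' cluster assignments, plus the provenance (parameters and RNG seed)
#' needed to regenerate it.
#'
#' @slot designs data.frame with one row per variant: \code{label},
#'   \code{kind} ("single"/"double"), \code{position1,wt1,mut1,delta1,rank1},
#'   \code{position2,wt2,mut2,delta2,rank2} (NA for singles) and
#'   \code{cluster} (NA for singles).
#' @slot wtSeq the wild-type sequence the designs apply to.
#' @slot params list of design parameters (see [designParams()]).
#' @slot seed integer RNG seed used for the per-cluster draws.
#'
#' @export
setClass("VariantLibrary",
  slots = c(designs = "data.frame", wtSeq = "character",
            params = "list", seed = "integer"))

setValidity("VariantLibrary", function(object) {
  d <- object@designs
  msgs <- character()
  need <- c("label", "kind", "position1", "wt1", "mut1", "delta1")
  if (!all(need %in% names(d)))
    msgs <- c(msgs, "designs is missing required columns")
  else {
    if (anyDuplicated(d$label))
      msgs <- c(msgs, "variant labels must be unique")
    if (!all(d$kind %in% c("single", "double")))
      msgs <- c(msgs, "kind must be 'single' or 'double'")
  }
  if (length(msgs)) msgs else TRUE
})

#' KineticParams: parameters of a single-substrate rate law
#'
#' Vmax (relative-activity units), Km (umol/L) and, when the enzyme is
#' substrate inhibited, Ki (umol/L). Absence of inhibition is encoded
#' explicitly as \code{Ki = NA} (never a large sentinel number), in which
#' case the rate law reduces to Michaelis-Menten.
#'
#' @slot Vmax,Km,Ki numeric scalars; \code{Ki} is \code{NA_real_} for a
#'   non-inhibited enzyme.
#'
#' @seealso [kineticParams()], [haldaneRate()], [fitKinetics()]
#' @export
setClass("KineticParams",
  slots = c(Vmax = "numeric", Km = "numeric", Ki = "numeric"))

setValidity("KineticParams", function(object) {
  msgs <- character()
  if (length(object@Vmax) != 1L || !is.finite(object@Vmax) || object@Vmax <= 0)
    msgs <- c(msgs, "Vmax must be a single positive number")
  if (length(object@Km) != 1L || !is.finite(object@Km) || object@Km <= 0)
    msgs <- c(msgs, "Km must be a single positive number")
  if (length(object@Ki) != 1L ||
      (!is.na(object@Ki) && (!is.finite(object@Ki) || object@Ki <= 0)))
    msgs <- c(msgs, "Ki must be a single positive number or NA (no inhibition)")
  if (length(msgs)) msgs else TRUE
})

#' KineticFit: result of fitting both rate laws to assay data
#'
#' Holds the least-squares fits of the Haldane substrate-inhibition law and
#' the Michaelis-Menten law to the same (S, v) data, their residual sums of
#' squares and small-sample corrected information criteria (AICc), and the
#' resulting classification of the enzyme.
#'
#' @slot haldane,mm [KineticParams-class] estimates under each law.
#' @slot rssHaldane,rssMM residual sums of squares.
#' @slot aiccHaldane,aiccMM corrected information criteria.
#' @slot n number of data points.
#' @slot classification "substrate_inhibited" or "michaelis_menten",
#'   whichever law has the smaller AICc.
#' @slot kiUnbounded TRUE when the fitted Ki ran to the upper bound,
#'   i.e. the inhibition term is not identifiable from the data.
#'
#' @seealso [fitKinetics()], [compareEnzymes()]
#' @export
setClass("KineticFit",
  slots = c(haldane = "KineticParams", mm = "KineticParams",
            rssHaldane = "numeric", rssMM = "numeric",
            aiccHaldane = "numeric", aiccMM = "numeric",
            n = "integer", classification = "character",
            kiUnbounded = "logical"))

setValidity("KineticFit", function(object) {
  msgs <- character()
  if (!object@classification %in% c("substrate_inhibited", "michaelis_menten"))
    msgs <- c(msgs, "unknown classification")
  if (object@rssHaldane < 0 || object@rssMM < 0)
    msgs <- c(msgs, "residual sums of squares must be non-negative")
  want <- if (object@aiccHaldane <= object@aiccMM)
    "substrate_inhibited" else "michaelis_menten"
  if (object@classification != want)
    msgs <- c(msgs, "classification must match the smaller AICc")
  if (length(msgs)) msgs else TRUE
})

#' PathwaySim: trajectory of the flow-restrictor pathway model
#'
#' Time courses of the GGPP (G), lycopene (L) and beta-carotene (B) pools
#' produced by [simulatePathway()], together with the parameters used.
#'
#' @slot trajectory data.frame with columns \code{time, G, L, B} (hours, uM).
#' @slot params the list of simulation parameters (see [pathwayParams()]).
#'
#' @export
setClass("PathwaySim",
  slots = c(trajectory = "data.frame", params = "list"))

setValidity("PathwaySim", function(object) {
  tr <- object@trajectory
  msgs <- character()
  if (!all(c("time", "G", "L", "B") %in% names(tr)))
    msgs <- c(msgs, "trajectory must have columns time, G, L, B")
  else {
    if (any(tr$G < 0 | tr$L < 0 | tr$B < 0))
      msgs <- c(msgs, "all pools must be non-negative")
    if (any(diff(tr$B) < -1e-9 * max(1, max(tr$B))))
      msgs <- c(msgs, "product pool B must be non-decreasing")
  }
  if (length(msgs)) msgs else TRUE
})
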