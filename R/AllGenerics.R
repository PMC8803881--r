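#' Accessors for SubInhib classes
#'
#' @param x a \linkS4class{PSSM}, \linkS4class{VariantLibrary},
#'   \linkS4class{KineticFit} or \linkS4class{PathwaySim} object.
#' @return \code{wtSeq}: the wild-type sequence string. \code{scoreMatrix}:
#'   the L x 20 score matrix. \code{alphabetOrder}: the residue column
#'   order. \code{designs}: the design table. \code{classification}: the
#'   model-selection verdict. \code{trajectory}: the simulated time
#'   courses.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wtSeq", function(x) standardGeneric("wtSeq"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("alphabetOrder", function(x) standardGeneric("alphabetOrder"))

#' @rdname accessors
#' @export
setGeneric("designs", function(x) standardGeneric("designs"))

#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' @rdname accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname accessors
#' @export
setMethod("wtSeq", "PSSM", function(x) x@wtSeq)

#' @rdname accessors
#' @export
setMethod("wtSeq", "VariantLibrary", function(x) x@wtSeq)

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "PSSM", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("alphabetOrder", "PSSM", function(x) x@alphabetOrder)

#' @rdname accessors
#' @export
setMethod("designs", "VariantLibrary", function(x) x@designs)

#' @rdname accessors
#' @export
setMethod("classification", "KineticFit", function(x) x@classification)

#' @rdname accessors
#' @export
setMethod("trajectory", "PathwaySim", function(x) x@trajectory)

setMethod("show", "PSSM", function(object) {
  cat(sprintf("PSSM of length %d (half-bit integer scores)\n",
              nchar(object@wtSeq)))
  cat(sprintf("  wild type: %s%s\n",
              substr(object@wtSeq, 1, 40),
              if (nchar(object@wtSeq) > 40) "..." else ""))
  cat(sprintf("  score range: [%d, %d]\n",
              min(object@scores), max(object@scores)))
})

setMethod("show", "VariantLibrary", function(object) {
  d <- object@designs
  cat(sprintf("VariantLibrary with %d designs (%d doubles, %d singles), seed %d\n",
              nrow(d), sum(d$kind == "double"), sum(d$kind == "single"),
              object@seed))
  cat("  first labels:", paste(head(d$label, 5), collapse = ", "), "...\n")
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf("KineticParams: Vmax = %.4g, Km = %.4g uM, %s\n",
              object@Vmax, object@Km,
              if (is.na(object@Ki)) "no substrate inhibition"
              else sprintf("Ki = %.4g uM", object@Ki)))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit on %d points: %s\n", object@n,
              object@classification))
  cat(sprintf("  Haldane: Vmax = %.4g, Km = %.4g, Ki = %s (RSS %.4g, AICc %.4g)\n",
              object@haldane@Vmax, object@haldane@Km,
              if (object@kiUnbounded) "unbounded"
              else sprintf("%.4g", object@haldane@Ki),
              object@rssHaldane, object@aiccHaldane))
  cat(sprintf("  Michaelis-Menten: Vmax = %.4g, Km = %.4g (RSS %.4g, AICc %.4g)\n",
              object@mm@Vmax, object@mm@Km, object@rssMM, object@aiccMM))
})

setMethod("show", "PathwaySim", function(object) {
  tr <- object@trajectory
  last <- tr[nrow(tr), ]
  cat(sprintf("PathwaySim: %d time points over %.3g h (v_in = %.4g uM/h)\n",
              nrow(tr), max(tr$time), object@params$v_in))
  cat(sprintf("  end pools (uM): GGPP %.4g, lycopene %.4g, beta-carotene %.4g\n",
              last$G, last$L, last$B))
})
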