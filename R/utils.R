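# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# stream afterwards so package functions never perturb user randomness.
withSeed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Split a protein string into residues, validating against the alphabet.
# `allow_gap` admits '-' (alignment columns); errors name the first bad
# position so malformed input is easy to locate.
splitResidues <- function(seq, allow_gap = FALSE, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty string")
  res <- strsplit(seq, "")[[1]]
  ok <- res %in% AA_ORDER | (allow_gap & res == "-")
  if (!all(ok))
    stop(sprintf("%s contains invalid character '%s' at position %d",
                 what, res[which(!ok)[1]], which(!ok)[1]))
  res
}
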