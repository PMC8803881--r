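#' Molar carbon-to-nitrogen ratio of a glucose / yeast extract / peptone
#' medium
#'
#' Computes moles of carbon from glucose over moles of nitrogen from the
#' complex nitrogen sources:
#' \deqn{C/N = \frac{(X / 180.156)\times 6}
#'                  {(0.109\,Y + 0.154\,Z) / 14}}
#' with X, Y, Z the glucose, yeast extract and peptone concentrations in
#' g/L; glucose contributes 6 carbons at 180.156 g/mol, yeast extract and
#' peptone contain 10.9% and 15.4% nitrogen by mass (N at 14 g/mol).
#' Carbon contained in the complex sources is ignored by default (it is
#' negligible next to glucose); supply mass carbon fractions via
#' \code{carbon_ye}/\code{carbon_pep} to include it for sensitivity
#' analyses.
#'
#' @param glucose,yeast_extract,peptone concentrations in g/L (>= 0).
#' @param carbon_ye,carbon_pep optional carbon mass fractions of yeast
#'   extract and peptone (default 0 = ignored), counted at 12.011 g/mol.
#' @return the molar C/N ratio (mol C per mol N).
#' @examples
#' cnRatio(50, 10, 10)              # ~8.86, the 9:1 optimum medium
#' formatCnRatio(cnRatio(50, 10, 10))
#' @export
cnRatio <- function(glucose, yeast_extract, peptone,
                    carbon_ye = 0, carbon_pep = 0) {
  if (glucose < 0 || yeast_extract < 0 || peptone < 0)
    stop("concentrations must be >= 0")
  molN <- (0.109 * yeast_extract + 0.154 * peptone) / 14
  if (molN <= 0)
    stop("medium contains no nitrogen source; C/N ratio undefined")
  molC <- (glucose / 180.156) * 6 +
    (carbon_ye * yeast_extract + carbon_pep * peptone) / 12.011
  molC / molN
}

#' Format a C/N ratio as "N:1"
#'
#' @param ratio molar ratio from [cnRatio()].
#' @return string such as "9:1" (nearest integer).
#' @export
formatCnRatio <- function(ratio) {
  sprintf("%d:1", as.integer(round(ratio)))
}

#' Dry cell weight from optical density
#'
#' Linear OD600 to DCW conversion calibrated per product strain:
#' 0.35 g/L per OD unit for beta-carotene producers, 0.30 for lycopene
#' producers.
#'
#' @param od600 optical density at 600 nm (>= 0).
#' @param product "beta_carotene" or "lycopene".
#' @return dry cell weight in g/L.
#' @examples
#' dcwFromOd(100, "beta_carotene")  # 35
#' @export
dcwFromOd <- function(od600, product = c("beta_carotene", "lycopene")) {
  product <- match.arg(product)
  if (any(od600 < 0)) stop("od600 must be >= 0")
  factor <- c(beta_carotene = 0.35, lycopene = 0.30)[[product]]
  factor * od600
}

#' Carotenoid selectivity
#'
#' Percent of one species relative to the sum of all carotenoids in a
#' profile (titers in any single consistent unit).
#'
#' @param profile named non-negative numeric vector of per-species titers.
#' @param product name of the species of interest (must be in the
#'   profile).
#' @return selectivity in percent.
#' @examples
#' selectivity(c(beta_carotene = 2.38, lycopene = 0.0486), "beta_carotene")
#' @export
selectivity <- function(profile, product) {
  if (is.null(names(profile)) || any(!nzchar(names(profile))))
    stop("profile must be a named vector of titers")
  if (any(profile < 0)) stop("titers must be >= 0")
  total <- sum(profile)
  if (total <= 0) stop("total carotenoid titer must be > 0")
  if (!product %in% names(profile))
    stop(sprintf("product '%s' absent from the profile", product))
  100 * profile[[product]] / total
}

#' Volumetric productivity
#'
#' @param titer_gL final titer in g/L.
#' @param hours fermentation time in hours (> 0).
#' @param digits rounding (default 3 decimal places, the convention for
#'   g/L/h figures).
#' @return productivity in g/L/h.
#' @examples
#' productivity(39.5, 240)  # 0.165
#' @export
productivity <- function(titer_gL, hours, digits = 3) {
  if (hours <= 0) stop("hours must be > 0")
  if (titer_gL < 0) stop("titer must be >= 0")
  round(titer_gL / hours, digits)
}

#' Fold improvement between two titers
#'
#' @param final,initial titers in the same unit; \code{initial > 0}.
#' @param rounding "floor" (default: an improvement is only counted once
#'   fully attained) or "round".
#' @return integer-valued fold change.
#' @examples
#' foldChange(39500, 27.4)  # 1441
#' @export
foldChange <- function(final, initial, rounding = c("floor", "round")) {
  rounding <- match.arg(rounding)
  if (initial <= 0) stop("initial titer must be > 0")
  if (final < 0) stop("final titer must be >= 0")
  x <- final / initial
  if (rounding == "floor") floor(x) else round(x)
}

#' Percent increase between two titers
#'
#' @param initial,final titers in the same unit; \code{initial > 0}.
#' @param digits rounding of the percentage (default whole percent).
#' @return percent increase, \code{100 * (final - initial) / initial}.
#' @examples
#' percentIncrease(3.43, 4.22)  # 23
#' @export
percentIncrease <- function(initial, final, digits = 0) {
  if (initial <= 0) stop("initial titer must be > 0")
  round(100 * (final - initial) / initial, digits)
}
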