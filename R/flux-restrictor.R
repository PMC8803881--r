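#' Parameters of the flow-restrictor pathway model
#'
#' A three-pool model of the terminal carotenoid pathway segment:
#' a zero-order GGPP supply (the GGPPS "flow restrictor" dial), a lumped
#' saturation step GGPP -> lycopene (carB, standing in for the phytoene
#' synthase/dehydrogenase steps), and a substrate-inhibited cyclase step
#' lycopene -> beta-carotene.
#'
#' @param v_in upstream GGPP supply rate in uM/h (the in vivo GGPP
#'   synthesis rate of the chosen GGPPS ortholog).
#' @param carB \linkS4class{KineticParams} for the saturation step
#'   (Ki must be absent).
#' @param cyclase \linkS4class{KineticParams} for the cyclase step
#'   (Ki present = substrate inhibited; NA = inhibition-free variant).
#' @param t_end simulation horizon in hours.
#' @param dt output grid step in hours (< t_end).
#' @param dilution optional first-order dilution rate (1/h) applied to all
#'   pools; default 0 (per-volume cumulative model).
#' @return a validated named list.
#' @export
pathwayParams <- function(v_in, carB, cyclase, t_end = 100, dt = 0.1,
                          dilution = 0) {
  stopifnot(is(carB, "KineticParams"), is(cyclase, "KineticParams"))
  if (!noInhibition(carB))
    stop("carB is the lumped upstream saturation step; it takes no Ki")
  if (length(v_in) != 1L || v_in < 0) stop("v_in must be a single rate >= 0")
  if (t_end <= 0 || dt <= 0 || dt >= t_end)
    stop("need 0 < dt < t_end")
  if (dilution < 0) stop("dilution must be >= 0")
  list(v_in = v_in, carB = carB, cyclase = cyclase,
       t_end = t_end, dt = dt, dilution = dilution)
}

#' Simulate the GGPP -> lycopene -> beta-carotene segment
#'
#' Integrates
#' \deqn{dG/dt = v_{in} - r_{carB}(G),\quad
#'       dL/dt = r_{carB}(G) - r_{cyc}(L),\quad
#'       dB/dt = r_{cyc}(L)}
#' with \eqn{r_{cyc}} the Haldane law, using a stiff-capable adaptive
#' integrator at tight tolerances. Without dilution the system conserves
#' mass: \eqn{G + L + B = v_{in} t} to relative 1e-6, which is checked and
#' enforced as an error. Negative pools beyond integration tolerance are
#' surfaced as failures, never clipped.
#'
#' @param params list from [pathwayParams()].
#' @return a \linkS4class{PathwaySim}.
#' @examples
#' p <- pathwayParams(v_in = 3,
#'                    carB = kineticParams(50, 10),
#'                    cyclase = kineticParams(10, 100, 400),
#'                    t_end = 50, dt = 0.5)
#' simulatePathway(p)
#' @export
simulatePathway <- function(params) {
  rhs <- function(t, y, p) {
    rB <- haldaneRate(max(y[["G"]], 0), params$carB)
    rC <- haldaneRate(max(y[["L"]], 0), params$cyclase)
    list(c(G = params$v_in - rB - params$dilution * y[["G"]],
           L = rB - rC - params$dilution * y[["L"]],
           B = rC - params$dilution * y[["B"]]))
  }
  times <- seq(0, params$t_end, by = params$dt)
  sol <- deSolve::ode(y = c(G = 0, L = 0, B = 0), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-10, maxsteps = 50000)
  tr <- as.data.frame(sol)
  scale <- pmax(1, params$v_in * tr$time)
  if (any(tr$G < -1e-6 * scale | tr$L < -1e-6 * scale |
          tr$B < -1e-6 * scale))
    stop("integration produced negative pools beyond tolerance")
  tr$G <- pmax(tr$G, 0); tr$L <- pmax(tr$L, 0); tr$B <- pmax(tr$B, 0)
  if (params$dilution == 0) {
    supplied <- params$v_in * tr$time
    err <- abs(tr$G + tr$L + tr$B - supplied) / pmax(supplied, 1e-12)
    if (any(err[supplied > 0] > 1e-6))
      stop("mass balance violated beyond relative 1e-6")
  }
  new("PathwaySim", trajectory = tr, params = params)
}

#' Critical GGPP supply rate of a substrate-inhibited cyclase
#'
#' The maximal steady-state throughput of the Haldane law,
#' \eqn{\max_S r_{cyc}(S) = V_{max}/(1 + 2\sqrt{K_m/K_i})}, reached at
#' \eqn{S^* = \sqrt{K_m K_i}}. Supply above this rate admits no finite
#' lycopene steady state: the pool grows without bound (runaway) and the
#' product share collapses. At or below it a stable steady state exists on
#' the rising branch of the curve. For an inhibition-free cyclase the
#' supremum is Vmax (approached asymptotically) and runaway never occurs
#' for \code{v_in < Vmax}; this is flagged on the result.
#'
#' @param cyclase a \linkS4class{KineticParams}.
#' @return the threshold rate (uM/h), with attribute
#'   \code{no_inhibition} = TRUE when Ki is absent.
#' @examples
#' criticalSupply(kineticParams(10, 100, 400))  # 5
#' @export
criticalSupply <- function(cyclase) {
  stopifnot(is(cyclase, "KineticParams"))
  if (noInhibition(cyclase))
    return(structure(cyclase@Vmax, no_inhibition = TRUE))
  structure(cyclase@Vmax / (1 + 2 * sqrt(cyclase@Km / cyclase@Ki)),
            no_inhibition = FALSE)
}

#' Detect lycopene runaway in a simulated trajectory
#'
#' A simulation is in runaway when the lycopene pool is still accumulating
#' a substantial share of the supply at the end of the horizon: the mean
#' dL/dt over the trailing \code{window} fraction of the time course
#' exceeds \code{frac * v_in}. Below the critical supply rate this slope
#' decays to zero as L settles on the rising branch; above it the slope
#' tends to \code{v_in - criticalSupply(cyclase)}.
#'
#' @param sim a \linkS4class{PathwaySim}.
#' @param window trailing fraction of the horizon to measure (default 0.1).
#' @param frac slope threshold as a fraction of the supply rate (default
#'   0.05).
#' @return TRUE when the lycopene pool has not settled.
#' @export
runawayDetected <- function(sim, window = 0.1, frac = 0.05) {
  stopifnot(is(sim, "PathwaySim"))
  tr <- trajectory(sim)
  t_end <- max(tr$time)
  i0 <- which.min(abs(tr$time - (1 - window) * t_end))
  slope <- (tr$L[nrow(tr)] - tr$L[i0]) / (tr$time[nrow(tr)] - tr$time[i0])
  slope > frac * sim@params$v_in
}

#' Sweep the supply rate and profile the product spectrum
#'
#' Runs one simulation per supply rate and reports end-point pools and
#' beta-carotene selectivity (percent of beta-carotene among the
#' carotenoids lycopene + beta-carotene). Across the runaway transition
#' the selectivity drops from near-exclusive product to lycopene-dominated.
#'
#' @param base list from [pathwayParams()]; its \code{v_in} is replaced by
#'   each grid value.
#' @param v_in_grid numeric vector of supply rates (uM/h).
#' @return data.frame with columns \code{v_in}, \code{selectivity_B},
#'   \code{L_end}, \code{B_end}.
#' @export
productProfileSweep <- function(base, v_in_grid) {
  if (!length(v_in_grid) || any(v_in_grid < 0))
    stop("v_in_grid must be non-negative rates")
  rows <- lapply(v_in_grid, function(vi) {
    p <- base; p$v_in <- vi
    tr <- trajectory(simulatePathway(p))
    last <- tr[nrow(tr), ]
    sel <- if (last$L + last$B > 0)
      selectivity(c(beta_carotene = last$B, lycopene = last$L),
                  "beta_carotene")
    else NA_real_
    data.frame(v_in = vi, selectivity_B = sel,
               L_end = last$L, B_end = last$B)
  })
  do.call(rbind, rows)
}
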