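#' Fenestration structural parameters
#'
#' Container for the constants of the fenestration number and diameter ODEs.
#' Defaults are the best-fit values of the published calibration: formation
#' rate `kform` (1/h), loss rate `kloss` (1/h), shape factor `nf`, healthy
#' and diseased steady-state numbers `yNumber_ss1 > yNumber_ss2`, diameter
#' stress rate `ks` (nm/h), diameter restoration rate `kd` (1/h), baseline
#' phospho-MLC `pMLC0`, baseline diameter `yDiameter0` (nm) and the
#' phospho-MLC time constant `tau_pMLC` (h).
#'
#' @param kform,kloss,nf,yNumber_ss1,yNumber_ss2,ks,kd,pMLC0,yDiameter0,tau_pMLC
#'   see description.
#' @return object of class `fen_params` (a named list).
#' @export
fenestration_params <- function(kform = 1.01, kloss = 4.61, nf = 4.00,
                                yNumber_ss1 = 7.00, yNumber_ss2 = 4.02,
                                ks = 65.9, kd = 2.04, pMLC0 = 0,
                                yDiameter0 = 47.91, tau_pMLC = 400.0) {
  p <- list(kform = kform, kloss = kloss, nf = nf,
            yNumber_ss1 = yNumber_ss1, yNumber_ss2 = yNumber_ss2,
            ks = ks, kd = kd, pMLC0 = pMLC0,
            yDiameter0 = yDiameter0, tau_pMLC = tau_pMLC)
  if (any(unlist(p[c("kform", "kloss", "ks", "kd", "tau_pMLC")]) <= 0)) {
    stop("rates and time constants must be positive")
  }
  if (nf < 1) stop("shape factor nf must be >= 1")
  if (!(yNumber_ss1 > yNumber_ss2 && yNumber_ss2 > 0)) {
    stop("need yNumber_ss1 > yNumber_ss2 > 0")
  }
  if (yDiameter0 <= 0) stop("yDiameter0 must be positive")
  if (pMLC0 < 0 || pMLC0 > 1) stop("pMLC0 must lie in [0, 1]")
  structure(p, class = "fen_params")
}

## Sign-preserving power, tolerating transient pmlc < pMLC0 with
## non-integer exponents.
signpow <- function(x, p) sign(x) * abs(x)^p

#' Rate of change of fenestration number
#'
#' `kform * Actin_r * |ss1 - y|^nf - kloss * Actin_s * |ss2 - y|^nf`:
#' relaxed actin forms fenestrations toward the healthy steady state,
#' stressed actin removes them toward the diseased steady state; the
#' absolute-value powers make each fixed point one-sided (semi-stable).
#'
#' @param yNumber current fenestration number (dimensionless density scale).
#' @param actin_r,actin_s relaxed and stressed actin activities in \[0, 1\].
#' @param params a [fenestration_params()] object.
#' @return d yNumber / dt (1/h).
#' @export
number_rhs <- function(yNumber, actin_r, actin_s, params) {
  params$kform * actin_r * abs(params$yNumber_ss1 - yNumber)^params$nf -
    params$kloss * actin_s * abs(params$yNumber_ss2 - yNumber)^params$nf
}

#' Rate of change of fenestration diameter
#'
#' `ks * (pMLC - pMLC0)^nf - kd * (yDiameter - yDiameter0)`: myosin
#' light-chain phosphorylation stretches fenestrations, an unspecified
#' restoring force relaxes the diameter back to baseline. The power is
#' computed sign-preservingly so that transient `pMLC < pMLC0` is tolerated
#' with non-integer `nf`.
#'
#' @param yDiameter current diameter (nm).
#' @param pmlc phospho-MLC activity in \[0, 1\].
#' @inheritParams number_rhs
#' @return d yDiameter / dt (nm/h).
#' @export
diameter_rhs <- function(yDiameter, pmlc, params) {
  params$ks * signpow(pmlc - params$pMLC0, params$nf) -
    params$kd * (yDiameter - params$yDiameter0)
}

#' Integrate the fenestration ODEs driven by a network trajectory
#'
#' Drives the number and diameter equations with piecewise-linear
#' interpolants of the `Actin_r`, `Actin_s` and `pMLC` columns of a
#' simulated network trajectory. The coupled alternative (structure states
#' integrated jointly with the network) is available through
#' [simulate_network()] with `structure = TRUE`; the two agree to solver
#' tolerance.
#'
#' @param network_traj a `fen_trajectory` containing `Actin_r`, `Actin_s`
#'   and `pMLC` columns.
#' @param params a [fenestration_params()] object.
#' @param y0_number,y0_diameter initial values; defaults are the healthy
#'   baselines (`yNumber_ss1`, `yDiameter0`).
#' @param t_span integration span (hours); default the trajectory's span.
#' @param dt output resolution (hours).
#' @param first_term_only logical; when TRUE only the formation term of the
#'   number ODE is active (the stage-1 healthy calibration model).
#' @param rtol,atol solver tolerances.
#' @return data.frame of class `fen_structure` with columns `time`,
#'   `yNumber`, `yDiameter`.
#' @export
simulate_structure <- function(network_traj, params = fenestration_params(),
                               y0_number = params$yNumber_ss1,
                               y0_diameter = params$yDiameter0,
                               t_span = NULL, dt = 1,
                               first_term_only = FALSE,
                               rtol = 1e-6, atol = 1e-6) {
  tr <- as.data.frame(network_traj)
  need <- c("Actin_r", "Actin_s", "pMLC")
  missing_sp <- setdiff(need, names(tr))
  if (length(missing_sp)) {
    stop("network trajectory lacks driver species: ",
         paste(missing_sp, collapse = ", "))
  }
  if (is.null(t_span)) t_span <- range(tr$time)
  if (t_span[1] < min(tr$time) - 1e-9 || t_span[2] > max(tr$time) + 1e-9) {
    stop("t_span outside the driving trajectory's coverage")
  }
  ar <- stats::approxfun(tr$time, tr$Actin_r, rule = 2)
  as_ <- stats::approxfun(tr$time, tr$Actin_s, rule = 2)
  pm <- stats::approxfun(tr$time, tr$pMLC, rule = 2)

  rhs <- function(t, y, parms) {
    dn <- if (first_term_only) {
      params$kform * ar(t) * abs(params$yNumber_ss1 - y[1])^params$nf
    } else {
      number_rhs(y[1], ar(t), as_(t), params)
    }
    list(c(dn, diameter_rhs(y[2], pm(t), params)))
  }
  times <- unique(c(seq(t_span[1], t_span[2], by = dt), t_span[2]))
  sol <- deSolve::lsoda(c(y0_number, y0_diameter), times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  out <- data.frame(time = sol[, 1], yNumber = sol[, 2], yDiameter = sol[, 3])
  class(out) <- c("fen_structure", "data.frame")
  out
}
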