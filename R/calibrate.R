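#' Printed Latin-hypercube sampling ranges for the structural parameters
#'
#' Also used as the optimizer's box constraints.
#'
#' @return named list of `c(lo, hi)` ranges.
#' @export
default_ranges <- function() {
  list(kform = c(0.1, 4), yNumber_ss1 = c(6, 8), nf = c(2, 5),
       kloss = c(1, 5), yNumber_ss2 = c(3, 5),
       ks = c(45, 75), kd = c(1, 4), tau_pMLC = c(400, 600))
}

#' Latin hypercube start points
#'
#' `count` points whose marginals each place exactly one sample in each of
#' `count` equal strata of the given range.
#'
#' @param ranges named list of `c(lo, hi)` per parameter.
#' @param count number of starts (default 25).
#' @param seed RNG seed.
#' @return matrix `count x length(ranges)` with named columns.
#' @export
lhs_starts <- function(ranges, count = 25, seed = 1L) {
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(lo >= hi)) stop("each range needs lo < hi")
  u <- withr_seed(seed, lhs::randomLHS(count, length(ranges)))
  pts <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(pts) <- names(ranges)
  pts
}

#' Sum of squared errors
#'
#' Plain unweighted `sum((pred - obs)^2)`.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return scalar SSE.
#' @export
sse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("sse(): predicted and observed lengths differ")
  }
  sum((predicted - observed)^2)
}

#' Fenestration observation container
#'
#' @param df data.frame with columns `week` (in \{6, 10, 15, 20\} typically),
#'   `arm` (`"healthy"` or `"diabetic"`), `quantity` (`"density"` or
#'   `"width_nm"`), `mean`, `sd`.
#' @return the validated data.frame, class `fen_observations`.
#' @export
fen_observations <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("week", "arm", "quantity", "mean", "sd") %in% names(df)))
  if (any(df$sd < 0)) stop("observation SDs must be >= 0")
  if (!all(df$arm %in% c("healthy", "diabetic"))) stop("unknown arm")
  if (!all(df$quantity %in% c("density", "width_nm"))) stop("unknown quantity")
  df <- df[order(df$arm, df$quantity, df$week), ]
  class(df) <- c("fen_observations", "data.frame")
  df
}

obs_slice <- function(obs, arm, quantity) {
  s <- obs[obs$arm == arm & obs$quantity == quantity, ]
  if (!nrow(s)) stop(sprintf("no %s %s observations", arm, quantity))
  s
}

## Reaction drive for one species, recomputed from a trajectory's columns
## (valid when the species does not feed back into its own inputs).
drive_for_species <- function(net, traj, species) {
  hits <- which(net$reactions$target == species)
  if (!length(hits)) return(rep(0, nrow(traj)))
  drive <- rep(0, nrow(traj))
  for (j in hits) {
    inp <- net$inputs[[j]]
    cst <- hill_constants(net$reactions$n[j], net$reactions$EC50[j])
    fac <- rep(1, nrow(traj))
    for (k in seq_len(nrow(inp))) {
      x <- pmax(traj[[inp$species[k]]], 0)
      f <- cst$B * x^net$reactions$n[j] / (cst$Kn + x^net$reactions$n[j])
      fac <- fac * if (inp$sign[k] == "inhibiting") 1 - f else f
    }
    a <- pmin(pmax(net$reactions$W[j] * fac, 0), 1)
    drive <- drive + a - drive * a
  }
  drive
}

## Exponential integrator for dy/dt = (F(t) - y) / tau on a uniform grid
## with piecewise-linear forcing F; exact per step, O(n) via a compiled
## recursive filter.
lin_relax <- function(f, dt, tau, y0) {
  n <- length(f)
  a <- exp(-dt / tau)
  cc <- (f[-1] - f[-n]) / dt
  b <- f[-1] - tau * cc + (tau * cc - f[-n]) * a
  y <- stats::filter(b, a, method = "recursive", init = y0)
  c(y0, as.numeric(y))
}

## Closed-form solution of the formation-only number equation
## dy/dt = kform * Ar(t) * (ss1 - y)^nf (y < ss1, nf > 1):
## (ss1-y)^(1-nf) grows linearly in the cumulative actin integral.
formation_closed_form <- function(time, ar, kform, ss1, nf, y0) {
  u0 <- ss1 - y0
  if (u0 <= 0) return(rep(min(y0, ss1), length(time)))
  dt <- diff(time)
  cint <- c(0, cumsum((ar[-1] + ar[-length(ar)]) / 2 * dt))
  u <- (u0^(1 - nf) + (nf - 1) * kform * cint)^(-1 / (nf - 1))
  ss1 - u
}

## Multi-start bound-constrained least squares. objective(theta) -> SSE.
multi_start_fit <- function(objective, ranges, count = 25, seed = 1L) {
  starts <- lhs_starts(ranges, count, seed)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  fits <- vector("list", count)
  for (i in seq_len(count)) {
    fits[[i]] <- tryCatch({
      o <- stats::nlminb(starts[i, ], objective,
                         lower = lo, upper = hi, scale = 1 / (hi - lo),
                         control = list(eval.max = 4000, iter.max = 1000,
                                        abs.tol = 0, rel.tol = 1e-12,
                                        x.tol = 1e-10))
      list(par = o$par, sse = o$objective,
           converged = o$convergence == 0,
           start = starts[i, ])
    }, error = function(e) {
      list(par = starts[i, ], sse = Inf, converged = FALSE,
           start = starts[i, ], error = conditionMessage(e))
    })
  }
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  if (all(!is.finite(sses))) stop("all optimization starts failed")
  best <- which.min(sses)
  tab <- data.frame(start = seq_len(count),
                    do.call(rbind, lapply(fits, `[[`, "par")),
                    sse = sses,
                    converged = vapply(fits, `[[`, logical(1), "converged"))
  list(estimates = fits[[best]]$par, sse = sses[best], best = best,
       starts = tab)
}

## Exponential Rosenbrock-Euler integration of the full number equation on
## the driver grid: y_{k+1} = y_k + f(y_k) * dt * phi(lambda * dt) with
## lambda the local Jacobian (always <= 0 inside the admissible band, so
## the step is stable through the fast transient and exact for linear
## decay). Shared by the synthetic-data generator and the calibration
## objective, so the two see the same discretization.
solve_number_grid <- function(time, ar, as_, params, y0) {
  n <- length(time)
  s1 <- params$yNumber_ss1; s2 <- params$yNumber_ss2; nf <- params$nf
  a <- params$kform * ar; b <- params$kloss * as_
  y <- numeric(n); y[1] <- y0
  yk <- y0
  for (k in seq_len(n - 1)) {
    dt <- time[k + 1] - time[k]
    u1 <- s1 - yk; u2 <- yk - s2
    f <- a[k] * abs(u1)^nf - b[k] * abs(u2)^nf
    lam <- -nf * (a[k] * abs(u1)^(nf - 1) * sign(u1) +
                    b[k] * abs(u2)^(nf - 1) * sign(u2))
    z <- lam * dt
    phi <- if (abs(z) < 1e-8) 1 else expm1(z) / z
    yk <- yk + f * dt * phi
    y[k + 1] <- yk
  }
  y
}

## Predicted fenestration number at obs times from actin drivers given on a
## uniform time grid. The formation-only (stage 1) model has a closed form.
predict_number <- function(weeks, grid, params, y0,
                           first_term_only = FALSE) {
  t_obs <- weeks * 168
  if (first_term_only) {
    y <- formation_closed_form(grid$time, grid$ar, params$kform,
                               params$yNumber_ss1, params$nf, y0)
    return(y[match(t_obs, grid$time)])
  }
  y <- solve_number_grid(grid$time, grid$ar, grid$as, params, y0)
  y[match(t_obs, grid$time)]
}

## Predicted diameter at obs times: pMLC re-solved from its network drive
## for the candidate tau_pMLC, then the linear diameter equation, both by
## exact exponential integration on the trajectory grid.
predict_width <- function(weeks, grid, params) {
  p <- lin_relax(grid$pm_drive, grid$dt, params$tau_pMLC, params$pMLC0)
  dss <- params$yDiameter0 +
    (params$ks / params$kd) * signpow(p - params$pMLC0, params$nf)
  d <- lin_relax(dss, grid$dt, 1 / params$kd, params$yDiameter0)
  d[match(weeks * 168, grid$time)]
}

## Uniform-grid drivers extracted from a network trajectory.
driver_grid <- function(net, traj) {
  dt <- unique(round(diff(traj$time), 9))
  if (length(dt) != 1) stop("driver trajectory must be on a uniform grid")
  list(time = traj$time, dt = dt,
       ar = traj$Actin_r, as = traj$Actin_s,
       pm_drive = drive_for_species(net, traj, "pMLC"))
}

#' Stage 1: fit the formation parameters on healthy-arm density
#'
#' Healthy-variant network (Rho/Rock activates MLCP), formation term only;
#' fits `kform`, `yNumber_ss1` and `nf` by bound-constrained least squares
#' from 25 Latin hypercube starts.
#'
#' @param obs a [fen_observations()] table containing healthy densities.
#' @param net the disease-variant network (switched internally).
#' @param schedule glucose schedule (the single mean trajectory).
#' @param y0_number initial number for the healthy formation scenario;
#'   default is the diseased steady state, so the healthy model forms
#'   fenestrations toward its own steady state.
#' @param ranges,starts,seed multi-start controls.
#' @param traj optional pre-computed healthy trajectory (to amortize the
#'   network simulation across replicates).
#' @return list with `estimates`, `sse`, `starts` (all 25 fits), `stage`.
#' @export
fit_stage1_healthy <- function(obs, net = fen_network(),
                               schedule = fen_glucose(),
                               y0_number = 4.02,
                               ranges = default_ranges(),
                               starts = 25, seed = 1L, traj = NULL) {
  d <- obs_slice(obs, "healthy", "density")
  if (is.null(traj)) {
    traj <- simulate_network(network_variant(net, "healthy"), schedule)
  }
  grid <- driver_grid(net, traj)
  base <- fenestration_params()
  objective <- function(theta) {
    p <- base
    p$kform <- theta[["kform"]]; p$yNumber_ss1 <- theta[["yNumber_ss1"]]
    p$nf <- theta[["nf"]]
    pred <- predict_number(d$week, grid, p, y0 = y0_number,
                           first_term_only = TRUE)
    sse(pred, d$mean)
  }
  fit <- multi_start_fit(objective, ranges[c("kform", "yNumber_ss1", "nf")],
                         starts, seed)
  c(fit, list(stage = 1L))
}

#' Stage 2: fit the loss and diameter parameters on diabetic data
#'
#' Two independent sub-fits against the disease-variant simulation: `kloss`
#' and `yNumber_ss2` on diabetic density (full number equation, `nf` held at
#' the stage-1 estimate) and `ks`, `kd`, `tau_pMLC` on diabetic width.
#'
#' @param obs a [fen_observations()] table with diabetic densities/widths.
#' @param stage1 named stage-1 estimates (`kform`, `yNumber_ss1`, `nf`).
#' @inheritParams fit_stage1_healthy
#' @return list with `density` and `width` sub-fit results.
#' @export
fit_stage2_disease <- function(obs, stage1, net = fen_network(),
                               schedule = fen_glucose(),
                               ranges = default_ranges(),
                               starts = 25, seed = 1L, traj = NULL) {
  dd <- obs_slice(obs, "diabetic", "density")
  dw <- obs_slice(obs, "diabetic", "width_nm")
  if (is.null(traj)) {
    traj <- simulate_network(network_variant(net, "disease"), schedule)
  }
  grid <- driver_grid(net, traj)
  base <- fenestration_params()
  base$kform <- stage1[["kform"]]
  base$yNumber_ss1 <- stage1[["yNumber_ss1"]]
  base$nf <- stage1[["nf"]]

  obj_density <- function(theta) {
    p <- base
    p$kloss <- theta[["kloss"]]; p$yNumber_ss2 <- theta[["yNumber_ss2"]]
    pred <- predict_number(dd$week, grid, p, y0 = p$yNumber_ss1)
    sse(pred, dd$mean)
  }
  fit_d <- multi_start_fit(obj_density, ranges[c("kloss", "yNumber_ss2")],
                           starts, seed)

  obj_width <- function(theta) {
    p <- base
    p$ks <- theta[["ks"]]; p$kd <- theta[["kd"]]
    p$tau_pMLC <- theta[["tau_pMLC"]]
    pred <- predict_width(dw$week, grid, p)
    sse(pred, dw$mean)
  }
  fit_w <- multi_start_fit(obj_width, ranges[c("ks", "kd", "tau_pMLC")],
                           starts, seed + 1L)
  list(density = c(fit_d, list(stage = 2L)),
       width = c(fit_w, list(stage = 2L)))
}

#' Fit the fenestration structural model
#'
#' The central estimator: staged multi-start nonlinear least squares for the
#' eight structural parameters, reproducing the published two-stage
#' procedure. Stage 1 fits the formation parameters (`kform`,
#' `yNumber_ss1`, `nf`) to healthy-arm fenestration density with the
#' healthy network variant and only the formation term active; stage 2
#' fixes `nf` and fits (`kloss`, `yNumber_ss2`) to diabetic density and
#' (`ks`, `kd`, `tau_pMLC`) to diabetic width under the disease variant.
#' Each (sub-)fit runs bound-constrained local least squares from 25 Latin
#' hypercube starts over the printed parameter ranges, keeping the lowest
#' SSE.
#'
#' @inheritParams fit_stage1_healthy
#' @param net the network model (disease variant; the healthy variant is
#'   derived internally).
#' @return object of class `fenfit` with methods `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot` and `simulate` (posterior
#'   ensemble).
#' @examples
#' \donttest{
#' study <- synthetic_study(seed = 7)
#' fit <- fit_fenestration(study$obs, seed = 7)
#' coef(fit)
#' }
#' @export
fit_fenestration <- function(obs, net = fen_network(),
                             schedule = fen_glucose(),
                             ranges = default_ranges(),
                             starts = 25, seed = 1L,
                             y0_number = 4.02) {
  obs <- fen_observations(obs)
  traj_h <- simulate_network(network_variant(net, "healthy"), schedule)
  traj_d <- simulate_network(network_variant(net, "disease"), schedule)
  s1 <- fit_stage1_healthy(obs, net, schedule, y0_number = y0_number,
                           ranges = ranges, starts = starts, seed = seed,
                           traj = traj_h)
  s2 <- fit_stage2_disease(obs, s1$estimates, net, schedule,
                           ranges = ranges, starts = starts, seed = seed,
                           traj = traj_d)
  est <- fenestration_params(
    kform = s1$estimates[["kform"]],
    yNumber_ss1 = s1$estimates[["yNumber_ss1"]],
    nf = s1$estimates[["nf"]],
    kloss = s2$density$estimates[["kloss"]],
    yNumber_ss2 = s2$density$estimates[["yNumber_ss2"]],
    ks = s2$width$estimates[["ks"]],
    kd = s2$width$estimates[["kd"]],
    tau_pMLC = s2$width$estimates[["tau_pMLC"]])
  structure(list(params = est, stage1 = s1, stage2 = s2, obs = obs,
                 net = net, schedule = schedule,
                 traj_healthy = traj_h, traj_disease = traj_d,
                 ranges = ranges, starts = starts, seed = seed,
                 y0_number = y0_number),
            class = "fenfit")
}
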