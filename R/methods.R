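#' @export
coef.fenfit <- function(object, ...) {
  p <- object$params
  c(kform = p$kform, yNumber_ss1 = p$yNumber_ss1, nf = p$nf,
    kloss = p$kloss, yNumber_ss2 = p$yNumber_ss2,
    ks = p$ks, kd = p$kd, tau_pMLC = p$tau_pMLC)
}

#' @export
print.fenfit <- function(x, ...) {
  cat("Staged multi-start least-squares fit of fenestration dynamics\n")
  cat(sprintf("  %d Latin hypercube starts per (sub-)fit, seed %d\n",
              x$starts, x$seed))
  cat(sprintf("  SSE: stage 1 %.4g; stage 2 density %.4g; width %.4g\n",
              x$stage1$sse, x$stage2$density$sse, x$stage2$width$sse))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.fenfit <- function(object, ...) {
  est <- coef(object)
  rng <- object$ranges[names(est)]
  tab <- data.frame(
    estimate = est,
    lower = vapply(rng, `[`, numeric(1), 1),
    upper = vapply(rng, `[`, numeric(1), 2),
    stage = c(1, 1, 1, 2, 2, 2, 2, 2))
  out <- list(coefficients = tab,
              sse = c(stage1 = object$stage1$sse,
                      stage2_density = object$stage2$density$sse,
                      stage2_width = object$stage2$width$sse),
              n_obs = nrow(object$obs), starts = object$starts)
  class(out) <- "summary.fenfit"
  out
}

#' @export
print.summary.fenfit <- function(x, ...) {
  cat("Fenestration structural model: staged multi-start least squares\n\n")
  print(round(x$coefficients[, c("estimate", "lower", "upper")], 4))
  cat(sprintf("\nSSE  stage 1: %.4g   stage 2 density: %.4g   width: %.4g\n",
              x$sse[1], x$sse[2], x$sse[3]))
  cat(sprintf("%d observations, %d starts per fit\n", x$n_obs, x$starts))
  invisible(x)
}

## Predicted structure trajectories at a given parameter set, reusing the
## fit's cached network trajectories (same grid integrators as the
## calibration objectives). `dt` subsamples the hourly grid for output.
fenfit_predict_traj <- function(object, params,
                                arm = c("diabetic", "healthy"), dt = 1) {
  arm <- match.arg(arm)
  if (arm == "healthy") {
    grid <- driver_grid(object$net, object$traj_healthy)
    y <- formation_closed_form(grid$time, grid$ar, params$kform,
                               params$yNumber_ss1, params$nf,
                               object$y0_number)
    st <- data.frame(time = grid$time, yNumber = y,
                     yDiameter = params$yDiameter0)
  } else {
    grid <- driver_grid(object$net, object$traj_disease)
    p <- lin_relax(grid$pm_drive, grid$dt, params$tau_pMLC, params$pMLC0)
    dss <- params$yDiameter0 +
      (params$ks / params$kd) * signpow(p - params$pMLC0, params$nf)
    d <- lin_relax(dss, grid$dt, 1 / params$kd, params$yDiameter0)
    num <- solve_number_grid(grid$time, grid$ar, grid$as, params,
                             params$yNumber_ss1)
    st <- data.frame(time = grid$time, yNumber = num, yDiameter = d)
  }
  keep <- seq(1, nrow(st), by = max(1L, round(dt / diff(st$time[1:2]))))
  st[union(keep, nrow(st)), , drop = FALSE]
}

#' Predict fenestration number and diameter from a fitted model
#'
#' @param object a `fenfit`.
#' @param weeks times (weeks) at which to report predictions; default the
#'   fit's observation weeks.
#' @param arm `"diabetic"` (full model) or `"healthy"` (formation-only
#'   stage-1 model).
#' @param ... unused.
#' @return data.frame with `week`, `yNumber`, `yDiameter`.
#' @export
predict.fenfit <- function(object, weeks = NULL,
                           arm = c("diabetic", "healthy"), ...) {
  arm <- match.arg(arm)
  if (is.null(weeks)) weeks <- sort(unique(object$obs$week))
  st <- fenfit_predict_traj(object, object$params, arm)
  i <- vapply(weeks * 168, function(t) which.min(abs(st$time - t)),
              integer(1))
  data.frame(week = weeks, yNumber = st$yNumber[i],
             yDiameter = st$yDiameter[i])
}

#' @export
residuals.fenfit <- function(object, ...) {
  obs <- object$obs
  res <- numeric(nrow(obs))
  ph <- predict(object, sort(unique(obs$week)), arm = "healthy")
  pd <- predict(object, sort(unique(obs$week)), arm = "diabetic")
  for (i in seq_len(nrow(obs))) {
    src <- if (obs$arm[i] == "healthy") ph else pd
    pred <- if (obs$quantity[i] == "density") {
      src$yNumber[src$week == obs$week[i]]
    } else {
      src$yDiameter[src$week == obs$week[i]]
    }
    res[i] <- obs$mean[i] - pred
  }
  res
}

#' Plot a fitted fenestration model
#'
#' Two base-graphics panels: fenestration number and diameter over time at
#' the best-fit parameters, with the observations overlaid.
#'
#' @param x a `fenfit`.
#' @param ... passed to [plot.default()].
#' @export
plot.fenfit <- function(x, ...) {
  st <- fenfit_predict_traj(x, x$params, "diabetic")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  wk <- st$time / 168
  graphics::plot(wk, st$yNumber, type = "l", xlab = "weeks",
                 ylab = "fenestration number", ...)
  o <- obs_slice(x$obs, "diabetic", "density")
  graphics::points(o$week, o$mean, pch = 16)
  graphics::segments(o$week, o$mean - o$sd, o$week, o$mean + o$sd)
  graphics::plot(wk, st$yDiameter, type = "l", xlab = "weeks",
                 ylab = "fenestration diameter (nm)", ...)
  o <- obs_slice(x$obs, "diabetic", "width_nm")
  graphics::points(o$week, o$mean, pch = 16)
  graphics::segments(o$week, o$mean - o$sd, o$week, o$mean + o$sd)
  invisible(x)
}

#' Posterior ensemble predictions from a fitted model
#'
#' Applies the resampling uncertainty-propagation procedure: keeps the
#' multi-start fits within 20% of the lowest SSE, resamples each parameter
#' independently (with replacement) from the acceptable subset, and
#' propagates the `nsim` parameter vectors through the structural model.
#'
#' @param object a `fenfit`.
#' @param nsim ensemble size (default 100).
#' @param seed RNG seed.
#' @param ... unused.
#' @return a [posterior_ensemble()] object.
#' @export
simulate.fenfit <- function(object, nsim = 100, seed = 1L, ...) {
  posterior_ensemble(object, n = nsim, seed = seed)
}
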