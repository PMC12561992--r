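#' Acceptable multi-start subset
#'
#' Fits whose SSE lies within 20% of the lowest SSE
#' (`sse <= 1.2 * min(sse)`).
#'
#' @param fits data.frame of multi-start results with an `sse` column (as in
#'   the `starts` table of a fit), or a list with such a table.
#' @return the qualifying rows.
#' @export
acceptable_subset <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits) && !is.null(fits$starts)) {
    fits <- fits$starts
  }
  fits <- as.data.frame(fits)
  if (!nrow(fits)) stop("empty fit set")
  ok <- is.finite(fits$sse)
  if (!any(ok)) stop("no converged fits")
  fits <- fits[ok, , drop = FALSE]
  fits[fits$sse <= 1.2 * min(fits$sse), , drop = FALSE]
}

#' Resample a parameter posterior from an acceptable subset
#'
#' Each parameter is drawn uniformly at random, independently per parameter
#' and with replacement, from that parameter's values in the subset:
#' marginals are preserved, joint correlations are deliberately broken.
#'
#' @param subset data.frame of acceptable fits (parameter columns).
#' @param parameters character vector of columns to resample; default all
#'   except bookkeeping columns.
#' @param n number of samples (default 100).
#' @param seed RNG seed.
#' @return data.frame of `n` resampled parameter vectors.
#' @export
resample_posterior <- function(subset, parameters = NULL, n = 100,
                               seed = 1L) {
  subset <- as.data.frame(subset)
  if (!nrow(subset)) stop("empty acceptable subset")
  if (is.null(parameters)) {
    parameters <- setdiff(names(subset), c("start", "sse", "converged"))
  }
  withr_seed(seed, {
    out <- lapply(parameters, function(p) {
      # index-based draw: robust to length-one populations
      subset[[p]][sample.int(nrow(subset), n, replace = TRUE)]
    })
  })
  stats::setNames(as.data.frame(out), parameters)
}

#' Equal-tail credible interval of an ensemble
#'
#' Per-time empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`
#' (linear interpolation between order statistics, quantile type 7).
#'
#' @param predictions matrix (time points x ensemble members) or data.frame.
#' @param level credibility level (default 0.95).
#' @return data.frame with columns `lo`, `hi` (one row per time point).
#' @export
credible_interval <- function(predictions, level = 0.95) {
  m <- as.matrix(predictions)
  if (ncol(m) < 2) stop("need at least two ensemble members")
  a <- (1 - level) / 2
  qs <- t(apply(m, 1, stats::quantile, probs = c(a, 1 - a),
                names = FALSE, type = 7))
  data.frame(lo = qs[, 1], hi = qs[, 2])
}

#' Posterior ensemble of structural predictions
#'
#' Builds the acceptable subsets of the three (sub-)fits of a [fenfit],
#' resamples each parameter independently with replacement to `n` vectors,
#' propagates every vector through the structural model driven by the
#' disease-variant network trajectory, and summarizes the prediction
#' ensemble with 95% equal-tail credible bands.
#'
#' @param fit a `fenfit`.
#' @param n ensemble size (default 100).
#' @param seed RNG seed.
#' @param level credibility level.
#' @return object of class `posterior_ensemble`: `samples` (parameter
#'   vectors), `number`, `diameter` (time x member matrices), `time`, and
#'   `bands` (per-time credible intervals for both outputs).
#' @export
posterior_ensemble <- function(fit, n = 100, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "fenfit"))
  sub1 <- acceptable_subset(fit$stage1$starts)
  sub2d <- acceptable_subset(fit$stage2$density$starts)
  sub2w <- acceptable_subset(fit$stage2$width$starts)
  samples <- cbind(
    resample_posterior(sub1, c("kform", "yNumber_ss1", "nf"), n, seed),
    resample_posterior(sub2d, c("kloss", "yNumber_ss2"), n, seed + 1L),
    resample_posterior(sub2w, c("ks", "kd", "tau_pMLC"), n, seed + 2L))

  time <- NULL; num <- NULL; dia <- NULL
  for (i in seq_len(n)) {
    p <- fit$params
    for (nm in names(samples)) p[[nm]] <- samples[[nm]][i]
    st <- fenfit_predict_traj(fit, p, "diabetic", dt = 24)
    if (is.null(time)) {
      time <- st$time
      num <- matrix(NA_real_, length(time), n)
      dia <- matrix(NA_real_, length(time), n)
    }
    num[, i] <- st$yNumber
    dia[, i] <- st$yDiameter
  }
  structure(list(samples = samples, time = time,
                 number = num, diameter = dia,
                 bands = list(number = credible_interval(num, level),
                              diameter = credible_interval(dia, level)),
                 level = level, seed = seed),
            class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf("Posterior ensemble: %d members, %g%% equal-tail bands\n",
              ncol(x$number), 100 * x$level))
  i <- length(x$time)
  cat(sprintf("  at %g weeks: number [%.3f, %.3f], diameter [%.2f, %.2f] nm\n",
              x$time[i] / 168,
              x$bands$number$lo[i], x$bands$number$hi[i],
              x$bands$diameter$lo[i], x$bands$diameter$hi[i]))
  invisible(x)
}
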