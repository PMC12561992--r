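#' Dimensional glucose along the early linear segment
#'
#' Blood glucose in diabetic mice rises approximately linearly between weeks
#' 2 and 6; the fitted line is `G(t) = 0.051 t - 9.38` mmol/l with `t` in
#' hours on \[336, 1008\].
#'
#' @param t time in hours, within \[336, 1008\].
#' @param slope,intercept line coefficients (mmol/l/h, mmol/l).
#' @return glucose concentration in mmol/l.
#' @export
linear_glucose <- function(t, slope = 0.051, intercept = -9.38) {
  if (any(t < 336 - 1e-9 | t > 1008 + 1e-9)) {
    stop("linear_glucose(): t outside the fitted span [336, 1008] h")
  }
  slope * t + intercept
}

#' Build a glucose stimulus schedule
#'
#' The schedule is the linear segment on \[336, 1008\] h followed by a
#' piecewise-constant (left-closed, right-open) interval function at the
#' supplied values. The normalization anchors are `gmin`, the predicted
#' concentration at 2 weeks from the linear fit, and `gmax`, the maximum
#' mean + SD among the late (12--20 week) intervals, so the normalized
#' weight may exceed 1 on the earlier weekly intervals.
#'
#' @param intervals data.frame with columns `t_start_h`, `t_end_h`,
#'   `mean_mmol_l`, `sd_mmol_l`; contiguous, covering `[1008, t_end]`.
#' @param values per-interval glucose values actually used (mmol/l);
#'   defaults to the interval means (the single mean trajectory).
#' @param slope,intercept linear-segment coefficients.
#' @param gmax normalization maximum (mmol/l); default is the maximum
#'   `mean + sd` over intervals starting at or after 2016 h (12 weeks).
#' @param t_end end of coverage in hours; when beyond the last interval the
#'   final value is held constant (used for intervention runs to 30 weeks).
#' @return object of class `glucose_schedule`.
#' @export
glucose_schedule <- function(intervals, values = NULL,
                             slope = 0.051, intercept = -9.38,
                             gmax = NULL, t_end = NULL) {
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("t_start_h", "t_end_h", "mean_mmol_l", "sd_mmol_l")
                %in% names(intervals)))
  o <- order(intervals$t_start_h)
  intervals <- intervals[o, , drop = FALSE]
  if (any(intervals$sd_mmol_l < 0)) stop("interval SDs must be >= 0")
  if (abs(intervals$t_start_h[1] - 1008) > 1e-9) {
    stop("first interval must start at 1008 h (6 weeks)")
  }
  gaps <- intervals$t_start_h[-1] - intervals$t_end_h[-nrow(intervals)]
  if (any(abs(gaps) > 1e-9)) stop("intervals must be contiguous")

  if (is.null(values)) values <- intervals$mean_mmol_l
  if (length(values) != nrow(intervals)) {
    stop("need one glucose value per interval")
  }
  gmin <- slope * 336 + intercept
  if (is.null(gmax)) {
    late <- intervals$t_start_h >= 2016
    if (!any(late)) late <- rep(TRUE, nrow(intervals))
    gmax <- max(intervals$mean_mmol_l[late] + intervals$sd_mmol_l[late])
  }
  if (gmax <= gmin) stop("degenerate normalization range: gmax <= gmin")

  last <- max(intervals$t_end_h)
  if (is.null(t_end)) t_end <- last
  structure(list(intervals = intervals, values = as.numeric(values),
                 slope = slope, intercept = intercept,
                 gmin = gmin, gmax = gmax,
                 t_end = t_end, control_at = Inf),
            class = "glucose_schedule")
}

#' Evaluate a glucose schedule
#'
#' Linear on \[336, 1008\) h, then the piecewise-constant interval value
#' (left-closed, right-open); beyond the last interval the final value is
#' held (when the schedule's `t_end` allows). After a glucose-control time
#' (see [glucose_control()]) the concentration is reset to `gmin`.
#'
#' @param schedule a `glucose_schedule`.
#' @param t times in hours.
#' @return glucose concentration(s) in mmol/l.
#' @export
glucose_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "glucose_schedule"))
  if (any(t < 336 - 1e-9 | t > schedule$t_end + 1e-9)) {
    stop("glucose_at(): time outside schedule coverage")
  }
  iv <- schedule$intervals
  g <- numeric(length(t))
  lin <- t < 1008
  g[lin] <- schedule$slope * t[lin] + schedule$intercept
  if (any(!lin)) {
    idx <- findInterval(t[!lin], iv$t_start_h)  # left-closed, right-open
    g[!lin] <- schedule$values[pmin(idx, nrow(iv))]
  }
  g[t >= schedule$control_at] <- schedule$gmin
  g
}

#' Normalized glucose reaction weight
#'
#' Affine normalization of the dimensional schedule,
#' `W'(t) = (G(t) - gmin) / (gmax - gmin)`; values above 1 are allowed (and
#' occur on the weekly intervals whose means exceed the late-interval
#' normalization anchor).
#'
#' @inheritParams glucose_at
#' @return dimensionless weight(s).
#' @export
glucose_weight <- function(schedule, t) {
  (glucose_at(schedule, t) - schedule$gmin) / (schedule$gmax - schedule$gmin)
}

#' Apply a glucose-control intervention
#'
#' From `t_c` onward the schedule returns `G(t) = gmin`, i.e. a normalized
#' weight of exactly 0.
#'
#' @param schedule a `glucose_schedule`.
#' @param t_c intervention time in hours.
#' @return the modified schedule.
#' @export
glucose_control <- function(schedule, t_c) {
  stopifnot(inherits(schedule, "glucose_schedule"))
  schedule$control_at <- t_c
  schedule
}

#' Extend schedule coverage by holding the final value
#'
#' @param schedule a `glucose_schedule`.
#' @param t_end new end of coverage (hours).
#' @return the schedule with extended coverage.
#' @export
extend_schedule <- function(schedule, t_end) {
  stopifnot(inherits(schedule, "glucose_schedule"))
  schedule$t_end <- max(schedule$t_end, t_end)
  schedule
}

#' Virtual mouse population of glucose schedules
#'
#' Draws `n` independent normal samples per interval (mean and SD from the
#' interval statistics) and assembles one piecewise-constant schedule per
#' virtual mouse; all mice share the linear segment and the normalization
#' anchors. Reproducible under a fixed seed. Negative draws are kept (the
#' observation model is plain additive normal) with a warning.
#'
#' @param schedule the mean `glucose_schedule` carrying the interval stats.
#' @param n population size (default 100).
#' @param seed RNG seed.
#' @return object of class `glucose_population`: list of schedules plus the
#'   sampling metadata.
#' @export
sample_population <- function(schedule, n = 100, seed = 1L) {
  stopifnot(inherits(schedule, "glucose_schedule"), n >= 1)
  iv <- schedule$intervals
  if (any(iv$sd_mmol_l < 0)) stop("interval SDs must be >= 0")
  draws <- withr_seed(seed, {
    vapply(seq_len(nrow(iv)), function(k) {
      stats::rnorm(n, iv$mean_mmol_l[k], iv$sd_mmol_l[k])
    }, numeric(n))
  })
  draws <- matrix(draws, nrow = n)  # n x intervals
  if (any(draws < 0)) {
    warning("negative glucose draws kept un-truncated (",
            sum(draws < 0), " values)")
  }
  mice <- lapply(seq_len(n), function(i) {
    s <- schedule
    s$values <- draws[i, ]
    s
  })
  structure(list(mice = mice, n = n, seed = seed, draws = draws,
                 interval_stats = iv),
            class = "glucose_population")
}

## Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' The hyperglycemic glucose fixture shipped with the package
#'
#' Weekly intervals for weeks 6--11 at hyperglycemic values and biweekly
#' intervals for weeks 12--20 at the slightly lower late-stage
#' values that anchor the normalization; see the package vignette for the
#' rationale. The fixture is synthetic: it emulates the shape and variance
#' of the published mouse measurements, which are not tabulated here.
#'
#' @inheritParams glucose_schedule
#' @return a `glucose_schedule`.
#' @export
fen_glucose <- function(t_end = NULL) {
  dir <- system.file("extdata", package = "fenestra")
  read_glucose_fixture(file.path(dir, "glucose_intervals.csv"),
                       file.path(dir, "glucose_meta.json"),
                       t_end = t_end)
}

#' @export
print.glucose_schedule <- function(x, ...) {
  cat(sprintf(paste0("Glucose schedule: linear %0.3f*t%+0.2f on [336, 1008] h, ",
                     "%d intervals to %g h\n"),
              x$slope, x$intercept, nrow(x$intervals),
              max(x$intervals$t_end_h)))
  cat(sprintf("gmin = %.3f, gmax = %.2f mmol/l", x$gmin, x$gmax))
  if (is.finite(x$control_at)) {
    cat(sprintf("; glucose control from %g h", x$control_at))
  }
  cat("\n")
  invisible(x)
}
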