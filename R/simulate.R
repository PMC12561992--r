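## Compile a network into flat arrays for fast right-hand-side evaluation.
compile_network <- function(net) {
  sp <- net$species
  idx <- stats::setNames(seq_len(nrow(sp)), sp$id)
  nr <- nrow(net$reactions)
  in1 <- integer(nr); s1 <- integer(nr)
  in2 <- rep(NA_integer_, nr); s2 <- integer(nr)
  for (j in seq_len(nr)) {
    inp <- net$inputs[[j]]
    if (nrow(inp) > 2) {
      stop("reactions with more than two inputs are not supported")
    }
    in1[j] <- idx[[inp$species[1]]]
    s1[j] <- if (inp$sign[1] == "inhibiting") -1L else 1L
    if (nrow(inp) == 2) {
      in2[j] <- idx[[inp$species[2]]]
      s2[j] <- if (inp$sign[2] == "inhibiting") -1L else 1L
    }
  }
  cst <- hill_constants(net$reactions$n, net$reactions$EC50)
  list(n_species = nrow(sp), idx = idx,
       ymax = sp$ymax, y0 = sp$y0, tau = sp$tau,
       glu = idx[[net$stimulus]],
       target = idx[net$reactions$target],
       in1 = in1, s1 = s1, in2 = in2, s2 = s2,
       has2 = !is.na(in2),
       W = net$reactions$W, nh = net$reactions$n,
       B = cst$B, Kn = cst$Kn)
}

#' Assemble the network right-hand side
#'
#' For every species `i` the dynamics are
#' `dy_i/dt = (ymax_i * F_i(y, t) - y_i) / tau_i`, where `F_i` is the
#' OR-fold (in reaction-table order) of the weighted, \[0, 1\]-clipped AND
#' products of the normalized-Hill edge transfers of its incoming reactions.
#' The stimulus species takes `F = W'(t)`, the normalized glucose weight,
#' which may exceed 1.
#'
#' @param net a `fen_network`.
#' @param schedule a `glucose_schedule` covering the simulation span.
#' @param structure optional [fenestration_params()]; when supplied the
#'   returned derivative also integrates the fenestration number and
#'   diameter as two appended states.
#' @return function `(t, y, parms)` suitable for [deSolve::lsoda()].
#' @export
assemble_rhs <- function(net, schedule, structure = NULL) {
  cm <- compile_network(net)
  ## clamp: the stiff solver's internal trial steps may overshoot coverage
  wfun <- function(t) {
    glucose_weight(schedule, min(max(t, 336), schedule$t_end))
  }
  make_rhs(cm, wfun, structure)
}

make_rhs <- function(cm, wfun, structure = NULL) {
  ns <- cm$n_species
  force(structure)
  function(t, y, parms) {
    ys <- pmax(y[seq_len(ns)], 0)
    f1 <- cm$B * ys[cm$in1]^cm$nh / (cm$Kn + ys[cm$in1]^cm$nh)
    fac <- ifelse(cm$s1 < 0, 1 - f1, f1)
    if (any(cm$has2)) {
      i2 <- which(cm$has2)
      x2 <- ys[cm$in2[i2]]
      f2 <- cm$B[i2] * x2^cm$nh[i2] / (cm$Kn[i2] + x2^cm$nh[i2])
      fac[i2] <- fac[i2] * ifelse(cm$s2[i2] < 0, 1 - f2, f2)
    }
    a <- pmin(pmax(cm$W * fac, 0), 1)
    f_drive <- numeric(ns)
    for (j in seq_along(a)) {            # left-associative OR fold
      tg <- cm$target[j]
      f_drive[tg] <- f_drive[tg] + a[j] - f_drive[tg] * a[j]
    }
    f_drive[cm$glu] <- wfun(t)
    dy <- (cm$ymax * f_drive - ys) / cm$tau
    if (is.null(structure)) return(list(dy))
    p <- structure
    nN <- y[ns + 1L]; nD <- y[ns + 2L]
    iar <- cm$idx[["Actin_r"]]; ias <- cm$idx[["Actin_s"]]
    ipm <- cm$idx[["pMLC"]]
    dn <- number_rhs(nN, ys[iar], ys[ias], p)
    dd <- diameter_rhs(nD, ys[ipm], p)
    list(c(dy, dn, dd))
  }
}

#' Simulate the logic-based ODE network
#'
#' Integrates the network (optionally with the fenestration structure states
#' appended) over `t_span` with a stiff solver at tolerance 1e-6 and dense
#' hourly output. Timed parameter overrides are applied by splitting the
#' integration at the event times and restarting with the modified
#' parameters and continuous state; each override replaces the stored value
#' with `scale * pristine value`, computed once from the pristine network,
#' so repeated events do not compound.
#'
#' @param net a `fen_network`.
#' @param schedule a `glucose_schedule`; automatically extended (holding the
#'   final glucose value) when `t_span` runs past its coverage.
#' @param t_span simulation span in hours, default `c(336, 3360)`
#'   (2--20 weeks); intervention runs use up to 5040 h (30 weeks).
#' @param events list of overrides, each
#'   `list(time =, type = "ymax"|"W", target = species or reaction id,
#'   scale =)` with `0 <= scale <= 1`.
#' @param structure optional [fenestration_params()]; when supplied the
#'   trajectory gains `yNumber` and `yDiameter` columns (joint integration).
#' @param y0 optional initial state for the species (defaults to the
#'   network's `y0`).
#' @param y0_number,y0_diameter structure initial values (healthy
#'   baselines by default).
#' @param dt dense-output resolution (hours).
#' @param rtol,atol solver tolerances.
#' @return data.frame of class `fen_trajectory`: `time` plus one column per
#'   species (and the two structure columns when requested).
#' @export
simulate_network <- function(net, schedule, t_span = c(336, 3360),
                             events = list(), structure = NULL,
                             y0 = NULL,
                             y0_number = NULL, y0_diameter = NULL,
                             dt = 1, rtol = 1e-6, atol = 1e-6) {
  stopifnot(inherits(net, "fen_network"), length(t_span) == 2,
            t_span[2] > t_span[1])
  schedule <- extend_schedule(schedule, t_span[2])
  if (!is.null(structure)) {
    if (isTRUE(structure)) structure <- fenestration_params()
    if (is.null(y0_number)) y0_number <- structure$yNumber_ss1
    if (is.null(y0_diameter)) y0_diameter <- structure$yDiameter0
  }
  ev_times <- vapply(events, `[[`, numeric(1), "time")
  if (length(ev_times) && (any(ev_times < t_span[1]) ||
                           any(ev_times > t_span[2]))) {
    stop("event time outside the simulation span")
  }
  breaks <- sort(unique(c(t_span, ev_times)))

  state <- if (is.null(y0)) net$species$y0 else y0
  if (!is.null(structure)) state <- c(state, y0_number, y0_diameter)
  pieces <- vector("list", length(breaks) - 1)
  for (k in seq_len(length(breaks) - 1)) {
    seg <- c(breaks[k], breaks[k + 1])
    active <- events[ev_times <= seg[1] + 1e-9]
    seg_net <- apply_overrides(net, active)
    rhs <- assemble_rhs(seg_net, schedule, structure)
    times <- unique(c(seq(seg[1], seg[2], by = dt), seg[2]))
    sol <- deSolve::lsoda(state, times, rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("solver failed on segment [%g, %g] h", seg[1], seg[2]))
    }
    state <- sol[nrow(sol), -1]
    pieces[[k]] <- if (k == 1) sol else sol[-1, , drop = FALSE]
  }
  sol <- do.call(rbind, pieces)
  out <- as.data.frame(sol)
  names(out) <- c("time", net$species$id,
                  if (!is.null(structure)) c("yNumber", "yDiameter"))
  class(out) <- c("fen_trajectory", "data.frame")
  out
}

## Apply ymax / W overrides to a pristine network copy.
apply_overrides <- function(net, overrides) {
  for (ov in overrides) {
    if (is.null(ov$scale) || ov$scale < 0 || ov$scale > 1) {
      stop("override scale must lie in [0, 1]")
    }
    if (ov$type == "ymax") {
      i <- match(ov$target, net$species$id)
      if (is.na(i)) stop("unknown species in override: ", ov$target)
      net$species$ymax[i] <- ov$scale * net$species$ymax[i]
      net$species$y0[i] <- min(net$species$y0[i], net$species$ymax[i])
    } else if (ov$type == "W") {
      i <- match(as.character(ov$target), as.character(net$reactions$id))
      if (is.na(i)) stop("unknown reaction in override: ", ov$target)
      net$reactions$W[i] <- ov$scale * net$reactions$W[i]
    } else {
      stop("override type must be 'ymax' or 'W'")
    }
  }
  net
}
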