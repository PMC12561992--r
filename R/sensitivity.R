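## Chemical agents with known inhibitory action on network targets.
CHEMICAL_AGENTS <- c("KN93" = "Ca", "ML-7" = "MLCK", "Y27632" = "RhoRock",
                     "calyculin A" = "MLCP", "cytochalasin B" = "Actin_s")

#' Normalized local sensitivity index
#'
#' `S = 100 * (dY / dP) * (P / Y_base)` in percent. For a complete knockdown
#' (`dP = -P`) this reduces to `-100 * dY / Y_base`: a positive index means
#' the perturbed model predicted a smaller output than the unperturbed one.
#'
#' @param y_base,y_pert output at the optimal and perturbed parameter.
#' @param p optimal parameter value.
#' @param delta_p applied perturbation (`p_perturbed - p`), non-zero.
#' @return sensitivity in percent.
#' @export
sensitivity_index <- function(y_base, y_pert, p, delta_p) {
  if (any(y_base == 0)) stop("zero baseline output")
  if (any(delta_p == 0)) stop("zero parameter perturbation")
  100 * ((y_pert - y_base) / delta_p) * (p / y_base)
}

#' Intervention plan
#'
#' @param kind `"species_knockdown"`, `"reaction_inhibition"`,
#'   `"glucose_control"` or `"chemical_agent"`.
#' @param target species id, reaction id, or agent name (one of
#'   KN93, ML-7, Y27632, calyculin A, cytochalasin B).
#' @param scale fraction of the pristine `ymax`/`W` retained (0 = complete
#'   inhibition, 0.5 = 50% reduction). Ignored for glucose control.
#' @param t_apply application time (hours).
#' @param t_end simulation end (hours), default 5040 (30 weeks).
#' @return a list of class `intervention_plan`.
#' @export
intervention_plan <- function(kind = c("species_knockdown",
                                       "reaction_inhibition",
                                       "glucose_control", "chemical_agent"),
                              target = NULL, scale = 0,
                              t_apply = 336, t_end = 5040) {
  kind <- match.arg(kind)
  if (scale < 0 || scale > 1) stop("scale must lie in [0, 1]")
  if (kind == "chemical_agent") {
    if (!target %in% names(CHEMICAL_AGENTS)) {
      stop("unknown chemical agent: ", target)
    }
  }
  structure(list(kind = kind, target = target, scale = scale,
                 t_apply = t_apply, t_end = t_end),
            class = "intervention_plan")
}

#' Translate an intervention plan into simulation inputs
#'
#' Glucose control resets the schedule to `gmin` (weight 0) from `t_apply`;
#' species knockdowns and chemical agents rescale the target's `ymax`,
#' reaction inhibitions rescale the reaction weight, both through the timed
#' event mechanism (chemical agents at the initial time by convention).
#'
#' @param net a `fen_network`.
#' @param schedule a `glucose_schedule`.
#' @param plan an [intervention_plan()].
#' @return list with `net`, `schedule`, `events`, `t_span` ready for
#'   [simulate_network()].
#' @export
apply_intervention <- function(net, schedule, plan) {
  stopifnot(inherits(plan, "intervention_plan"))
  events <- list()
  if (plan$kind == "glucose_control") {
    schedule <- glucose_control(schedule, plan$t_apply)
  } else if (plan$kind == "species_knockdown") {
    if (!plan$target %in% net$species$id) {
      stop("unknown species: ", plan$target)
    }
    events <- list(list(time = plan$t_apply, type = "ymax",
                        target = plan$target, scale = plan$scale))
  } else if (plan$kind == "reaction_inhibition") {
    if (!as.character(plan$target) %in% as.character(net$reactions$id)) {
      stop("unknown reaction: ", plan$target)
    }
    events <- list(list(time = plan$t_apply, type = "W",
                        target = plan$target, scale = plan$scale))
  } else {  # chemical agent: complete target knockdown at the initial time
    events <- list(list(time = plan$t_apply, type = "ymax",
                        target = CHEMICAL_AGENTS[[plan$target]],
                        scale = plan$scale))
  }
  list(net = net, schedule = schedule, events = events,
       t_span = c(336, plan$t_end))
}

#' Simulate an intervention scenario
#'
#' @inheritParams apply_intervention
#' @param structure [fenestration_params()] (appended structure states).
#' @param ... passed to [simulate_network()].
#' @return a `fen_trajectory` including `yNumber` and `yDiameter`.
#' @export
simulate_intervention <- function(net, schedule, plan,
                                  structure = fenestration_params(), ...) {
  parts <- apply_intervention(net, schedule, plan)
  simulate_network(parts$net, parts$schedule, t_span = parts$t_span,
                   events = parts$events, structure = structure, ...)
}

#' One-at-a-time knockdown / inhibition sensitivity screen
#'
#' Reduces each species' `ymax` and each reaction's `W` by 100% from its
#' optimal value for the entire simulation, one at a time, and reports the
#' normalized sensitivity index of the fenestration number and diameter at
#' the final time, with the 1.5% sensitive/non-sensitive classification.
#' Uses the single mean glucose trajectory.
#'
#' @param net a `fen_network` (disease variant).
#' @param schedule a `glucose_schedule`.
#' @param structure [fenestration_params()].
#' @param targets optional subset: list with `species` and/or `reactions`
#'   character vectors (default: all species and all reactions).
#' @param t_span simulation span (hours).
#' @param threshold sensitivity classification cutoff in percent.
#' @return data.frame with one row per target and output: `target`, `type`,
#'   `output`, `y_base`, `y_pert`, `S`, `sensitive`.
#' @export
screen_sensitivity <- function(net, schedule,
                               structure = fenestration_params(),
                               targets = NULL, t_span = c(336, 3360),
                               threshold = 1.5) {
  base <- simulate_network(net, schedule, t_span = t_span,
                           structure = structure)
  nb <- base$yNumber[nrow(base)]
  db <- base$yDiameter[nrow(base)]
  if (is.null(targets)) {
    targets <- list(species = net$species$id,
                    reactions = net$reactions$id)
  }
  rows <- list()
  run_one <- function(net2, label, type) {
    tr <- tryCatch(
      simulate_network(net2, schedule, t_span = t_span,
                       structure = structure),
      error = function(e) stop(sprintf("screen failed for %s '%s': %s",
                                       type, label, conditionMessage(e))))
    np <- tr$yNumber[nrow(tr)]; dp <- tr$yDiameter[nrow(tr)]
    data.frame(target = label, type = type,
               output = c("yNumber", "yDiameter"),
               y_base = c(nb, db), y_pert = c(np, dp),
               S = c(sensitivity_index(nb, np, 1, -1),
                     sensitivity_index(db, dp, 1, -1)))
  }
  for (sp in targets$species) {
    net2 <- apply_overrides(net, list(list(time = 0, type = "ymax",
                                           target = sp, scale = 0)))
    rows[[length(rows) + 1]] <- run_one(net2, sp, "species")
  }
  for (rj in targets$reactions) {
    net2 <- apply_overrides(net, list(list(time = 0, type = "W",
                                           target = rj, scale = 0)))
    i <- match(as.character(rj), as.character(net$reactions$id))
    rows[[length(rows) + 1]] <- run_one(net2, net$reactions$rule[i],
                                        "reaction")
  }
  out <- do.call(rbind, rows)
  out$sensitive <- abs(out$S) > threshold
  rownames(out) <- NULL
  out
}

#' Pooled-variance two-sample t test
#'
#' Equal-variance two-sided Student's t test between two groups, either
#' from raw values or from summary statistics (means, SDs, sizes); the two
#' routes agree algebraically.
#'
#' @param a,b numeric vectors (raw-value route).
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b summary-statistic route.
#' @return list with `t`, `df`, `p` and `stars` (significance annotation at
#'   0.05 / 0.01 / 0.001 / 0.0001).
#' @export
two_sample_ttest <- function(a = NULL, b = NULL,
                             mean_a = NULL, sd_a = NULL, n_a = NULL,
                             mean_b = NULL, sd_b = NULL, n_b = NULL) {
  if (!is.null(a) && !is.null(b)) {
    if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1, stars = ""))
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    t <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  } else {
    if (any(vapply(list(mean_a, sd_a, n_a, mean_b, sd_b, n_b), is.null,
                   logical(1)))) {
      stop("supply either raw values or all six summary statistics")
    }
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    if (sp2 == 0) return(list(t = 0, df = df, p = 1, stars = ""))
    t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    p <- 2 * stats::pt(-abs(t), df)
  }
  stars <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 1e-2) "**" else if (p < 0.05) "*" else ""
  list(t = t, df = df, p = p, stars = stars)
}

#' Chemical-agent knockout battery over a virtual population
#'
#' Simulates the untreated diseased population and each chemical-agent
#' knockout (target `ymax` set to 0 at the initial time) over the virtual
#' mouse population, reports group means and SDs of fenestration number and
#' diameter at the evaluation time, and pooled-variance t tests of each
#' treatment against the untreated group.
#'
#' @param net disease-variant `fen_network`.
#' @param population a [sample_population()] object.
#' @param structure [fenestration_params()].
#' @param agents agent names (default all five).
#' @param t_eval evaluation time in hours (default 3360, 20 weeks).
#' @return list with `values` (per-mouse outputs by group), `summary`
#'   (group means/SDs) and `tests` (vs the untreated group).
#' @export
agent_battery <- function(net, population,
                          structure = fenestration_params(),
                          agents = names(CHEMICAL_AGENTS),
                          t_eval = 3360) {
  stopifnot(inherits(population, "glucose_population"))
  groups <- c("no treatment", agents)
  run_group <- function(agent) {
    vapply(population$mice, function(sch) {
      plan <- if (is.null(agent)) NULL else
        intervention_plan("chemical_agent", agent, scale = 0,
                          t_apply = 336, t_end = t_eval)
      tr <- if (is.null(agent)) {
        simulate_network(net, sch, t_span = c(336, t_eval),
                         structure = structure)
      } else {
        simulate_intervention(net, sch, plan, structure = structure)
      }
      i <- nrow(tr)
      c(number = tr$yNumber[i], diameter = tr$yDiameter[i])
    }, numeric(2))
  }
  values <- c(list(run_group(NULL)),
              lapply(agents, run_group))
  names(values) <- groups
  summary <- do.call(rbind, lapply(groups, function(g) {
    v <- values[[g]]
    data.frame(group = g,
               number_mean = mean(v["number", ]),
               number_sd = stats::sd(v["number", ]),
               diameter_mean = mean(v["diameter", ]),
               diameter_sd = stats::sd(v["diameter", ]))
  }))
  tests <- do.call(rbind, lapply(agents, function(g) {
    tn <- two_sample_ttest(values[[g]]["number", ],
                           values[["no treatment"]]["number", ])
    td <- two_sample_ttest(values[[g]]["diameter", ],
                           values[["no treatment"]]["diameter", ])
    data.frame(group = g, number_t = tn$t, number_p = tn$p,
               diameter_t = td$t, diameter_p = td$p)
  }))
  list(values = values, summary = summary, tests = tests)
}

#' Change from baseline along a trajectory
#'
#' `y(t_eval) - y(t_ref)` per species / structural output.
#'
#' @param traj a `fen_trajectory`.
#' @param t_ref,t_eval reference and evaluation times (hours), within the
#'   trajectory's span.
#' @return named numeric vector of changes.
#' @export
relative_change_from_baseline <- function(traj, t_ref = NULL,
                                          t_eval = NULL) {
  traj <- as.data.frame(traj)
  if (is.null(t_ref)) t_ref <- min(traj$time)
  if (is.null(t_eval)) t_eval <- max(traj$time)
  if (t_ref < min(traj$time) - 1e-9 || t_eval > max(traj$time) + 1e-9) {
    stop("reference or evaluation time outside the trajectory span")
  }
  i0 <- which.min(abs(traj$time - t_ref))
  i1 <- which.min(abs(traj$time - t_eval))
  v <- unlist(traj[i1, -1]) - unlist(traj[i0, -1])
  stats::setNames(as.numeric(v), names(traj)[-1])
}
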