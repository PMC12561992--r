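#' Generate a synthetic hyperglycemic glucose fixture
#'
#' Emulates the shape of the published diabetic-mouse glucose measurements:
#' weekly intervals for weeks 6--11 near a hyperglycemic plateau and
#' biweekly intervals for weeks 12--20 near a slightly lower late level
#' that anchors the normalization, so the normalized weight reaches 1
#' around week 5 and stays near or above 1 afterwards.
#'
#' @param plateau_mmol_l weekly-interval (weeks 6--11) glucose level; must
#'   exceed the linear-segment endpoint at week 6.
#' @param sd_mmol_l reported SD of the weekly intervals.
#' @param late_mmol_l biweekly-interval (weeks 12--20) level.
#' @param late_sd_mmol_l reported SD of the biweekly intervals.
#' @param jitter SD of the normal jitter applied to the interval means
#'   (0 = constant plateau).
#' @param seed RNG seed for the jitter.
#' @return a `glucose_schedule`.
#' @export
make_glucose_fixture <- function(plateau_mmol_l = 44.5, sd_mmol_l = 5,
                                 late_mmol_l = 31.5, late_sd_mmol_l = 1.5,
                                 jitter = 0, seed = 1L) {
  lin_end <- 0.051 * 1008 - 9.38
  if (plateau_mmol_l <= lin_end) {
    stop(sprintf("plateau (%.1f) must exceed the linear endpoint %.2f mmol/l",
                 plateau_mmol_l, lin_end))
  }
  wk <- function(w) w * 168
  starts <- c(wk(6:11), wk(c(12, 14, 16, 18)))
  ends <- c(wk(7:12), wk(c(14, 16, 18, 20)))
  means <- c(rep(plateau_mmol_l, 6), rep(late_mmol_l, 4))
  sds <- c(rep(sd_mmol_l, 6), rep(late_sd_mmol_l, 4))
  if (jitter > 0) {
    means <- means + withr_seed(seed, stats::rnorm(length(means), 0, jitter))
  }
  glucose_schedule(data.frame(t_start_h = starts, t_end_h = ends,
                              mean_mmol_l = means, sd_mmol_l = sds))
}

#' Generate synthetic fenestration observations from the model
#'
#' Runs the healthy-variant (formation-only) and disease-variant structural
#' models at the supplied "true" parameters and adds independent normal
#' observation noise: healthy density, diabetic density and diabetic width
#' at the observation weeks. With all SDs zero the observations equal the
#' model predictions to solver tolerance.
#'
#' @param true_params [fenestration_params()] generating values.
#' @param weeks observation weeks (default `c(6, 10, 15, 20)`).
#' @param sd_density,sd_width_nm observation noise SDs (default roughly 10%
#'   of the healthy baselines).
#' @param seed RNG seed.
#' @param net,schedule network and glucose input (package defaults).
#' @param y0_healthy initial number for the healthy formation scenario.
#' @param traj_healthy,traj_disease optional pre-computed network
#'   trajectories (to amortize across replicates).
#' @return a [fen_observations()] table; the generating truth and the
#'   noiseless predictions are attached as attributes `truth` and
#'   `noiseless`.
#' @export
make_observations <- function(true_params = fenestration_params(),
                              weeks = c(6, 10, 15, 20),
                              sd_density = 0.7, sd_width_nm = 4.8,
                              seed = 1L,
                              net = fen_network(),
                              schedule = fen_glucose(),
                              y0_healthy = true_params$yNumber_ss2,
                              traj_healthy = NULL, traj_disease = NULL) {
  if (sd_density < 0 || sd_width_nm < 0) stop("noise SDs must be >= 0")
  if (is.null(traj_healthy)) {
    traj_healthy <- simulate_network(network_variant(net, "healthy"),
                                     schedule)
  }
  if (is.null(traj_disease)) {
    traj_disease <- simulate_network(network_variant(net, "disease"),
                                     schedule)
  }
  grid_h <- driver_grid(net, traj_healthy)
  grid_d <- driver_grid(net, traj_disease)

  dens_h <- predict_number(weeks, grid_h, true_params,
                           y0 = y0_healthy, first_term_only = TRUE)
  dens_d <- predict_number(weeks, grid_d, true_params,
                           y0 = true_params$yNumber_ss1)
  wid_d <- predict_width(weeks, grid_d, true_params)

  noise <- withr_seed(seed, {
    list(h = stats::rnorm(length(weeks), 0, sd_density),
         d = stats::rnorm(length(weeks), 0, sd_density),
         w = stats::rnorm(length(weeks), 0, sd_width_nm))
  })
  obs <- fen_observations(data.frame(
    week = rep(weeks, 3),
    arm = rep(c("healthy", "diabetic", "diabetic"), each = length(weeks)),
    quantity = rep(c("density", "density", "width_nm"), each = length(weeks)),
    mean = c(dens_h + noise$h, dens_d + noise$d, wid_d + noise$w),
    sd = rep(c(sd_density, sd_density, sd_width_nm), each = length(weeks))))
  attr(obs, "truth") <- true_params
  attr(obs, "noiseless") <- data.frame(week = weeks, density_healthy = dens_h,
                                       density_diabetic = dens_d,
                                       width_diabetic = wid_d)
  obs
}

#' Assemble a complete synthetic study
#'
#' Bundles the default network, the shipped glucose fixture, generating
#' parameters (the published best-fit values by default) and seeded
#' synthetic observations: everything the calibration, uncertainty and
#' intervention analyses need, with no external data.
#'
#' @inheritParams make_observations
#' @return list with `net`, `schedule`, `true_params`, `obs`,
#'   `traj_healthy`, `traj_disease`, `seed`.
#' @export
synthetic_study <- function(true_params = fenestration_params(),
                            sd_density = 0.7, sd_width_nm = 4.8,
                            seed = 1L,
                            net = fen_network(),
                            schedule = fen_glucose()) {
  traj_h <- simulate_network(network_variant(net, "healthy"), schedule)
  traj_d <- simulate_network(network_variant(net, "disease"), schedule)
  obs <- make_observations(true_params, sd_density = sd_density,
                           sd_width_nm = sd_width_nm, seed = seed,
                           net = net, schedule = schedule,
                           traj_healthy = traj_h, traj_disease = traj_d)
  list(net = net, schedule = schedule, true_params = true_params,
       obs = obs, traj_healthy = traj_h, traj_disease = traj_d, seed = seed)
}
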