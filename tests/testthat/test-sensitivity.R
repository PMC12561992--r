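test_that("the sensitivity index follows the normalized definition", {
  # complete knockdown: S = -100 * (Y_pert - Y_base) / Y_base
  expect_equal(sensitivity_index(4, 6, p = 1, delta_p = -1), -50)
  expect_equal(sensitivity_index(4, 4, p = 1, delta_p = -1), 0)
  expect_equal(sensitivity_index(10, 9, p = 2, delta_p = -1), 20)
  expect_error(sensitivity_index(0, 1, 1, -1), "baseline")
  expect_error(sensitivity_index(1, 1, 1, 0), "perturbation")
})

test_that("a null perturbation reproduces the baseline trajectory", {
  net <- default_net(); sch <- default_sch()
  base <- simulate_network(net, sch, t_span = c(336, 1400),
                           structure = fenestration_params())
  plan <- intervention_plan("species_knockdown", "RhoRock", scale = 1,
                            t_apply = 900, t_end = 1400)
  null <- simulate_intervention(net, sch, plan)
  expect_equal(null$yDiameter, base$yDiameter, tolerance = 1e-4)
  expect_equal(null$RhoRock, base$RhoRock, tolerance = 1e-4)
})

test_that("species with no path to the structural drivers have zero index", {
  sc <- screen_sensitivity(default_net(), default_sch(),
                           targets = list(species = c("IL6", "pJunction"),
                                          reactions = integer(0)))
  expect_true(all(abs(sc$S) < 1e-3))
  expect_true(all(!sc$sensitive))
  expect_equal(nrow(sc), 4)  # two targets x two outputs, all classified
})

test_that("species knockdown dominates single-reaction inhibition in |S|", {
  sc <- screen_sensitivity(default_net(), default_sch(),
                           targets = list(species = "PI3K", reactions = 7))
  s_species <- sc$S[sc$type == "species" & sc$output == "yNumber"]
  s_reaction <- sc$S[sc$type == "reaction" & sc$output == "yNumber"]
  # PI3K has a single incoming reaction, so the two coincide
  expect_gte(abs(s_species) + 1e-9, abs(s_reaction))
  expect_equal(s_species, s_reaction, tolerance = 1e-6)
  # every screened target carries a classification
  expect_true(all(sc$sensitive %in% c(TRUE, FALSE)))
})

test_that("pooled t test matches its summary-statistic form and extremes", {
  expect_equal(two_sample_ttest(c(1, 1, 1), c(1, 1, 1)),
               list(t = 0, df = 4, p = 1, stars = ""))
  sep <- two_sample_ttest(c(0, 0, 0, 0) + rnorm(4, 0, 1e-4),
                          c(1, 1, 1, 1) + rnorm(4, 0, 1e-4))
  expect_lt(sep$p, 1e-4)

  set.seed(12)
  a <- rnorm(8, 1); b <- rnorm(11, 1.7)
  raw <- two_sample_ttest(a, b)
  summ <- two_sample_ttest(mean_a = mean(a), sd_a = sd(a), n_a = 8,
                           mean_b = mean(b), sd_b = sd(b), n_b = 11)
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  expect_error(two_sample_ttest(1, 2), ">= 2 values")
})

test_that("changes from baseline vanish for degenerate comparisons", {
  tr <- disease_traj()
  expect_true(all(relative_change_from_baseline(tr, 1000, 1000) == 0))
  const <- data.frame(time = 0:10, a = 1, b = 2)
  expect_true(all(relative_change_from_baseline(const) == 0))
  expect_gt(relative_change_from_baseline(tr, 336, 3360)[["pMLC"]], 0.9)
  expect_error(relative_change_from_baseline(tr, 1, 2), "span")
})

test_that("glucose control from the start preserves the healthy structure", {
  plan <- intervention_plan("glucose_control", t_apply = 336, t_end = 1200)
  tr <- simulate_intervention(default_net(), default_sch(), plan)
  # the glucose cascade never fires ...
  quiet <- setdiff(names(tr), c("time", "yNumber", "yDiameter",
                                "MLCP", "MLC", "Actin_r"))
  expect_lt(max(abs(as.matrix(tr[quiet]))), 1e-5)
  # ... while the inhibitor-gated phosphatase branch is constitutively on,
  # keeping relaxed actin active and the structure at its healthy baseline
  expect_gt(tail(tr$Actin_r, 1), 0.99)
  expect_equal(tail(tr$yNumber, 1), 7.00, tolerance = 1e-6)
  expect_equal(tail(tr$yDiameter, 1), 47.91, tolerance = 1e-5)
})

test_that("late glucose control fails to rescue fenestration structure", {
  plan <- intervention_plan("glucose_control", t_apply = 1680,
                            t_end = 3360)  # 10 weeks: established disease
  tr <- simulate_intervention(default_net(), default_sch(), plan)
  base <- disease_traj()
  # the self-sustained network keeps the structural damage in place
  expect_lt(tail(tr$yNumber, 1), 4.5)
  expect_gt(tail(tr$yDiameter, 1), 0.9 * tail(base$yDiameter, 1))
})

test_that("agent knockouts act through their mapped targets", {
  expect_error(intervention_plan("chemical_agent", "aspirin"),
               "unknown chemical agent")
  pop <- sample_population(default_sch(), n = 4, seed = 21)
  out <- agent_battery(default_net(), pop, agents = "Y27632")
  expect_named(out$values, c("no treatment", "Y27632"))
  # Rho/Rock inhibition restores the fenestration number toward healthy
  expect_gt(out$summary$number_mean[2], out$summary$number_mean[1] + 1)
  expect_lt(out$summary$diameter_mean[2], 50)
  expect_lt(out$tests$number_p, 0.05)
})
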