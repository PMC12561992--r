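test_that("the number equation vanishes at its one-sided fixed points", {
  p <- fenestration_params()
  expect_equal(number_rhs(7.00, actin_r = 0.8, actin_s = 0, p), 0)
  expect_equal(number_rhs(4.02, actin_r = 0, actin_s = 1, p), 0)
  expect_equal(number_rhs(5.5, actin_r = 0, actin_s = 0, p), 0)
  expect_equal(diameter_rhs(47.91, pmlc = 0, p), 0)
})

test_that("with stressed actin only, the number decays to the diseased state
           from above without crossing", {
  p <- fenestration_params()
  tr <- data.frame(time = seq(0, 5000), Actin_r = 0, Actin_s = 1, pMLC = 0)
  st <- simulate_structure(tr, p, y0_number = 7, y0_diameter = p$yDiameter0)
  expect_true(all(diff(st$yNumber) <= 1e-9))          # monotone decrease
  expect_gte(min(st$yNumber), p$yNumber_ss2 - 1e-6)   # never crosses
  expect_equal(tail(st$yNumber, 1), p$yNumber_ss2, tolerance = 0.05)
  expect_equal(st$yDiameter, rep(p$yDiameter0, nrow(st)), tolerance = 1e-6)
})

test_that("held pMLC gives the analytic diameter relaxation", {
  p <- fenestration_params()
  for (pm in c(0.4, 1)) {
    tr <- data.frame(time = seq(0, 30, by = 0.05), Actin_r = 0,
                     Actin_s = 0, pMLC = pm)
    st <- simulate_structure(tr, p, y0_number = 7,
                             y0_diameter = p$yDiameter0,
                             dt = 0.05, rtol = 1e-10, atol = 1e-10)
    analytic <- p$yDiameter0 + (p$ks / p$kd) * pm^p$nf *
      (1 - exp(-p$kd * st$time))
    expect_equal(st$yDiameter, analytic, tolerance = 1e-6)
  }
  # closed-form fixed point at full phospho-MLC activation
  expect_equal(47.91 + 65.9 / 2.04, 80.21, tolerance = 1e-3)
})

test_that("steady-state diameter is non-decreasing in held pMLC", {
  p <- fenestration_params()
  ss <- vapply(seq(0, 1, by = 0.2), function(pm) {
    p$yDiameter0 + (p$ks / p$kd) * pm^p$nf
  }, numeric(1))
  expect_true(all(diff(ss) >= 0))
})

test_that("joint and driven structure integration agree", {
  coupled <- disease_traj()
  driven <- simulate_structure(coupled, fenestration_params())
  expect_equal(driven$yNumber, coupled$yNumber, tolerance = 1e-3)
  expect_equal(driven$yDiameter, coupled$yDiameter, tolerance = 1e-3)
})

test_that("all-zero drivers freeze the structure at its baselines", {
  p <- fenestration_params()
  tr <- data.frame(time = 0:100, Actin_r = 0, Actin_s = 0, pMLC = 0)
  st <- simulate_structure(tr, p)
  expect_equal(st$yNumber, rep(p$yNumber_ss1, 101), tolerance = 1e-8)
  expect_equal(st$yDiameter, rep(p$yDiameter0, 101), tolerance = 1e-8)
})

test_that("parameter validation rejects inconsistent values", {
  expect_error(fenestration_params(kform = -1), "positive")
  expect_error(fenestration_params(yNumber_ss1 = 3, yNumber_ss2 = 4),
               "yNumber_ss1 > yNumber_ss2")
  expect_error(fenestration_params(nf = 0.5), "nf")
  expect_error(simulate_structure(data.frame(time = 0:10, Actin_r = 0,
                                             Actin_s = 0)),
               "driver species")
})
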