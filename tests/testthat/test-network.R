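test_that("rule parsing handles signs, gates and malformed input", {
  r <- parse_rule("GLU => AGE")
  expect_equal(r$target, "AGE")
  expect_equal(r$inputs$species, "GLU")
  expect_equal(r$inputs$sign, "activating")

  r <- parse_rule("!RhoRock => MLCP")
  expect_equal(r$inputs$sign, "inhibiting")

  r <- parse_rule("Ca & !NO => MLCK")
  expect_equal(r$inputs$species, c("Ca", "NO"))
  expect_equal(r$inputs$sign, c("activating", "inhibiting"))

  expect_error(parse_rule("A -> B"), "=>")
  expect_error(parse_rule("A => "), "target")
  expect_error(parse_rule(" => B"), "input")
  expect_error(parse_rule("A & => B"), "input")
})

test_that("network validation catches structural mistakes", {
  sp <- data.frame(id = c("A", "B"), ymax = 1, y0 = 0,
                   tau_class = "signaling", tau = NA, compartment = "GEC")
  rx <- data.frame(id = 1, rule = "A => B", W = 1, n = 1.4, EC50 = 0.5)
  expect_s3_class(network_spec(sp, rx, stimulus = "A"), "fen_network")

  expect_error(network_spec(rbind(sp, sp[1, ]), rx, stimulus = "A"),
               "duplicate species")
  bad <- rx; bad$rule <- "A => Z"
  expect_error(network_spec(sp, bad, stimulus = "A"), "undeclared")
  bad <- rx; bad$rule <- "B => A"
  expect_error(network_spec(sp, bad, stimulus = "A"), "stimulus")
  bad <- sp; bad$y0 <- c(0, 2)
  expect_error(network_spec(bad, rx, stimulus = "A"), "y0")
})

test_that("healthy and disease variants differ only in the MLCP edge", {
  net <- default_net()
  h <- network_variant(net, "healthy")
  d <- network_variant(h, "disease")
  expect_equal(d$reactions$rule, net$reactions$rule)
  diff_rules <- which(h$reactions$rule != net$reactions$rule)
  expect_length(diff_rules, 1)
  expect_equal(net$reactions$rule[diff_rules], "!RhoRock => MLCP")
  expect_equal(h$reactions$rule[diff_rules], "RhoRock => MLCP")
  expect_equal(h$species, net$species)
})

test_that("assembled right-hand side matches a brute-force oracle", {
  net <- toy_network()
  sch <- held_weight_schedule(0.6)
  rhs <- assemble_rhs(net, sch)
  t <- 1500
  w <- glucose_weight(sch, t)

  brute <- function(y) {
    names(y) <- c("A", "B", "C", "D")
    tf <- function(x, n, ec50, inhib = FALSE) {
      en <- ec50^n; B <- (en - 1) / (2 * en - 1); Kn <- B - 1
      f <- B * x^n / (Kn + x^n)
      if (inhib) 1 - f else f
    }
    aB <- min(max(0.8 * tf(y[["A"]], 1.4, 0.5), 0), 1)
    aC <- min(max(0.9 * tf(y[["A"]], 1.4, 0.5, inhib = TRUE), 0), 1)
    aD1 <- min(max(1 * tf(y[["A"]], 1.4, 0.4) * tf(y[["B"]], 1.4, 0.4), 0), 1)
    aD2 <- min(max(0.7 * tf(y[["C"]], 1.4, 0.6), 0), 1)
    FD <- aD1 + aD2 - aD1 * aD2
    c((1 * w - y[["A"]]) / 1,
      (1 * aB - y[["B"]]) / 1,
      (0.9 * aC - y[["C"]]) / 1,
      (1 * FD - y[["D"]]) / 1)
  }
  set.seed(42)
  for (i in 1:100) {
    y <- runif(4)
    expect_equal(unname(rhs(t, y, NULL)[[1]]), unname(brute(y)),
                 tolerance = 1e-12)
  }
})

test_that("activities stay within [0, ymax] up to solver tolerance", {
  tr <- disease_traj()
  net <- default_net()
  for (i in seq_len(nrow(net$species))) {
    id <- net$species$id[i]
    if (id == "GLU") next  # stimulus may exceed 1 by design
    expect_gte(min(tr[[id]]), -1e-5)
    expect_lte(max(tr[[id]]), net$species$ymax[i] + 1e-5)
  }
  expect_gt(max(tr$GLU), 1)  # hyperglycemic overshoot of the normalization
})

test_that("steady-state activities increase with the held stimulus", {
  net <- default_net()
  age_ss <- vapply(c(0.3, 0.6, 0.9), function(w) {
    tr <- simulate_network(net, held_weight_schedule(w),
                           t_span = c(1008, 1400))
    tail(tr$AGE, 1)
  }, numeric(1))
  expect_true(all(diff(age_ss) > 0))
})

test_that("splitting the integration at an event is consistent", {
  net <- default_net(); sch <- default_sch()
  whole <- simulate_network(net, sch, t_span = c(336, 1400))
  split <- simulate_network(net, sch, t_span = c(336, 1400),
                            events = list(list(time = 900, type = "ymax",
                                               target = "AKT", scale = 1)))
  expect_equal(whole$time, split$time)
  expect_equal(as.matrix(whole[-1]), as.matrix(split[-1]),
               tolerance = 1e-4)
})
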