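test_that("fecundity reproduces the baseline, shared-restraint and equal-effort forms", {
  pars <- caption_params()
  # fully selfish: social term vanishes, f = mu * q
  expect_equal(fecundity(1, 1, "H", "R", pars), 1 * 1)
  expect_equal(fecundity(1, 1, "L", "R", pars), 1 * 0.1)
  expect_equal(fecundity(1, 1, "H", "P", pars), 0.1 * 1)
  # both at 0.5 with mu = q = 1: f = 1 * (1 + 1 * 0.5) = 1.5
  pars2 <- kc_params(d = 0.1, c = 0.9, p = 0.5, tau = 0, mu_R = 1, mu_P = 1,
                     q_HR = 1, q_LR = 1, q_HP = 1, q_LP = 1)
  expect_equal(fecundity(0.5, 0.5, "H", "R", pars2), 1.5)
  # equal efforts x0: f = mu (q + 1 - x0), decreasing in x0
  set.seed(42)
  for (i in 1:10) {
    x0 <- runif(1, 0.1, 1)
    expect_equal(fecundity(x0, x0, "L", "P", pars),
                 pars$mu_P * (pars$q_LP + 1 - x0), tolerance = 1e-12)
  }
  expect_error(fecundity(0, 0, "H", "R", pars), "share undefined")
})

test_that("patch output depends on efforts only through the mean effort", {
  set.seed(7)
  for (i in 1:20) {
    pars <- random_params()
    x_H <- runif(1, 0.05, 1)
    x_L <- runif(1, 0.05, 1)
    s <- sample(c("R", "P"), 1)
    total <- fecundity(x_H, x_L, "H", s, pars) + fecundity(x_H, x_L, "L", s, pars)
    xbar <- (x_H + x_L) / 2
    expect_equal(total,
                 pars$mu[[s]] * (pars$q["H", s] + pars$q["L", s] + 2 * (1 - xbar)),
                 tolerance = 1e-12)
  }
})

test_that("own effort raises own fecundity where share gain beats pool depletion", {
  pars <- caption_params()
  h <- 1e-6
  # partner effort always hurts; own effort helps iff n xbar (1 - xbar) >
  # x_own (the marginal share gain exceeds the actor's share of the
  # depleted public good)
  for (x in list(c(0.3, 0.6), c(0.2, 0.4), c(0.4, 0.9))) {
    own_up <- fecundity(x[1] + h, x[2], "H", "R", pars)
    own_dn <- fecundity(x[1] - h, x[2], "H", "R", pars)
    expect_gt(own_up, own_dn)
    partner_up <- fecundity(x[1], x[2] + h, "H", "R", pars)
    partner_dn <- fecundity(x[1], x[2] - h, "H", "R", pars)
    expect_lt(partner_up, partner_dn)
  }
  # beyond that threshold the depletion dominates: at equal efforts above
  # one half, further effort lowers own fecundity
  expect_lt(fecundity(0.8 + h, 0.2, "H", "R", pars),
            fecundity(0.8 - h, 0.2, "H", "R", pars))
  expect_lt(fecundity(0.7 + h, 0.7, "H", "R", pars),
            fecundity(0.7 - h, 0.7, "H", "R", pars))
})

test_that("marginal cost and benefit match channel-wise finite differences", {
  set.seed(11)
  for (i in 1:20) {
    pars <- random_params()
    x_H <- runif(1, 0.1, 1)
    x_L <- runif(1, 0.1, 1)
    s <- sample(c("R", "P"), 1)
    for (actor in c("H", "L")) {
      mt <- marginal_terms(x_H, x_L, actor, s, pars)
      mu <- pars$mu[[s]]
      h <- 1e-6
      x_a <- if (actor == "H") x_H else x_L
      x_r <- if (actor == "H") x_L else x_H
      xbar <- function(xa) (xa + x_r) / 2
      theta <- function(xa) (1 - xbar(xa)) / xbar(xa)
      # Psi-channel: vary the actor's personal component, group term frozen
      psi_fd <- mu * ((x_a + h) - (x_a - h)) / (2 * h) * theta(x_a)
      expect_equal(-mt[["C"]], psi_fd, tolerance = 1e-8)
      # Theta-channel on the recipient: vary actor effort inside Theta only
      theta_fd <- mu * x_r * (theta(x_a + h) - theta(x_a - h)) / (2 * h)
      expect_equal(mt[["B"]], theta_fd, tolerance = 1e-6)
    }
  }
  # selfish corner: C = 0 (public good exhausted), B = -mu/2 at n = 2
  pars <- caption_params()
  mt <- marginal_terms(1, 1, "H", "R", pars)
  expect_equal(mt[["C"]], 0)
  expect_equal(mt[["B"]], -pars$mu_R / 2)
  # below full effort both marginals are negative, and symmetric inputs
  # give identical marginals for the two classes
  mt2 <- marginal_terms(0.6, 0.6, "H", "P", pars)
  expect_lt(mt2[["C"]], 0)
  expect_lt(mt2[["B"]], 0)
  expect_equal(mt2, marginal_terms(0.6, 0.6, "L", "P", pars))
})
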