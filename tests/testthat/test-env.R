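test_that("transition matrix has the stated stationary distribution and autocorrelation", {
  set.seed(1)
  for (i in 1:25) {
    p <- runif(1, 0.05, 0.95)
    tau_min <- -min(p, 1 - p) / max(p, 1 - p)
    tau <- runif(1, tau_min, 1)
    env <- env_process(tau, p)
    expect_equal(rowSums(env$forward), c(R = 1, P = 1), tolerance = 1e-12)
    # stationarity: pi %*% forward = pi
    expect_equal(as.numeric(env$stationary %*% env$forward),
                 as.numeric(env$stationary), tolerance = 1e-12)
    # lag-1 autocorrelation of a two-state chain
    expect_equal(env$forward["R", "R"] + env$forward["P", "P"] - 1, tau,
                 tolerance = 1e-12)
    # backward consistent with Bayes at stationarity
    joint <- unname(env$stationary["R"] * env$forward["R", "P"])
    expect_equal(unname(env$backward["P", "R"] * env$stationary["P"]), joint,
                 tolerance = 1e-12)
  }
})

test_that("edge correlations give frozen, independent and alternating environments", {
  expect_equal(diag(env_process(1, 0.5)$forward), c(R = 1, P = 1))
  expect_equal(as.vector(env_process(0, 0.5)$forward), rep(0.5, 4))
  expect_equal(diag(env_process(-1, 0.5)$forward), c(R = 0, P = 0))
  # backward reduces to forward for the symmetric chain
  env <- env_process(0.37, 0.5)
  expect_equal(env$backward, env$forward, tolerance = 1e-12)
})

test_that("parameter validation enforces the model invariants", {
  raw <- list(d = 0.1, c = 0.9, p = 0.5, tau = 0, mu_R = 1, mu_P = 0.1,
              q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1)
  pars <- validate_params(raw)
  expect_s3_class(pars, "kc_params")
  expect_identical(pars$n, 2L)   # defaults filled
  expect_equal(pars$Q, 0.5)

  expect_error(validate_params(modifyList(raw, list(d = 1.5))), "'d'")
  expect_error(validate_params(modifyList(raw, list(mu_P = 0))), "'mu_P'")
  expect_error(validate_params(raw[-1]), "missing parameter")
  expect_error(validate_params(modifyList(raw, list(n = 3))), "'n'")
  # tau = -1 is infeasible off the symmetric case: p_RR would go negative
  expect_error(validate_params(modifyList(raw, list(tau = -1, p = 0.3))),
               "'tau'")
  # but feasible at p = 0.5
  expect_silent(validate_params(modifyList(raw, list(tau = -1))))
})

test_that("config files round-trip through read_params with overrides", {
  raw <- list(d = 0.1, c = 0.9, p = 0.5, tau = 0.25, mu_R = 1, mu_P = 0.1,
              q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path)
  pars <- read_params(path)
  expect_equal(pars$tau, 0.25)
  pars2 <- read_params(path, tau = -0.4, d = 0.2)
  expect_equal(pars2$tau, -0.4)
  expect_equal(pars2$d, 0.2)
})
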