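test_that("fully symmetric parameters give a symmetric singular strategy", {
  fit <- ess_solve(symmetric_params())
  expect_true(fit$converged)
  expect_lt(max(fit$z_star) - min(fit$z_star), 1e-6)
  expect_true(fit$stable)
})

test_that("re-solving from the solution terminates immediately at the same point", {
  pars <- caption_params(tau = 0.5)
  fit <- ess_solve(pars)
  expect_true(fit$converged)
  again <- ess_solve(pars, init = fit$z_star)
  expect_lte(again$iterations, 2L)
  expect_equal(again$z_star, fit$z_star, tolerance = 1e-7)
})

test_that("warm and cold starts agree", {
  pars <- caption_params(tau = -0.3)
  cold <- ess_solve(pars)
  warm <- ess_solve(pars, init = c(HR = 0.9, LR = 0.2, HP = 0.35, LP = 0.8))
  expect_equal(warm$z_star, cold$z_star, tolerance = 1e-6)
})

test_that("stability verdicts respond to the gradient map as constructed", {
  pars <- caption_params(tau = 0.5)
  fit <- ess_solve(pars)
  cs <- convergence_stability(fit$z_star, pars)
  expect_true(cs$stable)
  # negative control: a sign-reversed gradient map turns the attractor into
  # a repeller
  anti <- convergence_stability(fit$z_star, pars,
                                gradient_fn = function(z) -selection_gradient(z, pars))
  expect_false(anti$stable)
})

test_that("competitive effort falls with stability in rich patches and rises in poor", {
  f_stable <- ess_solve(caption_params(tau = 0.9))
  f_unstable <- ess_solve(caption_params(tau = -0.9))
  expect_lt(f_stable$z_star[["HR"]], f_unstable$z_star[["HR"]])
  expect_lt(f_stable$z_star[["LR"]], f_unstable$z_star[["LR"]])
  expect_gt(f_stable$z_star[["HP"]], f_unstable$z_star[["HP"]])
  expect_gt(f_stable$z_star[["LP"]], f_unstable$z_star[["LP"]])
})

test_that("tau sweeps warm-start, keep the declared schema and handle edge grids", {
  pars <- symmetric_params()
  sw <- tau_sweep(pars, c(-0.3, 0, 0.3))
  expect_s3_class(sw, "kc_sweep")
  expect_identical(names(sw)[1:24],
                   c("tau", "z_HR", "z_LR", "z_HP", "z_LP",
                     "f_HR", "f_LR", "f_HP", "f_LP", "r_R", "r_P",
                     "A_HR", "A_LR", "A_HP", "A_LP",
                     "G_omega_R", "G_omega_P", "G_beta", "F_R", "F_P",
                     "F_rel_R", "F_rel_P", "stable", "iterations"))
  # symmetric parameters: tau = +/- 0.3 rows identical up to labels
  expect_equal(sw$z_HR[1], sw$z_HR[3], tolerance = 1e-6)
  expect_equal(sw$G_beta, rep(0, 3), tolerance = 1e-8)
  expect_equal(sw$F_rel_R, sw$F_rel_P, tolerance = 1e-8)
  # empty grid: empty table, no error
  sw0 <- tau_sweep(pars, numeric(0))
  expect_identical(nrow(sw0), 0L)
  # CSV round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, path)
  back <- utils::read.csv(path)
  expect_equal(back$z_HR, sw$z_HR, tolerance = 1e-12)
})

test_that("the fitted object exposes the standard accessors", {
  fit <- ess_solve(caption_params(tau = 0.5))
  expect_named(coef(fit), c("HR", "LR", "HP", "LP"))
  expect_output(print(fit), "Convergence-stable")
  s <- summary(fit)
  expect_s3_class(s, "summary.kc_ess")
  expect_output(print(s), "Inequality")
})
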