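test_that("patch compositions are binomial in the number of high-quality members", {
  expect_equal(unname(composition_probs(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(composition_probs(1)[["HH"]], 1)
  expect_equal(composition_probs(0)[["LL"]], 1)
  set.seed(31)
  for (i in 1:5) {
    Q <- runif(1)
    expect_equal(sum(composition_probs(Q)), 1, tolerance = 1e-12)
  }
})

test_that("the extended resident state keeps unit growth and binomial class structure", {
  pars <- caption_params(tau = 0.4)
  z <- setNames(runif(8, 0.3, 0.9), NULL)
  st <- eq_resident_state(z, pars)
  expect_equal(st$lam, 1, tolerance = 1e-10)
  expect_equal(sum(st$u * st$v), 1, tolerance = 1e-10)
  # class frequencies factorise: patch type x own-quality x partner-quality
  u <- st$u
  for (s in c("R", "P")) {
    pi_s <- if (s == "R") pars$p else 1 - pars$p
    for (own in c("H", "L")) for (pt in c("H", "L")) {
      q_o <- if (own == "H") pars$Q else 1 - pars$Q
      q_p <- if (pt == "H") pars$Q else 1 - pars$Q
      expect_equal(u[[paste0(own, pt, "_", s)]], pi_s * q_o * q_p,
                   tolerance = 1e-8)
    }
  }
  # composition marginals match the binomial probabilities
  p_HH <- sum(u[c("HH_R", "HH_P")])
  p_HL <- sum(u[c("HL_R", "LH_R", "HL_P", "LH_P")])
  expect_equal(c(p_HH, p_HL), unname(composition_probs(pars$Q)[c("HH", "HL")]),
               tolerance = 1e-8)
})

test_that("the extension collapses to the main model when qualities are symmetric", {
  pars_eq <- symmetric_params()
  fit8 <- ess_solve(pars_eq, model = "early-quality")
  fit4 <- ess_solve(pars_eq)
  expect_true(fit8$converged)
  # partner-conditioning is irrelevant when classes are interchangeable:
  # all eight efforts equal the symmetric four-class solution
  expect_lt(max(fit8$z_star) - min(fit8$z_star), 1e-5)
  expect_equal(unname(fit8$z_star[1]), unname(fit4$z_star[1]), tolerance = 1e-4)
  # relatedness matches the main model's closed-form symmetric limit
  phi <- ((1 - pars_eq$d) / (1 - pars_eq$c * pars_eq$d))^2
  expect_equal(unname(fit8$r), rep(phi / (2 - phi), 2), tolerance = 1e-6)
})

test_that("mixed patches carry the extreme efforts in the unstable regime", {
  fit <- ess_solve(caption_params(tau = -0.5), model = "early-quality")
  z <- fit$z_star
  rich <- z[c("HH_R", "HL_R", "LH_R", "LL_R")]
  expect_identical(names(which.max(rich)), "HL_R")
  expect_identical(names(which.min(rich)), "LH_R")
  # pure patches: low-quality pairs compete hardest in rich patches
  expect_gt(z[["LL_R"]], z[["HH_R"]])
})
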