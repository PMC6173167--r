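test_that("offspring pools and settlement reduce correctly at the dispersal extremes", {
  pars <- caption_params(tau = 0.3)
  z <- random_traits()

  p0 <- validate_params(modifyList(unclass(pars), list(d = 0)))
  pools0 <- offspring_pools(z, p0)
  expect_equal(pools0$I, 0)
  expect_equal(unname(pools0$O), unname(pools0$T))

  p1 <- validate_params(modifyList(unclass(pars), list(d = 1)))
  pools1 <- offspring_pools(z, p1)
  expect_equal(unname(pools1$O), c(0, 0))
  env <- env_process(p1$tau, p1$p)
  expect_equal(pools1$I, (1 - p1$c) * sum(env$stationary * pools1$T))
  expect_equal(unname(settlement(z, p1)$h), c(0, 0))

  pdead <- modifyList(unclass(pars), list(d = 1, c = 1))
  expect_error(offspring_pools(z, validate_params(pdead)), "collapse")
})

test_that("philopatry share matches the classic island-model form in the symmetric limit", {
  set.seed(3)
  for (i in 1:10) {
    d <- runif(1, 0.05, 0.95)
    cc <- runif(1, 0, 0.95)
    pars <- symmetric_params(d = d, c = cc)
    stl <- settlement(rep(0.7, 4), pars)
    expect_equal(unname(stl$h), rep((1 - d) / (1 - cc * d), 2), tolerance = 1e-12)
  }
  # cost-free dispersal: h = 1 - d
  pars <- symmetric_params(d = 0.4, c = 0)
  expect_equal(unname(settlement(rep(0.5, 4), pars)$h), rep(0.6, 2),
               tolerance = 1e-12)
})

test_that("the resident fitness matrix conserves recruitment and has unit growth", {
  set.seed(5)
  for (i in 1:10) {
    pars <- random_params()
    z <- random_traits()
    st <- resident_state(z, pars)
    expect_equal(st$lam, 1, tolerance = 1e-10)
    # stable class frequencies: patches hold one breeder of each quality, so
    # class frequency is half the stationary patch-type frequency
    expect_equal(unname(st$u),
                 c(pars$p / 2, pars$p / 2, (1 - pars$p) / 2, (1 - pars$p) / 2),
                 tolerance = 1e-10)
    # left-eigenvector identity v = w v and the normalisations
    expect_equal(as.numeric(st$w %*% st$v), unname(st$v), tolerance = 1e-10)
    expect_equal(sum(st$u), 1, tolerance = 1e-12)
    expect_equal(sum(st$u * st$v), 1, tolerance = 1e-10)
    # per-patch recruitment: u' = u under w implies n recruits per patch
    expect_equal(as.numeric(st$u %*% st$w), unname(st$u), tolerance = 1e-10)
  }
})

test_that("reproductive values collapse to equality in the fully symmetric model", {
  pars <- symmetric_params()
  st <- resident_state(rep(0.6, 4), pars)
  expect_equal(unname(st$v), rep(1, 4), tolerance = 1e-10)
  expect_equal(unname(st$u), rep(0.25, 4), tolerance = 1e-10)
  # d = 1, c = 0: all patches fed by the common pool only
  pars2 <- symmetric_params(d = 1, c = 0)
  st2 <- resident_state(rep(0.6, 4), pars2)
  expect_equal(unname(st2$u), rep(0.25, 4), tolerance = 1e-10)
})

test_that("offspring value is mother-independent and philopatric value tracks fecundity", {
  set.seed(9)
  for (i in 1:10) {
    pars <- random_params()
    z <- random_traits()
    st <- resident_state(z, pars)
    # v_alpha_sigma = f_alpha_sigma * V_sigma (offspring identical in quality)
    expect_equal(unname(st$v),
                 unname(c(st$f["H", "R"] * st$V[["R"]],
                          st$f["L", "R"] * st$V[["R"]],
                          st$f["H", "P"] * st$V[["P"]],
                          st$f["L", "P"] * st$V[["P"]])),
                 tolerance = 1e-9)
    # philopatric components are in fecundity ratio
    expect_equal(st$v_phi["H", "R"] / st$v_phi["L", "R"],
                 st$f["H", "R"] / st$f["L", "R"], tolerance = 1e-12)
  }
})

test_that("high-quality breeders in rich patches carry the larger philopatric value across tau", {
  for (tau in seq(-0.9, 0.9, by = 0.3)) {
    st <- resident_state(rep(1, 4), caption_params(tau = tau))
    expect_gt(st$v_phi["H", "R"], st$v_phi["L", "R"])
    expect_gt(st$v_phi["H", "P"], st$v_phi["L", "P"])
  }
})
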