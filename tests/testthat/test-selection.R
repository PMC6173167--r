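test_that("resident phenotypes are neutral: class fitness one, mean fitness one", {
  set.seed(19)
  for (i in 1:8) {
    pars <- random_params()
    z <- random_traits()
    st <- resident_state(z, pars)
    W_R <- class_fitness(z[["HR"]], z[["LR"]], "R", z, pars, st)
    W_P <- class_fitness(z[["HP"]], z[["LP"]], "P", z, pars, st)
    expect_equal(unname(c(W_R, W_P)), rep(1, 4), tolerance = 1e-10)
    expect_equal(mean_fitness(z, pars, st), 1, tolerance = 1e-10)
  }
})

test_that("raising own effort raises own class fitness and lowers the partner's", {
  pars <- caption_params(tau = 0.2)
  z <- c(HR = 0.6, LR = 0.6, HP = 0.6, LP = 0.6)
  st <- resident_state(z, pars)
  up <- class_fitness(0.6 + 1e-4, 0.6, "R", z, pars, st)
  dn <- class_fitness(0.6 - 1e-4, 0.6, "R", z, pars, st)
  expect_gt(up[["H"]], dn[["H"]])
  expect_lt(up[["L"]], dn[["L"]])
})

test_that("symmetry: identical classes experience identical selection", {
  pars <- symmetric_params()
  z <- rep(0.55, 4)
  S <- selection_gradient(z, pars)
  expect_equal(max(S) - min(S), 0, tolerance = 1e-9)
  H <- hamilton_decomposition(z, pars)
  expect_equal(max(H$lhs) - min(H$lhs), 0, tolerance = 1e-9)
  A <- potential_for_helping(z, pars)
  expect_equal(max(A) - min(A), 0, tolerance = 1e-10)
})

test_that("the Hamilton decomposition is exactly proportional to the direct gradient", {
  set.seed(23)
  for (i in 1:20) {
    pars <- random_params()
    z <- random_traits()
    st <- resident_state(z, pars)
    S <- selection_gradient(z, pars, st)
    H <- hamilton_decomposition(z, pars, st)
    expect_true(all(H$kappa > 0))
    # lhs = kappa * S with kappa = 1 / u per class
    expect_lt(max(abs(H$lhs / H$kappa - S)), 1e-6 * max(abs(S), 1e-8))
    expect_equal(H$kappa, unname(1 / st$u), tolerance = 1e-10)
  }
  # consistency check mode raises no error on a regular configuration
  expect_silent(hamilton_decomposition(random_traits(), caption_params(0.3),
                                       check = TRUE))
})

test_that("full dispersal removes kin competition and the potential for helping", {
  pars <- validate_params(modifyList(unclass(caption_params()), list(d = 1)))
  z <- rep(0.7, 4)
  st <- resident_state(z, pars)
  H <- hamilton_decomposition(z, pars, st)
  expect_equal(H$kin_competition_cost, rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(potential_for_helping(z, pars, st)), rep(0, 4),
               tolerance = 1e-12)
})

test_that("low-quality breeders always have the higher potential for helping", {
  for (tau in seq(-0.9, 0.9, by = 0.3)) {
    A <- potential_for_helping(rep(1, 4), caption_params(tau = tau))
    expect_gt(A[["LR"]], A[["HR"]])
    expect_gt(A[["LP"]], A[["HP"]])
    expect_true(all(A < 1))
  }
})

test_that("selection on the selfish corner favours restraint more weakly in high-quality breeders", {
  S <- selection_gradient(rep(1, 4), caption_params(tau = 0.5))
  # competitive effort at its ceiling: selection to reduce it in rich patches,
  # more strongly for the low-quality class
  expect_lt(S[["LR"]], 0)
  expect_lt(S[["LR"]], S[["HR"]])
})

test_that("helping potential peaks at stable correlation in rich patches and unstable in poor", {
  grid <- seq(-0.9, 0.95, by = 0.05)
  A <- sapply(grid, function(tau)
    potential_for_helping(rep(1, 4), caption_params(tau = tau)))
  # rich patches: interior maximum near (but below) full stability
  i_R <- which.max(A["HR", ])
  expect_gt(grid[i_R], 0.5)
  expect_lt(grid[i_R], 1)
  # poor patches: maximum at the unstable end of the grid
  expect_equal(which.max(A["HP", ]), 1L)
})
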