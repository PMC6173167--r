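#' Patch-composition probabilities under early-life quality acquisition
#'
#' When quality is acquired at birth (high with probability `Q`,
#' independently per settled offspring), the number of high-quality members
#' of an `n`-member patch is binomial, so composition frequencies are
#' `choose(n, k) Q^k (1 - Q)^(n - k)`.
#'
#' @param Q Probability of becoming high-quality at birth.
#' @param n Patch size (default 2, the analysed case).
#' @return For `n = 2`, named vector `c(HH =, HL =, LL =)`; otherwise the
#'   full binomial vector over `k = n, ..., 0` high-quality members.
#' @examples
#' composition_probs(0.5)  # 1/4, 1/2, 1/4
#' @export
composition_probs <- function(Q, n = 2L) {
  if (Q < 0 || Q > 1) stop("parameter 'Q' violates: 0 <= Q <= 1")
  k <- n:0
  p <- stats::dbinom(k, n, Q)
  if (n == 2L) names(p) <- c("HH", "HL", "LL") else names(p) <- paste0("k", k)
  p
}

# class bookkeeping for the early-quality model: own quality, partner
# quality, patch type; 8 classes for n = 2
eq_classes <- function() {
  as.vector(outer(c("HH", "HL", "LH", "LL"), c("R", "P"),
                  function(a, b) paste0(a, "_", b)))
}

eq_trait <- function(z, own, partner, sigma) z[[paste0(own, partner, "_", sigma)]]

# fecundity of the (own, partner) member of a sigma patch at efforts
# (x_own, x_partner)
eq_fecundity <- function(x_own, x_partner, own, sigma, params) {
  xbar <- (x_own + x_partner) / 2
  if (xbar <= 0) stop("mean effort is zero: effort share undefined")
  params$mu[[sigma]] * (params$q[own, sigma] + (x_own / xbar) * (1 - xbar))
}

#' Resident state of the early-life quality-acquisition model
#'
#' Mirror of [resident_state()] for the model variant in which each settled
#' offspring becomes high-quality with probability `Q` independently, so
#' patches come in compositions HH, HL, LL with binomial frequencies and
#' traits condition on own quality, partner quality and patch type (8
#' classes for `n = 2`). Pair relatedness per patch type remains
#' composition-independent because quality is assigned independently of
#' parentage.
#'
#' @param z Named length-8 trait profile over classes
#'   `HH_R, HL_R, LH_R, LL_R, HH_P, HL_P, LH_P, LL_P` (own quality, partner
#'   quality, patch type).
#' @param params A [kc_params()] object (with `n = 2`).
#' @return A list of class `"kc_state_eq"` with the same kinds of
#'   components as [resident_state()] over the extended class set:
#'   fecundities `f` (named length-8), composition totals `T` and pools
#'   `O` (3x2 over compositions x patch types), `I`, per-composition
#'   settlement `w_phi`, 8x8 fitness matrix `w`, `u`, `v`, `lam`, `s`, `D`,
#'   and relatedness `r`.
#' @export
eq_resident_state <- function(z, params) {
  if (params$n != 2L)
    stop("the early-quality variant is implemented for patch size n = 2")
  z <- eq_as_profile(z)
  env <- env_process(params$tau, params$p)
  Q <- params$Q
  pcomp <- composition_probs(Q, 2L)
  cls <- eq_classes()
  # per-class fecundities
  f <- stats::setNames(numeric(8L), cls)
  for (sigma in c("R", "P")) for (own in c("H", "L")) for (pt in c("H", "L")) {
    x_o <- eq_trait(z, own, pt, sigma)
    x_p <- eq_trait(z, pt, own, sigma)
    f[paste0(own, pt, "_", sigma)] <- eq_fecundity(x_o, x_p, own, sigma, params)
  }
  # composition patch totals and philopatric pools
  comp <- c("HH", "HL", "LL")
  Tt <- matrix(NA_real_, 3L, 2L, dimnames = list(comp, c("R", "P")))
  for (sigma in c("R", "P")) {
    Tt["HH", sigma] <- 2 * f[paste0("HH_", sigma)]
    Tt["HL", sigma] <- f[paste0("HL_", sigma)] + f[paste0("LH_", sigma)]
    Tt["LL", sigma] <- 2 * f[paste0("LL_", sigma)]
  }
  O <- (1 - params$d) * Tt
  I <- params$d * (1 - params$c) *
    sum(rep(env$stationary, each = 3L) * pcomp * Tt)
  if (all(O + I <= 0)) stop("demographic collapse: no surviving offspring")
  win <- 2 / (O + I)                     # per-offspring slot-win rate by (comp, type)
  w_phi <- (1 - params$d) * win
  # quality draw probabilities for (own eta, partner eps2)
  qp <- c(H = Q, L = 1 - Q)
  P <- env$forward
  # mean slot-win rate over a random landing patch, by current type
  win_bar <- colSums(pcomp * win)
  disp <- params$d * (1 - params$c)
  w <- matrix(0, 8L, 8L, dimnames = list(cls, cls))
  for (sigma in c("R", "P")) for (own in c("H", "L")) for (pt in c("H", "L")) {
    parent <- paste0(own, pt, "_", sigma)
    ij <- c(HH = "HH", HL = "HL", LH = "HL", LL = "LL")[[paste0(own, pt)]]
    for (gam in c("R", "P")) {
      trans <- (1 - params$d) * win[ij, sigma] * P[sigma, gam] +
        disp * sum(env$stationary * win_bar * P[, gam])
      for (eta in c("H", "L")) for (e2 in c("H", "L")) {
        w[parent, paste0(eta, e2, "_", gam)] <-
          w[parent, paste0(eta, e2, "_", gam)] +
          f[parent] * qp[[eta]] * qp[[e2]] * trans
      }
    }
  }
  eqn <- eigen_quantities(w)
  # settled-winner value: quality and partner quality drawn, then transition
  vbar <- c(R = 0, P = 0)
  for (gam in c("R", "P")) {
    acc <- 0
    for (eta in c("H", "L")) for (e2 in c("H", "L"))
      acc <- acc + qp[[eta]] * qp[[e2]] * eqn$v[[paste0(eta, e2, "_", gam)]]
    vbar[gam] <- acc
  }
  s <- c(R = sum(P["R", ] * vbar), P = sum(P["P", ] * vbar))
  D <- disp * sum(env$stationary * win_bar * s)
  # relatedness: composition-marginalised recursion
  pb <- env$backward
  ab <- c(R = 0, P = 0); mb <- c(R = 0, P = 0)
  for (gam in c("R", "P")) {
    for (ij in comp) {
      members <- switch(ij, HH = c("HH", "HH"), HL = c("HL", "LH"),
                        LL = c("LL", "LL"))
      fm <- f[paste0(members, "_", gam)]
      Ushare <- fm / sum(fm)
      same <- sum(Ushare^2)
      phi <- (O[ij, gam] / (O[ij, gam] + I))^2
      ab[gam] <- ab[gam] + pcomp[[ij]] * phi * same
      mb[gam] <- mb[gam] + pcomp[[ij]] * phi * (1 - same)
    }
  }
  a <- as.numeric(pb %*% ab)
  M <- sweep(pb, 2L, mb, "*")
  r <- solve(diag(2L) - M, a)
  names(r) <- c("R", "P")
  st <- list(z = z, params = params, env = env, pcomp = pcomp,
             f = f, T = Tt, O = O, I = I, w_phi = w_phi, win = win,
             w = w, u = eqn$u, v = eqn$v, lam = eqn$lam,
             s = s, D = D, r = pmin(pmax(r, 0), 1))
  class(st) <- "kc_state_eq"
  st
}

# fitness of the focal member of an early-quality focal pair whose efforts
# deviate; background resident
eq_pair_fitness <- function(x_own, x_partner, own, partner, sigma, state) {
  params <- state$params
  f_o <- eq_fecundity(x_own, x_partner, own, sigma, params)
  f_p <- eq_fecundity(x_partner, x_own, partner, sigma, params)
  Tloc <- f_o + f_p
  expected <- f_o * ((1 - params$d) * 2 * state$s[[sigma]] /
                       ((1 - params$d) * Tloc + state$I) + state$D)
  expected / state$v[[paste0(own, partner, "_", sigma)]]
}

#' Selection gradient of the early-quality model
#'
#' Neighbour-modulated gradient on the eight partner-conditioned efforts.
#' For trait `(alpha, eps, sigma)` the actor class is `(alpha, eps, sigma)`
#' and the partner class is `(eps, alpha, sigma)`; the partner's fitness
#' derivative is weighted by the patch-type relatedness. In pure patches
#' the two contributions fall on the same class.
#'
#' @param z Named length-8 trait profile.
#' @param params A [kc_params()] object.
#' @param state Optional precomputed [eq_resident_state()].
#' @param step Central finite-difference step.
#' @return Named length-8 gradient vector.
#' @export
eq_selection_gradient <- function(z, params, state = NULL, step = 1e-6) {
  z <- eq_as_profile(z)
  if (is.null(state)) state <- eq_resident_state(z, params)
  S <- stats::setNames(numeric(8L), eq_classes())
  for (sigma in c("R", "P")) for (alpha in c("H", "L")) for (eps in c("H", "L")) {
    tr <- paste0(alpha, eps, "_", sigma)
    x_a <- eq_trait(z, alpha, eps, sigma)
    x_p <- eq_trait(z, eps, alpha, sigma)
    r <- state$r[[sigma]]
    # own-class fitness wrt own trait
    dW_self <- (eq_pair_fitness(x_a + step, x_p, alpha, eps, sigma, state) -
                  eq_pair_fitness(x_a - step, x_p, alpha, eps, sigma, state)) / (2 * step)
    # partner-class fitness wrt the actor's trait
    dW_part <- (eq_pair_fitness(x_p, x_a + step, eps, alpha, sigma, state) -
                  eq_pair_fitness(x_p, x_a - step, eps, alpha, sigma, state)) / (2 * step)
    u_a <- state$u[[tr]]; v_a <- state$v[[tr]]
    pc <- paste0(eps, alpha, "_", sigma)
    u_p <- state$u[[pc]]; v_p <- state$v[[pc]]
    S[tr] <- u_a * v_a * dW_self + u_p * v_p * r * dW_part
  }
  S
}

eq_as_profile <- function(z, floor = 1e-6) {
  cls <- eq_classes()
  if (is.null(names(z))) {
    if (length(z) == 1L) z <- rep(z, 8L)
    stopifnot(length(z) == 8L)
    names(z) <- cls
  }
  z <- z[cls]
  if (any(!is.finite(z)) || any(z < floor - 1e-15) || any(z > 1 + 1e-15))
    stop("early-quality efforts must lie in [", floor, ", 1] over classes ",
         paste(cls, collapse = ", "))
  z
}

# early-quality ESS solve; called through ess_solve(model = "early-quality")
ess_solve_early_quality <- function(params, init = NULL, control = ess_control()) {
  if (is.null(init)) init <- stats::setNames(rep(0.5, 8L), eq_classes())
  init <- eq_as_profile(init, floor = control$floor)
  grad <- function(z) eq_selection_gradient(z, params, step = control$step)
  sol <- ess_iterate(grad, init, control)
  cs <- convergence_stability(sol$z, params, exclude = sol$boundary_classes,
                              gradient_fn = grad)
  st <- eq_resident_state(sol$z, params)
  res <- list(z_star = sol$z, gradient = sol$S,
              gradient_norm = sol$gradient_norm,
              iterations = sol$iterations, converged = sol$converged,
              boundary_classes = sol$boundary_classes,
              jacobian = cs$jacobian, stable = cs$stable,
              model = "early-quality", params = params, control = control,
              state = st, r = st$r,
              inequality = eq_inequality_report(st))
  class(res) <- "kc_ess"
  res
}

# inequality/productivity for the early-quality model: within-group
# inequality is carried by mixed patches (pure patches are egalitarian by
# symmetry); productivity averages patch totals over compositions
eq_inequality_report <- function(state) {
  f <- state$f
  Fv <- c(R = sum(state$pcomp * state$T[, "R"]),
          P = sum(state$pcomp * state$T[, "P"]))
  c(G_omega_R = within_group_inequality(f[["HL_R"]], f[["LH_R"]]),
    G_omega_P = within_group_inequality(f[["HL_P"]], f[["LH_P"]]),
    G_beta = between_group_inequality(Fv[["R"]], Fv[["P"]]),
    F_R = Fv[["R"]], F_P = Fv[["P"]])
}
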