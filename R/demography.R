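#' Offspring pools at the resident demography
#'
#' Computes, per patch currently of each type, the expected philopatric
#' offspring pool `O_sigma = (1 - d) * T_sigma` (with `T_sigma` the total
#' patch fecundity) and the common immigrant pool
#' `I = d (1 - c) * sum_sigma pi_sigma T_sigma` arising from uniform
#' redistribution of surviving dispersers over infinitely many patches.
#'
#' @param z Named resident trait profile `c(HR =, LR =, HP =, LP =)`, efforts
#'   in `(0, 1]`.
#' @param params A [kc_params()] object.
#' @param env Optional [env_process()] object (recomputed from `params` if
#'   missing).
#' @return List with `O` (named length-2, rich/poor), `I` (scalar), `f`
#'   (2x2 per-class fecundities) and `T` (named length-2 patch totals).
#' @export
offspring_pools <- function(z, params, env = NULL) {
  z <- as_trait_profile(z)
  if (is.null(env)) env <- env_process(params$tau, params$p)
  f <- resident_fecundities(z, params)
  Tt <- (params$n / 2) * (f["H", ] + f["L", ])
  O <- (1 - params$d) * Tt
  I <- params$d * (1 - params$c) * sum(env$stationary * Tt)
  if (all(O + I <= 0))
    stop("demographic collapse: no surviving offspring compete for breeding sites")
  list(O = O, I = I, f = f, T = Tt)
}

#' Settlement probabilities
#'
#' `h_sigma` is the philopatric fraction of the competitor pool at a slot of
#' a type-`sigma` patch; `w_phi_sigma = (1 - d) n / (O_sigma + I)` is the
#' probability that a random native offspring both stays and wins one of the
#' `n` local breeding slots (infinite-fecundity lottery).
#'
#' @inheritParams offspring_pools
#' @return List with named length-2 vectors `h` and `w_phi`.
#' @export
settlement <- function(z, params, env = NULL) {
  if (is.null(env)) env <- env_process(params$tau, params$p)
  pools <- offspring_pools(z, params, env)
  h <- pools$O / (pools$O + pools$I)
  w_phi <- (1 - params$d) * params$n / (pools$O + pools$I)
  list(h = h, w_phi = w_phi)
}

#' Class fitness matrix of the resident population
#'
#' Builds the 4x4 matrix `w` whose entry `w[rho pi, eta gamma]` is the
#' expected number of offspring of a class-`(rho, pi)` breeder that secure a
#' breeding slot as a class-`(eta, gamma)` breeder. An offspring either stays
#' (probability `1 - d`) and competes in the natal patch, or disperses,
#' survives with probability `1 - c`, and competes in a random patch;
#' winners are assigned quality `H` or `L` with probability 1/2 each
#' (offspring are identical in quality), and the patch then undergoes its
#' state transition. Class order is `HR, LR, HP, LP`.
#'
#' @inheritParams offspring_pools
#' @return 4x4 numeric matrix with dimnames, rows = parent class, columns =
#'   offspring class.
#' @export
fitness_matrix <- function(z, params, env = NULL) {
  if (is.null(env)) env <- env_process(params$tau, params$p)
  pools <- offspring_pools(z, params, env)
  n <- params$n
  P <- env$forward
  pi_st <- env$stationary
  # per-offspring settlement success if competing in a current-type-s patch
  win <- n / (pools$O + pools$I)                       # named over R, P
  cls <- kc_classes()
  w <- matrix(0, 4L, 4L, dimnames = list(cls, cls))
  for (pi_ in c("R", "P")) {
    for (gam in c("R", "P")) {
      # settle locally (current type pi_) then transition to gam, or settle
      # in a random current-type-s patch that transitions to gam
      trans <- (1 - params$d) * win[[pi_]] * P[pi_, gam] +
        params$d * (1 - params$c) * sum(pi_st * win * P[, gam])
      for (rho in c("H", "L")) {
        for (eta in c("H", "L")) {
          w[paste0(rho, pi_), paste0(eta, gam)] <-
            pools$f[rho, pi_] * 0.5 * trans
        }
      }
    }
  }
  w
}

#' Eigen-quantities of the class fitness matrix
#'
#' Stable class frequencies `u`, breeder reproductive values `v` and the
#' leading eigenvalue `lam` of a class fitness matrix (rows = parent class).
#' `u` solves `t(w) u = lam u` (class-frequency dynamics) and is normalised
#' to sum to one; `v` solves `w v = lam v` (the reproductive-value identity
#' `v_rho_pi = sum w[rho pi, eta gamma] v_eta_gamma` at `lam = 1`) and is
#' normalised so that `sum(u * v) = 1`. Dense direct eigen-decomposition is
#' used so that the reducible structures arising at `tau = 1` or `tau = -1`
#' are handled without iteration.
#'
#' @param w Square non-negative class fitness matrix.
#' @return List with `u`, `v` (named numeric vectors) and `lam` (scalar).
#' @export
eigen_quantities <- function(w) {
  er <- eigen(w)
  i <- which.max(Re(er$values))
  lam <- Re(er$values[i])
  v <- Re(er$vectors[, i])
  el <- eigen(t(w))
  j <- which.max(Re(el$values))
  u <- Re(el$vectors[, j])
  if (sum(u) < 0) u <- -u
  if (sum(v) < 0) v <- -v
  if (any(u < -1e-8 * max(abs(u))) || any(v < -1e-8 * max(abs(v))))
    stop("leading eigenvectors are not non-negative; fitness matrix may be degenerate")
  u <- pmax(u, 0)
  v <- pmax(v, 0)
  u <- u / sum(u)
  v <- v / sum(u * v)
  names(u) <- names(v) <- rownames(w)
  list(u = u, v = v, lam = lam)
}

# Expected reproductive value of a newly settled winner in a patch currently
# of each type: the winner is assigned quality 1/2-1/2, then the patch
# transitions. s_sigma = sum_gamma P[sigma, gamma] (v_H_gamma + v_L_gamma)/2.
settled_value <- function(v, env) {
  vbar <- c(R = (v[["HR"]] + v[["LR"]]) / 2,
            P = (v[["HP"]] + v[["LP"]]) / 2)
  c(R = sum(env$forward["R", ] * vbar),
    P = sum(env$forward["P", ] * vbar))
}

#' Full resident demographic and genetic state
#'
#' Solves the complete resident state of a monomorphic population at trait
#' profile `z`: fecundities, offspring pools, settlement probabilities, the
#' class fitness matrix with its eigen-quantities, offspring and philopatric
#' reproductive values, and the equilibrium patch-type-conditioned
#' relatedness coefficients. This is the quantity every selection analysis
#' in the package is built on.
#'
#' @inheritParams offspring_pools
#' @return An object of class `"kc_state"`: list with elements `z`, `params`,
#'   `env`, `f` (2x2 fecundities), `T`, `O`, `I`, `h`, `w_phi`, `w` (4x4
#'   fitness matrix), `u`, `v`, `lam`, `s` (settled-winner value by current
#'   patch type), `D` (dispersal component of offspring value), `V`
#'   (offspring reproductive value by patch type), `v_phi` (2x2 philopatric
#'   value components) and `r` (named length-2 relatedness).
#' @examples
#' pars <- kc_params(d = 0.1, c = 0.9, p = 0.5, tau = 0.5, mu_R = 1,
#'                   mu_P = 0.1, q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1)
#' st <- resident_state(rep(0.8, 4), pars)
#' st$r      # relatedness in rich and poor patches
#' st$lam    # leading eigenvalue: 1 at any resident demography
#' @export
resident_state <- function(z, params, env = NULL) {
  z <- as_trait_profile(z)
  if (is.null(env)) env <- env_process(params$tau, params$p)
  pools <- offspring_pools(z, params, env)
  stl <- settlement(z, params, env)
  w <- fitness_matrix(z, params, env)
  eq <- eigen_quantities(w)
  s <- settled_value(eq$v, env)
  win <- params$n / (pools$O + pools$I)
  D <- params$d * (1 - params$c) * sum(env$stationary * win * s)
  V <- stl$w_phi * s + D
  v_phi <- pools$f * rep(stl$w_phi * s, each = 2L)
  st <- list(z = z, params = params, env = env,
             f = pools$f, T = pools$T, O = pools$O, I = pools$I,
             h = stl$h, w_phi = stl$w_phi,
             w = w, u = eq$u, v = eq$v, lam = eq$lam,
             s = s, D = D, V = V, v_phi = v_phi)
  st$r <- solve_relatedness(z, params, env, st)
  class(st) <- "kc_state"
  st
}

#' @export
print.kc_state <- function(x, ...) {
  cat("Resident state (class 'kc_state')\n")
  cat("  traits:", paste(sprintf("%s = %.4f", names(x$z), x$z), collapse = ", "), "\n")
  cat("  fecundities: ",
      paste(sprintf("f_%s%s = %.4f",
                    rep(c("H", "L"), 2), rep(c("R", "P"), each = 2),
                    c(x$f[, "R"], x$f[, "P"])), collapse = ", "), "\n")
  cat(sprintf("  relatedness: r_R = %.4f, r_P = %.4f\n", x$r[["R"]], x$r[["P"]]))
  cat(sprintf("  leading eigenvalue = %.10f\n", x$lam))
  invisible(x)
}

# coerce/validate a trait profile to the canonical named numeric vector
as_trait_profile <- function(z, floor = 1e-6) {
  cls <- kc_classes()
  if (is.null(names(z))) {
    if (length(z) == 1L) z <- rep(z, 4L)
    stopifnot(length(z) == 4L)
    names(z) <- cls
  }
  z <- z[cls]
  if (any(!is.finite(z))) stop("trait profile must be finite over classes ", paste(cls, collapse = ", "))
  if (any(z < floor - 1e-15) || any(z > 1 + 1e-15))
    stop("competitive efforts must lie in [", floor, ", 1]")
  z
}
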