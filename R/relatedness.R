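#' Coefficients of the relatedness recursion
#'
#' For each previous-generation patch type `gamma`, the recursion for
#' pairwise relatedness needs the probability `phi_gamma = h_gamma^2` that
#' two random slot winners are both philopatric (independent draws from the
#' lottery, a consequence of infinite fecundity) and the maternity shares
#' `U_H_gamma`, `U_L_gamma`: the probability that a philopatric winner
#' descends from the high- (resp. low-) quality mother. For patch sizes
#' above two, the per-mother share generalises to
#' `f_rho_gamma / T_gamma` with `n/2` mothers per quality.
#'
#' @inheritParams offspring_pools
#' @param state Optional precomputed [resident_state()] (avoids re-solving).
#' @return List with `phi` (named length-2), `U` (2x2 matrix, rows `H`/`L`,
#'   columns `R`/`P`) and `same_mother` (named length-2: probability two
#'   philopatric winners share a mother).
#' @export
recursion_coefficients <- function(z, params, env = NULL, state = NULL) {
  if (is.null(env)) env <- env_process(params$tau, params$p)
  if (is.null(state)) {
    pools <- offspring_pools(z, params, env)
    stl <- settlement(z, params, env)
    f <- pools$f; Tt <- pools$T; h <- stl$h
  } else {
    f <- state$f; Tt <- state$T; h <- state$h
  }
  phi <- h^2
  U <- sweep(f, 2L, f["H", ] + f["L", ], "/")
  # single-mother pool share; with n/2 mothers per quality the probability
  # that two philopatric winners are sibs is sum_rho (n/2) share^2
  share <- sweep(f, 2L, Tt, "/")
  same_mother <- (params$n / 2) * colSums(share^2)
  list(phi = phi, U = U, same_mother = same_mother)
}

#' Equilibrium relatedness between patch-mates
#'
#' Solves the two-equation linear system for the equilibrium probability of
#' identity by descent between two random distinct breeders of a patch,
#' conditioned on the patch's current resource state. Conditioning on the
#' previous state `gamma` (with backward probability `p_{gamma|sigma}`),
#' both breeders are philopatric with probability `phi_gamma`; if they are
#' sibs their relatedness is one, otherwise it is the previous generation's
#' `r_gamma`. Non-philopatric pairs are unrelated (infinite island).
#' Inheritance is haploid and asexual; no mutation enters the recursion.
#'
#' @inheritParams recursion_coefficients
#' @param form `"pair"` writes the sibship term as `U_H^2 + U_L^2` (the
#'   two-breeder maternity-share form, only valid at `n = 2`); `"general"`
#'   uses the patch-size-general same-mother probability; `"auto"` (default)
#'   picks the pair form at `n = 2`. The two must agree at `n = 2`.
#' @return Named numeric vector `c(R =, P =)` of equilibrium relatedness.
#' @examples
#' pars <- kc_params(d = 0.1, c = 0.9, p = 0.5, tau = 0, mu_R = 1, mu_P = 0.1,
#'                   q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1)
#' solve_relatedness(rep(1, 4), pars)
#' @export
solve_relatedness <- function(z, params, env = NULL, state = NULL,
                              form = c("auto", "pair", "general")) {
  form <- match.arg(form)
  if (form == "auto") form <- if (params$n == 2L) "pair" else "general"
  if (form == "pair" && params$n != 2L)
    stop("the pair form of the recursion requires patch size n = 2")
  if (is.null(env)) env <- env_process(params$tau, params$p)
  co <- recursion_coefficients(z, params, env, state)
  pb <- env$backward                        # pb[sigma, gamma]
  if (form == "pair") {
    # pair form: U_H^2 + U_L^2 + 2 U_H U_L r
    sib <- co$U["H", ]^2 + co$U["L", ]^2
    cross <- 2 * co$U["H", ] * co$U["L", ]
  } else {
    sib <- co$same_mother
    cross <- 1 - co$same_mother
  }
  # r_sigma = sum_gamma pb[sigma, gamma] phi_gamma (sib_gamma + cross_gamma r_gamma)
  a <- as.numeric(pb %*% (co$phi * sib))
  M <- sweep(pb, 2L, co$phi * cross, "*")
  A <- diag(2L) - M
  if (abs(det(A)) < 1e-14)
    stop("relatedness recursion is singular (degenerate closed demography)")
  r <- solve(A, a)
  names(r) <- c("R", "P")
  pmin(pmax(r, 0), 1)
}
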