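#' Fecundity under competitive effort
#'
#' Expected offspring number of a breeder as a function of the competitive
#' efforts expressed in its patch. Fecundity is the product of the patch
#' resource level and the sum of a baseline quality and a social term: the
#' focal's share of total effort, `x / xbar`, times the remaining public
#' good, `1 - xbar`, where `xbar` is the mean effort in the patch. Raising
#' own effort increases the focal's share but depletes the common pool, so
#' competition is a selfish (harming) trait and restraint is a helping trait.
#'
#' @param x_H,x_L Competitive efforts, in `(0, 1]`, of the high- and
#'   low-quality breeders of the patch (each quality class shares one effort
#'   value; patches hold `n/2` breeders of each quality).
#' @param quality `"H"` or `"L"`: the quality of the focal breeder.
#' @param patch_type `"R"` or `"P"`: the current resource state of the patch.
#' @param params A [kc_params()] object.
#' @return Expected offspring number (non-negative scalar).
#' @examples
#' pars <- kc_params(d = 0.1, c = 0.9, p = 0.5, tau = 0, mu_R = 1, mu_P = 0.1,
#'                   q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1)
#' fecundity(1, 1, "H", "R", pars)      # fully selfish: baseline mu * q
#' fecundity(0.5, 0.5, "H", "R", pars)  # shared restraint raises fecundity
#' @export
fecundity <- function(x_H, x_L, quality, patch_type, params) {
  xbar <- (x_H + x_L) / 2
  if (xbar <= 0) stop("mean effort is zero: effort share undefined")
  x_own <- if (quality == "H") x_H else x_L
  params$mu[[patch_type]] *
    (params$q[quality, patch_type] + (x_own / xbar) * (1 - xbar))
}

# Fecundities of every member of a patch given an explicit effort vector.
# x: length-n efforts; qual: length-n "H"/"L" labels. Returns length-n f.
patch_fecundities <- function(x, qual, patch_type, params) {
  xbar <- mean(x)
  if (xbar <= 0) stop("mean effort is zero: effort share undefined")
  params$mu[[patch_type]] *
    (params$q[cbind(qual, patch_type)] + (x / xbar) * (1 - xbar))
}

# Analytic derivative of member i's fecundity with respect to member j's
# effort: d f_i / d x_j = mu * (1[i==j] (1-xbar)/xbar - x_i / (n xbar^2)).
patch_fecundity_derivs <- function(x, qual, patch_type, params) {
  n <- length(x)
  xbar <- mean(x)
  mu <- params$mu[[patch_type]]
  outer_term <- -mu * x / (n * xbar^2)            # group-channel, all pairs
  D <- matrix(outer_term, n, n)                   # D[i, j] = d f_i / d x_j
  diag(D) <- diag(D) + mu * (1 - xbar) / xbar     # personal channel
  D
}

#' Marginal fecundity cost and benefit of competitive effort
#'
#' Decomposes the effect of a focal actor's competitive effort into the two
#' channels of the multiplicative personal-by-group fecundity model. The cost
#' `C` is minus the effect through the actor's personal component (its effort
#' share) holding the group component fixed; the benefit `B` is the effect of
#' the actor's effort on a recipient's fecundity through the group component
#' (the public good `1 - xbar`), evaluated with the recipient's personal
#' component. Both are in fecundity units (scaled by the patch resource
#' level). With effort a harming trait, `C <= 0` (more effort raises own
#' share) and `B <= 0` (more effort depletes patch-mates' resources).
#'
#' @inheritParams fecundity
#' @param actor_quality `"H"` or `"L"`: the quality of the actor; the
#'   recipient is a patch-mate of the complementary quality.
#' @return Named numeric vector `c(C =, B =)`.
#' @examples
#' pars <- kc_params(d = 0.1, c = 0.9, p = 0.5, tau = 0, mu_R = 1, mu_P = 0.1,
#'                   q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1)
#' marginal_terms(1, 1, "H", "R", pars)  # C = 0 at the selfish corner
#' @export
marginal_terms <- function(x_H, x_L, actor_quality, patch_type, params) {
  n <- params$n
  xbar <- (x_H + x_L) / 2
  if (xbar <= 0) stop("mean effort is zero: effort share undefined")
  mu <- params$mu[[patch_type]]
  x_recip <- if (actor_quality == "H") x_L else x_H
  theta <- (1 - xbar) / xbar
  dtheta <- -1 / (n * xbar^2)          # d Theta / d x_actor
  c(C = -mu * 1 * theta,               # -(dPsi/dx) Theta, Psi = x
    B = mu * dtheta * x_recip)         # (dTheta/dx) Psi_recipient
}

# resident per-class fecundities f_rho_sigma at a resident trait profile
# z: named vector c(HR=, LR=, HP=, LP=). Returns 2x2 matrix rows H/L cols R/P.
resident_fecundities <- function(z, params) {
  f <- matrix(NA_real_, 2L, 2L, dimnames = list(c("H", "L"), c("R", "P")))
  for (s in c("R", "P")) {
    xH <- z[[paste0("H", s)]]
    xL <- z[[paste0("L", s)]]
    f["H", s] <- fecundity(xH, xL, "H", s, params)
    f["L", s] <- fecundity(xH, xL, "L", s, params)
  }
  f
}
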