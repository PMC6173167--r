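#' Within-group inequality coefficient
#'
#' `G_omega = 1 - f_L / f_H`: zero when both breeders of a patch produce
#' equally, approaching one as the low-quality breeder's fecundity becomes
#' negligible.
#'
#' @param f_H,f_L Fecundities of the high- and low-quality breeders
#'   (`f_H > 0`, `0 <= f_L <= f_H`).
#' @return Scalar in `[0, 1]`.
#' @examples
#' within_group_inequality(2, 1)   # 0.5
#' @export
within_group_inequality <- function(f_H, f_L) {
  if (any(f_H <= 0)) stop("f_H must be positive")
  if (any(f_L < 0)) stop("f_L must be non-negative")
  if (any(f_L > f_H * (1 + 1e-12)))
    stop("f_L > f_H: quality labels swapped upstream")
  1 - f_L / f_H
}

#' Between-group inequality coefficient
#'
#' `G_beta = 1 - F_P / F_R`, with `F_sigma` the total productivity of
#' type-`sigma` patches; zero for equally productive patch types,
#' approaching one as poor-patch productivity becomes negligible.
#'
#' @param F_R,F_P Productivities of rich and poor patches (`F_R > 0`).
#' @return Scalar.
#' @examples
#' between_group_inequality(10, 4)  # 0.6
#' @export
between_group_inequality <- function(F_R, F_P) {
  if (any(F_R <= 0)) stop("F_R must be positive")
  1 - F_P / F_R
}

#' Baseline (fully selfish) inequality coefficients
#'
#' Inequality levels with social interactions switched off, i.e. all efforts
#' at the selfish corner `x = z = 1`, where fecundity reduces to
#' `mu_sigma q_rho_sigma`: `G0_omega_sigma = 1 - q_L_sigma / q_H_sigma` and
#' `G0_beta = 1 - mu_P (q_HP + q_LP) / (mu_R (q_HR + q_LR))`. The difference
#' between baseline and evolved inequality isolates the effect of the
#' evolved social behaviour.
#'
#' @param params A [kc_params()] object.
#' @return Named vector `c(G0_omega_R =, G0_omega_P =, G0_beta =)`.
#' @export
baseline_inequality <- function(params) {
  if (params$q_HR <= 0 || params$q_HP <= 0)
    stop("baseline inequality undefined: q_H must be positive")
  den <- params$mu_R * (params$q_HR + params$q_LR)
  if (den <= 0) stop("baseline inequality undefined: rich-patch baseline productivity is zero")
  c(G0_omega_R = 1 - params$q_LR / params$q_HR,
    G0_omega_P = 1 - params$q_LP / params$q_HP,
    G0_beta = 1 - params$mu_P * (params$q_HP + params$q_LP) / den)
}

#' Inequality and productivity report at a resident state
#'
#' @param state A [resident_state()] object (or an early-quality resident
#'   state).
#' @return Named vector with `G_omega_R`, `G_omega_P`, `G_beta`, `F_R`,
#'   `F_P`.
#' @export
inequality_report <- function(state) {
  f <- state$f
  Ft <- state$T
  c(G_omega_R = within_group_inequality(f["H", "R"], f["L", "R"]),
    G_omega_P = within_group_inequality(f["H", "P"], f["L", "P"]),
    G_beta = between_group_inequality(Ft[["R"]], Ft[["P"]]),
    F_R = Ft[["R"]], F_P = Ft[["P"]])
}

#' Productivity relative to the stable-environment reference
#'
#' `F_rel_sigma = F_sigma(tau) / F_sigma(tau = 1)`, the convention used to
#' compare productivities across temporal-correlation regimes.
#'
#' @param F_tau Named vector `c(F_R =, F_P =)` at the focal `tau`.
#' @param F_ref Same at `tau = 1`.
#' @return Named vector `c(F_rel_R =, F_rel_P =)`.
#' @export
relative_productivity <- function(F_tau, F_ref) {
  if (any(F_ref <= 0)) stop("missing or degenerate tau = 1 reference")
  c(F_rel_R = F_tau[["F_R"]] / F_ref[["F_R"]],
    F_rel_P = F_tau[["F_P"]] / F_ref[["F_P"]])
}
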