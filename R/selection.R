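# Fitness of one member of a focal patch whose phenotypes deviate from the
# resident, holding the global background (immigrant pool, reproductive
# values, class frequencies) at resident values: first-order (weak
# selection) convention. x: length-n member efforts; qual: member
# qualities; who: index of the focal member; sigma: current patch type.
patch_member_fitness <- function(x, qual, who, sigma, state) {
  params <- state$params
  f <- patch_fecundities(x, qual, sigma, params)
  Tloc <- sum(f)
  expected <- f[who] *
    ((1 - params$d) * params$n * state$s[[sigma]] /
       ((1 - params$d) * Tloc + state$I) + state$D)
  expected / state$v[[paste0(qual[who], sigma)]]
}

# canonical member layout of a fixed-roles patch: n/2 H then n/2 L
patch_layout <- function(z, sigma, params) {
  half <- params$n / 2
  list(x = c(rep(z[[paste0("H", sigma)]], half),
             rep(z[[paste0("L", sigma)]], half)),
       qual = c(rep("H", half), rep("L", half)))
}

#' Neighbour-modulated class fitness under a focal-patch deviation
#'
#' Reproductive-value-weighted expected fitness of the two quality classes
#' of a single focal patch in which the expressed efforts deviate from the
#' resident profile. Only the focal patch's fecundities (and hence its local
#' competitor pool) change; the population-wide immigrant pool, reproductive
#' values and class frequencies stay at their resident values. At the
#' resident phenotypes every class fitness equals one (resident neutrality
#' under the `sum(u v) = 1` normalisation).
#'
#' @param x_H,x_L Efforts expressed by the high- and low-quality members of
#'   the focal patch.
#' @param patch_type `"R"` or `"P"`.
#' @param z Resident trait profile (named length-4).
#' @param params A [kc_params()] object.
#' @param state Optional precomputed [resident_state()].
#' @return Named vector `c(H =, L =)` of class fitnesses.
#' @export
class_fitness <- function(x_H, x_L, patch_type, z, params, state = NULL) {
  if (is.null(state)) state <- resident_state(z, params)
  half <- params$n / 2
  x <- c(rep(x_H, half), rep(x_L, half))
  qual <- c(rep("H", half), rep("L", half))
  c(H = patch_member_fitness(x, qual, 1L, patch_type, state),
    L = patch_member_fitness(x, qual, half + 1L, patch_type, state))
}

#' Selection gradient on the four conditional competitive efforts
#'
#' Slope of a random breeder's expected (reproductive-value-weighted)
#' fitness on the breeding value of each class-conditional trait, computed
#' by the neighbour-modulated route: the direct effect of a focal deviant on
#' its own class fitness plus relatedness-weighted effects of the deviant on
#' each patch-mate's class fitness. Behaviour expressed in one patch type
#' does not touch classes of the other patch type, whose contribution is
#' exactly zero. Partial derivatives are central finite differences (default
#' step `1e-6`) of [class_fitness()]-type evaluations around the resident.
#'
#' @param z Resident trait profile (named length-4, order `HR, LR, HP, LP`).
#' @param params A [kc_params()] object.
#' @param state Optional precomputed [resident_state()].
#' @param step Finite-difference step.
#' @return Named length-4 numeric vector of gradients `S`.
#' @examples
#' pars <- kc_params(d = 0.1, c = 0.9, p = 0.5, tau = 0.5, mu_R = 1,
#'                   mu_P = 0.1, q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1)
#' selection_gradient(rep(1, 4), pars)   # selection on the selfish corner
#' @export
selection_gradient <- function(z, params, state = NULL, step = 1e-6) {
  z <- as_trait_profile(z)
  if (step <= 0 || step < 1e-12)
    stop("finite-difference step underflows the trait floor")
  if (is.null(state)) state <- resident_state(z, params)
  half <- params$n / 2
  S <- numeric(4L)
  names(S) <- kc_classes()
  for (sigma in c("R", "P")) {
    lay <- patch_layout(z, sigma, params)
    r <- state$r[[sigma]]
    for (alpha in c("H", "L")) {
      rho <- if (alpha == "H") "L" else "H"
      i <- if (alpha == "H") 1L else half + 1L          # focal deviant
      k <- if (alpha == "H") half + 1L else 1L          # cross-quality mate
      Wd <- function(xvec, who) patch_member_fitness(xvec, lay$qual, who, sigma, state)
      dx <- function(idx) { xp <- lay$x; xp[idx] <- xp[idx] + step; xp }
      mx <- function(idx) { xm <- lay$x; xm[idx] <- xm[idx] - step; xm }
      dW_self  <- (Wd(dx(i), i) - Wd(mx(i), i)) / (2 * step)
      dW_cross <- (Wd(dx(i), k) - Wd(mx(i), k)) / (2 * step)
      u_a <- state$u[[paste0(alpha, sigma)]]
      v_a <- state$v[[paste0(alpha, sigma)]]
      u_r <- state$u[[paste0(rho, sigma)]]
      v_r <- state$v[[paste0(rho, sigma)]]
      g <- u_a * v_a * dW_self + (half) * r * u_r * v_r * dW_cross
      if (half > 1L) {
        j <- i + 1L                                     # same-quality mate
        dW_same <- (Wd(dx(j), i) - Wd(mx(j), i)) / (2 * step)
        g <- g + (half - 1L) * r * u_a * v_a * dW_same
      }
      S[paste0(alpha, sigma)] <- g
    }
  }
  S
}

#' Hamilton's-rule decomposition of the selection gradient
#'
#' Partitions selection on each conditional competitive effort into a
#' primary cost, a primary benefit and a kin-competition cost, using
#' analytic fecundity derivatives. The actor's cost `C` is the total
#' marginal loss of its own fecundity (personal-share channel plus its own
#' share of the depleted public good); the benefit `B` is the total marginal
#' fecundity effect on its `n - 1` patch-mates, relatedness-weighted. The
#' kin-competition term charges the `B - C` extra locally produced offspring
#' with displacing, per extra recruit, a uniformly random winner among the
#' `n` local slots, destroying philopatric reproductive value of the actor
#' and (relatedness-depreciated) of its mates: the displacement factor is
#' `w_phi / n`. Under this normalisation the three-term sum is exactly
#' proportional to the direct gradient of [selection_gradient()], with
#' per-class constant `kappa = 1 / u_alpha_sigma` (`lhs = kappa * S`).
#'
#' @inheritParams selection_gradient
#' @param check If `TRUE`, recompute the direct gradient and verify the
#'   proportionality; inconsistency beyond `1e-6` relative raises an error
#'   rather than being silently absorbed.
#' @return A data.frame with one row per class: `primary_cost`,
#'   `primary_benefit`, `kin_competition_cost`, `lhs`, `kappa`.
#' @export
hamilton_decomposition <- function(z, params, state = NULL, check = FALSE) {
  z <- as_trait_profile(z)
  if (is.null(state)) state <- resident_state(z, params)
  half <- params$n / 2
  cls <- kc_classes()
  out <- data.frame(class = cls, primary_cost = NA_real_,
                    primary_benefit = NA_real_, kin_competition_cost = NA_real_,
                    lhs = NA_real_, kappa = NA_real_)
  rownames(out) <- cls
  for (sigma in c("R", "P")) {
    lay <- patch_layout(z, sigma, params)
    Dm <- patch_fecundity_derivs(lay$x, lay$qual, sigma, params)
    r <- state$r[[sigma]]
    V <- state$V[[sigma]]
    for (alpha in c("H", "L")) {
      rho <- if (alpha == "H") "L" else "H"
      i <- if (alpha == "H") 1L else half + 1L
      k <- if (alpha == "H") half + 1L else 1L
      C_eff <- -Dm[i, i]                       # total own-fecundity cost
      B_cross <- Dm[k, i]                      # effect on one cross-quality mate
      B_same <- if (half > 1L) Dm[i + 1L, i] else 0
      Tprime <- sum(Dm[, i])                   # change in total patch output
      vp_a <- state$v_phi[alpha, sigma]
      vp_r <- state$v_phi[rho, sigma]
      K_weight <- (state$w_phi[[sigma]] / params$n) *
        (vp_a * (1 + (half - 1L) * r) + half * r * vp_r)
      cost <- -C_eff * V
      benefit <- r * ((half - 1L) * B_same + half * B_cross) * V
      kin <- -Tprime * K_weight
      cl <- paste0(alpha, sigma)
      out[cl, c("primary_cost", "primary_benefit", "kin_competition_cost")] <-
        c(cost, benefit, kin)
      out[cl, "lhs"] <- cost + benefit + kin
      out[cl, "kappa"] <- 1 / state$u[[cl]]
    }
  }
  if (any(out$kappa <= 0))
    stop("decomposition inconsistency: non-positive proportionality constant")
  if (check) {
    S <- selection_gradient(z, params, state)
    resc <- out$lhs / out$kappa
    if (any(abs(resc - S) > 1e-6 * pmax(abs(S), 1e-8)))
      stop("decomposition inconsistency: lhs is not proportional to the direct gradient")
  }
  out
}

#' Potential for helping
#'
#' The critical marginal cost-benefit ratio `A` below which helping (effort
#' restraint conferring fecundity on patch-mates) is favoured for each
#' class: setting the Hamilton's-rule left-hand side to zero and solving
#' `C / B = A` gives `A = (r V - K) / (V - K)`, where `K` is the
#' kin-competition displacement weight of [hamilton_decomposition()]
#' (same `w_phi / n` normalisation). `A > 0` means helping can evolve;
#' `A < 0` means harming is favoured whenever its cost is small enough.
#'
#' @inheritParams selection_gradient
#' @return Named length-4 numeric vector `A`.
#' @export
potential_for_helping <- function(z, params, state = NULL) {
  z <- as_trait_profile(z)
  if (is.null(state)) state <- resident_state(z, params)
  half <- params$n / 2
  A <- numeric(4L)
  names(A) <- kc_classes()
  for (sigma in c("R", "P")) {
    r <- state$r[[sigma]]
    V <- state$V[[sigma]]
    for (alpha in c("H", "L")) {
      rho <- if (alpha == "H") "L" else "H"
      K <- (state$w_phi[[sigma]] / params$n) *
        (state$v_phi[alpha, sigma] * (1 + (half - 1L) * r) +
           half * r * state$v_phi[rho, sigma])
      den <- V - K
      if (abs(den) < 1e-14) {
        warning("threshold regime: offspring value exactly offset by kin competition for class ",
                paste0(alpha, sigma))
        A[paste0(alpha, sigma)] <- NaN
      } else {
        A[paste0(alpha, sigma)] <- (r * V - K) / den
      }
    }
  }
  A
}

#' Mean fitness of a random breeder
#'
#' Class-frequency and reproductive-value weighted mean fitness
#' `wbar = sum u v W`; equal to one at the resident equilibrium under the
#' `sum(u v) = 1` normalisation.
#'
#' @inheritParams selection_gradient
#' @return Scalar.
#' @export
mean_fitness <- function(z, params, state = NULL) {
  z <- as_trait_profile(z)
  if (is.null(state)) state <- resident_state(z, params)
  W <- c(class_fitness(z[["HR"]], z[["LR"]], "R", z, params, state),
         class_fitness(z[["HP"]], z[["LP"]], "P", z, params, state))
  W <- W[c(1L, 2L, 3L, 4L)]
  names(W) <- kc_classes()
  sum(state$u * state$v * W)
}

#' Full selection report at a resident trait profile
#'
#' Bundles the per-class selection gradient, Hamilton's-rule terms,
#' potential for helping, and the demographic components they are built
#' from.
#'
#' @inheritParams selection_gradient
#' @return A list of class `"kc_selection"` with elements `gradient`,
#'   `hamilton`, `A`, `wbar` and `state`.
#' @export
selection_report <- function(z, params, state = NULL) {
  z <- as_trait_profile(z)
  if (is.null(state)) state <- resident_state(z, params)
  structure(list(gradient = selection_gradient(z, params, state),
                 hamilton = hamilton_decomposition(z, params, state),
                 A = potential_for_helping(z, params, state),
                 wbar = mean_fitness(z, params, state),
                 state = state),
            class = "kc_selection")
}

#' @export
print.kc_selection <- function(x, ...) {
  cat("Selection analysis (class 'kc_selection')\n")
  cat("  gradient S:", paste(sprintf("%s = %+.3e", names(x$gradient), x$gradient),
                             collapse = ", "), "\n")
  cat("  potential for helping A:",
      paste(sprintf("%s = %+.4f", names(x$A), x$A), collapse = ", "), "\n")
  cat(sprintf("  mean fitness wbar = %.8f\n", x$wbar))
  invisible(x)
}
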