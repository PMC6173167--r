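#' Control settings for the ESS solver
#'
#' @param tol Convergence tolerance on the max-norm of the selection
#'   gradient.
#' @param max_iter Iteration cap of the damped fixed-point scheme.
#' @param eta0 Initial damping step.
#' @param eta_max Damping-step cap.
#' @param floor Lower trait bound (efforts live in `[floor, 1]`).
#' @param step Finite-difference step passed to [selection_gradient()].
#' @return A list of class `"kc_control"`.
#' @export
ess_control <- function(tol = 1e-8, max_iter = 10000L, eta0 = 0.25,
                        eta_max = 0.5, floor = 1e-6, step = 1e-6) {
  structure(list(tol = tol, max_iter = as.integer(max_iter), eta0 = eta0,
                 eta_max = eta_max, floor = floor, step = step),
            class = "kc_control")
}

# generic damped fixed-point ascent on a gradient map; used by both the
# fixed-roles and early-quality solvers. gradient_fn(z) -> named vector.
ess_iterate <- function(gradient_fn, init, control) {
  z <- init
  eta <- control$eta0
  S <- gradient_fn(z)
  nS <- max(abs(S))
  iter <- 0L
  repeat {
    if (nS < control$tol) break
    if (nS < 1e-4 && iter >= 25L) break    # hand the tail to the Newton polish
    iter <- iter + 1L
    if (iter > control$max_iter) break
    accepted <- FALSE
    for (try in 1:40) {
      z_new <- pmin(pmax(z + eta * S, control$floor), 1)
      S_new <- gradient_fn(z_new)
      # at the bounds only the inward gradient components count
      eff <- S_new
      eff[z_new >= 1 & S_new > 0] <- 0
      eff[z_new <= control$floor & S_new < 0] <- 0
      if (max(abs(eff)) <= nS * (1 + 1e-12) || max(abs(eff)) < control$tol) {
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) break   # stalled: hand over to the polish below
    z <- z_new
    S <- S_new
    eff <- S
    eff[z >= 1 & S > 0] <- 0
    eff[z <= control$floor & S < 0] <- 0
    nS <- max(abs(eff))
    eta <- min(eta * 1.25, control$eta_max)
    if (nS < control$tol) break
  }
  # Newton polish on the interior components: the damped ascent is robust
  # globally but linearly convergent, with a slow tail when the Jacobian
  # eigenvalues are small (near-frozen environments); a few Newton steps
  # finish the root-find quadratically.
  for (polish in 1:12) {
    eff <- S
    eff[z >= 1 - 1e-9 & S > 0] <- 0
    eff[z <= control$floor + 1e-9 & S < 0] <- 0
    if (max(abs(eff)) < control$tol) break
    interior <- names(z)[!((z >= 1 - 1e-9 & S > 0) |
                             (z <= control$floor + 1e-9 & S < 0))]
    if (length(interior) == 0L) break
    hstep <- 1e-5
    J <- matrix(NA_real_, length(interior), length(interior),
                dimnames = list(interior, interior))
    for (l in interior) {
      zp <- z; zp[l] <- zp[l] + hstep
      zm <- z; zm[l] <- zm[l] - hstep
      J[, l] <- (gradient_fn(zp)[interior] - gradient_fn(zm)[interior]) /
        (2 * hstep)
    }
    delta <- tryCatch(-solve(J, S[interior]), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) break
    step_cap <- 0.1
    if (max(abs(delta)) > step_cap) delta <- delta * step_cap / max(abs(delta))
    z_new <- z
    z_new[interior] <- pmin(pmax(z[interior] + delta, control$floor), 1)
    S_new <- gradient_fn(z_new)
    iter <- iter + 1L
    eff_new <- S_new
    eff_new[z_new >= 1 - 1e-9 & S_new > 0] <- 0
    eff_new[z_new <= control$floor + 1e-9 & S_new < 0] <- 0
    if (max(abs(eff_new)) >= max(abs(eff))) break
    z <- z_new
    S <- S_new
  }
  eff <- S
  eff[z >= 1 - 1e-9 & S > 0] <- 0
  eff[z <= control$floor + 1e-9 & S < 0] <- 0
  boundary <- names(z)[(z >= 1 - 1e-9 & S > 0) | (z <= control$floor + 1e-9 & S < 0)]
  list(z = z, S = S, gradient_norm = max(abs(eff)), iterations = iter,
       converged = max(abs(eff)) < control$tol, boundary_classes = boundary)
}

#' Solve for the convergence-stable competitive efforts
#'
#' Locates the joint singular point `z*` of the four (fixed-roles model) or
#' eight (early-quality model) conditional competitive efforts: the trait
#' profile at which the selection gradient of every class vanishes (or
#' points outward at a trait bound). The solver is a damped fixed-point
#' iteration `z <- clip(z + eta * S(z), [floor, 1])` with an adaptive step
#' (halved on overshoot), recomputing the full resident state — fecundities,
#' pools, fitness matrix, eigen-quantities, relatedness — at every step.
#' Convergence stability of the solution is then verified from the Jacobian
#' of the gradient map.
#'
#' @param params A [kc_params()] object.
#' @param model `"fixed-roles"` (one H and one L breeder pair per patch,
#'   4 traits; the default) or `"early-quality"` (quality drawn at birth
#'   with probability `Q`, partner-conditioned traits, 8 traits).
#' @param init Initial trait profile; default all efforts 0.5.
#' @param control An [ess_control()] list.
#' @return An object of class `"kc_ess"`: list with `z_star`, `gradient`,
#'   `gradient_norm`, `iterations`, `converged`, `boundary_classes`,
#'   `jacobian`, `stable`, `model`, `params`, and (fixed-roles) the resident
#'   `state`, potential for helping `A` and inequality metrics at `z*`.
#' @examples
#' \donttest{
#' pars <- kc_params(d = 0.1, c = 0.9, p = 0.5, tau = 0.5, mu_R = 1,
#'                   mu_P = 0.1, q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1)
#' fit <- ess_solve(pars)
#' coef(fit)
#' summary(fit)
#' }
#' @export
ess_solve <- function(params, model = c("fixed-roles", "early-quality"),
                      init = NULL, control = ess_control()) {
  model <- match.arg(model)
  if (model == "early-quality")
    return(ess_solve_early_quality(params, init = init, control = control))
  if (is.null(init)) init <- stats::setNames(rep(0.5, 4L), kc_classes())
  init <- as_trait_profile(init, floor = control$floor)
  grad <- function(z) selection_gradient(z, params, step = control$step)
  sol <- ess_iterate(grad, init, control)
  cs <- convergence_stability(sol$z, params,
                              exclude = sol$boundary_classes,
                              gradient_fn = grad)
  st <- resident_state(sol$z, params)
  res <- list(z_star = sol$z, gradient = sol$S,
              gradient_norm = sol$gradient_norm,
              iterations = sol$iterations, converged = sol$converged,
              boundary_classes = sol$boundary_classes,
              jacobian = cs$jacobian, stable = cs$stable,
              model = model, params = params, control = control,
              state = st,
              A = potential_for_helping(sol$z, params, st),
              inequality = inequality_report(st))
  class(res) <- "kc_ess"
  res
}

#' Convergence stability of a singular trait profile
#'
#' Numerical Jacobian (central differences, step `1e-5`) of the selection
#' gradient with respect to the resident trait values, restricted to
#' interior (non-boundary) classes. The singular point is convergence stable
#' when every eigenvalue of the Jacobian has negative real part, the
#' standard multidimensional criterion for gradual trait dynamics
#' `dz/dt = S(z)` to converge to `z*` from nearby residents.
#'
#' @param z_star Singular trait profile.
#' @param params A [kc_params()] object.
#' @param exclude Character vector of boundary-pinned classes to drop from
#'   the Jacobian.
#' @param step Jacobian finite-difference step.
#' @param gradient_fn Gradient map to differentiate; defaults to
#'   [selection_gradient()] at `params`. Exposed so that modified maps
#'   (e.g. sign-reversed negative controls) can be assessed.
#' @return List with `jacobian` (matrix over interior classes), `stable`
#'   (logical; `NA` if the Jacobian is ill-conditioned) and `eigenvalues`.
#' @export
convergence_stability <- function(z_star, params, exclude = character(),
                                  step = 1e-5, gradient_fn = NULL) {
  if (is.null(gradient_fn))
    gradient_fn <- function(z) selection_gradient(z, params)
  z_star <- stats::setNames(as.numeric(z_star),
                            if (is.null(names(z_star))) kc_classes() else names(z_star))
  keep <- setdiff(names(z_star), exclude)
  if (length(keep) == 0L)
    return(list(jacobian = matrix(numeric(0), 0, 0), stable = NA,
                eigenvalues = numeric(0)))
  J <- matrix(NA_real_, length(keep), length(keep),
              dimnames = list(keep, keep))
  for (l in keep) {
    zp <- z_star; zp[l] <- zp[l] + step
    zm <- z_star; zm[l] <- zm[l] - step
    J[, l] <- (gradient_fn(zp)[keep] - gradient_fn(zm)[keep]) / (2 * step)
  }
  ev <- eigen(J, only.values = TRUE)$values
  stable <- if (any(!is.finite(ev))) NA else all(Re(ev) < 0)
  if (!is.na(stable) && kappa(J) > 1e12) stable <- NA
  list(jacobian = J, stable = stable, eigenvalues = ev)
}

#' Sweep the ESS analysis over a temporal-correlation grid
#'
#' Re-solves the full model at each value of the temporal correlation `tau`
#' (warm-starting each solve from the previous solution) and collects the
#' evolved efforts, fecundities, relatedness, potential for helping,
#' inequality coefficients and productivities in one table. Productivities
#' are also reported relative to the stable-environment reference
#' `F(tau = 1)`.
#'
#' @param params A [kc_params()] object; its `tau` field is ignored in
#'   favour of the grid.
#' @param tau_grid Numeric vector of temporal correlations.
#' @param model Passed to [ess_solve()].
#' @param control An [ess_control()] list.
#' @return An object of class `"kc_sweep"`: a data.frame with columns
#'   `tau, z_HR, z_LR, z_HP, z_LP, f_HR, f_LR, f_HP, f_LP, r_R, r_P, A_HR,
#'   A_LR, A_HP, A_LP, G_omega_R, G_omega_P, G_beta, F_R, F_P, F_rel_R,
#'   F_rel_P, stable, iterations` (the early-quality model adds the eight
#'   partner-conditioned effort columns instead of four). Failed solves
#'   yield `NA` rows and a warning; the sweep continues. The fully selfish
#'   baselines are attached as attribute `"baselines"`.
#' @export
tau_sweep <- function(params, tau_grid, model = c("fixed-roles", "early-quality"),
                      control = ess_control()) {
  model <- match.arg(model)
  tau_grid <- as.numeric(tau_grid)
  solve_at <- function(tau, init) {
    pars <- params
    pars$tau <- tau
    pars <- validate_params(unclass(pars)[c("d", "c", "p", "tau", "mu_R", "mu_P",
                                            "q_HR", "q_LR", "q_HP", "q_LP", "n", "Q")])
    ess_solve(pars, model = model, init = init, control = control)
  }
  ref <- solve_at(1, NULL)
  F_ref <- ref$inequality[c("F_R", "F_P")]
  rows <- vector("list", length(tau_grid))
  init <- NULL
  for (i in seq_along(tau_grid)) {
    fit <- tryCatch(solve_at(tau_grid[i], init), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("solve failed at tau = ", tau_grid[i], ": ", conditionMessage(fit))
      rows[[i]] <- data.frame(tau = tau_grid[i])
      next
    }
    init <- fit$z_star
    m <- fit$inequality
    if (model == "fixed-roles") {
      f <- fit$state$f
      rows[[i]] <- data.frame(
        tau = tau_grid[i],
        z_HR = fit$z_star[["HR"]], z_LR = fit$z_star[["LR"]],
        z_HP = fit$z_star[["HP"]], z_LP = fit$z_star[["LP"]],
        f_HR = f["H", "R"], f_LR = f["L", "R"],
        f_HP = f["H", "P"], f_LP = f["L", "P"],
        r_R = fit$state$r[["R"]], r_P = fit$state$r[["P"]],
        A_HR = fit$A[["HR"]], A_LR = fit$A[["LR"]],
        A_HP = fit$A[["HP"]], A_LP = fit$A[["LP"]],
        G_omega_R = m[["G_omega_R"]], G_omega_P = m[["G_omega_P"]],
        G_beta = m[["G_beta"]],
        F_R = m[["F_R"]], F_P = m[["F_P"]],
        F_rel_R = m[["F_R"]] / F_ref[["F_R"]],
        F_rel_P = m[["F_P"]] / F_ref[["F_P"]],
        stable = fit$stable, iterations = fit$iterations)
    } else {
      zc <- as.list(fit$z_star)
      rows[[i]] <- cbind(data.frame(tau = tau_grid[i]),
                         as.data.frame(zc),
                         data.frame(
                           r_R = fit$r[["R"]], r_P = fit$r[["P"]],
                           G_omega_R = m[["G_omega_R"]],
                           G_omega_P = m[["G_omega_P"]],
                           G_beta = m[["G_beta"]],
                           F_R = m[["F_R"]], F_P = m[["F_P"]],
                           F_rel_R = m[["F_R"]] / F_ref[["F_R"]],
                           F_rel_P = m[["F_P"]] / F_ref[["F_P"]],
                           stable = fit$stable,
                           iterations = fit$iterations))
    }
  }
  if (length(rows) == 0L) {
    cols <- if (model == "fixed-roles")
      c("tau", "z_HR", "z_LR", "z_HP", "z_LP", "f_HR", "f_LR", "f_HP", "f_LP",
        "r_R", "r_P", "A_HR", "A_LR", "A_HP", "A_LP", "G_omega_R", "G_omega_P",
        "G_beta", "F_R", "F_P", "F_rel_R", "F_rel_P", "stable", "iterations")
    else
      c("tau", eq_classes(), "r_R", "r_P", "G_omega_R", "G_omega_P", "G_beta",
        "F_R", "F_P", "F_rel_R", "F_rel_P", "stable", "iterations")
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    attr(out, "baselines") <- baseline_inequality(params)
    attr(out, "model") <- model
    attr(out, "params") <- params
    class(out) <- c("kc_sweep", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    template <- rows[[which(vapply(rows, ncol, 1L) == max(vapply(rows, ncol, 1L)))[1]]]
    if (ncol(r) < ncol(template)) {
      miss <- setdiff(names(template), names(r))
      for (m in miss) r[[m]] <- NA
      r <- r[names(template)]
    }
    r
  }))
  rownames(out) <- NULL
  attr(out, "baselines") <- baseline_inequality(params)
  attr(out, "model") <- model
  attr(out, "params") <- params
  class(out) <- c("kc_sweep", "data.frame")
  out
}

#' Write a sweep table to CSV
#'
#' Comma-separated, header row, UTF-8, '.' decimal.
#'
#' @param x A `"kc_sweep"` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
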