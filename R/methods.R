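#' @export
print.kc_ess <- function(x, ...) {
  cat("Convergence-stable competitive efforts (class 'kc_ess')\n")
  cat(sprintf("  model: %s;  tau = %.3g, d = %.3g, c = %.3g, p = %.3g, n = %d\n",
              x$model, x$params$tau, x$params$d, x$params$c, x$params$p,
              x$params$n))
  cat("  z*: ", paste(sprintf("%s = %.4f", names(x$z_star), x$z_star),
                      collapse = ", "), "\n")
  cat(sprintf("  converged: %s (|S|_max = %.2e, %d iterations); convergence stable: %s\n",
              x$converged, x$gradient_norm, x$iterations, x$stable))
  if (length(x$boundary_classes) > 0L)
    cat("  boundary classes:", paste(x$boundary_classes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.kc_ess <- function(object, ...) object$z_star

#' @export
summary.kc_ess <- function(object, ...) {
  out <- list(z_star = object$z_star,
              model = object$model,
              params = object$params,
              converged = object$converged,
              stable = object$stable,
              gradient_norm = object$gradient_norm,
              iterations = object$iterations,
              r = if (object$model == "fixed-roles") object$state$r else object$r,
              A = object$A,
              inequality = object$inequality,
              baselines = baseline_inequality(object$params),
              jacobian_eigen = eigen(object$jacobian, only.values = TRUE)$values)
  class(out) <- "summary.kc_ess"
  out
}

#' @export
print.summary.kc_ess <- function(x, ...) {
  cat("ESS summary (", x$model, " model)\n", sep = "")
  cat(sprintf("  tau = %.3g, d = %.3g, c = %.3g, p = %.3g\n",
              x$params$tau, x$params$d, x$params$c, x$params$p))
  cat("Evolved competitive efforts z*:\n")
  print(round(x$z_star, 5))
  cat("Relatedness:\n")
  print(round(x$r, 5))
  if (!is.null(x$A)) {
    cat("Potential for helping A:\n")
    print(round(x$A, 5))
  }
  cat("Inequality and productivity at z* (baselines in brackets):\n")
  b <- x$baselines
  cat(sprintf("  G_omega_R = %.4f [%.4f], G_omega_P = %.4f [%.4f], G_beta = %.4f [%.4f]\n",
              x$inequality[["G_omega_R"]], b[["G0_omega_R"]],
              x$inequality[["G_omega_P"]], b[["G0_omega_P"]],
              x$inequality[["G_beta"]], b[["G0_beta"]]))
  cat(sprintf("  F_R = %.4f, F_P = %.4f\n",
              x$inequality[["F_R"]], x$inequality[["F_P"]]))
  cat(sprintf("Convergence stable: %s (leading Jacobian eigenvalue %.3e)\n",
              x$stable, max(Re(x$jacobian_eigen))))
  invisible(x)
}

#' Simulate the finite-population counterpart of a fitted ESS
#'
#' Runs the individual-based model at the fitted parameter set, starting
#' the population at the analytically predicted efforts (so the run probes
#' whether finite-population evolution holds the population at the
#' predicted equilibrium).
#'
#' @param object A `"kc_ess"` fit (fixed-roles model).
#' @param nsim Unused (one run per call); present for generic consistency.
#' @param seed RNG seed forwarded to [sim_config()].
#' @param sim A [sim_config()] list; its seed is overridden by `seed` when
#'   that is supplied.
#' @param ... Passed to [simulate_population()].
#' @return A `"kc_sim"` object.
#' @export
simulate.kc_ess <- function(object, nsim = 1, seed = NULL,
                            sim = sim_config(), ...) {
  if (object$model != "fixed-roles")
    stop("simulation is implemented for the fixed-roles model")
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  simulate_population(object$params, sim = sim, z_init = object$z_star, ...)
}

#' @export
print.kc_sweep <- function(x, ...) {
  cat("Temporal-correlation sweep (class 'kc_sweep'), model:",
      attr(x, "model"), "\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Plot a temporal-correlation sweep
#'
#' Three layouts mirroring the package's standard figures: `"selection"`
#' (relatedness and potential for helping against tau), `"effort"` (evolved
#' efforts and fecundities), `"inequality"` (relative productivity and the
#' inequality coefficients with their fully selfish baselines as dotted
#' horizontal lines).
#'
#' @param x A `"kc_sweep"` object (fixed-roles model).
#' @param which One of `"selection"`, `"effort"`, `"inequality"`.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.kc_sweep <- function(x, which = c("inequality", "selection", "effort"),
                          ...) {
  which <- match.arg(which)
  df <- as.data.frame(x)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (which == "selection") {
    graphics::matplot(df$tau, df[, c("r_R", "r_P")], type = "l", lty = 1:2,
                      col = c("firebrick", "steelblue"), xlab = expression(tau),
                      ylab = "relatedness r", main = "Relatedness", ...)
    graphics::matplot(df$tau, df[, c("A_HR", "A_LR")], type = "l", lty = 1:2,
                      col = "firebrick", xlab = expression(tau),
                      ylab = "potential for helping A", main = "Rich patches", ...)
    graphics::abline(h = 0, col = "grey")
    graphics::matplot(df$tau, df[, c("A_HP", "A_LP")], type = "l", lty = 1:2,
                      col = "steelblue", xlab = expression(tau),
                      ylab = "potential for helping A", main = "Poor patches", ...)
    graphics::abline(h = 0, col = "grey")
  } else if (which == "effort") {
    graphics::matplot(df$tau, df[, c("z_HR", "z_LR")], type = "l", lty = 1:2,
                      col = "firebrick", xlab = expression(tau),
                      ylab = "effort z*", main = "Rich patches", ...)
    graphics::matplot(df$tau, df[, c("z_HP", "z_LP")], type = "l", lty = 1:2,
                      col = "steelblue", xlab = expression(tau),
                      ylab = "effort z*", main = "Poor patches", ...)
    graphics::matplot(df$tau, df[, c("f_HR", "f_LR", "f_HP", "f_LP")],
                      type = "l", lty = c(1, 2, 1, 2),
                      col = c("firebrick", "firebrick", "steelblue", "steelblue"),
                      xlab = expression(tau), ylab = "fecundity f",
                      main = "Fecundities", ...)
  } else {
    b <- attr(x, "baselines")
    graphics::matplot(df$tau, df[, c("F_rel_R", "F_rel_P")], type = "l",
                      lty = 1:2, col = c("firebrick", "steelblue"),
                      xlab = expression(tau), ylab = "relative productivity F",
                      main = "Productivity", ...)
    graphics::abline(h = 1, col = "grey")
    graphics::matplot(df$tau, df[, c("G_omega_R", "G_omega_P")], type = "l",
                      lty = 1:2, col = c("firebrick", "steelblue"),
                      xlab = expression(tau), ylab = expression(G[omega]),
                      main = "Within-group inequality", ...)
    if (!is.null(b)) graphics::abline(h = b[c("G0_omega_R", "G0_omega_P")],
                                      lty = 3, col = c("firebrick", "steelblue"))
    graphics::plot(df$tau, df$G_beta, type = "l", xlab = expression(tau),
                   ylab = expression(G[beta]), main = "Between-group inequality",
                   ...)
    if (!is.null(b)) graphics::abline(h = b[["G0_beta"]], lty = 3)
  }
  invisible(x)
}

#' Plot trait trajectories of an individual-based run
#'
#' @param x A `"kc_sim"` object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.kc_sim <- function(x, ...) {
  cols <- c("firebrick", "tomato", "steelblue", "skyblue3")
  graphics::matplot(x$traj$generation,
                    x$traj[, paste0("mean_", kc_classes())], type = "l",
                    lty = 1, col = cols, xlab = "generation",
                    ylab = "mean competitive effort", ...)
  graphics::legend("topright", legend = kc_classes(), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
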