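#' Model parameters for the class-structured island model
#'
#' Constructs and validates the full set of ecological, demographic and
#' genetic constants for a model run. The model describes an infinite-island
#' population in which each patch holds `n` breeders (half high-quality `H`,
#' half low-quality `L`) and patches switch between a resource-rich (`R`) and
#' a resource-poor (`P`) state under a two-state Markov process with
#' stationary rich-patch frequency `p` and lag-1 temporal autocorrelation
#' `tau`.
#'
#' @param d Dispersal probability of offspring, in `[0, 1]`.
#' @param c Mortality cost of dispersal, in `[0, 1]`.
#' @param p Stationary frequency of resource-rich patches, in `(0, 1)`.
#' @param tau Coefficient of temporal correlation of the patch state, in
#'   `[-1, 1]`. Negative values are feasible only down to
#'   `-min(p, 1 - p) / max(p, 1 - p)`, the point at which a transition
#'   probability of the two-state chain would leave `[0, 1]`.
#' @param mu_R,mu_P Resource levels of rich and poor patches; must satisfy
#'   `mu_R >= mu_P > 0`.
#' @param q_HR,q_LR,q_HP,q_LP Baseline (asocial) fecundity qualities of
#'   high/low-quality breeders in rich/poor patches; non-negative, with
#'   `q_HR >= q_LR` and `q_HP >= q_LP`.
#' @param n Patch size (number of breeders per patch); an even integer
#'   `>= 2`. Default 2.
#' @param Q Probability that an offspring becomes high-quality at birth; used
#'   only by the early-life quality-acquisition model variant. Default 0.5.
#'
#' @return An object of class `"kc_params"`: a validated list with the fields
#'   above plus `mu = c(R =, P =)` and the 2x2 quality matrix `q` (rows
#'   `H`/`L`, columns `R`/`P`) for internal use.
#'
#' @examples
#' # the parameter set used throughout the worked examples
#' pars <- kc_params(d = 0.1, c = 0.9, p = 0.5, tau = 0,
#'                   mu_R = 1, mu_P = 0.1,
#'                   q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1)
#' pars
#' @export
kc_params <- function(d, c, p, tau,
                      mu_R, mu_P,
                      q_HR, q_LR, q_HP, q_LP,
                      n = 2L, Q = 0.5) {
  validate_params(list(d = d, c = c, p = p, tau = tau,
                       mu_R = mu_R, mu_P = mu_P,
                       q_HR = q_HR, q_LR = q_LR, q_HP = q_HP, q_LP = q_LP,
                       n = n, Q = Q))
}

#' Validate a raw parameter list
#'
#' Checks a flat key-value list (e.g. read from a config file) against the
#' model's parameter invariants and returns a `"kc_params"` object. Missing
#' `n` and `Q` are filled with their defaults (2 and 0.5).
#'
#' @param raw A named list with numeric entries `d`, `c`, `p`, `tau`, `mu_R`,
#'   `mu_P`, `q_HR`, `q_LR`, `q_HP`, `q_LP` and optionally `n`, `Q`.
#' @return A `"kc_params"` object.
#' @seealso [kc_params()], [read_params()]
#' @export
validate_params <- function(raw) {
  if (!is.list(raw)) stop("'raw' must be a named list of parameters")
  required <- c("d", "c", "p", "tau", "mu_R", "mu_P",
                "q_HR", "q_LR", "q_HP", "q_LP")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  if (is.null(raw$n)) raw$n <- 2L
  if (is.null(raw$Q)) raw$Q <- 0.5

  num1 <- function(field) {
    x <- raw[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", field, "' must be a single finite number")
    as.numeric(x)
  }
  for (f in c(required, "n", "Q")) raw[[f]] <- num1(f)

  chk <- function(ok, field, what) {
    if (!ok) stop("parameter '", field, "' violates: ", what)
  }
  chk(raw$d >= 0 && raw$d <= 1, "d", "0 <= d <= 1")
  chk(raw$c >= 0 && raw$c <= 1, "c", "0 <= c <= 1")
  chk(raw$p > 0 && raw$p < 1, "p", "0 < p < 1")
  chk(raw$tau >= -1 && raw$tau <= 1, "tau", "-1 <= tau <= 1")
  tau_min <- -min(raw$p, 1 - raw$p) / max(raw$p, 1 - raw$p)
  chk(raw$tau >= tau_min - 1e-12, "tau",
      sprintf("tau >= -min(p,1-p)/max(p,1-p) = %.6g (transition probabilities must stay in [0,1])",
              tau_min))
  chk(raw$mu_P > 0, "mu_P", "mu_P > 0")
  chk(raw$mu_R >= raw$mu_P, "mu_R", "mu_R >= mu_P")
  for (f in c("q_HR", "q_LR", "q_HP", "q_LP"))
    chk(raw[[f]] >= 0, f, "q >= 0")
  chk(raw$q_HR >= raw$q_LR, "q_LR", "q_HR >= q_LR")
  chk(raw$q_HP >= raw$q_LP, "q_LP", "q_HP >= q_LP")
  chk(raw$n >= 2 && raw$n %% 2 == 0, "n", "n an even integer >= 2")
  chk(raw$Q >= 0 && raw$Q <= 1, "Q", "0 <= Q <= 1")

  out <- list(d = raw$d, c = raw$c, p = raw$p, tau = raw$tau,
              mu_R = raw$mu_R, mu_P = raw$mu_P,
              q_HR = raw$q_HR, q_LR = raw$q_LR,
              q_HP = raw$q_HP, q_LP = raw$q_LP,
              n = as.integer(raw$n), Q = raw$Q)
  out$mu <- c(R = out$mu_R, P = out$mu_P)
  out$q <- matrix(c(out$q_HR, out$q_LR, out$q_HP, out$q_LP), 2L, 2L,
                  dimnames = list(c("H", "L"), c("R", "P")))
  class(out) <- "kc_params"
  out
}

#' Read model parameters from a YAML config file
#'
#' The file is a flat key-value document whose keys are exactly the
#' [kc_params()] argument names; entries passed through `...` override file
#' values.
#'
#' @param path Path to a YAML file.
#' @param ... Named overrides (e.g. `tau = 0.5`).
#' @return A `"kc_params"` object.
#' @examples
#' cfg <- system.file("extdata", "example-params.yaml", package = "kincomp")
#' read_params(cfg, tau = -0.25)
#' @export
read_params <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  for (nm in names(over)) raw[[nm]] <- over[[nm]]
  validate_params(raw)
}

#' @export
print.kc_params <- function(x, ...) {
  cat("Island-model parameters (class 'kc_params')\n")
  cat(sprintf("  dispersal d = %.4g, cost c = %.4g, patch size n = %d\n",
              x$d, x$c, x$n))
  cat(sprintf("  environment: p(rich) = %.4g, temporal correlation tau = %.4g\n",
              x$p, x$tau))
  cat(sprintf("  resources: mu_R = %.4g, mu_P = %.4g\n", x$mu_R, x$mu_P))
  cat(sprintf("  qualities: q_HR = %.4g, q_LR = %.4g, q_HP = %.4g, q_LP = %.4g\n",
              x$q_HR, x$q_LR, x$q_HP, x$q_LP))
  cat(sprintf("  early-life quality probability Q = %.4g\n", x$Q))
  invisible(x)
}

#' Two-state Markov environment process
#'
#' Builds the forward transition matrix, the stationary distribution and the
#' backward (Bayes-at-stationarity) matrix of the patch-state process. The
#' chain is the unique two-state Markov chain with stationary distribution
#' `(p, 1 - p)` over (rich, poor) and lag-1 autocorrelation `tau`:
#' `p_RR = p + (1 - p) tau` and `p_PP = (1 - p) + p tau`.
#'
#' @param tau Lag-1 autocorrelation, in the feasible range (see
#'   [kc_params()]).
#' @param p Stationary frequency of rich patches, in `(0, 1)`.
#' @return An object of class `"kc_env"`: list with `forward` (2x2, rows =
#'   current state, columns = next state), `backward` (rows = current state
#'   sigma, columns = previous state gamma, entries `p_{gamma|sigma}`) and
#'   `stationary` (length-2 vector), all with dimnames over `c("R", "P")`.
#' @examples
#' env_process(tau = 0, p = 0.5)$forward      # all entries 1/2
#' env_process(tau = 1, p = 0.3)$forward      # identity: states frozen
#' @export
env_process <- function(tau, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("parameter 'p' violates: 0 < p < 1")
  if (!is.numeric(tau) || length(tau) != 1L || tau < -1 || tau > 1)
    stop("parameter 'tau' violates: -1 <= tau <= 1")
  tau_min <- -min(p, 1 - p) / max(p, 1 - p)
  if (tau < tau_min - 1e-12)
    stop(sprintf("parameter 'tau' violates: tau >= -min(p,1-p)/max(p,1-p) = %.6g",
                 tau_min))
  st <- c(R = p, P = 1 - p)
  p_RR <- p + (1 - p) * tau
  p_PP <- (1 - p) + p * tau
  forward <- matrix(c(p_RR, 1 - p_RR,
                      1 - p_PP, p_PP),
                    2L, 2L, byrow = TRUE,
                    dimnames = list(c("R", "P"), c("R", "P")))
  # backward[sigma, gamma] = P(previous = gamma | current = sigma)
  #                        = st[gamma] * forward[gamma, sigma] / st[sigma]
  backward <- sweep(t(st * forward), 1L, st, "/")
  dimnames(backward) <- dimnames(forward)
  structure(list(forward = forward, backward = backward, stationary = st),
            class = "kc_env")
}

#' @export
print.kc_env <- function(x, ...) {
  cat("Two-state patch environment (class 'kc_env')\n")
  cat(sprintf("  stationary: P(R) = %.4g, P(P) = %.4g; autocorrelation = %.4g\n",
              x$stationary["R"], x$stationary["P"],
              x$forward["R", "R"] + x$forward["P", "P"] - 1))
  cat("  forward transitions (rows: current, cols: next):\n")
  print(round(x$forward, 6))
  invisible(x)
}

# class bookkeeping shared across the package: order HR, LR, HP, LP
kc_classes <- function() c("HR", "LR", "HP", "LP")
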