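# shared fixtures: the standard worked-example parameter set and a fully
# symmetric set in which all classes are interchangeable
caption_params <- function(tau = 0, n = 2L, Q = 0.5) {
  kc_params(d = 0.1, c = 0.9, p = 0.5, tau = tau,
            mu_R = 1, mu_P = 0.1,
            q_HR = 1, q_LR = 0.1, q_HP = 1, q_LP = 0.1,
            n = n, Q = Q)
}

symmetric_params <- function(d = 0.3, c = 0.4, tau = 0.2, p = 0.5,
                             mu = 1, q = 0.5, n = 2L) {
  kc_params(d = d, c = c, p = p, tau = tau,
            mu_R = mu, mu_P = mu,
            q_HR = q, q_LR = q, q_HP = q, q_LP = q, n = n)
}

# random feasible parameter draw used by property-style tests
random_params <- function() {
  p <- stats::runif(1, 0.25, 0.75)
  tau_min <- -min(p, 1 - p) / max(p, 1 - p)
  mu_P <- stats::runif(1, 0.2, 1)
  q_H <- stats::runif(1, 0.5, 1.5)
  kc_params(d = stats::runif(1, 0.05, 0.95), c = stats::runif(1, 0, 0.95),
            p = p, tau = stats::runif(1, tau_min * 0.95, 0.95),
            mu_R = mu_P + stats::runif(1, 0, 1), mu_P = mu_P,
            q_HR = q_H, q_LR = stats::runif(1, 0.05, 1) * q_H,
            q_HP = q_H, q_LP = stats::runif(1, 0.05, 1) * q_H)
}

random_traits <- function(k = 4L) {
  stats::setNames(stats::runif(k, 0.15, 1),
                  if (k == 4L) c("HR", "LR", "HP", "LP") else NULL)
}
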