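#' Configuration of the individual-based simulation
#'
#' @param n_patches Number of patches (finite-population analogue of the
#'   infinite island model; at least 100 for oracle use).
#' @param generations Number of non-overlapping generations to simulate.
#' @param burn_in Generations discarded before summarising trait means
#'   (default: half the run).
#' @param mutation_rate Per-trait per-birth mutation probability.
#' @param mutation_sd Standard deviation of the Gaussian mutation kernel,
#'   reflected at the trait bounds.
#' @param n_loci Number of neutral marker loci used for the identity-based
#'   relatedness estimate (inheritance is clonal, so loci share one
#'   genealogy; several loci average over mutational noise).
#' @param marker_mutation Per-locus per-birth infinite-alleles mutation rate
#'   of the neutral markers (kept small so marker identity tracks identity
#'   by descent).
#' @param seed Integer RNG seed; runs are bit-reproducible given the seed.
#' @param record_every Recording interval (generations) for trait
#'   trajectories.
#' @param n_snapshots Number of evenly spaced relatedness snapshots over the
#'   second half of the run.
#' @return A list of class `"kc_simconfig"`.
#' @export
sim_config <- function(n_patches = 2000L, generations = 20000L,
                       burn_in = NULL, mutation_rate = 0.01,
                       mutation_sd = 0.02, n_loci = 8L,
                       marker_mutation = 1e-3, seed = 1L,
                       record_every = 10L, n_snapshots = 10L) {
  if (n_patches < 2L) stop("n_patches must be at least 2")
  if (is.null(burn_in)) burn_in <- floor(generations / 2)
  structure(list(n_patches = as.integer(n_patches),
                 generations = as.integer(generations),
                 burn_in = as.integer(burn_in),
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 n_loci = as.integer(n_loci),
                 marker_mutation = marker_mutation,
                 seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 n_snapshots = as.integer(n_snapshots)),
            class = "kc_simconfig")
}

#' Individual-based simulation of the island life cycle
#'
#' Finite-population stochastic counterpart of the analytical model, with
#' the exact life cycle: social interactions set fecundities from the
#' expressed class-conditional efforts; offspring stay with probability
#' `1 - d` or disperse (surviving with probability `1 - c`) into a common
#' migrant pool spread uniformly over patches; each patch's `n` breeding
#' slots are filled by fecundity-weighted lottery draws (with replacement,
#' the finite analogue of the infinite-fecundity lottery); winners are
#' assigned quality roles at random (`n/2` high, `n/2` low); traits mutate;
#' patch types then transition. Individuals carry heritable efforts for all
#' four classes (expressed conditionally) plus neutral infinite-alleles
#' markers from which realised relatedness is estimated.
#'
#' @param params A [kc_params()] object.
#' @param sim A [sim_config()] list.
#' @param z_init Initial trait profile (default all efforts 0.5).
#' @param evolve If `FALSE`, traits are held fixed at `z_init` (no
#'   mutation); used for neutral validation of the relatedness machinery.
#' @return An object of class `"kc_sim"`: list with `traj` (data.frame of
#'   recorded per-class trait means and sds), `r_snapshots` (data.frame of
#'   marker-based relatedness estimates over snapshots), `snapshot` (final
#'   state: traits, markers, patch ids, types, qualities), `trait_summary`
#'   (post-burn-in means with autocorrelation-consistent AR-spectral Monte-Carlo standard errors), `params`, `sim`.
#' @export
simulate_population <- function(params, sim = sim_config(), z_init = NULL,
                                evolve = TRUE) {
  if (is.null(z_init)) z_init <- stats::setNames(rep(0.5, 4L), kc_classes())
  z_init <- as_trait_profile(z_init)
  set.seed(sim$seed)
  n <- params$n
  np <- sim$n_patches
  N <- np * n
  half <- n / 2
  floor_ <- 1e-6

  patch_of <- rep(seq_len(np), each = n)
  # quality roles: first half of each patch H, rest L (reshuffled each gen)
  qual <- rep(rep(c("H", "L"), times = c(half, half)), np)
  # genotypes: N x 4 trait matrix
  G <- matrix(rep(z_init, each = N), N, 4L,
              dimnames = list(NULL, kc_classes()))
  markers <- matrix(seq_len(N), N, sim$n_loci)  # unique founder alleles
  allele_counter <- N
  ptype <- sample(c("R", "P"), np, replace = TRUE,
                  prob = c(params$p, 1 - params$p))
  fwd <- env_process(params$tau, params$p)$forward

  rec_gens <- seq(sim$record_every, sim$generations, by = sim$record_every)
  traj <- matrix(NA_real_, length(rec_gens), 8L,
                 dimnames = list(NULL, c(paste0("mean_", kc_classes()),
                                         paste0("sd_", kc_classes()))))
  snap_gens <- unique(round(seq(max(sim$burn_in, 1L), sim$generations,
                                length.out = sim$n_snapshots)))
  r_snap <- matrix(NA_real_, length(snap_gens), 2L,
                   dimnames = list(NULL, c("R", "P")))
  ri <- 0L

  mu_vec <- params$mu
  q_mat <- params$q

  for (gen in seq_len(sim$generations)) {
    type_ind <- ptype[patch_of]
    cls <- paste0(qual, type_ind)
    x <- G[cbind(seq_len(N), match(cls, kc_classes()))]
    xbar <- rep(tapply(x, patch_of, mean), each = n)
    f <- mu_vec[type_ind] * (q_mat[cbind(qual, type_ind)] + (x / xbar) * (1 - xbar))
    # pools
    fp <- rowsum(f, patch_of)[, 1L]
    O <- (1 - params$d) * fp
    I <- params$d * (1 - params$c) * sum(f) / np
    if (all(O + I <= 0)) stop("demographic collapse in simulation")
    # each of the n slots per patch: philopatric with prob O/(O+I)
    h <- O / (O + I)
    philo <- stats::runif(N) < h[patch_of]
    n_mig <- sum(!philo)
    parent <- integer(N)
    if (any(philo)) {
      # within-patch fecundity-weighted draw, vectorised via cumulative
      # shares within each patch
      u <- stats::runif(N) * fp[patch_of]
      cf <- matrix(f, n, np)
      if (n > 1L) for (k in 2:n) cf[k, ] <- cf[k, ] + cf[k - 1L, ]
      idx_in_patch <- rep(1L, N)
      for (k in seq_len(n - 1L)) {
        idx_in_patch <- idx_in_patch + (u > cf[k, patch_of])
      }
      parent_phil <- (patch_of - 1L) * n + idx_in_patch
      parent[philo] <- parent_phil[philo]
    }
    if (n_mig > 0L) {
      parent[!philo] <- sample.int(N, n_mig, replace = TRUE, prob = f)
    }
    G <- G[parent, , drop = FALSE]
    markers <- markers[parent, , drop = FALSE]
    # trait mutation: Gaussian, reflected into [floor_, 1]
    if (evolve) {
      hits <- which(stats::runif(N * 4L) < sim$mutation_rate)
      if (length(hits) > 0L) {
        gnew <- G[hits] + stats::rnorm(length(hits), 0, sim$mutation_sd)
        gnew <- abs(gnew - floor_) + floor_                # reflect at floor
        over <- gnew > 1
        gnew[over] <- 1 - abs(1 - gnew[over])              # reflect at 1
        gnew <- pmin(pmax(gnew, floor_), 1)
        G[hits] <- gnew
      }
    }
    # marker mutation: infinite alleles
    mhits <- which(stats::runif(N * sim$n_loci) < sim$marker_mutation)
    if (length(mhits) > 0L) {
      markers[mhits] <- allele_counter + seq_along(mhits)
      allele_counter <- allele_counter + length(mhits)
    }
    # random quality-role assignment: permute winners within each patch,
    # keeping the fixed role layout (first n/2 rows of a patch are H)
    perm <- order(patch_of + stats::runif(N) * 0.5)
    G <- G[perm, , drop = FALSE]
    markers <- markers[perm, , drop = FALSE]
    # patch state transition
    stay <- stats::runif(np) < fwd[cbind(ptype, ptype)]
    ptype <- ifelse(stay, ptype, ifelse(ptype == "R", "P", "R"))

    if (gen %in% rec_gens) {
      type_ind <- ptype[patch_of]
      cls <- paste0(qual, type_ind)
      # note: means taken over the class an individual will express next
      row <- match(gen, rec_gens)
      for (ci in seq_len(4L)) {
        sel <- cls == kc_classes()[ci]
        traj[row, ci] <- mean(G[sel, ci])
        traj[row, 4L + ci] <- stats::sd(G[sel, ci])
      }
    }
    if (gen %in% snap_gens) {
      ri <- ri + 1L
      r_snap[ri, ] <- marker_relatedness(markers, patch_of, ptype, n)
    }
  }

  traj_df <- data.frame(generation = rec_gens, traj)
  keep <- rec_gens > sim$burn_in
  ts <- apply(traj_df[keep, paste0("mean_", kc_classes())], 2L, function(v) {
    c(mean = mean(v), se = mcse_mean(v))
  })
  snapshot <- list(markers = markers, patch_of = patch_of, ptype = ptype,
                   qual = qual, G = G, n = n)
  out <- list(traj = traj_df,
              r_snapshots = data.frame(generation = snap_gens, r_snap),
              snapshot = snapshot,
              trait_summary = t(ts),
              params = params, sim = sim, z_init = z_init, evolve = evolve)
  class(out) <- "kc_sim"
  out
}

# Monte-Carlo standard error of the mean of an autocorrelated series, via
# the AR-fitted spectral density at frequency zero (the same construction
# as coda's spectrum0.ar). Under weak selection the class means wander with
# autocorrelation times comparable to the run length, where naive or
# short-batch estimators underestimate badly; the AR estimator stays
# consistent by pricing in the fitted long-range dependence.
mcse_mean <- function(v) {
  v <- v[is.finite(v)]
  Tn <- length(v)
  if (Tn < 10L || stats::sd(v) == 0) return(0)
  fit <- tryCatch(stats::ar(v, aic = TRUE,
                            order.max = min(30L, floor(Tn / 3))),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0L)
    return(stats::sd(v) / sqrt(Tn))
  rho <- sum(fit$ar)
  rho <- min(rho, 1 - 1e-4)          # guard the near-unit-root boundary
  s0 <- fit$var.pred / (1 - rho)^2
  sqrt(s0 / Tn)
}

# identity-based relatedness from neutral markers: within-patch pairwise
# identity, corrected by population-wide identity, per current patch type
marker_relatedness <- function(markers, patch_of, ptype, n) {
  np <- length(ptype)
  L <- ncol(markers)
  # per-patch mean pairwise identity across loci
  Qw <- numeric(np)
  pairs <- utils::combn(n, 2L)
  for (p_ in seq_len(np)) {
    rows <- ((p_ - 1L) * n + 1L):(p_ * n)
    m <- markers[rows, , drop = FALSE]
    id <- 0
    for (k in seq_len(ncol(pairs)))
      id <- id + mean(m[pairs[1L, k], ] == m[pairs[2L, k], ])
    Qw[p_] <- id / ncol(pairs)
  }
  # population identity from allele frequencies (between-patch scale)
  Qp <- mean(vapply(seq_len(L), function(l) {
    tab <- tabulate(factor(markers[, l]))
    N <- sum(tab)
    sum(tab * (tab - 1)) / (N * (N - 1))
  }, 0))
  est <- function(sel) {
    if (!any(sel)) return(NA_real_)
    (mean(Qw[sel]) - Qp) / (1 - Qp)
  }
  c(R = est(ptype == "R"), P = est(ptype == "P"))
}

#' Marker-based relatedness estimate with bootstrap standard errors
#'
#' Applies the identity-based estimator (within-patch pairwise marker
#' identity relative to population-wide identity) to a simulation snapshot
#' and attaches patch-bootstrap standard errors.
#'
#' @param sim_result A `"kc_sim"` object.
#' @param n_boot Number of patch-bootstrap resamples.
#' @return Data.frame with rows `R`, `P` and columns `estimate`, `se`.
#' @export
estimate_relatedness <- function(sim_result, n_boot = 1000L) {
  sn <- sim_result$snapshot
  np <- length(sn$ptype)
  n <- sn$n
  L <- ncol(sn$markers)
  pairs <- utils::combn(n, 2L)
  Qw <- numeric(np)
  for (p_ in seq_len(np)) {
    rows <- ((p_ - 1L) * n + 1L):(p_ * n)
    m <- sn$markers[rows, , drop = FALSE]
    id <- 0
    for (k in seq_len(ncol(pairs)))
      id <- id + mean(m[pairs[1L, k], ] == m[pairs[2L, k], ])
    Qw[p_] <- id / ncol(pairs)
  }
  Qp <- mean(vapply(seq_len(L), function(l) {
    tab <- tabulate(factor(sn$markers[, l]))
    N <- sum(tab)
    sum(tab * (tab - 1)) / (N * (N - 1))
  }, 0))
  out <- data.frame(estimate = c(R = NA_real_, P = NA_real_),
                    se = c(NA_real_, NA_real_))
  for (s in c("R", "P")) {
    sel <- which(sn$ptype == s)
    if (length(sel) == 0L) next
    out[s, "estimate"] <- (mean(Qw[sel]) - Qp) / (1 - Qp)
    boots <- vapply(seq_len(n_boot), function(b) {
      take <- sample(sel, length(sel), replace = TRUE)
      (mean(Qw[take]) - Qp) / (1 - Qp)
    }, 0)
    out[s, "se"] <- stats::sd(boots)
  }
  out
}

#' @export
print.kc_sim <- function(x, ...) {
  cat("Individual-based simulation (class 'kc_sim')\n")
  cat(sprintf("  %d patches x %d breeders, %d generations (burn-in %d), seed %d\n",
              x$sim$n_patches, x$params$n, x$sim$generations, x$sim$burn_in,
              x$sim$seed))
  cat("  post-burn-in trait means (MCSE):\n")
  ts <- x$trait_summary
  for (cl in rownames(ts))
    cat(sprintf("    %s: %.4f (%.4f)\n", sub("mean_", "", cl),
                ts[cl, "mean"], ts[cl, "se"]))
  rs <- colMeans(x$r_snapshots[, c("R", "P"), drop = FALSE], na.rm = TRUE)
  cat(sprintf("  marker relatedness (snapshot mean): r_R = %.4f, r_P = %.4f\n",
              rs[["R"]], rs[["P"]]))
  invisible(x)
}

#' @export
summary.kc_sim <- function(object, ...) {
  rs <- object$r_snapshots[, c("R", "P"), drop = FALSE]
  K <- sum(stats::complete.cases(rs))
  structure(list(trait_summary = object$trait_summary,
                 relatedness = data.frame(
                   estimate = colMeans(rs, na.rm = TRUE),
                   se = apply(rs, 2L, stats::sd, na.rm = TRUE) / sqrt(max(K, 1L))),
                 sim = object$sim, params = object$params),
            class = "summary.kc_sim")
}

#' @export
print.summary.kc_sim <- function(x, ...) {
  cat("Simulation summary\n")
  cat("Trait means (MCSE):\n")
  print(round(x$trait_summary, 5))
  cat("Marker relatedness (snapshot mean, between-snapshot SE):\n")
  print(round(x$relatedness, 5))
  invisible(x)
}
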