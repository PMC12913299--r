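#' Inference configuration
#'
#' @param n_particles particles in the bootstrap filter (>= 2).
#' @param n_iter total Metropolis-Hastings iterations (> `burn_in`).
#' @param burn_in iterations discarded (and used for proposal adaptation).
#' @param traj_thin keep the sampled latent trajectory of every
#'   `traj_thin`-th retained iteration.
#' @param proposal_scale initial random-walk proposal SDs on the transformed
#'   scale, in the order (v0, logit beta, log b_tau, log sigma_v,
#'   log sigma_a, log sigma_tau).
#' @param adapt_window iterations between proposal-scale adaptations during
#'   burn-in (targets 20-40 percent acceptance).
#' @param seed integer seed for the whole chain.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_particles = 512, n_iter = 2500, burn_in = 500,
                       traj_thin = 5,
                       proposal_scale = c(0.10, 0.10, 0.10, 0.25, 0.25, 0.25),
                       adapt_window = 25, seed = 1) {
  if (n_particles < 2) stop("`n_particles` must be >= 2")
  if (n_iter <= burn_in) stop("`n_iter` must exceed `burn_in`")
  structure(list(n_particles = as.integer(n_particles),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 traj_thin = as.integer(traj_thin),
                 proposal_scale = proposal_scale,
                 adapt_window = as.integer(adapt_window),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Default priors for static parameters and walk scales
#'
#' `v0 ~ Normal(0, 1)`, `beta ~ Beta(5, 5)`, `b_tau ~ half-Normal(0, 0.3)`,
#' each walk scale `~ half-Normal(0, 0.1)`; initial-state priors as in
#' [init_prior()].
#'
#' @param v0 `c(mean, sd)` of the normal prior on the base drift.
#' @param beta `c(shape1, shape2)` of the beta prior on the starting point.
#' @param b_tau half-normal scale for the per-cue non-decision increment.
#' @param sigma half-normal scale shared by the three walk scales.
#' @param init an [init_prior()] for the trial-1 latent state.
#' @return A list of class `dlm_priors`.
#' @export
default_priors <- function(v0 = c(0, 1), beta = c(5, 5), b_tau = 0.3,
                           sigma = 0.1, init = init_prior()) {
  structure(list(v0 = v0, beta = beta, b_tau = b_tau, sigma = sigma,
                 init = init),
            class = "dlm_priors")
}

# records (one participant) -> observation vectors for the C++ filter
records_to_obs <- function(records, env) {
  stopifnot(all(c("bits", "choice", "rt") %in% names(records)))
  if ("trial" %in% names(records)) records <- records[order(records$trial), ]
  list(validity = validity_regressor(records$bits, env),
       ncues = as.integer(n_cues(records$bits)),
       upper = as_upper(records$choice),
       rt = as.numeric(records$rt))
}

#' Exact log-likelihood in the static (zero-walk) limit
#'
#' With all walk scales zero the latent state is constant and the model
#' collapses to a static four-parameter Wiener model, whose log-likelihood is
#' the plain sum of per-trial WFPT log densities. Serves as the exact oracle
#' for the particle filter's marginal-likelihood estimate.
#'
#' @param records one participant's trial records (`bits`, `choice`, `rt`).
#' @param statics a [static_params()].
#' @param state the constant [latent_state()].
#' @param env environment supplying pattern validities.
#' @return The summed log-likelihood (0 for an empty record set).
#' @export
static_loglik <- function(records, statics, state,
                          env = canonical_environment()) {
  if (nrow(records) == 0) return(0)
  obs <- records_to_obs(records, env)
  v <- trial_drift(statics$v0, state$b_v, obs$validity)
  tau <- trial_ndt(state$tau0, statics$b_tau, obs$ncues)
  sum(dwfpt(obs$rt, obs$upper, v, state$a, tau, statics$beta))
}

#' Bootstrap particle filter for one participant
#'
#' Sequential Monte Carlo over the latent random-walk trajectory: particles
#' are propagated by the Gaussian-walk transition (with reflection at the
#' supports), weighted by the trial's WFPT density, and systematically
#' resampled whenever the effective sample size drops below half the particle
#' count. The log marginal likelihood estimate is unbiased in expectation;
#' with all scales zero and a degenerate initial distribution it equals the
#' static log-likelihood exactly. Total weight collapse on a trial is flagged
#' (`degenerate = TRUE`) and charged at the log-floor instead of raising an
#' error.
#'
#' @param records one participant's trial records, ordered by trial.
#' @param statics a [static_params()].
#' @param scales a [noise_scales()].
#' @param init an [init_prior()] (possibly with zero scales) or a
#'   [latent_state()] for a degenerate initial distribution.
#' @param n_particles number of particles.
#' @param env environment supplying pattern validities.
#' @param summaries if `TRUE`, return per-trial filtered means and 5/50/95
#'   percent weighted quantiles of each latent component.
#' @param seed optional integer seed.
#' @return A list of class `filter_result`: `loglik`, `ess` (per-trial
#'   effective sample sizes), `degenerate`, `path` (one trajectory sampled
#'   from the filter's ancestral paths), and, when requested, `filtered`
#'   (a data frame of per-trial summaries).
#' @export
particle_filter <- function(records, statics, scales, init,
                            n_particles = 512,
                            env = canonical_environment(),
                            summaries = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- records_to_obs(records, env)
  if (inherits(init, "latent_state")) {
    init <- list(mu = c(init$b_v, init$a, init$tau0), sd = c(0, 0, 0))
  }
  bounds <- latent_bounds()
  res <- .particle_filter_cpp(obs$validity, obs$ncues, obs$upper, obs$rt,
                              statics$v0, statics$b_tau, statics$beta,
                              scales$sigma_v, scales$sigma_a,
                              scales$sigma_tau,
                              as.numeric(init$mu), as.numeric(init$sd),
                              bounds$a_min, bounds$tau0_min,
                              as.integer(n_particles), summaries)
  out <- list(loglik = res$loglik, ess = res$ess,
              degenerate = res$degenerate,
              path = traj_from_matrix(res$path))
  if (summaries) {
    T <- length(obs$rt)
    comp <- c("b_v", "a", "tau0")
    filtered <- data.frame(trial = seq_len(T))
    for (j in 1:3) {
      filtered[[paste0(comp[j], "_mean")]] <- res$filtered_mean[, j]
      filtered[[paste0(comp[j], "_q05")]] <- res$filtered_q05[, j]
      filtered[[paste0(comp[j], "_median")]] <- res$filtered_median[, j]
      filtered[[paste0(comp[j], "_q95")]] <- res$filtered_q95[, j]
    }
    out$filtered <- filtered
  }
  class(out) <- "filter_result"
  out
}

traj_from_matrix <- function(m) {
  out <- data.frame(trial = seq_len(nrow(m)),
                    b_v = m[, 1], a = m[, 2], tau0 = m[, 3])
  class(out) <- c("latent_trajectory", "data.frame")
  out
}

# log prior density on the transformed parameter vector
# theta = (v0, logit beta, log b_tau, log s_v, log s_a, log s_tau)
log_prior_transformed <- function(theta, priors) {
  v0 <- theta[1]
  beta <- plogis(theta[2])
  pos <- exp(theta[3:6])
  lp <- dnorm(v0, priors$v0[1], priors$v0[2], log = TRUE)
  lp <- lp + dbeta(beta, priors$beta[1], priors$beta[2], log = TRUE) +
    log(beta) + log(1 - beta)                     # logit Jacobian
  halfn <- function(x, s) log(2) + dnorm(x, 0, s, log = TRUE)
  lp <- lp + halfn(pos[1], priors$b_tau) + theta[3] +
    sum(halfn(pos[2:4], priors$sigma)) + sum(theta[4:6])  # log Jacobians
  lp
}

theta_to_params <- function(theta) {
  list(statics = static_params(v0 = theta[1], b_tau = exp(theta[3]),
                               beta = plogis(theta[2])),
       scales = noise_scales(sigma_v = exp(theta[4]),
                             sigma_a = exp(theta[5]),
                             sigma_tau = exp(theta[6])))
}

sample_theta_from_prior <- function(priors) {
  c(rnorm(1, priors$v0[1], priors$v0[2]),
    qlogis(rbeta_safe(priors$beta)),
    log(abs(rnorm(1, 0, priors$b_tau)) + 1e-4),
    log(abs(rnorm(3, 0, priors$sigma)) + 1e-4))
}

rbeta_safe <- function(shape) {
  x <- stats::rbeta(1, shape[1], shape[2])
  min(max(x, 1e-4), 1 - 1e-4)
}

#' Particle-marginal Metropolis-Hastings for one participant
#'
#' Pseudo-marginal MCMC over the static parameters (`v0`, `beta`, `b_tau`)
#' and walk scales (`sigma_v`, `sigma_a`, `sigma_tau`): each proposal's
#' likelihood is estimated by a bootstrap particle filter, which leaves the
#' exact posterior invariant despite the estimate's Monte Carlo noise.
#' Proposals are independent Gaussian random walks on transformed parameters
#' (log for the positive ones, logit for `beta`), with scales adapted during
#' burn-in towards 20-40 percent acceptance. A latent trajectory sampled from
#' the accepted filter's ancestral paths is stored for thinned iterations;
#' trajectory estimates near trial 1 are dominated by the initial prior and
#' should not be over-interpreted.
#'
#' @param records one participant's trial records.
#' @param priors a [default_priors()].
#' @param config a [fit_config()].
#' @param env environment supplying pattern validities.
#' @return A list of class `dlm_fit`: `samples` (data frame of retained
#'   draws of the six parameters plus the log-likelihood estimate),
#'   `trajectories` (list of sampled latent trajectories for thinned
#'   iterations), `trajectory_iterations`, `acceptance_rate`, `config`,
#'   and the participant's `records`.
#' @export
pmmh <- function(records, priors = default_priors(), config = fit_config(),
                 env = canonical_environment()) {
  set.seed(config$seed)
  obs <- records_to_obs(records, env)
  bounds <- latent_bounds()
  run_filter <- function(theta) {
    p <- theta_to_params(theta)
    .particle_filter_cpp(obs$validity, obs$ncues, obs$upper, obs$rt,
                         p$statics$v0, p$statics$b_tau, p$statics$beta,
                         p$scales$sigma_v, p$scales$sigma_a,
                         p$scales$sigma_tau,
                         priors$init$mu, priors$init$sd,
                         bounds$a_min, bounds$tau0_min,
                         config$n_particles, FALSE)
  }

  # initialise at the best of several prior draws; refuse to start from a
  # non-finite (all-floored) likelihood
  theta <- NULL
  ll <- -Inf
  n_valid <- 0L
  for (try in 1:25) {
    cand <- sample_theta_from_prior(priors)
    res <- run_filter(cand)
    ok <- is.finite(res$loglik) && !res$degenerate &&
      res$loglik > nrow(records) * (.log_floor / 2)
    if (ok) {
      n_valid <- n_valid + 1L
      score <- res$loglik + log_prior_transformed(cand, priors)
      if (is.null(theta) || score > ll + lp) {
        theta <- cand
        ll <- res$loglik
        lp <- log_prior_transformed(cand, priors)
        path <- res$path
      }
      if (n_valid >= 8L) break
    }
  }
  if (is.null(theta))
    stop("PMMH initialization failed: no finite-likelihood draw from the ",
         "prior after 25 attempts")

  n_keep <- config$n_iter - config$burn_in
  samples <- matrix(NA_real_, n_keep, 7)
  colnames(samples) <- c("v0", "beta", "b_tau",
                         "sigma_v", "sigma_a", "sigma_tau", "loglik")
  trajectories <- list()
  traj_iter <- integer(0)
  scale <- config$proposal_scale
  n_acc <- 0L
  acc_window <- 0L

  for (it in seq_len(config$n_iter)) {
    prop <- theta + scale * rnorm(6)
    res <- run_filter(prop)
    lp_prop <- log_prior_transformed(prop, priors)
    log_alpha <- (res$loglik + lp_prop) - (ll + lp)
    if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
      theta <- prop
      ll <- res$loglik
      lp <- lp_prop
      path <- res$path
      n_acc <- n_acc + 1L
      acc_window <- acc_window + 1L
    }
    if (it <= config$burn_in && it %% config$adapt_window == 0) {
      rate <- acc_window / config$adapt_window
      # aim at 20-40% acceptance; clamp each update so one noisy window
      # cannot blow the scales up or collapse them
      scale <- scale * exp(min(max(rate - 0.3, -0.25), 0.25))
      acc_window <- 0L
    }
    if (it > config$burn_in) {
      k <- it - config$burn_in
      p <- theta_to_params(theta)
      samples[k, ] <- c(p$statics$v0, p$statics$beta, p$statics$b_tau,
                        p$scales$sigma_v, p$scales$sigma_a,
                        p$scales$sigma_tau, ll)
      if (k %% config$traj_thin == 0) {
        trajectories[[length(trajectories) + 1]] <- traj_from_matrix(path)
        traj_iter <- c(traj_iter, k)
      }
    }
  }

  out <- list(samples = as.data.frame(samples),
              trajectories = trajectories,
              trajectory_iterations = traj_iter,
              acceptance_rate = n_acc / config$n_iter,
              config = config,
              records = records)
  class(out) <- "dlm_fit"
  out
}

#' @export
print.dlm_fit <- function(x, ...) {
  cat(sprintf("Diffusion lens model fit: %d retained samples, acceptance %.2f\n",
              nrow(x$samples), x$acceptance_rate))
  print(round(vapply(x$samples[, 1:6], median, numeric(1)), 4))
  invisible(x)
}

#' Posterior summaries per participant and group
#'
#' Per participant: the posterior median of each static parameter and the
#' per-trial posterior median of each latent component (computed over the
#' stored trajectory samples). Across participants: mean and SD of the
#' individual medians per condition, the aggregation used for reporting
#' parameter trajectories and static-parameter estimates.
#'
#' @param fits list of `dlm_fit` objects (one per participant).
#' @param conditions optional character vector of condition labels, one per
#'   fit; taken from the records when absent.
#' @return A list with `statics` (per-participant medians),
#'   `statics_by_condition` (mean and SD of medians per condition),
#'   `trajectory` (per-participant per-trial medians, long format), and
#'   `trajectory_by_condition` (across-participant mean and SD per trial).
#' @export
posterior_summaries <- function(fits, conditions = NULL) {
  if (length(fits) == 0) stop("`fits` must be a non-empty list of fits")
  if (is.null(conditions)) {
    conditions <- vapply(fits, function(f) {
      if (!is.null(f$records$condition)) as.character(f$records$condition[1])
      else "none"
    }, character(1))
  }
  pars <- c("v0", "beta", "b_tau", "sigma_v", "sigma_a", "sigma_tau")
  statics <- do.call(rbind, lapply(seq_along(fits), function(i) {
    med <- vapply(fits[[i]]$samples[, pars], median, numeric(1))
    data.frame(participant = i, condition = conditions[i], t(med))
  }))
  sbc <- do.call(rbind, lapply(split(statics, statics$condition), function(d) {
    data.frame(condition = d$condition[1],
               parameter = pars,
               mean = vapply(d[, pars], mean, numeric(1)),
               sd = vapply(d[, pars], function(x)
                 if (length(x) > 1) sd(x) else NA_real_, numeric(1)))
  }))
  rownames(sbc) <- NULL

  traj <- do.call(rbind, lapply(seq_along(fits), function(i) {
    trs <- fits[[i]]$trajectories
    if (length(trs) == 0) return(NULL)
    T <- nrow(trs[[1]])
    med <- sapply(c("b_v", "a", "tau0"), function(comp) {
      apply(vapply(trs, function(tr) tr[[comp]], numeric(T)), 1, median)
    })
    data.frame(participant = i, condition = conditions[i],
               trial = seq_len(T), med)
  }))
  tbc <- NULL
  if (!is.null(traj)) {
    tbc <- do.call(rbind, lapply(split(traj, traj$condition), function(d) {
      do.call(rbind, lapply(split(d, d$trial), function(dd) {
        data.frame(condition = dd$condition[1], trial = dd$trial[1],
                   b_v_mean = mean(dd$b_v), b_v_sd = sd(dd$b_v),
                   a_mean = mean(dd$a), a_sd = sd(dd$a),
                   tau0_mean = mean(dd$tau0), tau0_sd = sd(dd$tau0))
      }))
    }))
    rownames(tbc) <- NULL
    tbc <- tbc[order(tbc$condition, tbc$trial), ]
  }
  list(statics = statics, statics_by_condition = sbc,
       trajectory = traj, trajectory_by_condition = tbc)
}
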