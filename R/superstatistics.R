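#' Latent-state containers for the across-trials model
#'
#' Three trial-level parameters evolve across trials as independent Gaussian
#' random walks: the drift sensitivity to cue validity (`b_v`, unbounded so
#' that below-chance utilization is representable), the boundary separation
#' (`a`, kept at or above `a_min`), and the base non-decision time (`tau0`,
#' kept at or above `tau0_min`). Support bounds are enforced by reflection,
#' which preserves the innovation magnitude and avoids the sticky boundaries
#' that clipping would create.
#'
#' @param b_v drift sensitivity to cue validity.
#' @param a boundary separation (>= `a_min`).
#' @param tau0 base non-decision time in seconds (>= `tau0_min`).
#' @return `latent_state()`: a named list with components `b_v`, `a`, `tau0`.
#' @export
#' @examples
#' s <- latent_state(b_v = 0, a = 1.5, tau0 = 0.3)
#' rw_step(s, noise_scales(0.1, 0.02, 0.005), seed = 1)
latent_state <- function(b_v, a, tau0) {
  bounds <- latent_bounds()
  if (a < bounds$a_min) stop("`a` must be >= ", bounds$a_min)
  if (tau0 < bounds$tau0_min) stop("`tau0` must be >= ", bounds$tau0_min)
  structure(list(b_v = b_v, a = a, tau0 = tau0), class = "latent_state")
}

#' @rdname latent_state
#' @param sigma_v,sigma_a,sigma_tau per-trial innovation standard deviations
#'   (all >= 0) for `b_v`, `a` and `tau0`.
#' @return `noise_scales()`: a named list of the three scales.
#' @export
noise_scales <- function(sigma_v = 0, sigma_a = 0, sigma_tau = 0) {
  if (any(c(sigma_v, sigma_a, sigma_tau) < 0))
    stop("innovation scales must be non-negative")
  list(sigma_v = sigma_v, sigma_a = sigma_a, sigma_tau = sigma_tau)
}

#' @rdname latent_state
#' @return `latent_bounds()`: the support bounds, `a_min = 0.1` and
#'   `tau0_min = 0`.
#' @export
latent_bounds <- function() {
  list(a_min = 0.1, tau0_min = 0)
}

#' Prior on the initial latent state
#'
#' Location/scale pairs for the trial-1 state, encoding an initial absence of
#' cue knowledge: `b_v` is centred at 0 (no sensitivity), `a` and `tau0` at
#' typical values for speeded binary decisions, truncated to their supports.
#'
#' @param b_v,a,tau0 length-2 numeric vectors `c(location, scale)`.
#' @return An `init_prior` list with `mu` and `sd` components (order:
#'   `b_v`, `a`, `tau0`).
#' @export
init_prior <- function(b_v = c(0, 0.5), a = c(1.5, 0.5), tau0 = c(0.3, 0.1)) {
  structure(list(mu = c(b_v[1], a[1], tau0[1]),
                 sd = c(b_v[2], a[2], tau0[2])),
            class = "init_prior")
}

reflect_lower <- function(x, lower) {
  while (any(x < lower)) x <- ifelse(x < lower, 2 * lower - x, x)
  x
}

#' One Gaussian random-walk step
#'
#' Perturbs each latent component by an independent Gaussian innovation with
#' its scale; `a` and `tau0` are reflected at their lower bounds.
#'
#' @param state a [latent_state()].
#' @param scales a [noise_scales()].
#' @param seed optional integer seed.
#' @return The perturbed `latent_state`.
#' @export
rw_step <- function(state, scales, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bounds <- latent_bounds()
  e <- rnorm(3)
  out <- list(
    b_v = state$b_v + scales$sigma_v * e[1],
    a = reflect_lower(state$a + scales$sigma_a * e[2], bounds$a_min),
    tau0 = reflect_lower(state$tau0 + scales$sigma_tau * e[3],
                         bounds$tau0_min)
  )
  class(out) <- "latent_state"
  out
}

#' Simulate a latent-parameter trajectory
#'
#' Iterates [rw_step()] from the given initial state: the first row equals
#' `init`, each subsequent row is the previous state plus independent
#' Gaussian innovations (with reflection at the support bounds).
#'
#' @param init a [latent_state()] for trial 1.
#' @param scales a [noise_scales()].
#' @param n_trials trajectory length T (>= 1).
#' @param seed optional integer seed.
#' @return Data frame of class `latent_trajectory` with columns `trial`,
#'   `b_v`, `a`, `tau0`.
#' @export
simulate_trajectory <- function(init, scales, n_trials, seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1)
    stop("`n_trials` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  n_trials <- as.integer(n_trials)
  bounds <- latent_bounds()
  b_v <- a <- tau0 <- numeric(n_trials)
  b_v[1] <- init$b_v; a[1] <- init$a; tau0[1] <- init$tau0
  if (n_trials > 1) {
    for (t in 2:n_trials) {
      b_v[t] <- b_v[t - 1] + scales$sigma_v * rnorm(1)
      a[t] <- reflect_lower(a[t - 1] + scales$sigma_a * rnorm(1),
                            bounds$a_min)
      tau0[t] <- reflect_lower(tau0[t - 1] + scales$sigma_tau * rnorm(1),
                               bounds$tau0_min)
    }
  }
  out <- data.frame(trial = seq_len(n_trials), b_v = b_v, a = a, tau0 = tau0)
  class(out) <- c("latent_trajectory", "data.frame")
  out
}

#' Draw an initial latent state from its prior
#'
#' Samples each component from an independent normal with the prior's
#' location and scale, truncated (by rejection) to the latent supports.
#' A zero scale returns the location.
#'
#' @param prior an [init_prior()].
#' @param seed optional integer seed.
#' @return A [latent_state()].
#' @export
sample_init <- function(prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bounds <- latent_bounds()
  lower <- c(-Inf, bounds$a_min, bounds$tau0_min)
  x <- numeric(3)
  for (j in 1:3) {
    if (prior$sd[j] <= 0) {
      x[j] <- max(prior$mu[j], if (is.finite(lower[j])) lower[j] else -Inf)
    } else {
      repeat {
        x[j] <- rnorm(1, prior$mu[j], prior$sd[j])
        if (x[j] >= lower[j]) break
      }
    }
  }
  latent_state(b_v = x[1], a = x[2], tau0 = x[3])
}

#' Write a latent trajectory as delimited text
#'
#' @param trajectory a `latent_trajectory` data frame.
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory)[, c("trial", "b_v", "a", "tau0")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
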