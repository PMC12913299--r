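#' Trial-level parameter maps
#'
#' The drift rate on a trial is a linear function of the signed ecological
#' validity of the presented pattern, `v = v0 + b_v * validity`, where `b_v`
#' is the individual's current sensitivity to the cue validities and `v0` a
#' base drift capturing cue-unrelated dynamic bias. The non-decision time is
#' linear in the number of presented cues, `tau = tau0 + b_tau * n_cues`,
#' where `b_tau` is the extra encoding time per cue (seconds).
#'
#' @param v0 base drift rate (evidence/s).
#' @param b_v drift sensitivity to cue validity.
#' @param validity signed validity regressor, `P(positive | pattern) - 0.5`.
#' @return `trial_drift()`: drift rate(s) in evidence units per second.
#' @export
#' @examples
#' trial_drift(0, 6, 0.413)
#' trial_ndt(0.3, 0.15, 3)
trial_drift <- function(v0, b_v, validity) {
  v0 + b_v * validity
}

#' @rdname trial_drift
#' @param tau0 base non-decision time (seconds, >= 0).
#' @param b_tau additional non-decision time per presented cue (seconds, >= 0).
#' @param n_cues number of presented cues.
#' @return `trial_ndt()`: non-decision time(s) in seconds.
#' @export
trial_ndt <- function(tau0, b_tau, n_cues) {
  if (any(tau0 < 0) || any(b_tau < 0))
    stop("`tau0` and `b_tau` must be non-negative")
  tau0 + b_tau * n_cues
}

check_wiener_params <- function(v, a, tau, beta) {
  if (any(a <= 0)) stop("boundary separation `a` must be positive")
  if (any(beta <= 0 | beta >= 1)) stop("`beta` must lie strictly in (0, 1)")
  if (any(tau < 0)) stop("non-decision time `tau` must be non-negative")
  invisible(TRUE)
}

#' Wiener first-passage-time log density
#'
#' Log of the defective joint density of (boundary, response time) for a
#' unit-variance Wiener process with drift `v` between absorbing boundaries 0
#' and `a`, started at `beta * a`, with non-decision time `tau` added to the
#' hitting time. The upper boundary codes the positive outcome. Evaluated by
#' the standard small-time/large-time series with per-term truncation
#' tolerance 1e-7; observations with `rt <= tau` (or underflowing densities)
#' return the log-floor of -700 rather than an error.
#'
#' @param rt response time(s) in seconds.
#' @param choice `"upper"`/`"lower"`, or a logical/0-1 vector (1 = upper).
#' @param v drift rate.
#' @param a boundary separation (> 0).
#' @param tau non-decision time (>= 0).
#' @param beta relative starting point in (0, 1).
#' @return Numeric vector of log densities (recycled over arguments).
#' @export
#' @examples
#' dwfpt(0.8, "upper", v = 1, a = 1.5, tau = 0.3, beta = 0.5)
dwfpt <- function(rt, choice, v, a, tau, beta) {
  check_wiener_params(v, a, tau, beta)
  up <- as_upper(choice)
  n <- max(length(rt), length(up), length(v), length(a),
           length(tau), length(beta))
  .wfpt_log_density_cpp(rep_len(as.numeric(rt), n), rep_len(up, n),
                        as.numeric(v), as.numeric(a),
                        as.numeric(tau), as.numeric(beta))
}

as_upper <- function(choice) {
  if (is.character(choice)) {
    ok <- choice %in% c("upper", "lower", "positive", "negative")
    if (!all(ok)) stop("unknown choice label(s): ",
                       paste(unique(choice[!ok]), collapse = ", "))
    as.integer(choice %in% c("upper", "positive"))
  } else {
    as.integer(as.logical(choice))
  }
}

#' Analytic boundary-absorption probability
#'
#' Probability that the Wiener process is absorbed at the upper boundary,
#' `P(upper) = (1 - exp(-2 v a beta)) / (1 - exp(-2 v a))`, evaluated via
#' `expm1` for stability and by the analytic limit `beta` at `v = 0`.
#'
#' @inheritParams dwfpt
#' @return Probability of an upper-boundary (positive-outcome) response.
#' @export
#' @examples
#' wfpt_choice_prob(0, 1, 0.5)  # 0.5 by symmetry
wfpt_choice_prob <- function(v, a, beta) {
  if (any(a <= 0)) stop("boundary separation `a` must be positive")
  if (any(beta <= 0 | beta >= 1)) stop("`beta` must lie strictly in (0, 1)")
  n <- max(length(v), length(a), length(beta))
  v <- rep_len(v, n); a <- rep_len(a, n); beta <- rep_len(beta, n)
  p <- ifelse(abs(v * a) < 1e-10,
              beta,
              expm1(-2 * v * a * beta) / expm1(-2 * v * a))
  pmin(pmax(p, 0), 1)
}

#' Simulate Wiener first-passage trials
#'
#' Euler-Maruyama discretisation of the diffusion path with step `dt`
#' (default 1 ms), with a Brownian-bridge boundary-crossing test inside each
#' step. The bridge test removes the O(sqrt(dt)) boundary-overshoot bias of
#' the naive scheme; the remaining error is the O(dt) quantisation of the
#' recorded hitting time. The returned response time is strictly greater
#' than `tau`. Use `dt = 1e-4` when comparing against the exact density.
#'
#' @inheritParams dwfpt
#' @param n number of trials.
#' @param dt Euler step in seconds.
#' @param max_time cap on a single decision time (seconds); paths still
#'   unabsorbed are closed out towards the nearer boundary.
#' @param seed optional integer seed.
#' @return Data frame with columns `choice` (`"upper"`/`"lower"`) and `rt`.
#' @export
#' @examples
#' rwfpt(5, v = 1, a = 1.5, tau = 0.3, beta = 0.5, seed = 1)
rwfpt <- function(n, v, a, tau, beta, dt = 1e-3, max_time = 30, seed = NULL) {
  check_wiener_params(v, a, tau, beta)
  if (!is.null(seed)) set.seed(seed)
  m <- .wfpt_simulate_cpp(as.integer(n), v, a, tau, beta, dt, max_time)
  data.frame(choice = ifelse(m[, 1] == 1, "upper", "lower"), rt = m[, 2],
             stringsAsFactors = FALSE)
}
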