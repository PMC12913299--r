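#' Deterministic preset parameter trajectories
#'
#' Fixture trajectories emulating the characteristic learning-curve shapes of
#' supportive ("congruent") versus adverse ("incongruent") environments: the
#' drift sensitivity `b_v` rises from zero towards an asymptote (higher and
#' faster in the congruent preset), while boundary separation and base
#' non-decision time decay exponentially to floors (incongruent participants
#' stay more cautious and slower). These presets are integration-test
#' fixtures with a convenient functional form, not fitted curves; parameter
#' recovery uses random-walk-generated trajectories.
#'
#' @param condition `"congruent"` or `"incongruent"`.
#' @param n_trials trajectory length (>= 1).
#' @param bv_asymptote,bv_rate asymptote and exponential time constant
#'   (trials) of the rising sensitivity curve; defaults depend on `condition`.
#' @param a_start,a_end,tau0_start,tau0_end endpoints of the decaying
#'   boundary-separation and base non-decision-time curves.
#' @param decay_rate time constant (trials) of the decays.
#' @return A `latent_trajectory` data frame (`trial`, `b_v`, `a`, `tau0`).
#' @export
#' @examples
#' tr <- preset_trajectory("congruent", 246)
#' plot(tr$trial, tr$b_v, type = "l")
preset_trajectory <- function(condition = c("congruent", "incongruent"),
                              n_trials,
                              bv_asymptote = NULL, bv_rate = NULL,
                              a_start = NULL, a_end = NULL,
                              tau0_start = NULL, tau0_end = NULL,
                              decay_rate = 80) {
  condition <- match.arg(condition)
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1)
    stop("`n_trials` must be a positive integer")
  cong <- condition == "congruent"
  if (is.null(bv_asymptote)) bv_asymptote <- if (cong) 6 else 3.5
  if (is.null(bv_rate)) bv_rate <- if (cong) 60 else 90
  if (is.null(a_start)) a_start <- if (cong) 2.0 else 2.2
  if (is.null(a_end)) a_end <- if (cong) 1.3 else 1.5
  if (is.null(tau0_start)) tau0_start <- if (cong) 0.40 else 0.45
  if (is.null(tau0_end)) tau0_end <- if (cong) 0.25 else 0.30
  t <- seq_len(n_trials) - 1
  out <- data.frame(
    trial = seq_len(n_trials),
    b_v = bv_asymptote * (1 - exp(-t / bv_rate)),
    a = a_end + (a_start - a_end) * exp(-t / decay_rate),
    tau0 = tau0_end + (tau0_start - tau0_end) * exp(-t / decay_rate)
  )
  class(out) <- c("latent_trajectory", "data.frame")
  out
}

#' Static (time-invariant) trial-level parameters
#'
#' @param v0 base drift rate.
#' @param b_tau extra non-decision time per presented cue (seconds, >= 0).
#' @param beta relative starting point in (0, 1).
#' @return A named list of class `static_params`.
#' @export
static_params <- function(v0 = 0, b_tau = 0.15, beta = 0.5) {
  if (b_tau < 0) stop("`b_tau` must be non-negative")
  if (beta <= 0 || beta >= 1) stop("`beta` must lie strictly in (0, 1)")
  structure(list(v0 = v0, b_tau = b_tau, beta = beta),
            class = "static_params")
}

#' Simulate one participant's session
#'
#' Composes the two model levels: a trial sequence is drawn from the
#' environment, the latent trajectory supplies per-trial `(b_v, a, tau0)`,
#' the trial-level maps give drift `v0 + b_v * (P(positive|pattern) - 0.5)`
#' and non-decision time `tau0 + b_tau * n_cues`, and each (choice, rt) pair
#' is simulated from the Wiener process.
#'
#' @param env an environment as from [canonical_environment()].
#' @param statics a [static_params()].
#' @param trajectory a fixed `latent_trajectory` of length `n_trials`, or
#'   `NULL` to simulate one from `init`/`scales`.
#' @param scales a [noise_scales()] (used when `trajectory` is `NULL`).
#' @param init a [latent_state()] or [init_prior()] for trial 1 (used when
#'   `trajectory` is `NULL`).
#' @param mode session-sequence mode, `"exact_counts"` or `"iid"`.
#' @param n_trials trials per session (246 for `exact_counts` with the
#'   canonical environment).
#' @param dt Euler step for the trial simulator (seconds).
#' @param participant participant id recorded in the output.
#' @param condition condition label recorded in the output.
#' @param seed optional integer seed.
#' @return Data frame of trial records: `participant`, `trial`, `bits`,
#'   `n_cues`, `outcome`, `choice`, `rt`, `condition`.
#' @export
simulate_participant <- function(env, statics,
                                 trajectory = NULL, scales = NULL,
                                 init = NULL,
                                 mode = c("exact_counts", "iid"),
                                 n_trials = sum(env$total),
                                 dt = 1e-3, participant = 1L,
                                 condition = "none", seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  seq_df <- make_session_sequence(env, mode, n_trials)
  if (is.null(trajectory)) {
    if (is.null(scales)) scales <- noise_scales()
    if (is.null(init)) init <- init_prior()
    state1 <- if (inherits(init, "init_prior")) sample_init(init) else init
    trajectory <- simulate_trajectory(state1, scales, n_trials)
  }
  if (nrow(trajectory) != n_trials)
    stop("trajectory length (", nrow(trajectory),
         ") must equal n_trials (", n_trials, ")")
  validity <- validity_regressor(seq_df$bits, env)
  v <- trial_drift(statics$v0, trajectory$b_v, validity)
  tau <- trial_ndt(trajectory$tau0, statics$b_tau, seq_df$n_cues)
  m <- .simulate_session_cpp(v, trajectory$a, tau, statics$beta, dt, 30)
  data.frame(
    participant = participant,
    trial = seq_df$trial,
    bits = seq_df$bits,
    n_cues = seq_df$n_cues,
    outcome = seq_df$outcome,
    choice = ifelse(m[, 1] == 1, "positive", "negative"),
    rt = m[, 2],
    condition = condition,
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic experiment
#'
#' @param n_participants number of simulated participants.
#' @param n_trials trials per participant (must be 246 in `exact_counts`
#'   mode with the canonical environment).
#' @param mode session-sequence mode.
#' @param statics a [static_params()].
#' @param scales a [noise_scales()] (random-walk trajectories), or `NULL`.
#' @param init an [init_prior()] used when trajectories are random walks.
#' @param preset `"congruent"`, `"incongruent"`, or `NULL`; when set, every
#'   participant uses the deterministic [preset_trajectory()] for that
#'   condition and `condition` is labelled accordingly.
#' @param condition condition label when `preset` is `NULL`.
#' @param dt Euler step (seconds).
#' @param seed master seed; each participant runs in an independent
#'   substream derived from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 20, n_trials = 246,
                             mode = c("exact_counts", "iid"),
                             statics = static_params(),
                             scales = NULL, init = init_prior(),
                             preset = NULL, condition = "none",
                             dt = 1e-3, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "exact_counts" && n_trials != 246)
    stop("exact_counts mode requires n_trials = 246")
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 mode = mode, statics = statics, scales = scales,
                 init = init, preset = preset, condition = condition,
                 dt = dt, seed = seed),
            class = "synthetic_config")
}

#' Simulate a full synthetic experiment
#'
#' Simulates `n_participants` independent sessions under the configured
#' generative model. Each participant uses an RNG substream derived from the
#' master seed by a fixed offset, so the output is fully reproducible and
#' individual participants can be re-simulated in isolation.
#'
#' @param config a [synthetic_config()].
#' @param env environment to simulate from (canonical by default).
#' @return Data frame of all participants' trial records (a dataset).
#' @export
#' @examples
#' cfg <- synthetic_config(n_participants = 2, seed = 7,
#'                         preset = "congruent")
#' d <- simulate_experiment(cfg)
#' nrow(d)  # 2 * 246
simulate_experiment <- function(config, env = canonical_environment()) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    traj <- NULL
    cond <- config$condition
    if (!is.null(config$preset)) {
      traj <- preset_trajectory(config$preset, config$n_trials)
      cond <- config$preset
    }
    out[[i]] <- simulate_participant(
      env, config$statics, trajectory = traj, scales = config$scales,
      init = config$init, mode = config$mode, n_trials = config$n_trials,
      dt = config$dt, participant = i, condition = cond,
      seed = participant_seed(config$seed, i))
  }
  do.call(rbind, out)
}

# fixed per-participant substream offsets; kept below .Machine$integer.max
participant_seed <- function(master_seed, i) {
  as.integer((master_seed + 7919L * i) %% .Machine$integer.max)
}
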