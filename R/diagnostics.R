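#' Trailing moving average
#'
#' Smooths a per-trial series with a simple trailing moving average of the
#' given lag. The window is truncated at the start of the series: the first
#' smoothed values average over the points available so far. A centered
#' window (also truncated at both edges) is available via `align`.
#'
#' @param series numeric vector of per-trial values.
#' @param lag window length in trials (>= 1, default 20).
#' @param align `"trailing"` (default) or `"center"`.
#' @return Smoothed numeric vector of the same length.
#' @export
#' @examples
#' moving_average(1:10, lag = 3)
moving_average <- function(series, lag = 20, align = c("trailing", "center")) {
  align <- match.arg(align)
  if (length(series) == 0) stop("`series` must be non-empty")
  if (!is.numeric(lag) || length(lag) != 1 || lag < 1)
    stop("`lag` must be a positive integer")
  n <- length(series)
  half <- floor((lag - 1) / 2)
  vapply(seq_len(n), function(t) {
    if (align == "trailing") {
      mean(series[max(1, t - lag + 1):t])
    } else {
      mean(series[max(1, t - half):min(n, t + lag - 1 - half)])
    }
  }, numeric(1))
}

#' Accuracy of a trial
#'
#' Feedback-consistent scoring (`"outcome"`, the default) counts a trial as
#' correct when the choice equals that trial's realized outcome, matching a
#' probabilistic-feedback task. `"modal"` scoring instead compares the choice
#' with the more likely outcome given the pattern's designed probability.
#'
#' @param dataset trial records with `bits`, `outcome`, `choice`.
#' @param env environment (needed for `"modal"` scoring).
#' @param scoring `"outcome"` or `"modal"`.
#' @return Logical vector, one element per trial.
#' @export
trial_correct <- function(dataset, env = canonical_environment(),
                          scoring = c("outcome", "modal")) {
  scoring <- match.arg(scoring)
  if (scoring == "outcome") {
    dataset$choice == dataset$outcome
  } else {
    p <- env$p_designed[match(dataset$bits, env$bits)]
    modal <- ifelse(p >= 0.5, "positive", "negative")
    dataset$choice == modal
  }
}

#' RT and accuracy by ecological-validity level
#'
#' Groups the 14 patterns by absolute ecological validity,
#' `|P(positive | pattern) - 0.5|` rounded to 3 decimals (7 distinct levels
#' in the canonical environment), computes each participant's mean RT and
#' accuracy per level, and reports the across-participant mean and SD. RT
#' summaries use correct trials only by default, mirroring the convention
#' for correct-RT tables; `rt_trials = "all"` includes every trial.
#'
#' @param dataset trial records (`participant`, `bits`, `outcome`, `choice`,
#'   `rt`).
#' @param env environment defining the validity levels.
#' @param rt_trials `"correct"` (default) or `"all"`.
#' @param scoring accuracy scoring rule, see [trial_correct()].
#' @return Data frame keyed by `validity_level` with columns `n_patterns`,
#'   `rt_mean`, `rt_sd`, `acc_mean`, `acc_sd`.
#' @export
rt_accuracy_by_validity <- function(dataset, env = canonical_environment(),
                                    rt_trials = c("correct", "all"),
                                    scoring = "outcome") {
  rt_trials <- match.arg(rt_trials)
  idx <- match(dataset$bits, env$bits)
  if (anyNA(idx))
    stop("unknown pattern(s): ",
         paste(unique(dataset$bits[is.na(idx)]), collapse = ", "))
  dataset$level <- round(abs(env$p_designed[idx] - 0.5), 3)
  dataset$correct <- trial_correct(dataset, env, scoring)
  levels_all <- sort(unique(round(abs(env$p_designed - 0.5), 3)))

  per_part <- do.call(rbind, lapply(
    split(dataset, list(dataset$participant, dataset$level), drop = TRUE),
    function(d) {
      rts <- if (rt_trials == "correct") d$rt[d$correct] else d$rt
      data.frame(participant = d$participant[1], level = d$level[1],
                 rt = if (length(rts)) mean(rts) else NA_real_,
                 acc = mean(d$correct))
    }))
  out <- do.call(rbind, lapply(levels_all, function(lv) {
    d <- per_part[per_part$level == lv, ]
    np <- sum(round(abs(env$p_designed - 0.5), 3) == lv)
    if (nrow(d) == 0) {
      return(data.frame(validity_level = lv, n_patterns = np,
                        rt_mean = NA_real_, rt_sd = NA_real_,
                        acc_mean = NA_real_, acc_sd = NA_real_))
    }
    data.frame(validity_level = lv, n_patterns = np,
               rt_mean = mean(d$rt, na.rm = TRUE),
               rt_sd = if (sum(!is.na(d$rt)) > 1) sd(d$rt, na.rm = TRUE)
                       else NA_real_,
               acc_mean = mean(d$acc),
               acc_sd = if (nrow(d) > 1) sd(d$acc) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Mean correct RT by condition and cue count
#'
#' Only trials whose choice matched the outcome enter the cells. Cell means
#' and SDs are reported in seconds rounded to 3 decimals (millisecond
#' precision). A cell with no correct trials is reported as missing (`NA`),
#' never as zero.
#'
#' @param dataset trial records (`condition`, `n_cues`, `outcome`, `choice`,
#'   `rt`).
#' @return Data frame with columns `condition`, `n_cues`, `n_trials`,
#'   `rt_mean`, `rt_sd`.
#' @export
correct_rt_by_ncues <- function(dataset) {
  if (nrow(dataset) == 0) stop("`dataset` must be non-empty")
  correct <- dataset$choice == dataset$outcome
  cells <- expand.grid(condition = unique(dataset$condition),
                       n_cues = sort(unique(dataset$n_cues)),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- dataset$condition == cells$condition[i] &
      dataset$n_cues == cells$n_cues[i] & correct
    rts <- dataset$rt[sel]
    data.frame(condition = cells$condition[i], n_cues = cells$n_cues[i],
               n_trials = length(rts),
               rt_mean = if (length(rts)) round_half_up(mean(rts), 3)
                         else NA_real_,
               rt_sd = if (length(rts) > 1) round_half_up(sd(rts), 3)
                       else NA_real_)
  }))
  out[order(out$condition, out$n_cues), ]
}

#' The lens model equation
#'
#' Achievement, the correlation between the environmental criterion and the
#' individual's judgment, decomposed as
#' `r_a = G * Re * Ri + C * sqrt((1 - Re^2) * (1 - Ri^2))`,
#' where `G` is the matching correlation between the linear models of the
#' environment and the judge, `Re` the environmental predictability, `Ri`
#' the judge's response consistency, and `C` the correlation between the two
#' models' error terms. With independent errors (`C = 0`) achievement is
#' simply the product `G * Re * Ri`.
#'
#' @param G matching correlation, in \[-1, 1\].
#' @param Re environmental predictability, in \[0, 1\].
#' @param Ri response consistency, in \[0, 1\].
#' @param C error-term correlation, in \[-1, 1\].
#' @return Achievement `r_a`.
#' @export
#' @examples
#' lens_model_equation(G = 1, Re = 1, Ri = 1, C = 0)  # 1
lens_model_equation <- function(G, Re, Ri, C = 0) {
  if (any(abs(c(G, C)) > 1)) stop("`G` and `C` must lie in [-1, 1]")
  if (any(Re < 0 | Re > 1) || any(Ri < 0 | Ri > 1))
    stop("`Re` and `Ri` must lie in [0, 1]")
  G * Re * Ri + C * sqrt((1 - Re^2) * (1 - Ri^2))
}

#' Take-the-best prediction for a single cue pattern
#'
#' Adaptation of the lexicographic take-the-best heuristic to single-profile
#' binary prediction: the present cues are ranked by the extremity of their
#' marginal validity, `|P(positive | cue present) - 0.5|`, in descending
#' order. The most extreme present cue dictates the predicted outcome
#' (positive if its marginal validity exceeds 0.5). Cues whose extremities
#' tie within `tol` form one rank; if a rank contains cues pointing to
#' opposite outcomes it does not discriminate and the search falls through to
#' the next rank. If no rank discriminates (including near-chance cues with
#' extremity below `tol`), the prediction is a uniform guess.
#'
#' @param pattern bit string of the presented pattern.
#' @param env environment supplying the marginal cue validities.
#' @param tol tie/discrimination tolerance on the extremity scale
#'   (default 0.01).
#' @param seed optional integer seed for the guessing fallback.
#' @return `"positive"` or `"negative"`.
#' @export
#' @examples
#' env <- canonical_environment()
#' take_the_best_predict("1000", env)  # cue 1 alone: positive
take_the_best_predict <- function(pattern, env, tol = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nchar(env$bits[1])
  if (nchar(pattern) != k || grepl("[^01]", pattern))
    stop("`pattern` must be a ", k, "-character 0/1 string")
  present <- which(strsplit(pattern, "")[[1]] == "1")
  if (length(present) == 0 || length(present) == k)
    stop("all-absent and all-present patterns are inadmissible")
  marg <- vapply(present, function(j) marginal_cue_validity(env, j),
                 numeric(1))
  extremity <- abs(marg - 0.5)
  direction <- sign(marg - 0.5)
  ord <- order(extremity, decreasing = TRUE)
  extremity <- extremity[ord]
  direction <- direction[ord]
  i <- 1
  while (i <= length(extremity)) {
    if (extremity[i] <= tol) break  # remaining cues do not discriminate
    rank <- which(abs(extremity - extremity[i]) <= tol &
                    seq_along(extremity) >= i)
    dirs <- unique(direction[rank])
    if (length(dirs) == 1 && dirs != 0) {
      return(if (dirs > 0) "positive" else "negative")
    }
    i <- max(rank) + 1  # conflicting rank: fall through
  }
  if (runif(1) < 0.5) "positive" else "negative"
}

#' Posterior re-simulation (posterior predictive check)
#'
#' For each participant, draws `n_draws` (default 500) joint samples of the
#' static parameters and a stored latent trajectory from the fitted
#' posterior, re-simulates the participant's session (conditioning on the
#' observed cue-pattern and outcome sequence), and aggregates the predicted
#' RT and accuracy by absolute ecological-validity level and condition:
#' the median across draws of the per-draw participant means, together with
#' their mean and SD.
#'
#' @param fits list of `dlm_fit` objects (one per participant), each
#'   carrying its `records`.
#' @param env environment defining validities.
#' @param n_draws posterior draws per participant (default 500).
#' @param dt Euler step for re-simulation (seconds).
#' @param seed optional integer seed.
#' @return A list with `predicted` (re-simulated dataset in the observed
#'   dataset's schema, one replicate per draw indexed by `draw`) and
#'   `summary` (per condition and validity level: median, mean and SD across
#'   draws and participants of mean RT and accuracy).
#' @export
posterior_resimulate <- function(fits, env = canonical_environment(),
                                 n_draws = 500, dt = 1e-3, seed = NULL) {
  if (length(fits) == 0) stop("`fits` must be a non-empty list of fits")
  if (!is.null(seed)) set.seed(seed)
  pred <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    if (length(fit$trajectories) == 0)
      stop("fit ", i, " stores no latent trajectories")
    rec <- fit$records
    obs <- records_to_obs(rec, env)
    T <- length(obs$rt)
    # joint (statics, trajectory) draws: resample stored trajectory indices
    pick <- sample.int(length(fit$trajectories), n_draws, replace = TRUE)
    cond <- if (!is.null(rec$condition)) as.character(rec$condition[1])
            else "none"
    sims <- vector("list", n_draws)
    for (d in seq_len(n_draws)) {
      tr <- fit$trajectories[[pick[d]]]
      th <- fit$samples[fit$trajectory_iterations[pick[d]], ]
      v <- trial_drift(th$v0, tr$b_v, obs$validity)
      tau <- trial_ndt(tr$tau0, th$b_tau, obs$ncues)
      m <- .simulate_session_cpp(v, tr$a, tau, th$beta, dt, 30)
      sims[[d]] <- data.frame(
        participant = if (!is.null(rec$participant)) rec$participant[1]
                      else i,
        draw = d, trial = seq_len(T), bits = rec$bits,
        n_cues = obs$ncues, outcome = rec$outcome,
        choice = ifelse(m[, 1] == 1, "positive", "negative"),
        rt = m[, 2], condition = cond, stringsAsFactors = FALSE)
    }
    pred[[i]] <- do.call(rbind, sims)
  }
  predicted <- do.call(rbind, pred)

  predicted$level <- round(abs(
    env$p_designed[match(predicted$bits, env$bits)] - 0.5), 3)
  predicted$correct <- predicted$choice == predicted$outcome
  cells <- split(predicted,
                 list(predicted$condition, predicted$level), drop = TRUE)
  summary <- do.call(rbind, lapply(cells, function(d) {
    per_draw <- do.call(rbind, lapply(
      split(d, list(d$participant, d$draw), drop = TRUE), function(dd) {
        data.frame(rt = mean(dd$rt), acc = mean(dd$correct))
      }))
    data.frame(condition = d$condition[1], validity_level = d$level[1],
               rt_median = median(per_draw$rt), rt_mean = mean(per_draw$rt),
               rt_sd = sd(per_draw$rt),
               acc_median = median(per_draw$acc),
               acc_mean = mean(per_draw$acc), acc_sd = sd(per_draw$acc))
  }))
  rownames(summary) <- NULL
  summary <- summary[order(summary$condition, summary$validity_level), ]
  predicted$level <- NULL
  predicted$correct <- NULL
  list(predicted = predicted, summary = summary)
}
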