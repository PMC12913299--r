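#' The canonical four-cue probability-learning environment
#'
#' Returns the 14-pattern environment used in the modified weather prediction
#' task: four binary cues of which one to three are shown per trial, each
#' admissible cue pattern with its per-session presentation count, its
#' unconditional occurrence probability, the realized counts of positive
#' (`a`) and negative (`b`) outcomes across one 246-trial session, and the
#' designed conditional probability of the positive outcome given the pattern.
#' The four cues are individually associated with the positive outcome with
#' probabilities of roughly 0.8, 0.6, 0.4 and 0.2 (cue 1 strongest positive,
#' cue 4 strongest negative); see [marginal_cue_validity()].
#'
#' The designed probability and the realized counts are stored separately:
#' for four patterns the printed designed probability differs from
#' `a / (a + b)` because the frequency distribution was fixed by design before
#' outcomes were assigned. Sampling in `iid` mode uses the designed
#' probability; `exact_counts` mode reproduces the realized counts (see
#' [make_session_sequence()]).
#'
#' @return A data frame of class `mcpl_env` with one row per pattern and
#'   columns `label`, `bits` (4-character 0/1 string, leftmost = cue 1),
#'   `n_cues`, `total` (trials per 246-trial session), `p_pattern`
#'   (unconditional probability), `a`, `b` (realized positive/negative
#'   outcome counts) and `p_designed` (designed P(positive | pattern)).
#' @seealso [admissible_patterns()], [validity_regressor()],
#'   [make_session_sequence()]
#' @export
#' @examples
#' env <- canonical_environment()
#' sum(env$total)  # 246 trials per session
#' sum(env$a)      # 123 positive outcomes
canonical_environment <- function() {
  env <- data.frame(
    label = c("A", "B", "C", "D", "E", "F", "G",
              "H", "I", "J", "K", "L", "M", "N"),
    bits = c("1110", "1101", "1100", "1011", "1010", "1001", "1000",
             "0111", "0110", "0101", "0100", "0011", "0010", "0001"),
    total = c(23L, 11L, 32L, 11L, 15L, 8L, 23L,
              23L, 8L, 15L, 11L, 32L, 11L, 23L),
    p_pattern = c(0.093, 0.045, 0.130, 0.045, 0.061, 0.033, 0.093,
                  0.093, 0.033, 0.061, 0.045, 0.130, 0.045, 0.093),
    a = c(21L, 9L, 29L, 3L, 12L, 4L, 21L,
          2L, 4L, 3L, 6L, 2L, 5L, 2L),
    b = c(2L, 2L, 3L, 8L, 3L, 4L, 2L,
          21L, 4L, 12L, 5L, 30L, 6L, 21L),
    p_designed = c(0.913, 0.773, 0.906, 0.227, 0.800, 0.500, 0.913,
                   0.087, 0.500, 0.200, 0.546, 0.063, 0.454, 0.087),
    stringsAsFactors = FALSE
  )
  env$n_cues <- n_cues(env$bits)
  env <- env[, c("label", "bits", "n_cues", "total", "p_pattern",
                 "a", "b", "p_designed")]
  class(env) <- c("mcpl_env", "data.frame")
  validate_environment(env)
  env
}

#' Number of presented cues in a pattern
#'
#' @param bits character vector of 0/1 pattern strings.
#' @return Integer vector of set-bit counts.
#' @export
n_cues <- function(bits) {
  vapply(strsplit(bits, ""), function(b) sum(b == "1"), integer(1))
}

validate_environment <- function(env) {
  stopifnot(is.data.frame(env))
  need <- c("label", "bits", "total", "p_pattern", "a", "b", "p_designed")
  miss <- setdiff(need, names(env))
  if (length(miss)) stop("environment is missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(env$a + env$b != env$total))
    stop("realized outcome counts must sum to the session count per pattern")
  if (any(env$p_designed < 0 | env$p_designed > 1))
    stop("designed probabilities must lie in [0, 1]")
  nc <- n_cues(env$bits)
  if (any(nc < 1 | nc >= nchar(env$bits)))
    stop("all-absent and all-present cue patterns are inadmissible")
  invisible(env)
}

#' Enumerate admissible cue patterns
#'
#' All presence/absence patterns over `cue_count` cue positions excluding the
#' all-absent and all-present patterns, so that each trial shows between 1 and
#' `cue_count - 1` cues.
#'
#' @param cue_count number of cue positions (>= 2).
#' @return Character vector of `2^cue_count - 2` bit strings, leftmost
#'   character = cue 1.
#' @export
#' @examples
#' length(admissible_patterns(4))  # 14
admissible_patterns <- function(cue_count) {
  if (!is.numeric(cue_count) || length(cue_count) != 1 || cue_count < 2 ||
      cue_count != round(cue_count))
    stop("`cue_count` must be a single integer >= 2")
  k <- as.integer(cue_count)
  ints <- seq_len(2^k - 2)  # drops 0 (all absent) and 2^k - 1 (all present)
  vapply(ints, function(i) {
    paste(rev(as.integer(intToBits(i)[seq_len(k)])), collapse = "")
  }, character(1))
}

#' Ecological validity regressor of a cue pattern
#'
#' The drift rate of the trial-level diffusion process is linear in the
#' ecological validity of the presented pattern. The signed coding,
#' `P(positive | pattern) - 0.5`, is the regressor entering the drift map;
#' the absolute coding `|P(positive | pattern) - 0.5|` is used only for
#' grouping and plotting, with larger values reflecting higher validity.
#'
#' @param pattern bit string(s) present in `env`.
#' @param env an environment as from [canonical_environment()].
#' @param coding `"signed"` (default) or `"absolute"`.
#' @return Numeric vector of validities.
#' @export
#' @examples
#' env <- canonical_environment()
#' validity_regressor("1110", env)              # 0.413
#' validity_regressor("1011", env, "absolute")  # 0.273
validity_regressor <- function(pattern, env, coding = c("signed", "absolute")) {
  coding <- match.arg(coding)
  idx <- match(pattern, env$bits)
  if (anyNA(idx))
    stop("unknown pattern(s): ",
         paste(unique(pattern[is.na(idx)]), collapse = ", "))
  v <- env$p_designed[idx] - 0.5
  if (coding == "absolute") abs(v) else v
}

#' Marginal single-cue validity
#'
#' The realized probability of a positive outcome across all trials on which
#' the given cue is present: the sum of positive-outcome counts over rows with
#' the cue set, divided by the total session count of those rows. For the
#' canonical environment these recompute to approximately 0.805, 0.602, 0.398
#' and 0.203 for cues 1-4, matching the designed single-cue validities of
#' 0.8, 0.6, 0.4 and 0.2.
#'
#' @param env an environment as from [canonical_environment()].
#' @param cue_index cue position, 1-based (leftmost bit = cue 1).
#' @return Single numeric probability.
#' @export
marginal_cue_validity <- function(env, cue_index) {
  k <- nchar(env$bits[1])
  if (!is.numeric(cue_index) || length(cue_index) != 1 ||
      cue_index < 1 || cue_index > k || cue_index != round(cue_index))
    stop("`cue_index` must be a single integer in 1..", k)
  present <- substr(env$bits, cue_index, cue_index) == "1"
  sum(env$a[present]) / sum(env$total[present])
}

#' Generate a trial sequence from an environment
#'
#' `exact_counts` mode reproduces one designed session: exactly `total`
#' presentations of each pattern with exactly `a` positive and `b` negative
#' outcomes per pattern, in uniformly random order (identical multiset across
#' seeds). `iid` mode draws patterns with probability `p_pattern` and
#' outcomes Bernoulli(`p_designed`) independently per trial.
#'
#' @param env an environment as from [canonical_environment()].
#' @param mode `"exact_counts"` or `"iid"`.
#' @param n_trials number of trials; in `exact_counts` mode this must equal
#'   the session length `sum(env$total)`.
#' @param seed optional integer seed for reproducibility.
#' @return Data frame with columns `trial`, `bits`, `n_cues`, `outcome`
#'   (`"positive"`/`"negative"`).
#' @export
make_session_sequence <- function(env, mode = c("exact_counts", "iid"),
                                  n_trials = sum(env$total), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "exact_counts") {
    if (n_trials != sum(env$total))
      stop("exact_counts mode requires n_trials = ", sum(env$total))
    bits <- rep(env$bits, env$total)
    outcome <- unlist(lapply(seq_len(nrow(env)), function(i) {
      c(rep("positive", env$a[i]), rep("negative", env$b[i]))
    }))
    ord <- sample.int(n_trials)
    bits <- bits[ord]
    outcome <- outcome[ord]
  } else {
    p <- env$p_pattern / sum(env$p_pattern)
    idx <- sample.int(nrow(env), n_trials, replace = TRUE, prob = p)
    bits <- env$bits[idx]
    outcome <- ifelse(runif(n_trials) < env$p_designed[idx],
                      "positive", "negative")
  }
  data.frame(trial = seq_len(n_trials), bits = bits,
             n_cues = n_cues(bits), outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Read/write an environment table
#'
#' Environments are interchanged as comma-separated text with columns
#' `label, bits, total, p_pattern, a, b, p_designed`.
#'
#' @param path file path.
#' @return `read_environment()` returns a validated `mcpl_env` data frame.
#' @export
read_environment <- function(path) {
  env <- read.csv(path, colClasses = c(bits = "character"),
                  stringsAsFactors = FALSE)
  env$n_cues <- n_cues(env$bits)
  env <- env[, c("label", "bits", "n_cues", "total", "p_pattern",
                 "a", "b", "p_designed")]
  class(env) <- c("mcpl_env", "data.frame")
  validate_environment(env)
  env
}

#' @rdname read_environment
#' @param env environment to write.
#' @export
write_environment <- function(env, path) {
  validate_environment(env)
  write.csv(env[, c("label", "bits", "total", "p_pattern",
                    "a", "b", "p_designed")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mcpl_env <- function(x, ...) {
  cat(sprintf("Multiple-cue learning environment: %d patterns, %d trials/session\n",
              nrow(x), sum(x$total)))
  print.data.frame(x, row.names = FALSE, ...)
  cat(sprintf("Totals: %d trials, %d positive, %d negative; sum P(pattern) = %.3f\n",
              sum(x$total), sum(x$a), sum(x$b), sum(x$p_pattern)))
  invisible(x)
}
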