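# Shared fixtures, all built in code.

canon <- canonical_environment()

# constant-parameter trajectory of length n
flat_trajectory <- function(n, b_v, a, tau0) {
  out <- data.frame(trial = seq_len(n), b_v = b_v, a = a, tau0 = tau0)
  class(out) <- c("latent_trajectory", "data.frame")
  out
}

# one synthetic session with a constant latent state (memoised per argument set)
.session_cache <- new.env(parent = emptyenv())
cached_session <- function(b_v = 4, a = 1.5, tau0 = 0.3, seed = 11) {
  key <- paste(b_v, a, tau0, seed, sep = "_")
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- simulate_participant(
      canon, static_params(v0 = 0, b_tau = 0.15, beta = 0.5),
      trajectory = flat_trajectory(246, b_v, a, tau0), seed = seed)
  }
  .session_cache[[key]]
}

# hand-constructible toy dataset for the summary-table tests
toy_dataset <- function() {
  data.frame(
    participant = c(1, 1, 1, 1, 1, 1),
    trial = 1:6,
    bits = c("1000", "1100", "1110", "1000", "1100", "0001"),
    n_cues = c(1, 2, 3, 1, 2, 1),
    outcome = c("positive", "positive", "positive",
                "negative", "negative", "negative"),
    choice = c("positive", "positive", "negative",
               "positive", "negative", "negative"),
    rt = c(1.0, 1.5, 2.0, 1.2, 1.8, 0.9),
    condition = "toy",
    stringsAsFactors = FALSE
  )
}

# a small hand-made posterior fit object (for summary/re-simulation tests)
fake_fit <- function(records, samples, trajectories) {
  stopifnot(nrow(samples) %% length(trajectories) == 0)
  thin <- nrow(samples) / length(trajectories)
  structure(list(samples = samples,
                 trajectories = trajectories,
                 trajectory_iterations = seq_along(trajectories) * thin,
                 acceptance_rate = NA_real_,
                 config = NULL,
                 records = records),
            class = "dlm_fit")
}
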