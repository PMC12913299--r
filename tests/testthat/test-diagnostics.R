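test_that("moving average matches the brute-force trailing window", {
  expect_equal(moving_average(rep(3.7, 25), lag = 20), rep(3.7, 25))
  x <- c(5, 1, 4, 2, 8, 7, 3, 6, 9, 10)
  expect_equal(moving_average(x, lag = 1), x)
  brute <- vapply(seq_along(x), function(t) mean(x[max(1, t - 2):t]),
                  numeric(1))
  expect_equal(moving_average(x, lag = 3), brute)
  # commutes with affine transforms
  expect_equal(moving_average(2 * x + 1, lag = 4),
               2 * moving_average(x, lag = 4) + 1)
  expect_error(moving_average(numeric(0)), "non-empty")
  expect_error(moving_average(x, lag = 0), "positive")
})

test_that("validity-level table partitions the canonical patterns into 7 levels", {
  lv <- sort(unique(round(abs(canon$p_designed - 0.5), 3)))
  expect_equal(lv, c(0, 0.046, 0.273, 0.3, 0.406, 0.413, 0.437))
  d <- cached_session()
  tab <- rt_accuracy_by_validity(d, canon)
  expect_equal(tab$validity_level, lv)
  expect_equal(sum(tab$n_patterns), 14)
})

test_that("validity-level summaries match a hand computation on a toy set", {
  d <- toy_dataset()
  tab <- rt_accuracy_by_validity(d, canon)
  # pattern 1000 (level 0.413): trials 1 (correct) and 4 (incorrect);
  # patterns 1110 and 0001 share that level: trials 3 (incorrect), 6 (correct)
  r <- tab[tab$validity_level == 0.413, ]
  expect_equal(r$acc_mean, 2 / 4)
  expect_equal(r$rt_mean, mean(c(1.0, 0.9)))  # correct trials only
  # pattern 1100, level 0.406: trials 2 and 5, both choices match the outcome
  r2 <- tab[tab$validity_level == 0.406, ]
  expect_equal(r2$acc_mean, 1)
  expect_equal(r2$rt_mean, mean(c(1.5, 1.8)))
  all_rt <- rt_accuracy_by_validity(d, canon, rt_trials = "all")
  expect_equal(all_rt[all_rt$validity_level == 0.406, "rt_mean"],
               mean(c(1.5, 1.8)))
  expect_error(rt_accuracy_by_validity(transform(d, bits = "0000"), canon),
               "unknown pattern")
})

test_that("correct-RT table matches hand computation and flags empty cells", {
  tab <- correct_rt_by_ncues(toy_dataset())
  expect_equal(tab$n_cues, 1:3)
  # correct trials: 1 (1 cue, 1.0), 6 (1 cue, 0.9), 2 (2 cues, 1.5), 5 (2 cues, 1.8)
  expect_equal(tab$rt_mean[tab$n_cues == 1], round(mean(c(1.0, 0.9)), 3))
  expect_equal(tab$rt_mean[tab$n_cues == 2], round(mean(c(1.5, 1.8)), 3))
  expect_equal(tab$rt_sd[tab$n_cues == 2], round(sd(c(1.5, 1.8)), 3))
  expect_true(is.na(tab$rt_mean[tab$n_cues == 3]))  # no correct 3-cue trial
  all_wrong <- transform(toy_dataset(),
                         choice = ifelse(outcome == "positive",
                                         "negative", "positive"))
  expect_true(all(is.na(correct_rt_by_ncues(all_wrong)$rt_mean)))
  expect_error(correct_rt_by_ncues(toy_dataset()[0, ]), "non-empty")
})

test_that("lens model equation evaluates and is monotone in matching", {
  expect_equal(lens_model_equation(1, 1, 1, 0), 1)
  expect_equal(lens_model_equation(0.8, 0.9, 0.7, 0), 0.8 * 0.9 * 0.7)
  expect_equal(lens_model_equation(0.8, 0.9, 0.7, 0.1),
               0.504 + 0.1 * sqrt(0.19 * 0.51))
  g <- seq(-1, 1, by = 0.25)
  vals <- lens_model_equation(g, 0.9, 0.7, 0.1)
  expect_true(all(diff(vals) > 0))
  expect_error(lens_model_equation(1.2, 0.9, 0.7), "-1, 1")
  expect_error(lens_model_equation(0.5, 1.3, 0.7), "0, 1")
})

test_that("take-the-best follows the marginal-validity hierarchy", {
  expect_equal(take_the_best_predict("1000", canon), "positive")
  expect_equal(take_the_best_predict("0001", canon), "negative")
  expect_equal(take_the_best_predict("0100", canon), "positive")
  expect_equal(take_the_best_predict("0010", canon), "negative")
  # cues 1 and 4 tie in extremity and oppose: uniform guess
  set.seed(14)
  guesses <- replicate(200, take_the_best_predict("1001", canon))
  expect_gt(mean(guesses == "positive"), 0.35)
  expect_lt(mean(guesses == "positive"), 0.65)
  # strict tolerance breaks the tie in favour of cue 1
  expect_equal(take_the_best_predict("1001", canon, tol = 1e-6), "positive")
  expect_error(take_the_best_predict("0000", canon), "inadmissible")
})

test_that("take-the-best beats chance clearly on iid canonical trials", {
  preds <- setNames(vapply(canon$bits, function(b) {
    take_the_best_predict(b, canon, seed = 1)
  }, character(1)), canon$bits)
  guessing <- canon$bits[canon$bits %in% c("1001", "0110")]
  s <- make_session_sequence(canon, "iid", n_trials = 1e5, seed = 77)
  set.seed(78)
  pred <- preds[s$bits]
  gsel <- s$bits %in% guessing
  pred[gsel] <- ifelse(runif(sum(gsel)) < 0.5, "positive", "negative")
  expect_gt(mean(pred == s$outcome), 0.60)
})

test_that("posterior re-simulation defaults to 500 draws and matches recomputation", {
  expect_equal(formals(posterior_resimulate)$n_draws, 500)
  rec <- cached_session()[1:40, ]
  rec$condition <- "congruent"
  samples <- data.frame(v0 = 0, beta = 0.5, b_tau = 0.15,
                        sigma_v = 0, sigma_a = 0, sigma_tau = 0, loglik = 0)
  samples <- samples[rep(1, 10), ]
  trajs <- lapply(c(2, 4, 6, 8, 10), function(b) flat_trajectory(40, b, 1.5, 0.3))
  fit <- fake_fit(rec, samples, trajs)
  res <- posterior_resimulate(list(fit), canon, n_draws = 30, seed = 4)
  expect_setequal(c("participant", "draw", "trial", "bits", "n_cues",
                    "outcome", "choice", "rt", "condition"),
                  names(res$predicted))
  expect_equal(nrow(res$predicted), 30 * 40)
  expect_true(all(res$predicted$rt > 0.3 + 0.15 * res$predicted$n_cues))
  # summary matches brute-force recomputation from the predicted draws
  p <- res$predicted
  p$level <- round(abs(canon$p_designed[match(p$bits, canon$bits)] - 0.5), 3)
  for (lv in unique(p$level)) {
    d <- p[p$level == lv, ]
    per_draw_rt <- tapply(d$rt, d$draw, mean)
    per_draw_acc <- tapply(d$choice == d$outcome, d$draw, mean)
    row <- res$summary[res$summary$validity_level == lv, ]
    expect_equal(row$rt_median, median(per_draw_rt))
    expect_equal(row$acc_mean, mean(per_draw_acc))
    expect_equal(row$acc_sd, sd(per_draw_acc))
  }
})

test_that("re-simulated accuracy rises with validity when sensitivity is positive", {
  rec <- cached_session()
  rec$condition <- "congruent"
  samples <- data.frame(v0 = 0, beta = 0.5, b_tau = 0.15,
                        sigma_v = 0, sigma_a = 0, sigma_tau = 0, loglik = 0)
  samples <- samples[rep(1, 4), ]
  trajs <- list(flat_trajectory(246, 6, 1.5, 0.3),
                flat_trajectory(246, 6, 1.5, 0.3))
  fit <- fake_fit(rec, samples, trajs)
  res <- posterior_resimulate(list(fit), canon, n_draws = 40, seed = 9)
  s <- res$summary
  expect_gt(s$acc_mean[s$validity_level == 0.413],
            s$acc_mean[s$validity_level == 0.046])
  expect_error(posterior_resimulate(list(), canon), "non-empty")
})
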