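test_that("canonical environment satisfies its design invariants", {
  env <- canonical_environment()
  expect_s3_class(env, "mcpl_env")
  expect_equal(nrow(env), 14)
  expect_equal(sum(env$total), 246)
  expect_equal(sum(env$a), 123)
  expect_equal(sum(env$b), 123)
  expect_lt(abs(sum(env$p_pattern) - 1), 1e-3)
  expect_true(all(env$a + env$b == env$total))
  expect_true(all(env$n_cues %in% 1:3))
  # spot rows
  A <- env[env$label == "A", ]
  expect_equal(A$bits, "1110")
  expect_equal(A$total, 23L)
  expect_equal(A$p_pattern, 0.093)
  expect_equal(c(A$a, A$b), c(21L, 2L))
  expect_equal(A$p_designed, 0.913)
  F_ <- env[env$label == "F", ]
  expect_equal(F_$bits, "1001")
  expect_equal(F_$p_designed, 0.5)
  expect_equal(c(F_$a, F_$b), c(4L, 4L))
})

test_that("admissible_patterns enumerates all partial patterns", {
  expect_length(admissible_patterns(4), 14)
  expect_setequal(admissible_patterns(2), c("01", "10"))
  expect_length(admissible_patterns(5), 30)
  expect_setequal(admissible_patterns(4), canonical_environment()$bits)
  expect_error(admissible_patterns(1), "must be a single integer >= 2")
})

test_that("validity regressor implements signed and absolute codings", {
  expect_equal(validity_regressor("1001", canon), 0)
  expect_equal(validity_regressor("1110", canon), 0.413)
  expect_equal(validity_regressor("1011", canon, "absolute"), 0.273)
  expect_error(validity_regressor("0000", canon), "unknown pattern")
  # complementary rows with designed probabilities summing to 1 average to 0
  pairs <- list(c("A", "N"), c("G", "H"), c("E", "J"), c("F", "I"))
  for (p in pairs) {
    bits <- canon$bits[match(p, canon$label)]
    expect_equal(mean(validity_regressor(bits, canon)), 0, tolerance = 1e-12)
  }
})

test_that("marginal cue validities recompute the designed 0.8/0.6/0.4/0.2 ordering", {
  m <- vapply(1:4, function(j) marginal_cue_validity(canon, j), numeric(1))
  expect_equal(m[1], 99 / 123, tolerance = 1e-12)
  expect_equal(m[4], 25 / 123, tolerance = 1e-12)
  expect_true(all(abs(m - c(0.8, 0.6, 0.4, 0.2)) < 0.01))
  expect_true(all(diff(m) < 0))
  expect_error(marginal_cue_validity(canon, 5), "cue_index")
})

test_that("exact-counts sequences reproduce the designed session exactly", {
  s <- make_session_sequence(canon, "exact_counts", seed = 1)
  expect_equal(nrow(s), 246)
  tallies <- table(s$bits)
  expect_equal(as.integer(tallies[canon$bits]), canon$total)
  expect_equal(sum(s$outcome == "positive"), 123)
  # per-pattern outcome counts match the realized a/b columns
  for (i in seq_len(nrow(canon))) {
    sel <- s$bits == canon$bits[i]
    expect_equal(sum(s$outcome[sel] == "positive"), canon$a[i])
  }
  # identical multisets across seeds, identical sequence for the same seed
  s2 <- make_session_sequence(canon, "exact_counts", seed = 2)
  expect_equal(sort(paste(s$bits, s$outcome)), sort(paste(s2$bits, s2$outcome)))
  expect_false(identical(s$bits, s2$bits))
  expect_identical(s, make_session_sequence(canon, "exact_counts", seed = 1))
  expect_error(make_session_sequence(canon, "exact_counts", n_trials = 100),
               "requires n_trials")
})

test_that("iid sequences follow the designed conditional probabilities", {
  s <- make_session_sequence(canon, "iid", n_trials = 1e5, seed = 42)
  sel <- s$bits == "1110"
  phat <- mean(s$outcome[sel] == "positive")
  se <- sqrt(0.913 * 0.087 / sum(sel))
  expect_lt(abs(phat - 0.913), 3 * se)
  # pattern frequencies track p_pattern
  freq <- as.numeric(table(s$bits)[canon$bits]) / 1e5
  expect_true(all(abs(freq - canon$p_pattern) < 0.01))
})

test_that("environment tables round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_environment(canon, path)
  env2 <- read_environment(path)
  expect_equal(as.data.frame(env2), as.data.frame(canon))
})
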