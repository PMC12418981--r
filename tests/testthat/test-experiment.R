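test_that("expected ratings hit the anchors and interpolate in log space", {
  expect_equal(expected_rating(0.0035938), 10, tolerance = 1e-12)
  expect_equal(expected_rating(7.7426), 80, tolerance = 1e-12)
  expect_equal(expected_rating(sqrt(0.0035938 * 7.7426)), 45, tolerance = 1e-9)
  v <- measurement_viscosities()
  expect_length(v, 10)
  expect_true(all(diff(expected_rating(v)) > 0))   # strictly increasing
  expect_equal(v[1], 0.0020771)
  expect_equal(v[10], 40.103)
  expect_error(expected_rating(-1), "positive")
})

test_that("scale expansion widens the touched bound only, repeatably", {
  s <- rating_scale()
  s1 <- apply_scale_expansion(s, 0)
  expect_equal(s1$lower, -10)
  expect_equal(s1$upper, 100)
  expect_equal(apply_scale_expansion(s, 50)$lower, 0)  # interior: unchanged
  s2 <- apply_scale_expansion(s1, -10)
  expect_equal(s2$lower, -20)
  s3 <- apply_scale_expansion(s, 100)
  expect_equal(s3$upper, 110)
  expect_error(apply_scale_expansion(s, 101), "outside")
})

test_that("rating errors are element-wise actual minus expected", {
  tr <- data.frame(actual = c(60, 45, 30), expected = c(45, 45, 40),
                   aborted = c(FALSE, FALSE, TRUE))
  expect_equal(rating_error(tr), c(15, 0, NA))
  expect_equal(rating_error(tr[1, ]), 15)
})

test_that("Bonferroni alpha divides the family rate", {
  expect_equal(bonferroni_alpha(6), 0.05 / 6)
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_equal(bonferroni_alpha(10), 0.005)
  expect_error(bonferroni_alpha(0), "at least 1")
})

test_that("the moving window yields n - w + 1 values, matching a direct loop", {
  # hand-built 2-block toy with a known within-block reordering
  mk_block <- function(b, order, errs) {
    data.frame(block = b, stimulus_id = order,
               expected = 50, actual = 50 + errs, aborted = FALSE)
  }
  t1 <- mk_block(1, c(3, 1, 2, 5, 4, 6, 8, 7, 10, 9), 1:10)
  t2 <- mk_block(2, c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 11:20)
  toy <- rbind(t1, t2)
  got <- moving_window_rms(toy, w = 10)
  expect_length(got, 11)
  # direct loop oracle on the manually reordered error sequence
  e2 <- (11:20)[match(t1$stimulus_id, t2$stimulus_id)]
  e <- c(1:10, e2)
  want <- sapply(1:11, function(i) sqrt(mean(e[i:(i + 9)]^2)))
  expect_equal(got, want)

  # constant errors -> every window RMS equals |c|
  t2c <- t2; t2c$actual <- t2c$expected - 3
  t1c <- t1; t1c$actual <- t1c$expected - 3
  expect_equal(moving_window_rms(rbind(t1c, t2c), w = 10), rep(3, 11))

  # full design: 50 trials, w = 10 -> 41 windows
  tr <- simulate_observer(observer_model(), "pflow", 11)
  expect_length(moving_window_rms(tr), 41)

  # structural error: a block missing a stimulus
  broken <- toy; broken$stimulus_id[12] <- 1
  expect_error(moving_window_rms(broken), "exactly once")
})

test_that("participant summaries use blocks 3-5 and the sample SD", {
  base <- expand.grid(block = 1:5, stimulus_id = 1:10)
  base$expected <- 50; base$rt <- 5; base$aborted <- FALSE
  base$actual <- 50
  base$actual[base$stimulus_id == 1] <- 50 +
    c(9, 9, 0, 3, 6)[base$block[base$stimulus_id == 1]]
  s <- summarize_participant(base)
  expect_equal(s$mean_error[s$stimulus_id == 1], 3)   # mean(0, 3, 6)
  expect_equal(s$sd_error[s$stimulus_id == 1], 3)     # sample SD, n - 1
  expect_equal(s$n_reps, rep(3, 10))
  # perturbing the first two blocks changes nothing
  pert <- base
  pert$actual[pert$block <= 2] <- pert$actual[pert$block <= 2] + 100
  expect_equal(summarize_participant(pert), s)
  # aborted retained trials reduce repetitions and flag short stimuli
  ab <- base
  ab$aborted[ab$block %in% 3:4 & ab$stimulus_id == 2] <- TRUE
  s2 <- summarize_participant(ab)
  expect_equal(s2$n_reps[s2$stimulus_id == 2], 1)
  expect_true(s2$flagged[s2$stimulus_id == 2])
  expect_true(is.na(s2$sd_error[s2$stimulus_id == 2]))
})

test_that("check variables follow their printed definitions", {
  session <- data.frame(
    phase = c("training", "training", "practice", "practice", "practice",
              "measurement", "measurement"),
    rt = c(5, 5, 6, 6, 6, 61, 10),
    actual = c(12, 79, 53, 54, 50, NA, 48),
    expected = c(10, 80, 50, 50, 50, 50, 50),
    aborted = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  cv <- compute_check_variables(session)
  expect_equal(cv$n_aborted, 1)
  expect_equal(cv$n_training_trials, 2)     # both anchors placed first try
  expect_equal(cv$practice_rms, sqrt(25 / 3))  # errors 3, 4, 0
})

test_that("simulated observers are deterministic, unbiased in the noise-free
           limit, and match their nominal SD", {
  m0 <- observer_model(sigma_by_algorithm = c(original = 1e-9, pflow = 1e-9,
                                              lk = 1e-9))
  tr <- simulate_observer(m0, "pflow", 5)
  ok <- !tr$aborted
  expect_equal(tr$actual[ok], pflowr:::clamp(tr$expected[ok], 0, 100),
               tolerance = 1e-6)

  t1 <- simulate_observer(observer_model(), "lk", 21)
  t2 <- simulate_observer(observer_model(), "lk", 21)
  expect_identical(t1, t2)

  # ~1,000 repeated ratings of mid-scale stimuli (where the bounds never
  # clip): the sample SD lies in the chi-square interval for sigma = 8
  m <- observer_model()
  errs <- unlist(lapply(1:13, function(i) {
    tr <- simulate_observer(m, "pflow", 1000 + i)
    mid <- tr$stimulus_id %in% 4:7 & !tr$aborted
    tr$actual[mid] - tr$expected[mid]
  }))
  errs <- errs[seq_len(min(1000, length(errs)))]
  expect_gt(stats::sd(errs), 7.3)
  expect_lt(stats::sd(errs), 8.7)
})

test_that("sessions carry training, practice and measurement phases", {
  ses <- simulate_session(observer_model(), "original", 13)
  expect_setequal(unique(ses$phase), c("training", "practice", "measurement"))
  expect_equal(sum(ses$phase == "measurement"), 50)
  expect_gte(sum(ses$phase == "training"), 2)
  expect_lte(sum(ses$phase == "training"), 6)
  expect_equal(sum(ses$phase == "practice"), 3)
  cv <- compute_check_variables(ses)
  expect_true(is.finite(cv$practice_rms))
})

test_that("fast experiment summaries equal the per-participant operation", {
  ex <- simulate_experiment(observer_model(), n_per_group = 3, rng_seed = 17)
  fast <- pflowr:::summarize_trials(ex)
  for (p in unique(ex$participant)) {
    slow <- summarize_participant(ex[ex$participant == p, ])
    fi <- fast[fast$participant == p, ]
    fi <- fi[order(as.integer(fi$stimulus_id)), ]
    expect_equal(fi$mean_error, slow$mean_error, tolerance = 1e-12)
    expect_equal(fi$sd_error, slow$sd_error, tolerance = 1e-12)
    expect_equal(fi$mean_rt, slow$mean_rt, tolerance = 1e-12)
  }
})
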