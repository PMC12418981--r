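#' Synthetic observer model
#'
#' A stand-in for human raters with the structure the experiment is
#' designed to detect: all algorithms share the same accuracy (a common
#' additive bias, default 0) but differ in precision (the trial-to-trial
#' rating-error SD) and in response time. Default SDs follow the ordering
#' the display quality imposes — original movies easiest (SD 6), p-flow
#' next (8), Lucas-Kanade hardest (11) — and the LK condition carries a
#' log-RT location shift.
#'
#' @param bias Additive rating bias (rating units), common to algorithms.
#' @param sigma_by_algorithm Named vector of rating-error SDs (rating
#'   units) for `original`, `pflow`, `lk`; all `> 0`.
#' @param rt_meanlog,rt_sdlog Log-normal RT parameters (log seconds).
#' @param rt_shift_by_algorithm Named vector of additive log-RT location
#'   shifts per algorithm.
#' @param sigma_training SD of slider placement around the instructed
#'   anchor value during training trials.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(bias = 0,
                           sigma_by_algorithm = c(original = 6, pflow = 8,
                                                  lk = 11),
                           rt_meanlog = log(8), rt_sdlog = 0.4,
                           rt_shift_by_algorithm = c(original = 0, pflow = 0,
                                                     lk = 0.15),
                           sigma_training = 3) {
  stopifnot(all(sigma_by_algorithm > 0), sigma_training > 0)
  structure(list(bias = bias, sigma_by_algorithm = sigma_by_algorithm,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_shift_by_algorithm = rt_shift_by_algorithm,
                 sigma_training = sigma_training),
            class = "observer_model")
}

#' Pseudorandom measurement schedule
#'
#' Five blocks of ten trials; each block presents each of the ten
#' measurement stimuli exactly once in a per-block random order.
#'
#' @param rng_seed Integer seed.
#' @param n_blocks,stimuli Design constants; defaults are the standard
#'   design (5 blocks, the 10 measurement viscosities).
#' @return Data frame with `block`, `trial_index`, `stimulus_id`,
#'   `viscosity`.
#' @export
measurement_schedule <- function(rng_seed, n_blocks = 5,
                                 stimuli = measurement_viscosities()) {
  s <- length(stimuli)
  ord <- with_seed(rng_seed,
                   lapply(seq_len(n_blocks), function(b) sample.int(s)))
  do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    data.frame(block = b, trial_index = (b - 1) * s + seq_len(s),
               stimulus_id = ord[[b]], viscosity = stimuli[ord[[b]]])
  }))
}

#' Simulate one observer's measurement phase
#'
#' Each trial draws `actual = expected + bias + N(0, sigma_alg)`, clips it
#' to the current scale bounds, records it, and applies scale expansion
#' when the recorded rating sits on a bound. RTs are log-normal with the
#' algorithm's location shift; a trial whose RT reaches 60 s is aborted
#' (no rating). Deterministic under the seed.
#'
#' @param model An [observer_model()].
#' @param algorithm `"original"`, `"pflow"` or `"lk"`.
#' @param rng_seed Integer seed.
#' @param scale Starting [rating_scale()].
#' @param participant_id Identifier copied into the records.
#' @return Data frame of 50 trial records: `participant`, `algorithm`,
#'   `block`, `trial_index`, `stimulus_id`, `viscosity`, `expected`,
#'   `actual`, `rt`, `aborted`, plus attribute `"expanded"` (did the scale
#'   ever widen) and `"scale"` (final bounds).
#' @export
simulate_observer <- function(model, algorithm = "pflow", rng_seed = 1L,
                              scale = rating_scale(), participant_id = "p1") {
  stopifnot(inherits(model, "observer_model"),
            algorithm %in% names(model$sigma_by_algorithm))
  sched <- measurement_schedule(rng_seed)
  n <- nrow(sched)
  sigma <- model$sigma_by_algorithm[[algorithm]]
  shift <- model$rt_shift_by_algorithm[[algorithm]]
  draws <- with_seed(rng_seed + 1L, list(
    noise = stats::rnorm(n, 0, sigma),
    logrt = stats::rnorm(n, model$rt_meanlog + shift, model$rt_sdlog)))
  expected <- expected_rating(sched$viscosity, scale)
  actual <- numeric(n); aborted <- logical(n)
  rt <- pmin(exp(draws$logrt), 60)
  expanded <- FALSE
  for (i in seq_len(n)) {
    if (rt[i] >= 60) {                      # aborted: no rating recorded
      aborted[i] <- TRUE
      actual[i] <- NA_real_
      next
    }
    r <- clamp(expected[i] + model$bias + draws$noise[i],
               scale$lower, scale$upper)
    actual[i] <- r
    new_scale <- apply_scale_expansion(scale, r)
    if (new_scale$lower != scale$lower || new_scale$upper != scale$upper) {
      expanded <- TRUE
      scale <- new_scale
    }
  }
  out <- data.frame(participant = participant_id, algorithm = algorithm,
                    block = sched$block, trial_index = sched$trial_index,
                    stimulus_id = sched$stimulus_id,
                    viscosity = sched$viscosity,
                    expected = expected, actual = actual, rt = rt,
                    aborted = aborted, stringsAsFactors = FALSE)
  attr(out, "expanded") <- expanded
  attr(out, "scale") <- scale
  out
}

#' Simulate a full session (training, practice, measurement)
#'
#' Training: up to three attempts per anchor to place the slider within
#' the acceptance bands ([6, 14] for the low anchor at 10, [76, 84] for
#' the high anchor at 80). Practice: three rated trials drawn from the
#' practice viscosity range with feedback (feedback itself is not
#' modelled; only the ratings matter for the check variables). Then the
#' 50 measurement trials of [simulate_observer()].
#'
#' @inheritParams simulate_observer
#' @return Data frame of all phases with a `phase` column; measurement
#'   attributes (`expanded`, `scale`) are preserved.
#' @export
simulate_session <- function(model, algorithm = "pflow", rng_seed = 1L,
                             participant_id = "p1") {
  bands <- list(c(6, 14), c(76, 84)); targets <- c(10, 80)
  tr <- with_seed(rng_seed + 2L, {
    rows <- list()
    for (k in 1:2) {
      for (attempt in 1:3) {
        resp <- targets[k] + stats::rnorm(1, 0, model$sigma_training)
        rows[[length(rows) + 1L]] <- data.frame(
          phase = "training", block = 0L, trial_index = 0L,
          stimulus_id = NA_integer_, viscosity = NA_real_,
          expected = targets[k], actual = resp,
          rt = exp(stats::rnorm(1, model$rt_meanlog, model$rt_sdlog)),
          aborted = FALSE)
        if (resp >= bands[[k]][1] && resp <= bands[[k]][2]) break
      }
    }
    do.call(rbind, rows)
  })
  practice_visc <- with_seed(rng_seed + 3L,
    exp(stats::runif(3, log(0.0035938), log(7.7426))))
  sigma <- model$sigma_by_algorithm[[algorithm]]
  pr_expected <- expected_rating(practice_visc)
  pr <- with_seed(rng_seed + 4L, data.frame(
    phase = "practice", block = 0L, trial_index = seq_len(3),
    stimulus_id = NA_integer_, viscosity = practice_visc,
    expected = pr_expected,
    actual = pr_expected + model$bias + stats::rnorm(3, 0, sigma),
    rt = exp(stats::rnorm(3, model$rt_meanlog, model$rt_sdlog)),
    aborted = FALSE))
  meas <- simulate_observer(model, algorithm, rng_seed, participant_id = participant_id)
  meas_phase <- cbind(phase = "measurement",
                      meas[setdiff(names(meas), c("participant", "algorithm"))])
  out <- rbind(tr, pr, meas_phase)
  out$participant <- participant_id
  out$algorithm <- algorithm
  attr(out, "expanded") <- attr(meas, "expanded")
  attr(out, "scale") <- attr(meas, "scale")
  out
}

#' Simulate a whole between-group experiment
#'
#' @param model An [observer_model()].
#' @param n_per_group Participants per algorithm group.
#' @param rng_seed Master seed; per-participant seeds are derived from it.
#' @param algorithms Group labels.
#' @return Data frame of all participants' measurement trials with an
#'   `expanded` logical column (per participant).
#' @export
simulate_experiment <- function(model, n_per_group = 60, rng_seed = 1L,
                                algorithms = c("original", "pflow", "lk")) {
  seeds <- derive_seeds(rng_seed, n_per_group * length(algorithms))
  out <- vector("list", length(seeds))
  k <- 0L
  for (alg in algorithms) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      pid <- sprintf("%s_%03d", alg, i)
      tr <- simulate_observer(model, alg, seeds[k], participant_id = pid)
      tr$expanded <- attr(tr, "expanded")
      out[[k]] <- tr
    }
  }
  do.call(rbind, out)
}

#' Analyze a simulated (or recorded) experiment
#'
#' Per-participant, per-stimulus summaries (blocks 3-5) feed three
#' split-plot ANOVAs — mean rating error, SD of rating error, mean RT —
#' with the algorithm as the between factor and the stimulus as the within
#' factor, Tukey post hoc on the algorithm, and the Bonferroni-corrected
#' alpha for the six-test family.
#'
#' @param trials Measurement trials as from [simulate_experiment()].
#' @param exclude_expanded Drop participants whose rating scale was ever
#'   expanded (the experiment's own exclusion rule)? Default `FALSE`: with a
#'   constant-SD synthetic observer, extreme stimuli hit the scale bounds
#'   far more often than human raters do, and exclusion would gut the
#'   sample. Both filters are exposed.
#' @return List with `anova` (named list of [mixed_anova()] results for
#'   `mean_error`, `sd_error`, `mean_rt`), `alpha` (0.05/6), `summaries`
#'   (the participant x stimulus table), and `n_participants`.
#' @export
analyze_experiment <- function(trials, exclude_expanded = FALSE) {
  if (exclude_expanded && !is.null(trials$expanded)) {
    trials <- trials[!trials$expanded, , drop = FALSE]
  }
  summaries <- summarize_trials(trials)
  mk <- function(col) {
    d <- data.frame(participant = summaries$participant,
                    group = summaries$algorithm,
                    stimulus = summaries$stimulus_id,
                    value = summaries[[col]])
    mixed_anova(d)
  }
  list(anova = list(mean_error = mk("mean_error"),
                    sd_error = mk("sd_error"),
                    mean_rt = mk("mean_rt")),
       alpha = bonferroni_alpha(6),
       summaries = summaries,
       n_participants = length(unique(summaries$participant)))
}

# Vectorized participant x stimulus summaries over a whole trial table;
# agrees with summarize_participant() applied per participant.
summarize_trials <- function(trials, exclude_blocks = 2) {
  keep <- trials$block > exclude_blocks
  if (!is.null(trials$aborted)) keep <- keep & !trials$aborted
  d <- trials[keep, , drop = FALSE]
  e <- d$actual - d$expected
  key <- paste(d$participant, d$stimulus_id, sep = "\r")
  uk <- sort(unique(key))
  n <- as.vector(table(key)[uk])
  s1 <- rowsum(e, key)[uk, 1]
  s2 <- rowsum(e^2, key)[uk, 1]
  srt <- rowsum(d$rt, key)[uk, 1]
  mean_error <- s1 / n
  sd_error <- ifelse(n >= 2, sqrt(pmax(s2 - n * mean_error^2, 0) / (n - 1)),
                     NA_real_)
  parts <- sub("\r.*$", "", uk)
  alg <- trials$algorithm[match(parts, trials$participant)]
  data.frame(participant = parts,
             stimulus_id = sub("^.*\r", "", uk),
             algorithm = alg,
             mean_error = mean_error, sd_error = sd_error,
             mean_rt = srt / n, n_reps = n, flagged = n < 2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parameter-recovery study for the observer pipeline
#'
#' Repeatedly simulates the full experiment under the observer model (equal
#' biases, algorithm-dependent precision) and records, per replicate,
#' whether each ANOVA detects an algorithm effect at the Bonferroni alpha
#' and whether the Tukey-ordered group means of the SD of the rating error
#' recover `original < pflow < lk`. This is the qualitative dissociation
#' the experiment design is meant to resolve: a precision effect without an
#' accuracy effect.
#'
#' @param n_reps Number of replicates.
#' @param n_per_group Participants per algorithm per replicate.
#' @param rng_seed Master seed.
#' @param model An [observer_model()].
#' @return List with rejection rates `power_sd`, `rate_mean`, `rate_rt`,
#'   the Tukey-ordering rate among SD-detecting replicates
#'   (`ordering_rate`), `alpha`, and `n_reps`.
#' @export
observer_recovery <- function(n_reps = 200, n_per_group = 60, rng_seed = 1L,
                              model = observer_model()) {
  seeds <- derive_seeds(rng_seed, n_reps)
  alpha <- bonferroni_alpha(6)
  rej <- matrix(FALSE, n_reps, 3,
                dimnames = list(NULL, c("mean_error", "sd_error", "mean_rt")))
  ordered_ok <- rep(NA, n_reps)
  for (r in seq_len(n_reps)) {
    trials <- simulate_experiment(model, n_per_group, seeds[r])
    an <- analyze_experiment(trials)
    for (dv in colnames(rej)) {
      tb <- an$anova[[dv]]$table
      rej[r, dv] <- tb$p[tb$effect == "group"] < alpha
    }
    if (rej[r, "sd_error"]) {
      gm <- an$anova[["sd_error"]]$group_means
      m <- gm$mean[match(c("original", "pflow", "lk"), gm$group)]
      ordered_ok[r] <- !is.unsorted(m, strictly = TRUE)
    }
  }
  list(power_sd = mean(rej[, "sd_error"]),
       rate_mean = mean(rej[, "mean_error"]),
       rate_rt = mean(rej[, "mean_rt"]),
       ordering_rate = mean(ordered_ok[rej[, "sd_error"]]),
       alpha = alpha, n_reps = n_reps)
}
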