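#' Anchored viscosity rating scale
#'
#' The 101-point rating scale from 0 to 100, anchored during training at
#' rating 10 for the least viscous and rating 80 for the most viscous
#' baseline liquid (0.0035938 and 7.7426 Pa.s). The scale is flexible: a
#' rating at either bound widens that bound by `expansion_step`, without
#' limit, so observers are never forced to round extreme impressions.
#'
#' @param lower,upper Current scale bounds (rating units).
#' @param anchor_low,anchor_high Length-2 `(viscosity Pa.s, rating)` pairs.
#' @param expansion_step Widening step in rating units.
#' @return An object of class `rating_scale`.
#' @export
rating_scale <- function(lower = 0, upper = 100,
                         anchor_low = c(0.0035938, 10),
                         anchor_high = c(7.7426, 80),
                         expansion_step = 10) {
  stopifnot(lower < upper, anchor_low[1] > 0, anchor_high[1] > anchor_low[1],
            expansion_step > 0)
  structure(list(lower = lower, upper = upper,
                 anchor_low = anchor_low, anchor_high = anchor_high,
                 expansion_step = expansion_step),
            class = "rating_scale")
}

#' Expected rating for a simulated viscosity
#'
#' The expected rating is linear in log viscosity through the two training
#' anchors: `r = 10 + 70 * (log v - log v_lo) / (log v_hi - log v_lo)`.
#' Values outside `[10, 80]` are permitted — the measurement set spans a
#' wider viscosity range than the anchors and the anchor line is
#' extrapolated rather than re-anchored.
#'
#' @param viscosity Viscosity in Pa.s (`> 0`), vectorized.
#' @param scale A [rating_scale()].
#' @return Expected rating(s) in rating units; strictly increasing in
#'   viscosity.
#' @export
#' @examples
#' expected_rating(0.0035938)  # 10, the low anchor
#' expected_rating(7.7426)     # 80, the high anchor
expected_rating <- function(viscosity, scale = rating_scale()) {
  if (any(!is.finite(viscosity)) || any(viscosity <= 0)) {
    stop("viscosity must be positive and finite")
  }
  lo <- scale$anchor_low; hi <- scale$anchor_high
  lo[2] + (hi[2] - lo[2]) * (log(viscosity) - log(lo[1])) /
    (log(hi[1]) - log(lo[1]))
}

#' Expand the scale after an extreme rating
#'
#' If the recorded rating sits exactly on the current lower (upper) bound,
#' that bound is widened by `expansion_step`; interior ratings leave the
#' scale unchanged. Repeatable without limit.
#'
#' @param scale A [rating_scale()].
#' @param rating The recorded rating; must lie within the current bounds.
#' @return The (possibly widened) [rating_scale()].
#' @export
#' @examples
#' s <- apply_scale_expansion(rating_scale(), 0)
#' s$lower  # -10
apply_scale_expansion <- function(scale, rating) {
  if (rating < scale$lower || rating > scale$upper) {
    stop("rating outside the current scale bounds")
  }
  if (rating == scale$lower) scale$lower <- scale$lower - scale$expansion_step
  if (rating == scale$upper) scale$upper <- scale$upper + scale$expansion_step
  scale
}

#' The measurement-set viscosities
#'
#' Ten simulated viscosities spanning 0.0020771 to 40.103 Pa.s, evenly
#' spaced in log viscosity (the source stimulus set is evenly spaced in
#' rank over a log-spanning set; only its endpoints are known, so the
#' interior values are log-interpolated here).
#'
#' @return Numeric vector of 10 viscosities (Pa.s), increasing.
#' @export
measurement_viscosities <- function() {
  exp(seq(log(0.0020771), log(40.103), length.out = 10))
}

#' Rating error of trials
#'
#' The per-trial error `e = actual - expected`. Aborted trials carry no
#' rating and are excluded (their error is `NA`).
#'
#' @param trials Data frame with columns `actual`, `expected` and
#'   optionally `aborted`.
#' @return Numeric vector of errors, `NA` for aborted trials.
#' @export
rating_error <- function(trials) {
  e <- trials$actual - trials$expected
  if (!is.null(trials$aborted)) e[trials$aborted] <- NA_real_
  e
}

#' Bonferroni-corrected alpha
#'
#' @param n_tests Number of tests in the family (`>= 1`).
#' @param family_alpha Family-wise error rate.
#' @return `family_alpha / n_tests` (0.00833... for the six-test family at
#'   0.05).
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  family_alpha / n_tests
}

#' Moving-window RMS of the rating error
#'
#' Diagnostic time series of rating performance: trials in blocks 2 onward
#' are reordered within each block to match the stimulus order of the first
#' block, and the RMS rating error is computed over every contiguous window
#' of `w` trials (so each window spans all stimuli once). For the full
#' 5-block, 50-trial design with `w = 10` this yields 41 values.
#'
#' @param trials One participant's measurement trials, ordered by block and
#'   trial, with columns `block`, `stimulus_id`, `actual`, `expected` and
#'   optionally `aborted`.
#' @param w Window size in trials.
#' @return Numeric vector of `n_trials - w + 1` RMS values.
#' @export
moving_window_rms <- function(trials, w = 10) {
  blocks <- sort(unique(trials$block))
  per_block <- split(seq_len(nrow(trials)), trials$block)
  first <- trials$stimulus_id[per_block[[1]]]
  if (anyDuplicated(first)) stop("block 1 repeats a stimulus")
  reordered <- integer(0)
  for (b in blocks) {
    idx <- per_block[[as.character(b)]]
    sid <- trials$stimulus_id[idx]
    if (!setequal(sid, first) || anyDuplicated(sid)) {
      stop("block ", b, " does not contain each stimulus exactly once")
    }
    reordered <- c(reordered, idx[match(first, sid)])
  }
  e <- rating_error(trials)[reordered]
  n <- length(e)
  if (n < w) stop("fewer trials than the window size")
  vapply(seq_len(n - w + 1), function(i) {
    sqrt(mean(e[i:(i + w - 1)]^2, na.rm = TRUE))
  }, numeric(1))
}

#' Per-stimulus summaries for one participant
#'
#' Following the experiment's analysis rule, the first `exclude_blocks` blocks
#' are discarded (performance stabilizes after two blocks) and each
#' stimulus is summarized over its retained repetitions: mean rating error,
#' sample standard deviation (n-1 denominator), and mean response time.
#' Aborted trials are dropped first; a stimulus with fewer than two
#' retained repetitions gets `NA` SD and is flagged.
#'
#' @param trials One participant's measurement trials with columns `block`,
#'   `stimulus_id`, `actual`, `expected`, `rt`, `aborted`.
#' @param exclude_blocks Number of leading blocks to discard (default 2).
#' @return Data frame with one row per stimulus: `stimulus_id`,
#'   `mean_error`, `sd_error`, `mean_rt`, `n_reps`, `flagged`.
#' @export
summarize_participant <- function(trials, exclude_blocks = 2) {
  keep <- trials$block > exclude_blocks
  if (!is.null(trials$aborted)) keep <- keep & !trials$aborted
  d <- trials[keep, , drop = FALSE]
  e <- d$actual - d$expected
  ids <- sort(unique(trials$stimulus_id))
  out <- lapply(ids, function(s) {
    i <- d$stimulus_id == s
    n <- sum(i)
    data.frame(stimulus_id = s,
               mean_error = if (n > 0) mean(e[i]) else NA_real_,
               sd_error = if (n >= 2) stats::sd(e[i]) else NA_real_,
               mean_rt = if (n > 0) mean(d$rt[i]) else NA_real_,
               n_reps = n,
               flagged = n < 2)
  })
  do.call(rbind, out)
}

#' Session check variables
#'
#' Three per-participant sanity measures used to rule out extraneous
#' factors: the number of aborted trials (response time of 60 s or more),
#' the number of training trials needed to place the anchors as requested,
#' and the RMS rating error over the practice trials.
#'
#' @param session Data frame of all of one participant's trials with
#'   columns `phase` (`"training"`, `"practice"`, `"measurement"`), `rt`,
#'   `actual`, `expected`, and `aborted`.
#' @return List with `n_aborted`, `n_training_trials`, `practice_rms`.
#' @export
compute_check_variables <- function(session) {
  aborted <- if (!is.null(session$aborted)) session$aborted else
    session$rt >= 60
  tr <- session$phase == "training"
  pr <- session$phase == "practice" & !aborted
  e <- session$actual[pr] - session$expected[pr]
  list(n_aborted = sum(aborted),
       n_training_trials = sum(tr),
       practice_rms = if (any(pr)) sqrt(mean(e^2)) else NA_real_)
}
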