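# Independent oracles used across the suite; deliberately written as plain
# loops / direct formulas, never sharing code with the implementation.

# Subpixel shift estimate by phase correlation (integer peak + parabolic
# refinement along x).
phase_corr_shift_x <- function(f1, f2) {
  F1 <- stats::fft(f1); F2 <- stats::fft(f2)
  r <- F2 * Conj(F1)
  r <- r / pmax(Mod(r), 1e-12)
  c2 <- Re(stats::fft(r, inverse = TRUE)) / length(r)
  pk <- which(c2 == max(c2), arr.ind = TRUE)[1, ]
  w <- ncol(f1)
  xi <- pk[2]
  xm <- ((xi - 2) %% w) + 1; xp <- (xi %% w) + 1
  y <- pk[1]
  a <- c2[y, xm]; b <- c2[y, xi]; cc <- c2[y, xp]
  denom <- (a - 2 * b + cc)
  frac <- if (abs(denom) > 1e-12) 0.5 * (a - cc) / denom else 0
  sh <- (xi - 1) + frac
  if (sh > w / 2) sh <- sh - w
  sh
}

# Brute-force split-plot sums of squares by explicit nested loops over
# group/participant/stimulus means.
brute_force_split_plot <- function(d) {
  ps <- unique(d$participant); gs <- unique(d$group); ss <- unique(d$stimulus)
  grand <- mean(d$value)
  ss_total <- sum((d$value - grand)^2)
  ss_a <- 0
  for (g in gs) {
    yg <- d$value[d$group == g]
    ss_a <- ss_a + length(yg) * (mean(yg) - grand)^2
  }
  ss_between <- 0
  for (p in ps) {
    yp <- d$value[d$participant == p]
    ss_between <- ss_between + length(yp) * (mean(yp) - grand)^2
  }
  ss_subj <- ss_between - ss_a
  ss_s <- 0
  for (s in ss) {
    ys <- d$value[d$stimulus == s]
    ss_s <- ss_s + length(ys) * (mean(ys) - grand)^2
  }
  ss_cells <- 0
  for (g in gs) for (s in ss) {
    yc <- d$value[d$group == g & d$stimulus == s]
    ss_cells <- ss_cells + length(yc) * (mean(yc) - grand)^2
  }
  ss_as <- ss_cells - ss_a - ss_s
  ss_werr <- ss_total - ss_cells - ss_subj
  a <- length(gs); s_n <- length(ss); N <- length(ps)
  list(ss_a = ss_a, ss_subj = ss_subj, ss_s = ss_s, ss_as = ss_as,
       ss_werr = ss_werr, ss_total = ss_total,
       f_a = (ss_a / (a - 1)) / (ss_subj / (N - a)),
       f_s = (ss_s / (s_n - 1)) / (ss_werr / ((N - a) * (s_n - 1))),
       f_as = (ss_as / ((a - 1) * (s_n - 1))) /
         (ss_werr / ((N - a) * (s_n - 1))))
}

# Small grid of well-separated synthetic tracks for render round trips.
separated_tracks <- function(n = 20, T = 1, jitter_seed = 1) {
  set.seed(jitter_seed)
  gx <- rep(seq(8, 56, by = 12), 5)[seq_len(n)] + runif(n, -1, 1)
  gy <- rep(seq(8, 56, by = 12), each = 5)[seq_len(n)] + runif(n, -1, 1)
  df <- do.call(rbind, lapply(seq_len(T), function(t) {
    data.frame(track_id = seq_len(n), frame = t, x = gx, y = gy,
               score = 1, algorithm = "pflow")
  }))
  class(df) <- c("dot_tracks", "data.frame")
  df
}

# Balanced split-plot toy table with optional group/stimulus effects.
toy_anova_table <- function(seed = 1, n_per_group = 3, groups = c("A", "B"),
                            n_stim = 3, g_eff = 0, s_eff = 0, subj_sd = 1,
                            noise_sd = 1) {
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (gi in seq_along(groups)) {
    for (p in seq_len(n_per_group)) {
      pid <- pid + 1
      u <- rnorm(1, 0, subj_sd)
      for (s in seq_len(n_stim)) {
        rows[[length(rows) + 1]] <- data.frame(
          participant = sprintf("p%02d", pid), group = groups[gi],
          stimulus = sprintf("s%d", s),
          value = u + g_eff * (gi - 1) + s_eff * s + rnorm(1, 0, noise_sd))
      }
    }
  }
  do.call(rbind, rows)
}
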