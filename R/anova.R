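#' Split-plot (one-between, one-within) ANOVA
#'
#' Analysis of variance for the rating-experiment design: one
#' between-participant factor (the algorithm that generated a participant's
#' stimuli) and one within-participant factor (the stimulus), with every
#' participant measured once per stimulus level. Sums of squares follow the
#' standard split-plot decomposition: the between factor is tested against
#' participants-within-groups, the within factor and the interaction
#' against the within-participant residual. Effect sizes are
#' `eta^2 = SS_effect / SS_total`. No sphericity correction is applied (an
#' epsilon-corrected p would require one; none is used by default).
#'
#' @param data Long data frame with columns `participant`, `group` (the
#'   between factor), `stimulus` (the within factor) and `value`. Each
#'   participant must contribute exactly one value per stimulus level.
#' @return An object of class `anova_result`: data frame `table` with one
#'   row per effect (`effect`, `ss`, `df1`, `df2`, `F`, `p`, `eta2`),
#'   plus `posthoc` (Tukey table for the between factor, `NULL` when fewer
#'   than 3 groups would make it trivial it is still computed for 2+),
#'   `ms_subj`, `df_subj` and the group means used.
#' @export
mixed_anova <- function(data) {
  need <- c("participant", "group", "stimulus", "value")
  if (!all(need %in% names(data))) stop("missing columns in `data`")
  data$participant <- as.character(data$participant)
  data$group <- as.character(data$group)
  data$stimulus <- as.character(data$stimulus)
  if (any(!is.finite(data$value))) stop("non-finite values in `data`")

  tab <- table(data$participant, data$stimulus)
  if (any(tab != 1)) {
    stop("unbalanced within-factor: each participant needs one value per stimulus")
  }
  pg <- unique(data[c("participant", "group")])
  if (anyDuplicated(pg$participant)) stop("participant assigned to 2 groups")
  n_g <- table(pg$group)
  if (any(n_g < 2)) stop("need at least 2 participants per group")
  a <- length(n_g)
  s <- length(unique(data$stimulus))
  N <- nrow(pg)
  if (a < 2 || s < 2) stop("both factors need at least 2 levels")

  y <- data$value
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  m_p <- rowsum(y, data$participant) / s           # participant means
  m_g <- rowsum(y, data$group) / (s * as.vector(n_g[sort(unique(data$group))]))
  m_s <- rowsum(y, data$stimulus) / N
  cell_key <- paste(data$group, data$stimulus, sep = "\r")
  cell_n <- table(cell_key)
  m_gs <- rowsum(y, cell_key) / as.vector(cell_n[sort(unique(cell_key))])

  ss_between <- s * sum((m_p - grand)^2)
  ss_a <- s * sum(as.vector(n_g[rownames(m_g)]) * (m_g - grand)^2)
  ss_subj <- ss_between - ss_a
  ss_s <- N * sum((m_s - grand)^2)
  ncell <- as.vector(cell_n[rownames(m_gs)])
  ss_cells <- sum(ncell * (m_gs - grand)^2)
  ss_as <- ss_cells - ss_a - ss_s
  ss_werr <- ss_total - ss_cells - ss_subj

  df_a <- a - 1; df_subj <- N - a
  df_s <- s - 1; df_as <- (a - 1) * (s - 1); df_werr <- (N - a) * (s - 1)
  ms_subj <- ss_subj / df_subj
  ms_werr <- ss_werr / df_werr
  f_of <- function(ss, df, mse, df2) {
    if (ss <= .Machine$double.eps * max(1, ss_total)) return(c(0, 1))
    if (mse <= 0) return(c(Inf, 0))
    f <- (ss / df) / mse
    c(f, stats::pf(f, df, df2, lower.tail = FALSE))
  }
  fa <- f_of(ss_a, df_a, ms_subj, df_subj)
  fs <- f_of(ss_s, df_s, ms_werr, df_werr)
  fas <- f_of(ss_as, df_as, ms_werr, df_werr)
  tabout <- data.frame(
    effect = c("group", "stimulus", "group:stimulus"),
    ss = c(ss_a, ss_s, ss_as),
    df1 = c(df_a, df_s, df_as),
    df2 = c(df_subj, df_werr, df_werr),
    F = c(fa[1], fs[1], fas[1]),
    p = c(fa[2], fs[2], fas[2]),
    eta2 = c(ss_a, ss_s, ss_as) / if (ss_total > 0) ss_total else 1,
    stringsAsFactors = FALSE)

  gm <- data.frame(group = rownames(m_g), mean = as.vector(m_g),
                   n = as.vector(n_g[rownames(m_g)]),
                   stringsAsFactors = FALSE)
  posthoc <- tukey_posthoc(gm, ms_error = ms_subj / s, df_error = df_subj)
  structure(list(table = tabout, posthoc = posthoc,
                 ss_total = ss_total, ms_subj = ms_subj, df_subj = df_subj,
                 ms_within = ms_werr, df_within = df_werr,
                 group_means = gm),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Split-plot ANOVA (between: group, within: stimulus)\n")
  tb <- x$table
  tb$F <- signif(tb$F, 4); tb$p <- signif(tb$p, 4); tb$eta2 <- signif(tb$eta2, 4)
  print(tb, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("\nTukey post hoc (between factor):\n")
    ph <- x$posthoc
    ph$q <- signif(ph$q, 4); ph$p_adj <- signif(ph$p_adj, 4)
    print(ph, row.names = FALSE)
  }
  invisible(x)
}

#' Tukey (studentized range) post hoc comparisons
#'
#' All pairwise group comparisons using the Tukey-Kramer statistic
#' `q = |m_i - m_j| / sqrt((ms_error / 2) (1/n_i + 1/n_j))` and adjusted
#' p-values from the studentized range distribution. `ms_error` must be on
#' the scale of the units the means average over (for the between factor of
#' the split-plot design, participant means, i.e. `MS_subj / s`).
#'
#' @param group_summaries Data frame with columns `group`, `mean`, `n`.
#' @param ms_error Error mean square on the unit scale.
#' @param df_error Error degrees of freedom (`>= 1`).
#' @return Data frame with `group1`, `group2`, `diff`, `q`, `p_adj`.
#' @export
tukey_posthoc <- function(group_summaries, ms_error, df_error) {
  if (df_error < 1) stop("df_error must be at least 1")
  g <- group_summaries
  k <- nrow(g)
  if (k < 2) stop("need at least 2 groups")
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    dd <- g$mean[i] - g$mean[j]
    se <- sqrt((ms_error / 2) * (1 / g$n[i] + 1 / g$n[j]))
    q <- if (se > 0) abs(dd) / se else if (abs(dd) > 0) Inf else 0
    p <- if (q == 0) 1 else stats::ptukey(q, k, df_error, lower.tail = FALSE)
    c(diff = dd, q = q, p_adj = p)
  })
  data.frame(group1 = g$group[pairs[1, ]], group2 = g$group[pairs[2, ]],
             diff = res["diff", ], q = res["q", ], p_adj = res["p_adj", ],
             stringsAsFactors = FALSE)
}
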