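#' Repeated-measures ANOVA with generalized eta-squared
#'
#' Within-subject ANOVA by direct sums-of-squares decomposition for one or
#' two within factors (with interaction), on a balanced long-format table
#' with exactly one observation per subject x cell. Effect sizes are
#' generalized eta-squared (Olejnik--Algina / Bakeman): effect SS over
#' effect SS plus the subject SS and every error SS in the design -- for a
#' purely within design, `SS_effect / (SS_effect + SS_subject + sum of all
#' subject-by-factor error SS)`. Degrees of freedom are uncorrected (no
#' sphericity adjustment).
#'
#' @param table Long-format data frame.
#' @param dv Name of the value column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param subject Name of the subject identifier column.
#' @return A tibble with one row per effect: `effect`, `df_num`, `df_den`,
#'   `statistic` (F), `p_value`, `ges`.
#' @examples
#' tab <- tidyr::expand_grid(participant = 1:6, condition = c("A", "B", "C"))
#' tab$value <- rnorm(nrow(tab)) + as.numeric(factor(tab$condition))
#' rm_anova(tab)
#' @export
rm_anova <- function(table, dv = "value", within = "condition",
                     subject = "participant") {
  if (!length(within) %in% 1:2) abort("`within` must name one or two factors.")
  need <- c(dv, within, subject)
  if (!all(need %in% names(table))) {
    abort(sprintf("table lacks columns: %s", paste(setdiff(need, names(table)), collapse = ", ")))
  }
  v <- table[[dv]]
  s <- factor(table[[subject]])
  f1 <- factor(table[[within[1]]])
  f2 <- if (length(within) == 2) factor(table[[within[2]]]) else NULL
  cells <- if (is.null(f2)) list(s, f1) else list(s, f1, f2)
  counts <- table(interaction(cells, drop = FALSE))
  if (any(counts != 1)) {
    abort("unbalanced design: need exactly one observation per subject x cell.")
  }
  gm <- mean(v)
  n <- nlevels(s)
  a <- nlevels(f1)
  ss <- function(means, mult) mult * sum((means - gm)^2)
  m_s <- tapply(v, s, mean)
  m_a <- tapply(v, f1, mean)

  if (is.null(f2)) {
    ss_a <- ss(m_a, n)
    ss_s <- ss(m_s, a)
    ss_tot <- sum((v - gm)^2)
    ss_err <- ss_tot - ss_a - ss_s
    df1 <- a - 1
    df2 <- (a - 1) * (n - 1)
    f_stat <- if (ss_a == 0) 0 else (ss_a / df1) / (ss_err / df2)
    return(tibble::tibble(
      effect = within[1], df_num = df1, df_den = df2,
      statistic = f_stat, p_value = pf(f_stat, df1, df2, lower.tail = FALSE),
      ges = ss_a / (ss_a + ss_s + ss_err)
    ))
  }

  b <- nlevels(f2)
  m_b <- tapply(v, f2, mean)
  m_ab <- tapply(v, list(f1, f2), mean)
  m_as <- tapply(v, list(f1, s), mean)
  m_bs <- tapply(v, list(f2, s), mean)
  ss_a <- ss(m_a, n * b)
  ss_b <- ss(m_b, n * a)
  ss_s <- ss(m_s, a * b)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) - outer(rep(1, a), m_b) + gm)^2)
  ss_as <- b * sum((m_as - outer(m_a, rep(1, n)) - outer(rep(1, a), m_s) + gm)^2)
  ss_bs <- a * sum((m_bs - outer(m_b, rep(1, n)) - outer(rep(1, b), m_s) + gm)^2)
  ss_tot <- sum((v - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  err_all <- ss_as + ss_bs + ss_abs

  eff <- tibble::tibble(
    effect = c(within[1], within[2], paste(within, collapse = ":")),
    ss_eff = c(ss_a, ss_b, ss_ab),
    ss_err = c(ss_as, ss_bs, ss_abs),
    df_num = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df_den = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1))
  )
  dplyr::transmute(eff,
    effect = .data$effect, df_num = .data$df_num, df_den = .data$df_den,
    statistic = dplyr::if_else(
      .data$ss_eff == 0, 0,
      (.data$ss_eff / .data$df_num) / (.data$ss_err / .data$df_den)
    ),
    p_value = pf(.data$statistic, .data$df_num, .data$df_den, lower.tail = FALSE),
    ges = .data$ss_eff / (.data$ss_eff + ss_s + err_all)
  )
}

#' Bonferroni-corrected paired t tests with pairwise confidence intervals
#'
#' Classical paired t tests for a set of condition contrasts on a
#' within-subject table, with Bonferroni adjustment (`p_adj = min(1,
#' m * p_raw)`) and the pairwise 95% confidence interval
#' `mean_diff +/- t_{0.975, n-1} * SE(diff)` computed from each pair's own
#' difference scores (the Franz--Loftus form for within-subject designs).
#'
#' @inheritParams rm_anova
#' @param comparisons List of length-2 character vectors of factor levels
#'   (`c(level_a, level_b)` tests `a - b`); `NULL` for all level pairs.
#' @param m Number of comparisons in the Bonferroni family; defaults to
#'   `length(comparisons)`.
#' @param conf_level Confidence level of the pairwise interval.
#' @return A tibble: `level_a`, `level_b`, `n`, `mean_diff`, `statistic`
#'   (t), `df`, `p_raw`, `p_adj`, `conf_low`, `conf_high`.
#' @export
paired_t_bonferroni <- function(table, comparisons = NULL, m = NULL,
                                dv = "value", within = "condition",
                                subject = "participant", conf_level = 0.95) {
  lev <- unique(as.character(table[[within]]))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(lev, 2, simplify = FALSE)
  }
  m <- m %||% length(comparisons)
  rows <- purrr::map(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2)
    ta <- table[table[[within]] == cmp[1], c(subject, dv)]
    tb <- table[table[[within]] == cmp[2], c(subject, dv)]
    mg <- merge(ta, tb, by = subject, suffixes = c("_a", "_b"))
    d <- mg[[paste0(dv, "_a")]] - mg[[paste0(dv, "_b")]]
    n <- length(d)
    if (n < 2) abort("need at least 2 complete pairs.")
    se <- sd(d) / sqrt(n)
    df <- n - 1
    tval <- if (se == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      mean(d) / se
    }
    p <- 2 * pt(-abs(tval), df)
    crit <- qt(1 - (1 - conf_level) / 2, df)
    tibble::tibble(
      level_a = cmp[1], level_b = cmp[2], n = n, mean_diff = mean(d),
      statistic = tval, df = df, p_raw = p, p_adj = min(1, m * p),
      conf_low = mean(d) - crit * se, conf_high = mean(d) + crit * se
    )
  })
  dplyr::bind_rows(rows)
}

#' Screen out participants with any value beyond 2 SD
#'
#' Applies the per-condition outlier rule: within each condition, the mean
#' and SD are computed across participants (the candidate included); a
#' participant whose value lies outside `mean +/- sd_mult * SD` in at least
#' one condition is removed entirely (all their rows), and the analysis is
#' meant to be re-run on the reduced table.
#'
#' @inheritParams rm_anova
#' @param sd_mult SD multiplier (default 2).
#' @return A list: `table`, the filtered table; `removed`, the removed
#'   subject identifiers (possibly empty).
#' @export
remove_outliers_2sd <- function(table, dv = "value", within = "condition",
                                subject = "participant", sd_mult = 2) {
  flagged <- character(0)
  for (cond in unique(as.character(table[[within]]))) {
    sub <- table[table[[within]] == cond, ]
    if (nrow(sub) < 3) abort("need at least 3 participants per condition.")
    mu <- mean(sub[[dv]])
    sdev <- sd(sub[[dv]])
    out <- abs(sub[[dv]] - mu) > sd_mult * sdev
    flagged <- union(flagged, as.character(sub[[subject]][out]))
  }
  list(
    table = table[!as.character(table[[subject]]) %in% flagged, ],
    removed = flagged
  )
}
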