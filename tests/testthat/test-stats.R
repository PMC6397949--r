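test_that("one-way within ANOVA matches hand-computed sums of squares", {
  # 3 participants x 2 conditions, small integers:
  # cond means 2 and 5; SS_cond = 13.5, SS_subj = 13, SS_err = 3
  tab <- tibble::tibble(
    participant = rep(c("p1", "p2", "p3"), each = 2),
    condition = rep(c("c1", "c2"), 3),
    value = c(1, 3, 2, 4, 3, 8)
  )
  res <- rm_anova(tab)
  expect_equal(res$statistic, 9) # (13.5/1)/(3/2)
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, 2)
  expect_equal(res$ges, 13.5 / 29.5, tolerance = 1e-12)
})

test_that("constant per-participant values give F = 0", {
  tab <- tidyr::expand_grid(participant = paste0("p", 1:5), condition = c("a", "b", "c"))
  tab$value <- rep(c(2, 5, 1, 4, 3), each = 3)
  res <- rm_anova(tab)
  expect_equal(res$statistic, 0)
})

test_that("one-way F and p agree with the aov() oracle on random tables", {
  for (i in 1:10) {
    set.seed(50 + i)
    n <- sample(4:9, 1)
    k <- sample(3:5, 1)
    tab <- tidyr::expand_grid(participant = paste0("p", 1:n), condition = letters[1:k])
    tab$value <- rnorm(n * k) + rep(rnorm(n), each = k)
    res <- rm_anova(tab)
    ora <- oracle_rm_anova_F(tab, "value", "condition", "participant")$condition
    expect_equal(res$statistic, unname(ora["F"]), tolerance = 1e-8)
    expect_equal(res$p_value, unname(ora["p"]), tolerance = 1e-8)
  }
})

test_that("two-way within ANOVA agrees with the aov() oracle", {
  for (i in 1:5) {
    set.seed(60 + i)
    tab <- tidyr::expand_grid(
      participant = paste0("p", 1:6),
      condition = c("x", "y", "z"), session = paste0("s", 1:4)
    )
    tab$value <- rnorm(nrow(tab))
    res <- rm_anova(tab, within = c("condition", "session"))
    ora <- oracle_rm_anova_F(tab, "value", c("condition", "session"), "participant")
    expect_equal(res$statistic[res$effect == "condition"],
      unname(ora$condition["F"]),
      tolerance = 1e-8
    )
    expect_equal(res$statistic[res$effect == "session"],
      unname(ora$session["F"]),
      tolerance = 1e-8
    )
    expect_equal(res$statistic[res$effect == "condition:session"],
      unname(ora$`condition:session`["F"]),
      tolerance = 1e-8
    )
  }
})

test_that("unbalanced tables are rejected", {
  tab <- tibble::tibble(
    participant = c("p1", "p1", "p2"),
    condition = c("a", "b", "a"),
    value = 1:3
  )
  expect_error(rm_anova(tab), "unbalanced")
})

test_that("ANOVA type-I error is calibrated under the null", {
  alpha <- 0.05
  rej <- vapply(1:800, function(i) {
    set.seed(70000 + i)
    tab <- tidyr::expand_grid(participant = paste0("p", 1:6), condition = c("a", "b", "c"))
    tab$value <- rnorm(18) + rep(rnorm(6), each = 3)
    rm_anova(tab)$p_value < alpha
  }, logical(1))
  phat <- mean(rej)
  expect_lt(abs(phat - alpha), 3 * sqrt(alpha * (1 - alpha) / 800))
})

test_that("paired t equals the textbook formula on a hand example", {
  # differences (1, 2, 3): mean 2, sd 1, t = 2*sqrt(3), CI 2 +/- 4.302653*1/sqrt(3)
  tab <- tibble::tibble(
    participant = rep(c("p1", "p2", "p3"), 2),
    condition = rep(c("a", "b"), each = 3),
    value = c(3, 5, 10, 2, 3, 7)
  )
  res <- paired_t_bonferroni(tab, comparisons = list(c("a", "b")))
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$mean_diff, 2)
  crit <- qt(0.975, 2)
  expect_equal(res$conf_low, 2 - crit / sqrt(3), tolerance = 1e-12)
  expect_equal(res$conf_high, 2 + crit / sqrt(3), tolerance = 1e-12)
})

test_that("paired t agrees with the t.test() oracle and Bonferroni arithmetic", {
  set.seed(80)
  tab <- tidyr::expand_grid(participant = paste0("p", 1:10), condition = c("a", "b", "c"))
  tab$value <- rnorm(30)
  res <- paired_t_bonferroni(tab)
  expect_equal(nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    va <- tab$value[tab$condition == res$level_a[i]]
    vb <- tab$value[tab$condition == res$level_b[i]]
    tt <- t.test(va, vb, paired = TRUE)
    expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_raw[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$conf_low[i], tt$conf.int[1], tolerance = 1e-10)
    expect_equal(res$conf_high[i], tt$conf.int[2], tolerance = 1e-10)
  }
  expect_equal(res$p_adj, pmin(1, 3 * res$p_raw))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$conf_low <= res$mean_diff & res$mean_diff <= res$conf_high))
})

test_that("identical paired vectors give t = 0 and adjusted p = 1", {
  tab <- tibble::tibble(
    participant = rep(paste0("p", 1:5), 2),
    condition = rep(c("a", "b"), each = 5),
    value = rep(c(1, 4, 2, 5, 3), 2)
  )
  res <- paired_t_bonferroni(tab, comparisons = list(c("a", "b")), m = 6)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_adj, 1)
})

test_that("the 2-SD rule removes exactly the planted outlier participant", {
  # evenly spaced values keep every deviation under 1.6 per-condition SDs
  tab <- tidyr::expand_grid(participant = paste0("p", 1:10), condition = c("a", "b", "c", "d"))
  tab <- dplyr::arrange(tab, condition, participant)
  tab$value <- rep(seq(8, 12, length.out = 10), 4)
  clean <- remove_outliers_2sd(tab)
  expect_equal(clean$removed, character(0))
  expect_equal(nrow(clean$table), 40)

  sd_b <- sd(tab$value[tab$condition == "b"])
  tab$value[tab$participant == "p7" & tab$condition == "b"] <- 10 + 10 * sd_b
  scr <- remove_outliers_2sd(tab)
  expect_equal(scr$removed, "p7")
  expect_equal(nrow(scr$table), 36)
  # workflow: the ANOVA re-runs on the reduced (still balanced) table
  res <- rm_anova(scr$table)
  expect_equal(res$df_den, (4 - 1) * (9 - 1))
})
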