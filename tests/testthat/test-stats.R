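# ANOVA battery against hand-computed and independent reference oracles.

test_that("balanced 2x2 ANOVA matches the hand-computed decomposition", {
  # cells {1,2},{3,4},{5,6},{7,8}: SS_A = 32, SS_B = 8, SS_AB = 0,
  # MSE = 0.5 -> F_A = 64, F_B = 16, F_int = 0 (df 1, 4)
  tab <- data.frame(A = rep(c("a1", "a1", "a2", "a2"), each = 2),
                    B = rep(c("b1", "b2", "b1", "b2"), each = 2),
                    value = c(1, 2, 3, 4, 5, 6, 7, 8))
  res <- anova_two_way_between(tab)
  expect_equal(res$A$F, 64)
  expect_equal(res$A$df_num, 1)
  expect_equal(res$A$df_den, 4)
  expect_equal(res$B$F, 16)
  expect_equal(res$interaction$F, 0)
  expect_equal(res$ms_error, 0.5)
})

test_that("constant data give zero F for every effect", {
  tab <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  tab$value <- 5
  res <- anova_two_way_between(tab)
  expect_true(all(c(res$A$F, res$B$F, res$interaction$F) == 0))
})

test_that("empty or thin cells are rejected with the cell named", {
  tab <- data.frame(A = c("a1", "a1", "a2", "a2"),
                    B = c("b1", "b1", "b1", "b1"),
                    value = 1:4)
  expect_error(anova_two_way_between(tab), "at least 2 levels")
  tab2 <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:2)
  tab2$value <- rnorm(8)
  tab2 <- tab2[!(tab2$A == "a2" & tab2$B == "b2"), ]
  expect_error(anova_two_way_between(tab2), "empty cell: a2 x b2")
})

test_that("two-way Type-III F agrees with car::Anova on unbalanced tables", {
  skip_if_not_installed("car")
  set.seed(20)
  for (rep_i in 1:10) {
    ns <- matrix(sample(2:6, 4, replace = TRUE), 2)
    rows <- list()
    for (i in 1:2) for (j in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        A = paste0("a", i), B = paste0("b", j),
        value = rnorm(ns[i, j], mean = i + 2 * j + rnorm(1)))
    }
    tab <- do.call(rbind, rows)
    res <- anova_two_way_between(tab)
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    fit <- stats::lm(value ~ A * B, data = tab)
    ref <- car::Anova(fit, type = 3)
    options(op)
    expect_equal(res$A$F, ref["A", "F value"], tolerance = 1e-8)
    expect_equal(res$B$F, ref["B", "F value"], tolerance = 1e-8)
    expect_equal(res$interaction$F, ref["A:B", "F value"], tolerance = 1e-8)
  }
})

test_that("mixed ANOVA agrees with aov error strata on balanced tables", {
  set.seed(21)
  for (rep_i in 1:8) {
    n_per <- sample(3:5, 1)
    b <- sample(2:4, 1)
    tab <- expand.grid(subject = paste0("s", 1:(2 * n_per)),
                       within = paste0("w", 1:b))
    tab$between <- ifelse(as.integer(sub("s", "", tab$subject)) <= n_per,
                          "g1", "g2")
    tab$value <- rnorm(nrow(tab)) +
      2 * (tab$between == "g2") + 0.5 * (tab$within == "w2")
    res <- anova_mixed(tab)
    fit <- stats::aov(value ~ between * within +
                        Error(subject / within), data = tab)
    s <- summary(fit)
    bt <- s[["Error: subject"]][[1]]
    wt <- s[["Error: subject:within"]][[1]]
    expect_equal(res$between$F, bt["between", "F value"], tolerance = 1e-8)
    expect_equal(res$within$F, wt["within", "F value"], tolerance = 1e-8)
    expect_equal(res$interaction$F, wt["between:within", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("mixed ANOVA rejects incomplete within-subject data", {
  tab <- expand.grid(subject = c("s1", "s2", "s3", "s4"),
                     within = c("w1", "w2"))
  tab$between <- rep(c("g1", "g2"), 4)
  tab$value <- rnorm(8)
  expect_error(anova_mixed(tab[-3, ]), "not observed exactly once")
  # identical within levels per subject -> within F = 0
  tab$value <- rep(rnorm(4), 2)
  res <- anova_mixed(tab)
  expect_equal(res$within$F, 0, tolerance = 1e-12)
})

test_that("repeated-measures one-way ANOVA agrees with aov", {
  set.seed(22)
  for (rep_i in 1:8) {
    n <- sample(4:8, 1)
    k <- sample(2:5, 1)
    tab <- expand.grid(subject = paste0("s", 1:n),
                       level = paste0("l", 1:k))
    tab$value <- rnorm(nrow(tab)) + as.integer(factor(tab$level)) * 0.7 +
      rep(rnorm(n), k)
    res <- anova_one_way_within(tab)
    fit <- stats::aov(value ~ level + Error(subject), data = tab)
    ref <- summary(fit)[["Error: Within"]][[1]]
    expect_equal(res$result$F, ref["level", "F value"], tolerance = 1e-8)
  }
  two <- data.frame(subject = rep(c("s1", "s2", "s3"), 2),
                    level = rep(c("l1", "l2"), each = 3),
                    value = rep(c(1, 2, 3), 2))
  expect_equal(anova_one_way_within(two)$result$F, 0)
  expect_error(anova_one_way_within(two[-1, ]), "incomplete block")
})

test_that("Tukey HSD matches TukeyHSD and reduces to t for two groups", {
  set.seed(23)
  tab <- data.frame(g = rep(c("g1", "g2", "g3"), each = 6),
                    value = rnorm(18) + rep(c(0, 1, 2), each = 6))
  fit <- stats::aov(value ~ g, data = tab)
  ref <- stats::TukeyHSD(fit)$g
  means <- tapply(tab$value, tab$g, mean)
  ns <- table(tab$g)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfe <- summary(fit)[[1]]["Residuals", "Df"]
  got <- tukey_hsd(means, ns, mse, dfe)
  for (i in seq_len(nrow(got))) {
    pair <- paste(got$group_b[i], got$group_a[i], sep = "-")
    expect_equal(got$p_adj[i], ref[pair, "p adj"], tolerance = 1e-8)
  }
  # equal means -> q = 0, adjusted p = 1
  eq <- tukey_hsd(c(a = 1, b = 1), c(a = 5, b = 5), ms_error = 2,
                  df_error = 8)
  expect_equal(eq$q, 0)
  expect_equal(eq$p_adj, 1)
  # two groups: p equals the two-sided pooled t-test p
  x <- rnorm(6)
  y <- rnorm(6) + 1
  tt <- t_unpaired(x, y)
  mse2 <- ((5) * var(x) + (5) * var(y)) / 10
  two <- tukey_hsd(c(x = mean(x), y = mean(y)), c(x = 6, y = 6), mse2, 10)
  expect_equal(two$p_adj, tt$p, tolerance = 1e-8)
  expect_error(tukey_hsd(c(a = 1, b = 2), c(a = 3, b = 3), 1, 0),
               "df_error")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.02, 0.03)), c(0.04, 0.06))
  p <- runif(10)
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_true(all(bonferroni_adjust(p) <= 1))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("simple effects use the omnibus error and find planted slices", {
  set.seed(24)
  # effect of A only at b2
  tab <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:8)
  tab$value <- rnorm(nrow(tab), sd = 0.5) +
    ifelse(tab$A == "a2" & tab$B == "b2", 2, 0)
  se <- simple_effects(tab)
  expect_lt(se$b2$p, 0.05)
  expect_gt(se$b1$p, se$b2$p)
  omn <- anova_two_way_between(tab)
  expect_equal(se$b1$df_den, omn$df_error)
  one_level <- tab[tab$A == "a1", ]
  expect_error(simple_effects(one_level), "at least 2 levels|single level")
})

test_that("unpaired t-test matches t.test and handles degenerate input", {
  set.seed(25)
  x <- rnorm(8)
  y <- rnorm(10, 1)
  got <- t_unpaired(x, y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter))
  same <- t_unpaired(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(t_unpaired(1, c(1, 2)), "n >= 2")
})
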