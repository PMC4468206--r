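# The ANOVA battery: two-way between-subjects ANOVA (Type-III sums of
# squares, tolerant of unbalanced cells), mixed (between x within) ANOVA,
# one-way repeated-measures ANOVA, Tukey HSD, Bonferroni adjustment,
# simple-effects analysis and the pooled-variance unpaired t-test. The F
# statistics are computed from explicit design matrices and projections
# rather than delegated to a fitting engine, so each one can be checked
# against an independent reference in the test suite.

new_stat_result <- function(effect, F, df_num, df_den, p, followup = NULL,
                            extra = list()) {
  structure(c(list(effect = effect, F = F, df_num = df_num, df_den = df_den,
                   p = p, followup = followup), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: F(%g, %g) = %.4g, p = %.4g\n", x$effect, x$df_num,
              x$df_den, x$F, x$p))
  invisible(x)
}

# Residual sum of squares after projecting y on the column space of X.
rss <- function(X, y) {
  sum(qr.resid(qr(X), y)^2)
}

# F ratio with the zero-variance convention: when the error mean square is
# zero, a zero hypothesis sum of squares gives F = 0 (constant data), a
# positive one gives Inf.
f_ratio <- function(ss, df_num, ms_error, scale = 1) {
  ss <- as.numeric(ss)
  ms_error <- as.numeric(ms_error)
  tol <- 1e-12 * max(1, scale)
  if (ms_error <= tol) {
    return(if (ss <= tol) 0 else Inf)
  }
  (ss / df_num) / ms_error
}

#' Two-way between-subjects ANOVA (Type-III)
#'
#' Main effects of two between-subject factors and their interaction, with
#' Type-III sums of squares (each effect adjusted for all others under
#' sum-to-zero contrasts), the convention that keeps "main effect" tests
#' meaningful under unbalanced cell sizes.
#'
#' @param table A data.frame with columns `factorA`, `factorB`, `value`.
#' @param factorA,factorB,value Column names (defaults `"A"`, `"B"`,
#'   `"value"`).
#' @return A list of three `stat_result` objects (`A`, `B`, `A:B`), plus
#'   `ms_error` and `df_error` for follow-up tests.
#' @export
anova_two_way_between <- function(table, factorA = "A", factorB = "B",
                                  value = "value") {
  A <- factor(table[[factorA]])
  B <- factor(table[[factorB]])
  y <- as.numeric(table[[value]])
  if (nlevels(A) < 2 || nlevels(B) < 2) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  cells <- table(A, B)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: ", levels(A)[empty[1]], " x ", levels(B)[empty[2]],
         call. = FALSE)
  }
  if (any(cells < 2)) stop("each cell needs at least 2 observations",
                           call. = FALSE)
  # sum-to-zero contrasts make the Type-III hypotheses the unweighted ones
  Xa <- stats::model.matrix(~A, contrasts.arg = list(A = "contr.sum"))[, -1,
                                                                      drop = FALSE]
  Xb <- stats::model.matrix(~B, contrasts.arg = list(B = "contr.sum"))[, -1,
                                                                      drop = FALSE]
  Xab <- matrix(0, length(y), ncol(Xa) * ncol(Xb))
  k <- 0
  for (i in seq_len(ncol(Xa))) {
    for (j in seq_len(ncol(Xb))) {
      k <- k + 1
      Xab[, k] <- Xa[, i] * Xb[, j]
    }
  }
  one <- matrix(1, length(y), 1)
  full <- cbind(one, Xa, Xb, Xab)
  sse <- rss(full, cbind(y))
  df_err <- length(y) - ncol(full)
  mse <- sse / df_err
  eff <- function(label, drop_cols, df_num) {
    reduced <- full[, setdiff(seq_len(ncol(full)), drop_cols), drop = FALSE]
    ss <- rss(reduced, cbind(y)) - sse
    Fv <- f_ratio(ss, df_num, mse, scale = sum(y^2))
    new_stat_result(label, Fv, df_num, df_err,
                    stats::pf(Fv, df_num, df_err, lower.tail = FALSE))
  }
  ia <- 1 + seq_len(ncol(Xa))
  ib <- 1 + ncol(Xa) + seq_len(ncol(Xb))
  iab <- 1 + ncol(Xa) + ncol(Xb) + seq_len(ncol(Xab))
  list(A = eff(factorA, ia, ncol(Xa)),
       B = eff(factorB, ib, ncol(Xb)),
       interaction = eff(paste0(factorA, ":", factorB), iab, ncol(Xab)),
       ms_error = mse, df_error = df_err)
}

#' Mixed-design (between x within) two-way ANOVA
#'
#' Univariate repeated-measures ANOVA with one between-subjects factor and
#' one within-subjects factor observed on every subject. The between
#' effect is tested against the subject-within-group error; the within
#' main effect and the interaction are tested against the
#' subject-by-within error. Unequal group sizes are handled; incomplete
#' within-subject data are rejected.
#'
#' @param table A data.frame with columns `subject`, `between`, `within`,
#'   `value` (those names).
#' @return A list of three `stat_result` objects (`between`, `within`,
#'   `interaction`) plus the two error strata (`ms_error_between`,
#'   `df_error_between`, `ms_error_within`, `df_error_within`).
#' @export
anova_mixed <- function(table) {
  subj <- factor(table$subject)
  grp <- factor(table$between)
  win <- factor(table$within)
  y <- as.numeric(table$value)
  b <- nlevels(win)
  tab <- table(subj, win)
  if (any(tab != 1)) {
    bad <- levels(subj)[which(rowSums(tab != 1) > 0)[1]]
    stop("subject ", bad, " is not observed exactly once at every within ",
         "level", call. = FALSE)
  }
  subj_group <- tapply(as.character(grp), subj, function(g) g[1])
  n_subj <- nlevels(subj)
  a <- nlevels(grp)
  # subject means -> between stratum (one-way ANOVA scaled by b)
  s_mean <- tapply(y, subj, mean)
  g_of_s <- factor(subj_group[names(s_mean)], levels = levels(grp))
  grand <- mean(s_mean)
  g_means <- tapply(s_mean, g_of_s, mean)
  n_g <- table(g_of_s)
  ss_between <- b * sum(n_g * (g_means - grand)^2)
  ss_subj <- b * sum((s_mean - g_means[g_of_s])^2)
  df_between <- a - 1
  df_subj <- n_subj - a
  ms_subj <- ss_subj / df_subj
  F_b <- f_ratio(ss_between, df_between, ms_subj, scale = sum(y^2))
  # within stratum: remove subject means, then cell-mean decomposition
  d <- y - s_mean[as.character(subj)]
  cell <- tapply(d, list(grp, win), mean)          # a x b, subject-centred
  # within main effect (Type-III): unweighted means across groups, scaled
  # by the harmonic mean group size
  w_unw <- colMeans(cell)
  nh <- a / sum(1 / n_g)
  ss_within <- nh * a * sum((w_unw - mean(w_unw))^2)
  # interaction: group departures from the weighted grand within-profile
  w_wtd <- colSums(cell * as.numeric(n_g)) / sum(n_g)
  ss_inter <- 0
  for (i in seq_len(a)) {
    ss_inter <- ss_inter + n_g[i] * sum((cell[i, ] - mean(cell[i, ]) -
                                           w_wtd + mean(w_wtd))^2)
  }
  ss_err_w <- sum((d - cell[cbind(as.integer(grp), as.integer(win))])^2)
  df_within <- b - 1
  df_inter <- (a - 1) * (b - 1)
  df_err_w <- (n_subj - a) * (b - 1)
  ms_err_w <- as.numeric(ss_err_w / df_err_w)
  F_w <- f_ratio(ss_within, df_within, ms_err_w, scale = sum(y^2))
  F_i <- f_ratio(ss_inter, df_inter, ms_err_w, scale = sum(y^2))
  list(
    between = new_stat_result("between", F_b, df_between, df_subj,
                              stats::pf(F_b, df_between, df_subj,
                                        lower.tail = FALSE)),
    within = new_stat_result("within", F_w, df_within, df_err_w,
                             stats::pf(F_w, df_within, df_err_w,
                                       lower.tail = FALSE)),
    interaction = new_stat_result("between:within", F_i, df_inter, df_err_w,
                                  stats::pf(F_i, df_inter, df_err_w,
                                            lower.tail = FALSE)),
    ms_error_between = ms_subj, df_error_between = df_subj,
    ms_error_within = ms_err_w, df_error_within = df_err_w)
}

#' One-way within-subjects (repeated-measures) ANOVA
#'
#' Repeated-measures F with subject blocking: the treatment effect is
#' tested against the subject-by-treatment residual.
#'
#' @param table A data.frame with columns `subject`, `level`, `value`.
#' @return A `stat_result` plus `ms_error` and `df_error`.
#' @export
anova_one_way_within <- function(table) {
  subj <- factor(table$subject)
  lev <- factor(table$level)
  y <- as.numeric(table$value)
  tab <- table(subj, lev)
  if (any(tab != 1)) stop("incomplete block: every subject needs every level",
                          call. = FALSE)
  n <- nlevels(subj)
  k <- nlevels(lev)
  grand <- mean(y)
  m_lev <- tapply(y, lev, mean)
  m_subj <- tapply(y, subj, mean)
  ss_treat <- n * sum((m_lev - grand)^2)
  ss_subj <- k * sum((m_subj - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- max(ss_tot - ss_treat - ss_subj, 0)
  df_treat <- k - 1
  df_err <- (n - 1) * (k - 1)
  Fv <- f_ratio(ss_treat, df_treat, ss_err / df_err, scale = sum(y^2))
  res <- new_stat_result("level", Fv, df_treat, df_err,
                         stats::pf(Fv, df_treat, df_err, lower.tail = FALSE))
  list(result = res, ms_error = ss_err / df_err, df_error = df_err)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted p values for all pairwise differences of
#' group means (Tukey-Kramer standard errors under unequal group sizes).
#'
#' @param means Named numeric of group means.
#' @param ns Named numeric of group sizes (same names as `means`).
#' @param ms_error Pooled error mean square.
#' @param df_error Error degrees of freedom (> 0).
#' @return A data.frame with columns `group_a`, `group_b`, `diff`, `q`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(means, ns, ms_error, df_error) {
  if (length(means) < 2) stop("need at least 2 groups", call. = FALSE)
  if (df_error <= 0) stop("df_error must be positive", call. = FALSE)
  g <- names(means)
  k <- length(means)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(ms_error / 2 * (1 / ns[[g[i]]] + 1 / ns[[g[j]]]))
      q <- abs(means[[g[i]]] - means[[g[j]]]) / se
      p <- stats::ptukey(q, k, df_error, lower.tail = FALSE)
      out[[length(out) + 1]] <- data.frame(
        group_a = g[i], group_b = g[j],
        diff = means[[g[i]]] - means[[g[j]]], q = q, p_adj = p)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for a family of `m` p values.
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values.
#' @export
bonferroni_adjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "bonferroni")
}

#' Simple-effects analysis after a significant interaction
#'
#' Tests the effect of `factorA` separately at each level of `factorB`,
#' using the omnibus error term from the full two-way model (not the
#' per-slice error).
#'
#' @param table A data.frame with columns `factorA`, `factorB`, `value`.
#' @param factorA,factorB,value Column names.
#' @param omnibus Optional result of [anova_two_way_between()] on the same
#'   table (recomputed when absent).
#' @return A named list of `stat_result`, one per level of `factorB`.
#' @export
simple_effects <- function(table, factorA = "A", factorB = "B",
                           value = "value", omnibus = NULL) {
  B <- factor(table[[factorB]])
  if (nlevels(B) < 2) stop("factorB needs at least 2 levels", call. = FALSE)
  if (is.null(omnibus)) {
    omnibus <- anova_two_way_between(table, factorA, factorB, value)
  }
  mse <- omnibus$ms_error
  df_err <- omnibus$df_error
  out <- list()
  for (lev in levels(B)) {
    sl <- table[B == lev, ]
    A <- factor(sl[[factorA]])
    if (nlevels(A) < 2) stop("factorA has a single level at ", factorB,
                             " = ", lev, call. = FALSE)
    y <- as.numeric(sl[[value]])
    m <- tapply(y, A, mean)
    n <- table(A)
    ss <- sum(n * (m - sum(n * m) / sum(n))^2)
    df_num <- nlevels(A) - 1
    Fv <- f_ratio(ss, df_num, mse, scale = sum(y^2))
    out[[lev]] <- new_stat_result(
      paste0(factorA, " at ", factorB, "=", lev), Fv, df_num, df_err,
      stats::pf(Fv, df_num, df_err, lower.tail = FALSE))
  }
  out
}

#' Two-sample unpaired t-test (pooled variance)
#'
#' @param x,y Numeric samples (each `n >= 2`).
#' @param two_tailed Two-tailed p value (default `TRUE`).
#' @return A `stat_result`-like list with `t`, `df`, `p`, and the mean
#'   difference.
#' @export
t_unpaired <- function(x, y, two_tailed = TRUE) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in each sample", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  diff <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (diff == 0) {
      return(list(effect = "t", t = 0, df = n1 + n2 - 2, p = 1,
                  mean_diff = 0))
    }
    return(list(effect = "t", t = sign(diff) * Inf, df = n1 + n2 - 2, p = 0,
                mean_diff = diff))
  }
  tv <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- stats::pt(abs(tv), df, lower.tail = FALSE) * if (two_tailed) 2 else 1
  list(effect = "t", t = tv, df = df, p = min(p, 1), mean_diff = diff)
}
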