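#' One-way fixed-effects ANOVA with partial eta-squared
#'
#' Classical between/within sums-of-squares decomposition via [stats::aov()],
#' with the effect size computed from the same sums of squares:
#' partial eta^2 = SS_between / (SS_between + SS_within).
#'
#' @param values numeric outcome vector.
#' @param groups factor (or coercible) of group labels, same length.
#' @param outcome optional outcome name carried into the result.
#' @return one-row tibble: `outcome, F, df_between, df_within, p,
#'   partial_eta_sq`.
#' @export
one_way_anova <- function(values, groups, outcome = "outcome") {
  groups <- factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  if (stats::var(values) < .Machine$double.eps) {
    stop("zero total variance: ANOVA undefined")
  }
  fit <- stats::aov(values ~ groups)
  ss <- summary(fit)[[1]]
  ss_b <- ss[["Sum Sq"]][1]; ss_w <- ss[["Sum Sq"]][2]
  tibble::tibble(
    outcome = outcome,
    F = ss[["F value"]][1],
    df_between = ss[["Df"]][1],
    df_within = ss[["Df"]][2],
    p = ss[["Pr(>F)"]][1],
    partial_eta_sq = ss_b / (ss_b + ss_w)
  )
}

#' Fisher's LSD pairwise comparisons
#'
#' Unadjusted pairwise t-tests that reuse the ANOVA's pooled error mean
#' square and error degrees of freedom, per the least-significant-difference
#' convention. `mean_diff` is `mean(a) - mean(b)` for the pair `(a, b)`.
#'
#' @param values,groups as in [one_way_anova()].
#' @param pairs optional 2-column matrix or data frame of level pairs; by
#'   default all unordered pairs in level order.
#' @return tibble `level_a, level_b, mean_diff, t, df, lsd_p`.
#' @export
lsd_pairwise <- function(values, groups, pairs = NULL) {
  groups <- factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  lv <- levels(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_w <- length(values) - nlevels(groups)
  mse <- ssw / df_w
  if (is.null(pairs)) {
    cmb <- utils::combn(lv, 2)
    pairs <- data.frame(a = cmb[1, ], b = cmb[2, ])
  } else {
    pairs <- data.frame(a = as.character(pairs[[1]]), b = as.character(pairs[[2]]))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    se <- sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
    t_stat <- (m[[a]] - m[[b]]) / se
    tibble::tibble(
      level_a = a, level_b = b,
      mean_diff = m[[a]] - m[[b]],
      t = t_stat, df = df_w,
      lsd_p = 2 * stats::pt(-abs(t_stat), df_w)
    )
  })
  dplyr::bind_rows(res)
}

#' Cohen's d with a 95% confidence interval
#'
#' Standardized mean difference `d = (mean_a - mean_b) / s_pooled` with the
#' large-sample standard error
#' `se(d) = sqrt((n_a + n_b) / (n_a n_b) + d^2 / (2 (n_a + n_b - 2)))`
#' and a normal-theory interval `d +/- 1.96 se`.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return one-row tibble: `d, d_ci_low, d_ci_high, n_a, n_b`.
#' @export
cohens_d_ci <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need at least 2 observations per group")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance: d undefined")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb - 2)))
  tibble::tibble(
    d = d,
    d_ci_low = d - 1.96 * se,
    d_ci_high = d + 1.96 * se,
    n_a = na, n_b = nb
  )
}

# Opposition pairs ordered higher level first, so positive effects mean
# "superior against the stronger opponent".
.opposition_pairs <- function() {
  data.frame(
    a = c("first_league", "first_league", "second_league"),
    b = c("second_league", "amateur", "amateur")
  )
}

#' Compare an outcome across opposition levels
#'
#' One-way ANOVA plus LSD pairwise tests and Cohen's d (95% CI) for each
#' level pair, higher level first.
#'
#' @param values numeric outcome.
#' @param levels character/factor of opposition levels.
#' @param outcome outcome name.
#' @return list of tibbles `anova` and `pairwise` (LSD joined with d).
#' @export
compare_opposition <- function(values, levels, outcome = "outcome") {
  levels <- factor(as.character(levels), levels = opposition_levels())
  anova_tbl <- one_way_anova(values, levels, outcome)
  pw <- lsd_pairwise(values, levels, pairs = .opposition_pairs())
  ds <- lapply(seq_len(nrow(pw)), function(i) {
    tryCatch(
      cohens_d_ci(values[levels == pw$level_a[i]], values[levels == pw$level_b[i]]),
      error = function(e) tibble::tibble(
        d = NA_real_, d_ci_low = NA_real_, d_ci_high = NA_real_,
        n_a = sum(levels == pw$level_a[i], na.rm = TRUE),
        n_b = sum(levels == pw$level_b[i], na.rm = TRUE)
      )
    )
  })
  pairwise <- dplyr::bind_cols(pw, dplyr::bind_rows(ds))
  pairwise$outcome <- outcome
  list(anova = anova_tbl, pairwise = pairwise)
}
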