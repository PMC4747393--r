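# Burden-phenotype association statistics, implemented from first
# principles: contingency construction, Fisher's exact test (two-sided,
# probability-mass ordering, log-space), Pearson chi-square, Student/Welch
# t, Kaplan-Meier product-limit estimator and Mantel-Cox log-rank.

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "risk_test_result")
}

#' @export
print.risk_test_result <- function(x, ...) {
  cat(x$method, ": ", sep = "")
  if (!is.na(x$statistic)) cat("statistic = ", format(x$statistic), ", ", sep = "")
  if (!is.na(x$df)) cat("df = ", x$df, ", ", sep = "")
  cat("p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Burden-by-phenotype contingency table
#'
#' Cross-tabulates exact per-subject risk-variant counts (rows `0`, `1`,
#' ..., with counts at or above `max_count` pooled into a final
#' `"<max_count>+"` row) against the phenotype groups.
#'
#' @param profiles Burden tibble from [burden()].
#' @param phenotypes Tibble with `subject_id` and `phenotype`
#'   (`"neutral"`/`"poor"`), e.g. a classified cohort.
#' @param max_count Largest exact burden row; defaults to the maximum
#'   observed burden.
#' @return Integer matrix (burden x phenotype) with column order
#'   `neutral`, `poor`.
#' @export
burden_table <- function(profiles, phenotypes, max_count = NULL) {
  if (nrow(profiles) == 0) {
    abort("empty cohort: no burden profiles", class = "lynchburden_stats_error")
  }
  ph <- phenotypes$phenotype[match(profiles$subject_id,
                                   phenotypes$subject_id)]
  if (anyNA(ph) || any(!ph %in% c("neutral", "poor"))) {
    bad <- profiles$subject_id[is.na(ph) | !ph %in% c("neutral", "poor")]
    abort(paste0("missing or indeterminate phenotype for subject(s): ",
                 paste(bad, collapse = ", ")),
          class = "lynchburden_stats_error")
  }
  b <- profiles$n_risk_variants_non_mmr
  if (is.null(max_count)) max_count <- max(b)
  pooled <- pmin(b, max_count)
  rows <- c(if (max_count > 0) as.character(0:(max_count - 1)),
            paste0(max_count, "+"))
  counts <- table(factor(pooled, levels = 0:max_count),
                  factor(ph, levels = c("neutral", "poor")))
  m <- matrix(as.integer(counts), nrow = max_count + 1,
              dimnames = list(burden = rows,
                              phenotype = c("neutral", "poor")))
  m
}

row_burden_level <- function(tab) {
  as.integer(sub("\\+$", "", rownames(tab)))
}

#' Dichotomize a burden table at k variants
#'
#' Pools burden rows into `0..k-1` versus `>= k`, preserving margins.
#'
#' @param tab Burden-by-phenotype matrix from [burden_table()].
#' @param k Dichotomy threshold, default 2 (at least two risk-variants).
#' @return 2x2 integer matrix with rows `"0-<k-1>"` and `">=<k>"`.
#' @export
#' @examples
#' dichotomize(reference_burden_distribution(), k = 2)
dichotomize <- function(tab, k = 2) {
  lev <- row_burden_level(tab)
  if (all(lev < k) || all(lev >= k)) {
    abort(paste0("dichotomy at k = ", k,
                 " leaves an empty burden group (degenerate table)"),
          class = "lynchburden_stats_error")
  }
  lo <- colSums(tab[lev < k, , drop = FALSE])
  hi <- colSums(tab[lev >= k, , drop = FALSE])
  m <- rbind(lo, hi)
  rownames(m) <- c(if (k == 1) "0" else paste0("0-", k - 1), paste0(">=", k))
  m
}

#' The published burden-by-phenotype distribution
#'
#' The distribution of risk-variant counts outside the mismatch-repair
#' genes among the 35 successfully sequenced carriers of the motivating
#' cohort (13 neutral, 22 poor), as printed in the original report. Used as
#' a reference input for the association statistics.
#'
#' @return 6x2 integer matrix (burden 0..5 x neutral/poor).
#' @export
#' @examples
#' colSums(reference_burden_distribution())
reference_burden_distribution <- function() {
  matrix(c(5L, 6L, 1L, 1L, 0L, 0L,
           2L, 4L, 5L, 8L, 2L, 1L),
         nrow = 6,
         dimnames = list(burden = c("0", "1", "2", "3", "4", "5+"),
                         phenotype = c("neutral", "poor")))
}

# log hypergeometric point probability of table [[x, r1-x], [c1-x, ...]]
log_hyper_prob <- function(x, r1, r2, c1) {
  lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Enumerates all tables with the observed margins; the two-sided p-value
#' is the total hypergeometric probability of tables no more probable than
#' the observed one (probability-mass ordering, the convention of most
#' statistical software, not tail doubling). Probabilities are computed in
#' log space for numerical stability.
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @return A `risk_test_result` (statistic and df are not applicable).
#' @export
#' @examples
#' fisher_exact_2x2(dichotomize(reference_burden_distribution()))
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("fisher_exact_2x2 requires a 2x2 table of non-negative counts",
          class = "lynchburden_stats_error")
  }
  r <- rowSums(tab)
  cs <- colSums(tab)
  if (any(r == 0) || any(cs == 0)) {
    abort("fisher_exact_2x2 requires positive margins",
          class = "lynchburden_stats_error")
  }
  support <- max(0, cs[1] - r[2]):min(r[1], cs[1])
  lp <- log_hyper_prob(support, r[1], r[2], cs[1])
  lp_obs <- log_hyper_prob(tab[1, 1], r[1], r[2], cs[1])
  # tolerance guards against ties broken by floating-point noise
  p <- sum(exp(lp[lp <= lp_obs + 1e-7]))
  new_test_result(NA_real_, NA_integer_, min(1, p), "fisher_exact_2x2")
}

#' Pearson chi-square test of independence
#'
#' Statistic \eqn{\sum (O - E)^2 / E} with expected counts from the
#' margins, no continuity correction; the p-value comes from the upper tail
#' of the chi-square distribution with `(r-1)(c-1)` degrees of freedom. A
#' warning (not an error) is emitted when any expected count falls below 5.
#'
#' @param tab r x c matrix of non-negative counts with positive margins.
#' @return A `risk_test_result`.
#' @export
#' @examples
#' pearson_chi_square(reference_burden_distribution())
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  r <- rowSums(tab)
  cs <- colSums(tab)
  if (any(r == 0) || any(cs == 0)) {
    abort("pearson_chi_square requires positive margins",
          class = "lynchburden_stats_error")
  }
  n <- sum(tab)
  expected <- outer(r, cs) / n
  if (any(expected < 5)) {
    warning("chi-square approximation: one or more expected counts below 5",
            call. = FALSE)
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  new_test_result(stat, df, p, "pearson_chi_square")
}

#' Two-sample t test
#'
#' Student's t with pooled variance (default) or Welch's unequal-variance
#' form; two-sided p-value from the t distribution.
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A `risk_test_result`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) {
    abort("two_sample_t requires at least two observations per group",
          class = "lynchburden_stats_error")
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  stat <- if (se == 0) 0 else (mean(x) - mean(y)) / se
  p <- 2 * pt(abs(stat), df = df, lower.tail = FALSE)
  new_test_result(stat, df, p,
                  if (var_equal) "student_t_pooled" else "welch_t")
}

#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival function per group on the age scale. At tied
#' times, events precede censorings. Curves start at 1 and are
#' non-increasing.
#'
#' @param records Tibble with `time` (positive), `event` (logical; at most
#'   one event per subject) and `group`.
#' @return A tibble with one row per distinct time per group: `group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival` (the estimate just
#'   after `time`).
#' @export
kaplan_meier <- function(records) {
  if (any(records$time <= 0)) {
    abort("survival times must be positive", class = "lynchburden_stats_error")
  }
  per_group <- lapply(split(seq_len(nrow(records)), records$group),
                      function(i) {
    tt <- records$time[i]
    ev <- records$event[i]
    times <- sort(unique(tt))
    n_risk <- vapply(times, function(u) sum(tt >= u), 0L)
    n_event <- vapply(times, function(u) sum(tt == u & ev), 0L)
    n_censor <- vapply(times, function(u) sum(tt == u & !ev), 0L)
    surv <- cumprod(1 - n_event / n_risk)
    tibble(group = records$group[i][1], time = times, n_risk = n_risk,
           n_event = n_event, n_censor = n_censor, survival = surv)
  })
  bind_rows(per_group)
}

#' Mantel-Cox log-rank test for two groups
#'
#' At each distinct event time the observed events in group 1 are compared
#' with the expectation under the hypergeometric model given the risk sets;
#' the statistic \eqn{(\sum (O_1 - E_1))^2 / \sum V} is referred to the
#' chi-square distribution with one degree of freedom.
#'
#' @param records As for [kaplan_meier()]; exactly two groups, at least one
#'   event overall.
#' @return A `risk_test_result`.
#' @export
log_rank <- function(records) {
  groups <- sort(unique(records$group))
  if (length(groups) != 2) {
    abort("log_rank requires exactly two groups",
          class = "lynchburden_stats_error")
  }
  if (!any(records$event)) {
    abort("log_rank requires at least one event",
          class = "lynchburden_stats_error")
  }
  tt <- records$time
  ev <- records$event
  g1 <- records$group == groups[1]
  times <- sort(unique(tt[ev]))
  o_minus_e <- 0
  v <- 0
  for (u in times) {
    n <- sum(tt >= u)
    n1 <- sum(tt >= u & g1)
    d <- sum(tt == u & ev)
    d1 <- sum(tt == u & ev & g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  stat <- if (v == 0) 0 else o_minus_e^2 / v
  p <- if (v == 0) 1 else pchisq(stat, df = 1, lower.tail = FALSE)
  new_test_result(stat, 1L, p, "log_rank_mantel_cox")
}

#' Build survival records from a classified cohort and burden profiles
#'
#' Time runs on the age scale (origin at birth). The endpoint is the first
#' qualifying event: any poor-phenotype feature (endometrial cancer before
#' the age cutoff, or a second tumor), the early endometrial cancer alone,
#' or the second tumor alone. Subjects without an event are censored at
#' `age_at_last_followup`; subjects with neither an event nor a follow-up
#' age are dropped with a warning. Groups are `low_burden` (at most `k - 1`
#' risk-variants) versus `high_burden`.
#'
#' @param subjects Classified cohort tibble (with `age_ec`, `tumors`,
#'   `age_at_last_followup`).
#' @param profiles Burden tibble from [burden()].
#' @param k Burden dichotomy threshold, default 2.
#' @param endpoint `"any_poor_feature"` (default), `"young_ec"` or
#'   `"second_tumor"`.
#' @param age_cutoff Young-onset cutoff, default 50.
#' @return Tibble with `subject_id`, `time`, `event`, `group`.
#' @export
survival_records <- function(subjects, profiles, k = 2,
                             endpoint = c("any_poor_feature", "young_ec",
                                          "second_tumor"),
                             age_cutoff = 50) {
  endpoint <- match.arg(endpoint)
  b <- profiles$n_risk_variants_non_mmr[
    match(subjects$subject_id, profiles$subject_id)]
  ev_age <- vapply(seq_len(nrow(subjects)), function(i) {
    ages <- numeric()
    if (endpoint %in% c("any_poor_feature", "young_ec")) {
      a <- subjects$age_ec[i]
      if (!is.na(a) && a < age_cutoff) ages <- c(ages, a)
    }
    if (endpoint %in% c("any_poor_feature", "second_tumor")) {
      tt <- subjects$tumors[[i]]
      other <- tt$age_at_diagnosis[tt$site != "endometrium"]
      other <- other[!is.na(other)]
      if (length(other) > 0) ages <- c(ages, min(other))
    }
    if (length(ages) == 0) NA_real_ else min(ages)
  }, 0)
  event <- !is.na(ev_age)
  time <- ifelse(event, ev_age, as.numeric(subjects$age_at_last_followup))
  keep <- !is.na(time)
  if (any(!keep)) {
    warn(paste0(sum(!keep), " subject(s) without event or follow-up age ",
                "dropped from survival records"))
  }
  tibble(
    subject_id = subjects$subject_id[keep],
    time = time[keep],
    event = event[keep],
    group = ifelse(b[keep] >= k, "high_burden", "low_burden")
  )
}
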