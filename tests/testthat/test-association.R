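test_that("burden tables cross-tabulate exact counts against phenotype", {
  profiles <- tibble::tibble(subject_id = c("A", "B", "C", "D"),
                             n_risk_variants_non_mmr = c(0L, 2L, 2L, 5L))
  phen <- tibble::tibble(subject_id = c("A", "B", "C", "D"),
                         phenotype = c("neutral", "poor", "poor", "poor"))
  tab <- burden_table(profiles, phen)
  expect_equal(dim(tab), c(6L, 2L))
  expect_equal(colSums(tab), c(neutral = 1L, poor = 3L))
  expect_equal(unname(tab["2", ]), c(0L, 2L))

  expect_error(burden_table(profiles[0, ], phen),
               class = "lynchburden_stats_error")
  expect_error(burden_table(profiles, phen[1:2, ]), "subject",
               class = "lynchburden_stats_error")

  one <- burden_table(profiles[2, ], phen)
  expect_equal(sum(one), 1)
})

test_that("the published burden distribution dichotomizes to the printed 2x2", {
  tab <- reference_burden_distribution()
  expect_equal(unname(colSums(tab)), c(13L, 22L))

  d2 <- dichotomize(tab, k = 2)
  expect_equal(unname(d2), matrix(c(11L, 2L, 6L, 16L), 2))

  d1 <- dichotomize(tab, k = 1)
  expect_equal(unname(d1), matrix(c(5L, 8L, 2L, 20L), 2))

  # margins preserved for any k
  for (k in 1:5) {
    expect_equal(colSums(dichotomize(tab, k)), colSums(tab))
  }
  expect_error(dichotomize(tab, k = 10), class = "lynchburden_stats_error")
})

test_that("Fisher's exact test reproduces the published p and its invariances", {
  d <- dichotomize(reference_burden_distribution(), k = 2)
  expect_equal(round(fisher_exact_2x2(d)$p_value, 4), 0.0016)

  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  # exhaustive-enumeration oracle on a small table
  t31 <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact_2x2(t31)$p_value, oracle_fisher_p(t31),
               tolerance = 1e-12)

  set.seed(5)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6) + 1, 2)
    p <- fisher_exact_2x2(m)$p_value
    expect_equal(p, oracle_fisher_p(m), tolerance = 1e-10)
    # agreement with the independent reference implementation
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-10)
    # invariant to transposition and simultaneous row+column swap
    expect_equal(fisher_exact_2x2(t(m))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m[2:1, 2:1])$p_value, p,
                 tolerance = 1e-12)
    # hypergeometric masses over the enumeration sum to one
    r <- rowSums(m); cs <- colSums(m)
    supp <- max(0, cs[1] - r[2]):min(r[1], cs[1])
    masses <- exp(lynchburden:::log_hyper_prob(supp, r[1], r[2], cs[1]))
    expect_equal(sum(masses), 1, tolerance = 1e-12)
  }

  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)),
               class = "lynchburden_stats_error")
})

test_that("the chi-square test reproduces the published 6x2 statistic", {
  tab <- reference_burden_distribution()
  res <- suppressWarnings(pearson_chi_square(tab))
  expect_equal(round(res$statistic, 3), 11.225)
  expect_equal(res$df, 5L)
  expect_equal(round(res$p_value, 4), 0.0471)

  # zero when the table equals its expected counts
  even <- matrix(c(10, 20, 30, 5, 10, 15), 3)
  expect_equal(pearson_chi_square(even)$statistic, 0)

  # permutation invariance and agreement with the reference implementation
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(12, 9) + 1, 4)
    res <- pearson_chi_square(m)
    perm <- pearson_chi_square(m[sample(4), sample(3)])
    expect_equal(perm$statistic, res$statistic, tolerance = 1e-12)
    ref <- stats::chisq.test(m, correct = FALSE)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }

  expect_warning(pearson_chi_square(matrix(c(2, 3, 4, 1), 2)),
                 "expected counts")
})

test_that("the two-sample t test matches its closed form", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)

  res <- two_sample_t(c(0, 1), c(10, 11))
  expect_lt(res$p_value, 0.01)
  ref <- stats::t.test(c(0, 1), c(10, 11), var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  w <- two_sample_t(c(0, 1, 4), c(10, 11, 30), var_equal = FALSE)
  refw <- stats::t.test(c(0, 1, 4), c(10, 11, 30))
  expect_equal(w$p_value, refw$p.value, tolerance = 1e-12)
  expect_equal(w$df, unname(refw$parameter), tolerance = 1e-12)

  expect_error(two_sample_t(1, c(2, 3)), class = "lynchburden_stats_error")
})

test_that("the product-limit estimator handles censoring and ties", {
  # all censored: the curve stays at 1
  d <- tibble::tibble(subject_id = as.character(1:4),
                      time = c(50, 60, 70, 80), event = FALSE, group = "g")
  expect_true(all(kaplan_meier(d)$survival == 1))

  # single event among n subjects steps to (n-1)/n
  d$event[1] <- TRUE
  km <- kaplan_meier(d)
  expect_equal(km$survival[km$time == 50], 3 / 4)

  # without censoring the curve equals 1 - ECDF just after each time
  set.seed(2)
  tt <- sample(40:80, 12, replace = TRUE)
  d2 <- tibble::tibble(subject_id = as.character(1:12), time = tt,
                       event = TRUE, group = "g")
  km2 <- kaplan_meier(d2)
  ecdf_fn <- stats::ecdf(tt)
  expect_equal(km2$survival, 1 - ecdf_fn(km2$time), tolerance = 1e-12)

  expect_error(kaplan_meier(tibble::tibble(subject_id = "a", time = 0,
                                           event = TRUE, group = "g")),
               class = "lynchburden_stats_error")
})

test_that("the log-rank test is exact on degenerate and hand-computed cases", {
  # two identical groups: statistic 0, p exactly 1
  base <- tibble::tibble(subject_id = as.character(1:6),
                         time = c(50, 55, 60, 50, 55, 60),
                         event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                         group = rep(c("a", "b"), each = 3))
  res <- log_rank(base)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # all events early in one group: large statistic, small p
  sep <- tibble::tibble(subject_id = as.character(1:10),
                        time = c(41:45, 71:75),
                        event = c(rep(TRUE, 5), rep(FALSE, 5)),
                        group = rep(c("a", "b"), each = 5))
  expect_lt(log_rank(sep)$p_value, 0.01)

  # six-subject toy dataset against a hand-computed O/E/V table:
  # events at t=50 (a), t=60 (b), t=70 (a); censored: a@65, b@75, b@80
  toy <- tibble::tibble(
    subject_id = as.character(1:6),
    time = c(50, 70, 65, 60, 75, 80),
    event = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    group = c("a", "a", "a", "b", "b", "b"))
  # t=50: n=6, n_a=3, d=1, e_a=1/2, v=1/4
  # t=60: n=5, n_a=2, d=1, e_a=2/5, v=(2/5)(3/5)=6/25
  # t=70: n=3, n_a=1, d=1, e_a=1/3, v=(1/3)(2/3)=2/9
  o_minus_e <- (1 - 1 / 2) + (0 - 2 / 5) + (1 - 1 / 3)
  v <- 1 / 4 + 6 / 25 + 2 / 9
  res_toy <- log_rank(toy)
  expect_equal(res_toy$statistic, o_minus_e^2 / v, tolerance = 1e-12)

  expect_error(log_rank(base[base$group == "a", ]),
               class = "lynchburden_stats_error")
})

test_that("survival machinery agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(42)
  worst_km <- 0
  worst_lr <- 0
  for (i in 1:100) {
    n <- sample(6:40, 1)
    d <- tibble::tibble(subject_id = as.character(1:n),
                        time = round(runif(n, 30, 90), 1),
                        event = runif(n) < 0.7,
                        group = sample(c("a", "b"), n, replace = TRUE))
    if (length(unique(d$group)) < 2 || !any(d$event)) next
    km <- kaplan_meier(d)
    sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
    sm <- summary(sf, times = km$time[km$group == "a"], extend = TRUE)
    worst_km <- max(worst_km,
                    max(abs(km$survival[km$group == "a"] -
                              sm$surv[sm$strata == "group=a"])))
    sd1 <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    worst_lr <- max(worst_lr, abs(sd1$chisq - log_rank(d)$statistic))
  }
  expect_lt(worst_km, 1e-8)
  expect_lt(worst_lr, 1e-8)
})

test_that("survival records build on the age scale with burden groups", {
  subjects <- make_subjects(c("S1", "S2", "S3"), mmr_gene = "MSH6")
  subjects$age_ec <- c(45L, 60L, 58L)
  subjects$tumors <- list(
    tibble::tibble(site = "endometrium", age_at_diagnosis = 45L),
    tibble::tibble(site = c("endometrium", "colorectum"),
                   age_at_diagnosis = c(60L, 52L)),
    tibble::tibble(site = "endometrium", age_at_diagnosis = 58L))
  subjects$age_at_last_followup <- c(70L, 72L, 66L)
  profiles <- tibble::tibble(subject_id = c("S1", "S2", "S3"),
                             n_risk_variants_non_mmr = c(3L, 2L, 0L))
  sr <- survival_records(subjects, profiles)
  expect_equal(sr$time, c(45, 52, 66))
  expect_equal(sr$event, c(TRUE, TRUE, FALSE))
  expect_equal(sr$group, c("high_burden", "high_burden", "low_burden"))

  # endpoint restricted to the second tumor ignores the young diagnosis
  sr2 <- survival_records(subjects, profiles, endpoint = "second_tumor")
  expect_equal(sr2$event, c(FALSE, TRUE, FALSE))
  expect_equal(sr2$time[1], 70)
})
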