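test_that("median split labels below/at-above with ties to high", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 2, 9)), c("low", "high", "high", "high"))
  expect_error(median_split(c(5, 5, 5, 5)), "empty group")
  expect_error(median_split(3), "2 finite")
})

test_that("KM closed form: three events, no censoring", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$median, 2)
  # no censoring: KM equals the empirical survival function
  set.seed(1)
  t_ <- rexp(40)
  km2 <- km_estimate(t_, rep(1, 40))
  emp <- vapply(km2$time, function(tt) mean(t_ > tt), numeric(1))
  expect_equal(km2$surv, emp)
})

test_that("all-censored data give a flat survivor curve, median undefined", {
  km <- km_estimate(c(5, 8, 13), c(0, 0, 0))
  expect_length(km$time, 0)
  expect_true(is.na(km$median))
  expect_equal(km$events, 0)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM matches the independent product-limit oracle exactly", {
  d <- random_surv_fixture(20, seed = 4, round_times = TRUE)
  km <- km_estimate(d)
  orc <- oracle_km(d$time, d$event)
  expect_equal(km$time, orc$time)
  expect_equal(km$surv, orc$surv, tolerance = 1e-12)
})

test_that("KM curve, SE and CI agree with the survival package", {
  for (seed in c(2, 3)) {
    d <- random_surv_fixture(50, seed = seed, round_times = (seed == 3))
    km <- km_estimate(d)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                            conf.type = "log-log")
    ss <- summary(sf, times = km$time)
    expect_equal(km$surv, ss$surv, tolerance = 1e-6)
    fin <- is.finite(ss$std.err)
    expect_equal(km$se[fin], ss$std.err[fin], tolerance = 1e-6)
    fin <- is.finite(ss$lower)
    expect_equal(km$lower[fin], ss$lower[fin], tolerance = 1e-6)
    expect_equal(km$upper[fin], ss$upper[fin], tolerance = 1e-6)
    expect_equal(km$median, unname(stats::quantile(sf, 0.5)$quantile))
  }
})

test_that("log-rank is zero for identical groups and label-invariant", {
  d <- data.frame(time = c(1, 2, 3, 1, 2, 3), event = rep(1, 6))
  lr <- logrank_test(d, rep(c("a", "b"), each = 3))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  d2 <- random_surv_fixture(40, seed = 6)
  lr1 <- logrank_test(d2, d2$g)
  lr2 <- logrank_test(d2, 1 - d2$g)
  expect_equal(lr1$chisq, lr2$chisq, tolerance = 1e-12)
})

test_that("log-rank agrees with the survival package on random fixtures", {
  for (seed in 1:5) {
    d <- random_surv_fixture(60, seed = seed, round_times = seed %% 2 == 0)
    lr <- logrank_test(d, d$g)
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
    expect_equal(lr$chisq, sd_$chisq, tolerance = 1e-9)
  }
  # three groups
  d <- random_surv_fixture(90, seed = 11)
  g3 <- rep(c("a", "b", "c"), 30)
  lr <- logrank_test(d, g3)
  sd_ <- survival::survdiff(survival::Surv(d$time, d$event) ~ g3)
  expect_equal(lr$df, 2)
  expect_equal(lr$chisq, sd_$chisq, tolerance = 1e-9)
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
  set.seed(13)
  n <- 12
  d <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.8),
                  x = rbinom(n, 1, 0.5))
  if (sum(d$event) == 0) d$event[1] <- 1
  fit <- cox_fit(d, "x")
  b_grid <- oracle_cox_grid_1cov(d$time, d$event, d$x)
  expect_equal(unname(coef(fit)), b_grid, tolerance = 1e-4)
})

test_that("Cox fit agrees with coxph for both tie methods", {
  for (seed in 1:5) {
    d <- random_surv_fixture(60, seed = seed, round_times = TRUE)
    for (ties in c("efron", "breslow")) {
      fit <- cox_fit(d, c("x", "g"), ties = ties)
      ref <- survival::coxph(survival::Surv(time, event) ~ x + g, data = d,
                             ties = ties)
      expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(fit$coefficients$se, unname(sqrt(diag(stats::vcov(ref)))),
                   tolerance = 1e-6)
      expect_equal(unname(fit$loglik["final"]), ref$loglik[2],
                   tolerance = 1e-6)
    }
  }
})

test_that("symmetric groups give a zero coefficient", {
  d <- data.frame(time = rep(c(1, 2, 5, 7), 2), event = rep(c(1, 1, 1, 0), 2),
                  x = rep(c(0, 1), each = 4))
  fit <- cox_fit(d, "x")
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$beta))
})

test_that("Cox score test at zero equals the log-rank statistic", {
  # classical identity, exact without ties under Breslow weighting
  for (seed in c(21, 22, 23)) {
    d <- random_surv_fixture(50, seed = seed)
    st <- cox_score_test(d, "g", ties = "breslow")
    lr <- logrank_test(d, d$g)
    expect_equal(st$chisq, lr$chisq, tolerance = 1e-6)
  }
})

test_that("Cox fit rejects degenerate inputs and flags separation", {
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
                  x = c(1, 1, 1, 1))
  expect_error(cox_fit(d, "x"), "constant")
  expect_error(cox_fit(data.frame(time = 1:4, event = 0, x = rnorm(4)), "x"),
               "at least one event")
  # perfectly separated covariate: events strictly ordered by x
  sep <- data.frame(time = 1:8, event = rep(1, 8), x = 8:1)
  expect_error(cox_fit(sep, "x"), "converge|monotone")
})

test_that("backward elimination removes noise and respects boundaries", {
  cc <- cohort_config(n_patients = 300, censoring_rate = 0.2,
                      log_hazard_ratio_per_group = log(3),
                      covariates = list(
                        list(name = "noise", dist = "normal", mean = 0,
                             sd = 1, loghr = 0)),
                      seed = 31)
  d <- simulate_cohort(cc)
  d$grp01 <- as.integer(d$group == "high")
  be <- backward_eliminate(d, c("grp01", "noise"))
  expect_true("noise" %in% be$removed)
  expect_false("grp01" %in% be$removed)
  expect_equal(be$final$coefficients$term, "grp01")
  # alpha_out = 1 never eliminates
  be1 <- backward_eliminate(d, c("grp01", "noise"), alpha_out = 1)
  expect_length(be1$removed, 0)
  expect_length(be1$path, 1)
  # strong signal only: path length 1
  be2 <- backward_eliminate(d, "grp01")
  expect_length(be2$path, 1)
  expect_length(be2$removed, 0)
})

test_that("noise covariates are eliminated first across seeds", {
  hit <- 0
  for (seed in 1:10) {
    cc <- cohort_config(n_patients = 200, censoring_rate = 0.2,
                        log_hazard_ratio_per_group = log(3),
                        covariates = list(
                          list(name = "noise", dist = "normal", loghr = 0)),
                        seed = seed)
    d <- simulate_cohort(cc)
    d$grp01 <- as.integer(d$group == "high")
    be <- backward_eliminate(d, c("grp01", "noise"))
    if (length(be$removed) && be$removed[1] == "noise") hit <- hit + 1
    else if (!length(be$removed)) hit <- hit + 1   # both retained is fine too
  }
  expect_gte(hit, 9)
})

test_that("cox_fit recovers a true hazard ratio of 2 from simulated cohorts", {
  ok <- 0; n_rep <- 20
  for (seed in 1:n_rep) {
    cc <- cohort_config(n_patients = 500, censoring_rate = 0.2,
                        log_hazard_ratio_per_group = log(2), seed = seed)
    d <- simulate_cohort(cc)
    d$grp01 <- as.integer(d$group == "high")
    hr <- exp(unname(coef(cox_fit(d, "grp01"))))
    if (hr >= 1.6 && hr <= 2.5) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("median-split comparison wires split, KM and log-rank together", {
  cc <- cohort_config(n_patients = 120, censoring_rate = 0.2,
                      log_hazard_ratio_per_group = log(4),
                      covariates = list(
                        list(name = "marker", dist = "normal", loghr = 0)),
                      seed = 41)
  d <- simulate_cohort(cc)
  # marker tracks the true group so the split is informative
  d$marker <- as.integer(d$group == "high") + rnorm(nrow(d), 0, 0.1)
  cmp <- compare_survival_by_marker(d, "marker")
  expect_named(cmp$km, c("high", "low"))
  expect_lt(cmp$logrank$p_value, 0.01)
})
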