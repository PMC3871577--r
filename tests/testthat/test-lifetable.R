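# Actuarial life table, incidence curves, annual rates, Peto log-rank,
# Pearson chi-square.

test_that("life table degenerate cases are exact", {
  # no events: CI stays 0
  lt0 <- build_life_table(rep(10.5, 100), rep(FALSE, 100))
  expect_equal(ci_at(lt0, 10), 0)
  # one subject, one event at year 5: CI jumps to 1 at t = 6
  lt1 <- build_life_table(5.3, TRUE)
  expect_equal(ci_at(lt1, 5), 0)
  expect_equal(ci_at(lt1, 6), 1)
  expect_error(build_life_table(numeric(0), logical(0)), "empty")
  expect_error(build_life_table(c(1, -2), c(TRUE, FALSE)), "positive")
})

test_that("without withdrawals the actuarial CI is the empirical fraction", {
  set.seed(31)
  for (i in 1:5) {
    n <- 400
    evt_time <- stats::runif(n, 0.2, 19.8)
    event <- stats::runif(n) < 0.4
    time <- ifelse(event, evt_time, 20.5)  # censorings all beyond t
    lt <- build_life_table(time, event)
    for (t in c(5, 10, 20)) {
      expect_equal(ci_at(lt, t), mean(event & evt_time < t),
                   tolerance = 1e-12)
    }
  }
})

test_that("curve values equal the interval product recomputed directly", {
  set.seed(32)
  time <- stats::rexp(500, 0.05); event <- stats::runif(500) < 0.6
  time <- pmin(time, 30); event <- event & time < 30
  time <- pmax(time, 0.01)
  lt <- build_life_table(time, event)
  # independent product oracle from the raw interval counts
  q <- lt$d / (lt$n - lt$w / 2)
  expect_equal(lt$ci, 1 - cumprod(1 - q), tolerance = 1e-12)
  cv <- cumulative_incidence_curve(lt)
  expect_equal(cv$ci, c(0, lt$ci))
  expect_true(all(diff(cv$ci) >= -1e-12))
  expect_true(all(cv$ci >= 0 & cv$ci <= 1))
  # accounting identity n_{k+1} = n_k - d_k - w_k
  expect_equal(lt$n[-1], (lt$n - lt$d - lt$w)[-nrow(lt)])
})

test_that("constant-hazard cohort recovers the exponential closed form", {
  df <- sim_exp_cohort(10000, 0.01, 40, seed = 41)
  lt <- build_life_table(df$observed_years, df$cwp_status)
  truth <- 1 - exp(-0.4)
  se <- sqrt(truth * (1 - truth) / 10000)
  expect_lt(abs(ci_at(lt, 40) - truth), 3 * se)
})

test_that("annual average incidence is CI over follow-up", {
  lt0 <- build_life_table(rep(41, 50), rep(FALSE, 50))
  expect_equal(annual_average_incidence(lt0, 40), 0)
  expect_error(annual_average_incidence(lt0, 60), "span")
  expect_error(annual_average_incidence(lt0, 0), "positive")
  # the paper-scale arithmetic: CI 0.32 over 40 y is 8.0 per mille per year
  expect_equal(0.32 / 40, 0.008)
})

test_that("generated subgroup recovers its configured annual rate", {
  r <- default_subgroup_rates(); r$annual_rate <- 2.1e-3
  spec <- cohort_spec(n_workers = 5000,
                      category_mix = c(tunneling = 0, mining = 1,
                                       combining = 0, helping = 0),
                      era_mix = c("1970-" = 1, "1980-" = 0, "1990-" = 0),
                      entry_range = as.Date(c("1971-12-31", "1971-12-31")),
                      duration_mean = 50, duration_sd = 1,
                      rates = r, seed = 55)
  g <- generate_cohort(spec)
  lt <- build_life_table(observation_window(g$cohort$workers),
                         g$cohort$workers$cwp_status)
  est <- annual_average_incidence(lt, 40)
  ci <- ci_at(lt, 40)
  se <- sqrt(max(ci, 1e-6) * (1 - ci) / 5000) / 40
  expect_lt(abs(est - 2.1e-3), 3 * se)
})

test_that("Peto log-rank is null on exchangeable groups and symmetric", {
  d <- data.frame(observed_years = c(3, 7.2, 11, 15.5, 20),
                  cwp_status = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  same <- peto_logrank(d, d)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  set.seed(61)
  a <- data.frame(observed_years = stats::runif(40, 1, 30),
                  cwp_status = stats::runif(40) < 0.5)
  b <- data.frame(observed_years = stats::runif(40, 1, 20),
                  cwp_status = stats::runif(40) < 0.3)
  expect_equal(peto_logrank(a, b)$statistic, peto_logrank(b, a)$statistic,
               tolerance = 1e-12)
  expect_error(peto_logrank(a, b[0, ]), "non-empty")
})

test_that("unit-weight variant equals the classic log-rank oracle", {
  # six subjects, hand-checkable; survdiff is the independent reference
  ta <- c(2, 4, 6); ea <- c(1, 0, 1)
  tb <- c(1, 3, 5); eb <- c(1, 1, 0)
  mine <- peto_logrank(ta, tb, ea, eb, weights = "unit")
  sd0 <- survival::survdiff(
    survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, each = 3), rho = 0)
  expect_equal(mine$statistic, sd0$chisq, tolerance = 1e-9)
  expect_equal(mine$statistic, 0.4864865, tolerance = 1e-6)
})

test_that("Peto log-rank separates a tenfold hazard contrast", {
  a <- sim_exp_cohort(2000, 0.02, 40, seed = 71)
  b <- sim_exp_cohort(2000, 0.002, 40, seed = 72)
  cmp <- peto_logrank(a, b)
  expect_lt(cmp$p_value, 0.001)
  expect_gt(cmp$statistic, 0)
})

test_that("Pearson chi-square reproduces contingency statistics", {
  occ <- rbind(c(248, 245, 259, 86), c(1137, 2559, 2022, 10467))
  expect_equal(pearson_chi2(occ)$statistic, 1168.1, tolerance = 0.05)
  era <- rbind(c(710, 112, 16), c(5854, 5798, 4533))
  expect_equal(pearson_chi2(era)$statistic, 806.0, tolerance = 0.05)
  expect_equal(pearson_chi2(occ)$df, 3L)
  # identical row proportions give 0
  expect_equal(pearson_chi2(rbind(c(10, 20, 30), c(20, 40, 60)))$statistic,
               0, tolerance = 1e-12)
  # permutation invariance and scaling
  perm <- occ[, c(3, 1, 4, 2)]
  expect_equal(pearson_chi2(perm)$statistic, pearson_chi2(occ)$statistic,
               tolerance = 1e-9)
  expect_equal(pearson_chi2(occ * 3)$statistic,
               3 * pearson_chi2(occ)$statistic, tolerance = 1e-9)
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "zero row")
  expect_error(pearson_chi2(matrix(1:3, 3, 1)), "2x2")
})

test_that("subgroup rate estimation covers observed era x category cells", {
  g <- generate_cohort(cohort_spec(n_workers = 2000, seed = 81))
  d <- derive_exposures(g$cohort)
  rates <- estimate_subgroup_rates(d)
  expect_true(all(rates$annual_rate >= 0))
  expect_equal(sum(rates$n), nrow(d))
  expect_true(all(rates$ci_at_followup <= 1))
})
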