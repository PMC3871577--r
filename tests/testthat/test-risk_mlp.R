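# Risk perceptron: splitting, training, prediction, metrics, importance,
# calibration, classification.

test_that("the 7:3 split is disjoint, exhaustive and reproducible", {
  d <- make_derived(1001, duration = rep(20, 1001), cde = rep(100, 1001),
                    status = rep(c(TRUE, FALSE), length.out = 1001))
  s1 <- split_data(d, 0.7, seed = 3)
  s2 <- split_data(d, 0.7, seed = 3)
  expect_identical(s1$train_idx, s2$train_idx)
  expect_equal(nrow(s1$train), round(0.7 * 1001))
  expect_length(intersect(s1$train$worker_id, s1$validation$worker_id), 0)
  expect_setequal(c(s1$train$worker_id, s1$validation$worker_id),
                  d$worker_id)
  expect_error(split_data(d[1:5, ], 0.7), "fewer than 10")
  expect_error(split_data(d, 1.2), "ratio")
})

test_that("training separates separable features and is seed-stable", {
  set.seed(101)
  n <- 1200
  status <- rep(c(TRUE, FALSE), each = n / 2)
  d <- make_derived(n,
                    duration = ifelse(status, stats::rnorm(n, 30, 2),
                                      stats::rnorm(n, 6, 2)),
                    cde = ifelse(status, stats::rnorm(n, 2000, 100),
                                 stats::rnorm(n, 60, 15)),
                    status = status)
  sp <- split_data(d, 0.7, seed = 7)
  m <- train_model(sp$train, hidden_units = 9, seed = 7)
  p <- predict_risk(m, sp$validation)
  acc <- confusion_metrics(p$probability, sp$validation$cwp_status,
                           0.5)$accuracy
  expect_gt(acc, 95)
  m2 <- train_model(sp$train, hidden_units = 9, seed = 7)
  expect_identical(m$net$wts, m2$net$wts)
  expect_error(train_model(sp$train[sp$train$cwp_status, ]), "both classes")
})

test_that("shuffled labels carry no signal (AUC near one half)", {
  set.seed(102)
  n <- 4000  # balanced classes so the null AUC standard error is small
  d <- make_derived(n, duration = stats::runif(n, 2, 40),
                    cde = stats::runif(n, 10, 3000),
                    status = sample(rep(c(TRUE, FALSE), n / 2)))
  sp <- split_data(d, 0.7, seed = 8)
  m <- train_model(sp$train, seed = 8)
  p <- predict_risk(m, sp$validation)
  expect_lt(abs(auc_rank(p$probability, sp$validation$cwp_status) - 0.5),
            0.05)
})

test_that("predictions are valid probabilities and deterministic", {
  d <- make_derived(200, duration = stats::runif(200, 2, 40),
                    cde = stats::runif(200, 1, 2000),
                    status = rep(c(TRUE, FALSE), 100))
  m <- train_model(d, seed = 5)
  p <- predict_risk(m, d)
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  dup <- rbind(d[7, ], d[7, ])
  pd <- predict_risk(m, dup)
  expect_equal(pd$probability[1], pd$probability[2])
  bad <- d[1, ]; bad$category <- "clerk"
  expect_error(predict_risk(m, bad), "unseen")
})

test_that("confusion metrics match their defining counts", {
  # printed-count arithmetic: 682 detected of 838 cases
  y <- rep(c(TRUE, FALSE), c(838, 1000))
  p <- c(rep(0.9, 682), rep(0.05, 156), rep(0.05, 1000))
  cm <- confusion_metrics(p, y, 0.2)
  expect_equal(round(cm$sensitivity, 1), 81.4)
  expect_equal(cm$tp, 682); expect_equal(cm$p, 838)
  # identity accuracy*N = sensitivity*P + specificity*Neg (in counts)
  expect_equal(cm$accuracy * cm$n,
               cm$sensitivity * cm$p + cm$specificity * cm$n_neg,
               tolerance = 1e-9)
  perfect <- confusion_metrics(as.numeric(y), y, 0.5)
  expect_equal(c(perfect$accuracy, perfect$sensitivity,
                 perfect$specificity), c(100, 100, 100))
  allneg <- confusion_metrics(rep(0, length(y)), y, 0.2)
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 100)
  expect_error(confusion_metrics(numeric(0), logical(0)), "empty")
})

test_that("permutation importance normalizes and nulls constant inputs", {
  set.seed(103)
  n <- 600
  status <- rep(c(TRUE, FALSE), each = n / 2)
  d <- make_derived(n,
                    duration = rep(20, n),  # constant input
                    cde = ifelse(status, stats::rnorm(n, 1500, 200),
                                 stats::rnorm(n, 100, 30)),
                    status = status,
                    category = rep("mining", n), era = rep("1980-", n))
  m <- train_model(d, seed = 11)
  w <- capture_warnings(imp <- variable_importance(m, d, seed = 11))
  expect_true(any(grepl("constant", w)))
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_equal(unname(imp["duration_of_exposure"]), 0)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "cde")
})

test_that("threshold calibration hits its targets on a known grid", {
  set.seed(105)
  expect_equal(calibrate_thresholds(stats::runif(5000), 844, 2500)$target_high,
               1266)
  # order-statistics oracle: uniform probabilities, half below 0.5
  p <- (seq_len(10000) - 0.5) / 10000
  cal <- calibrate_thresholds(p, projected_total = 200, low_pool_size = 5000,
                              grid = seq(0.05, 0.95, by = 0.05))
  expect_equal(cal$c_low, 0.5)
  expect_lt(cal$c_low, cal$c_high)
  expect_equal(cal$n_low, 5000)
  expect_error(calibrate_thresholds(rep(0, 100), 844, 50), "no cutoff")
  expect_error(calibrate_thresholds(numeric(0), 844, 50), "no probabilities")
})

test_that("risk classes partition workers with the boundary convention", {
  a <- data.frame(worker_id = letters[1:5],
                  probability = c(0.05, 0.15, 0.25, 0.1, 0.2))
  cl <- classify_risk(a, 0.1, 0.2)
  expect_equal(as.character(cl$risk_class),
               c("low", "middle", "high", "middle", "high"))
  expect_equal(sum(table(cl$risk_class)), nrow(a))
  expect_error(classify_risk(a, 0.3, 0.2), "below")
  # raising the high cutoff never increases the high-risk count
  set.seed(104)
  p <- data.frame(worker_id = sprintf("x%03d", 1:300),
                  probability = stats::runif(300))
  highs <- vapply(seq(0.2, 0.9, by = 0.1), function(ch)
    sum(classify_risk(p, 0.1, ch)$risk_class == "high"), numeric(1))
  expect_true(all(diff(highs) <= 0))
})

test_that("stratified risk report mirrors the classification", {
  g <- generate_cohort(cohort_spec(n_workers = 1500, seed = 15))
  d <- derive_exposures(g$cohort)
  nc <- d[!d$cwp_status, ]
  m <- train_model(d, seed = 15)
  cl <- classify_risk(predict_risk(m, nc), 0.1, 0.2)
  rep5 <- stratified_risk_report(cl, nc)
  expect_named(rep5, c("occupational_category", "era_of_first_exposure",
                       "duration_years", "cde_mg_years"))
  occ <- rep5$occupational_category
  expect_equal(sum(occ$n), nrow(nc))
  expect_equal(occ$n_low + occ$n_middle + occ$n_high, occ$n)
})
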