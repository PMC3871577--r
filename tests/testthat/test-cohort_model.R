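# Cohort data model: classification cascade, CDE, observation windows,
# file round-trips.

test_that("occupational classification follows the rule cascade", {
  # single consistent area
  expect_equal(classify_occupation(rep("helping", 3), c(10, 10, 10)),
               "helping")
  # tunneling more than half
  expect_equal(classify_occupation(c("tunneling", "helping"), c(12, 8)),
               "tunneling")
  # tunneling >= 2 y and <= half -> combining
  expect_equal(classify_occupation(c("tunneling", "mining", "helping"),
                                   c(3, 15, 2)), "combining")
  # tunneling < 2 y and mining more than half -> mining
  expect_equal(classify_occupation(c("tunneling", "mining", "helping"),
                                   c(1, 12, 7)), "mining")
  # fallback
  expect_equal(classify_occupation(c("tunneling", "mining", "helping"),
                                   c(1, 5, 14)), "helping")
  # boundary conventions: exactly half is not "more than half";
  # exactly 2 years of tunneling is combining-eligible
  expect_equal(classify_occupation(c("tunneling", "helping"), c(10, 10)),
               "combining")
  expect_equal(classify_occupation(c("tunneling", "mining"), c(2, 18)),
               "combining")
})

test_that("classification is total, deterministic and order-invariant", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    area <- sample(cwp_categories(), k, replace = TRUE)
    dur <- round(stats::runif(k, 0.5, 20), 3)
    c1 <- classify_occupation(area, dur)
    expect_true(c1 %in% cwp_categories())
    perm <- sample(k)
    expect_identical(classify_occupation(area[perm], dur[perm]), c1)
  }
})

test_that("classification rejects invalid segment lists", {
  expect_error(classify_occupation(character(), numeric()), "empty")
  expect_error(classify_occupation("mining", 0), "non-positive")
  expect_error(classify_occupation(c("mining", "x"), c(1, 1)), "unknown")
})

test_that("CDE is duration times concentration at constant rate", {
  start <- as.Date("1971-01-01")
  end <- start + 3653  # ten calendar years
  seg <- data.frame(area = "tunneling", start_date = start, end_date = end)
  conc <- data.frame(area = "tunneling", year_start = 1970, year_end = 1990,
                     geometric_mean_mg_m3 = 5, gsd = 1)
  expect_equal(compute_cde(seg, conc), as.numeric(end - start) / 365.25 * 5,
               tolerance = 1e-12)
  expect_identical(compute_cde(seg[0, ], conc), 0)
})

test_that("CDE equals a per-day brute-force sum over the calendar", {
  conc <- default_concentration_table()
  seg <- data.frame(
    area = c("tunneling", "mining", "helping"),
    start_date = as.Date(c("1978-03-15", "1981-06-02", "1992-11-20")),
    end_date = as.Date(c("1981-06-02", "1992-11-20", "2003-02-01")))
  # oracle: every calendar day contributes (1/365.25) x that year's GM
  oracle <- 0
  for (i in seq_len(nrow(seg))) {
    days <- seq(seg$start_date[i], seg$end_date[i] - 1, by = "day")
    yrs <- as.integer(format(days, "%Y"))
    for (y in unique(yrs)) {
      gm <- conc$geometric_mean_mg_m3[conc$area == seg$area[i] &
                                        conc$year_start <= y &
                                        conc$year_end >= y]
      oracle <- oracle + sum(yrs == y) / 365.25 * gm
    }
  }
  expect_equal(compute_cde(seg, conc), oracle, tolerance = 1e-9)
})

test_that("CDE is additive under splitting a segment at any date", {
  conc <- default_concentration_table()
  set.seed(7)
  for (i in 1:20) {
    start <- as.Date("1975-01-01") + sample.int(8000, 1)
    len <- sample(400:6000, 1)
    area <- sample(cwp_categories(), 1)
    whole <- data.frame(area = area, start_date = start,
                        end_date = start + len)
    cut_at <- start + sample.int(len - 1, 1)
    parts <- data.frame(area = area,
                        start_date = c(start, cut_at),
                        end_date = c(cut_at, start + len))
    expect_equal(compute_cde(parts, conc), compute_cde(whole, conc),
                 tolerance = 1e-9)
  }
})

test_that("unresolvable concentration cells are reported", {
  seg <- data.frame(area = "tunneling", start_date = as.Date("1960-01-01"),
                    end_date = as.Date("1962-01-01"))
  expect_error(compute_cde(seg, default_concentration_table()),
               "tunneling, 196")
})

test_that("observation windows cover cases and censored workers", {
  w <- data.frame(
    worker_id = c("a", "b"),
    first_exposure_date = as.Date(c("1975-01-01", "2010-01-01")),
    cwp_status = c(TRUE, FALSE),
    diagnosis_date = as.Date(c("2004-01-01", NA)),
    censor_date = as.Date(c(NA, "2011-12-31")))
  yrs <- observation_window(w)
  expect_equal(yrs[1], 29.0, tolerance = 0.01)  # the latency-scale case
  expect_equal(yrs[2], 2.0, tolerance = 0.01)
  # diagnosis before first exposure violates the record invariant
  w2 <- w[1, ]; w2$diagnosis_date <- as.Date("1970-01-01")
  expect_error(observation_window(w2), "non-positive")
  w3 <- w[1, ]; w3$diagnosis_date <- as.Date(NA)
  expect_error(observation_window(w3), "without diagnosis_date")
})

test_that("cohort files round-trip and reject malformed input", {
  g <- generate_cohort(cohort_spec(n_workers = 100, seed = 11))
  wf <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".csv")
  write_cohort(g$cohort, wf, sf)
  back <- read_cohort(wf, sf)
  expect_equal(back$workers, g$cohort$workers)
  expect_equal(back$segments, g$cohort$segments)

  # duplicate worker_id names the id
  w <- g$cohort$workers; w$worker_id[2] <- w$worker_id[1]
  s <- g$cohort$segments
  expect_error(cwp_cohort(w, s), w$worker_id[1])

  # header only -> empty cohort with a warning
  writeLines("worker_id,birth_year,first_exposure_date,cwp_status,diagnosis_date,censor_date",
             wf)
  writeLines("worker_id,area,start_date,end_date", sf)
  expect_warning(empty <- read_cohort(wf, sf), "header")
  expect_equal(nrow(empty$workers), 0L)

  # missing column
  writeLines(c("worker_id,birth_year", "a,1950"), wf)
  expect_error(read_cohort(wf, sf), "missing columns")
})

test_that("cohort validation enforces record invariants", {
  fix <- make_fixture("tiny")
  w <- fix$workers; s <- fix$segments
  # overlapping spells are rejected, not merged
  s2 <- rbind(s, data.frame(worker_id = s$worker_id[1], area = "mining",
                            start_date = s$start_date[1] + 10,
                            end_date = s$start_date[1] + 400))
  expect_error(cwp_cohort(w, s2), "overlap")
  # first_exposure_date must equal the earliest spell start
  w2 <- w; w2$first_exposure_date[1] <- w2$first_exposure_date[1] - 30
  expect_error(cwp_cohort(w2, s), "earliest segment")
  # under 1 year of exposure violates the inclusion rule
  s3 <- s; s3$end_date[1] <- s3$start_date[1] + 100
  expect_error(cwp_cohort(w, s3), "1 year")
})
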