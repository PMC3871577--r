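# Shared test helpers: small constructors and independent oracles.

# rank-based (Wilcoxon) AUC
auc_rank <- function(p, y) {
  y <- as.logical(y)
  r <- rank(p)
  (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
}

# derived-exposures-style frame with controllable feature/label structure
make_derived <- function(n, duration, cde, status,
                         category = NULL, era = NULL) {
  data.frame(
    worker_id = sprintf("S%05d", seq_len(n)),
    category = factor(if (is.null(category))
      rep(cwp_categories(), length.out = n) else category,
      levels = cwp_categories()),
    era = factor(if (is.null(era))
      rep(cwp_eras(), length.out = n) else era, levels = cwp_eras()),
    total_duration = duration,
    cde = cde,
    observed_years = pmax(duration, 1),
    cwp_status = as.logical(status),
    current_age = rep(45, n),
    stringsAsFactors = FALSE
  )
}

# exponential-hazard survival sample censored at a horizon, as a
# life-table input frame
sim_exp_cohort <- function(n, lambda, horizon, seed) {
  set.seed(seed)
  evt <- stats::rexp(n, lambda)
  data.frame(observed_years = pmin(evt, horizon),
             cwp_status = evt <= horizon)
}

# per-worker per-year brute-force projection oracle: accumulate the
# annual rate year by year into the age band and future-time window
project_oracle <- function(workers, rates, le,
                           age_breaks = c(-Inf, 20, 30, 40, 50, 60, Inf),
                           window_breaks = c(0, 10, 20, 30, Inf),
                           rate_map = c("1990-" = "1980-")) {
  era_eff <- as.character(workers$era)
  hit <- era_eff %in% names(rate_map) &
    !(paste(era_eff, workers$category) %in% paste(rates$era, rates$category))
  era_eff[hit] <- rate_map[era_eff[hit]]
  r <- rates$annual_rate[match(paste(era_eff, workers$category),
                               paste(rates$era, rates$category))]
  nb <- length(age_breaks) - 1L
  nw <- length(window_breaks) - 1L
  by_age <- matrix(0, 4, nb)
  by_window <- matrix(0, 4, nw)
  for (i in seq_len(nrow(workers))) {
    m <- max(0, le - workers$current_age[i])
    ci <- match(as.character(workers$category[i]), cwp_categories())
    bi <- findInterval(workers$current_age[i], age_breaks)
    y <- 0
    while (y < m) {
      frac <- min(1, m - y)
      wi <- findInterval(y, window_breaks)
      by_window[ci, wi] <- by_window[ci, wi] + r[i] * frac
      by_age[ci, bi] <- by_age[ci, bi] + r[i] * frac
      y <- y + 1
    }
  }
  list(by_age = by_age, by_window = by_window)
}
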