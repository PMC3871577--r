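# Projection of expected future CWP cases among workers without CWP, by
# occupational category x current-age band and x future-time window,
# within life expectancy.

#' Project expected new CWP cases within life expectancy
#'
#' Each worker without CWP, with subgroup annual rate `r`, current age `a`
#' and remaining years `m = max(0, LE(a) - a)`, contributes `r * m`
#' expected cases (linear, non-compounding accumulation — the constant
#' annual-average-rate assumption), allocated across future-time windows
#' proportionally to the years of `m` falling in each window, and counted
#' in the worker's current-age band. Workers older than their life
#' expectancy contribute 0. Entrants of an era with no estimated rate can
#' be mapped to another era's rates via `rate_map` (default: 1990-
#' entrants use the 1980- rates, the most recent estimate).
#'
#' @param workers data.frame of non-cases with `era`, `category`,
#'   `current_age` (e.g. [derive_exposures()] rows with
#'   `cwp_status == FALSE`).
#' @param rates data.frame `era`, `category`, `annual_rate` (per year),
#'   e.g. [estimate_subgroup_rates()] output or
#'   [default_subgroup_rates()].
#' @param life_expectancy Scalar years, or a data.frame `age`,
#'   `life_expectancy` (step lookup by current age).
#' @param age_breaks,age_labels Current-age display bands (default <20,
#'   20-29, 30-39, 40-49, 50-59, 60-).
#' @param window_breaks,window_labels Future-time windows (default <10,
#'   10-19, 20-29, 30-).
#' @param rate_map Named character vector mapping an era to the era whose
#'   rates it should use.
#' @param compounding If TRUE use `1 - (1 - r)^m` for the total (windows
#'   then allocate the per-year increments); default FALSE (linear).
#' @return list of class `cwp_projection`: `by_age` and `by_window`
#'   (category x band matrices of expected counts), `n_by_age`
#'   (worker counts per band), `worker_expected` (per-worker totals),
#'   `total`.
#' @export
project_cases <- function(workers, rates, life_expectancy = 74,
                          age_breaks = c(-Inf, 20, 30, 40, 50, 60, Inf),
                          age_labels = c("<20", "20-29", "30-39", "40-49",
                                         "50-59", "60-"),
                          window_breaks = c(0, 10, 20, 30, Inf),
                          window_labels = c("<10", "10-19", "20-29", "30-"),
                          rate_map = c("1990-" = "1980-"),
                          compounding = FALSE) {
  if (nrow(workers) == 0L) stop("no workers to project")
  era_eff <- as.character(workers$era)
  mapped <- era_eff %in% names(rate_map) &
    !(paste(era_eff, workers$category) %in%
        paste(rates$era, rates$category))
  era_eff[mapped] <- rate_map[era_eff[mapped]]
  key <- paste(era_eff, workers$category)
  r <- rates$annual_rate[match(key, paste(rates$era, rates$category))]
  if (anyNA(r))
    stop("no rate for subgroup(s): ",
         paste(unique(key[is.na(r)]), collapse = ", "))
  le <- if (is.data.frame(life_expectancy)) {
    idx <- findInterval(workers$current_age, life_expectancy$age)
    life_expectancy$life_expectancy[pmax(idx, 1L)]
  } else rep(life_expectancy, nrow(workers))
  m <- pmax(0, le - workers$current_age)
  expected <- if (compounding) 1 - (1 - r)^m else r * m

  cat_f <- factor(as.character(workers$category), levels = cwp_categories())
  band <- cut(workers$current_age, breaks = age_breaks, labels = age_labels,
              right = FALSE)
  by_age <- tapply(expected, list(cat_f, band), sum, default = 0)
  n_by_age <- table(cat_f, band)

  nw <- length(window_labels)
  by_window <- matrix(0, 4, nw,
                      dimnames = list(cwp_categories(), window_labels))
  for (j in seq_len(nw)) {
    yrs_in <- pmin(m, window_breaks[j + 1]) - pmin(m, window_breaks[j])
    contrib <- if (compounding) {
      # per-window share of the compounded total, proportional to the
      # survival-discounted person-years in the window
      expected * yrs_in / ifelse(m > 0, m, 1)
    } else r * yrs_in
    by_window[, j] <- tapply(contrib, cat_f, sum, default = 0)
  }
  out <- list(by_age = unclass(by_age), by_window = by_window,
              n_by_age = unclass(n_by_age),
              worker_expected = data.frame(worker_id = workers$worker_id,
                                           expected = expected),
              total = sum(expected))
  if (!compounding &&
      abs(sum(out$by_age) - sum(out$by_window)) >
        1e-9 * max(1, sum(out$by_age)))
    stop("internal error: age and window partitions disagree")
  class(out) <- "cwp_projection"
  out
}

#' @export
print.cwp_projection <- function(x, ...) {
  cat("Projected new CWP cases:", round(x$total, 1), "\n")
  cat("\nBy current-age band:\n"); print(round(x$by_age, 1))
  cat("\nBy future-time window:\n"); print(round(x$by_window, 1))
  invisible(x)
}

#' Summarise a projection table with totals and percentages
#'
#' Appends a column-total row and expresses the totals as percentages of
#' the supplied denominators (worker counts per band, or a single cohort
#' size).
#'
#' @param counts A category x band matrix of expected counts (one of the
#'   matrices of a [project_cases()] result, or printed table values).
#' @param denominators Positive worker counts: one per column, or a
#'   single cohort total.
#' @return list: `table` (counts with a Total row), `percent` (per-column
#'   totals as % of the denominators), `grand_total`, `grand_percent`.
#' @export
summarize_projection <- function(counts, denominators) {
  counts <- as.matrix(counts)
  if (any(denominators <= 0)) stop("denominators must be positive")
  tot <- colSums(counts)
  grand <- sum(tot)
  if (length(denominators) == 1L) {
    grand_den <- denominators
    pct <- 100 * tot / denominators
  } else {
    if (length(denominators) != ncol(counts))
      stop("need one denominator per column (or a single total)")
    grand_den <- sum(denominators)
    pct <- 100 * tot / denominators
  }
  list(table = rbind(counts, Total = tot), percent = pct,
       grand_total = grand, grand_percent = 100 * grand / grand_den)
}
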