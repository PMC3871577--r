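# Synthetic cohort generator: occupational dust-exposure cohorts with the
# structure the downstream analyses assume (entry eras, category mix,
# age-at-entry and latency distributions, declining concentrations, per
# subgroup annual incidence), with ground truth recorded for every worker.

#' Default per-subgroup annual incidence rates
#'
#' Annual average incidence of CWP per (era of first exposure x
#' occupational category), as per-year probabilities. The 1970- entrants
#' carry 8.1/8.0/6.5/0.6 per 1000 (tunneling/mining/combining/helping);
#' 1980- and 1990- entrants carry 1.7/2.1/1.4/0.3 per 1000.
#'
#' @return data.frame with columns `era`, `category`, `annual_rate`.
#' @export
default_subgroup_rates <- function() {
  out <- expand.grid(category = cwp_categories(), era = cwp_eras(),
                     stringsAsFactors = FALSE)[, c("era", "category")]
  out$annual_rate <- c(8.1, 8.0, 6.5, 0.6,
                       1.7, 2.1, 1.4, 0.3,
                       1.7, 2.1, 1.4, 0.3) / 1000
  out
}

#' Specification of a synthetic occupational cohort
#'
#' Defaults emulate the study cohort: 17,023 workers, category mix from the
#' non-case margins (7.0/15.8/12.5/64.7%), entry-era mix 36.2/35.8/28.0%,
#' age at first exposure 21.4 +/- 4.0 y truncated to [16, 40], latency
#' 29.1 +/- 5.3 y truncated at >= 5 y, follow-up to 2011-12-31, and the
#' per-subgroup annual incidence rates of [default_subgroup_rates()].
#'
#' @param n_workers Cohort size.
#' @param category_mix Named proportions over the four categories.
#' @param era_mix Named proportions over the three entry eras.
#' @param age_mean,age_sd,age_bounds Age at first exposure: truncated
#'   normal parameters (years).
#' @param latency_mean,latency_sd,latency_min Onset-delay distribution for
#'   workers destined for CWP (years; normal truncated at `latency_min`).
#' @param duration_mean,duration_sd Exposure-career duration (years;
#'   truncated to [1, years available before study end]).
#' @param rates Subgroup annual rates (data.frame `era`, `category`,
#'   `annual_rate` as per-year probabilities).
#' @param onset Onset model. `"linear"` (default): conversion by exposed
#'   year t with probability rate*t, i.e. the constant annual-average-rate
#'   model the rate summaries assume; `"exponential"`: a true
#'   constant-hazard (exponential) event-time process at the subgroup
#'   rate; `"cde"`: dose-response regime where conversion probability is
#'   logistic in log10(CDE), giving the risk model a learnable
#'   exposure signal.
#' @param cde_onset_pars Intercept and slope of the logistic dose-response
#'   (on log10(CDE + 1)) for `onset = "cde"`.
#' @param life_expectancy Years; used by the projection stage.
#' @param study_end Administrative censoring date.
#' @param entry_range Optional Date pair overriding era-based entry
#'   sampling (entry drawn uniformly in the range); used to pin follow-up.
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_workers = 17023,
                        category_mix = c(tunneling = 0.070, mining = 0.158,
                                         combining = 0.125, helping = 0.647),
                        era_mix = c("1970-" = 0.362, "1980-" = 0.358,
                                    "1990-" = 0.280),
                        age_mean = 21.4, age_sd = 4.0,
                        age_bounds = c(16, 40),
                        latency_mean = 29.1, latency_sd = 5.3,
                        latency_min = 5,
                        duration_mean = 23.0, duration_sd = 10.4,
                        rates = default_subgroup_rates(),
                        onset = c("linear", "exponential", "cde"),
                        cde_onset_pars = c(intercept = -3.5, slope = 1.2),
                        life_expectancy = 74,
                        study_end = as.Date("2011-12-31"),
                        entry_range = NULL,
                        seed = 1L) {
  onset <- match.arg(onset)
  if (abs(sum(category_mix) - 1) > 1e-6 || abs(sum(era_mix) - 1) > 1e-6)
    stop("category_mix and era_mix must each sum to 1")
  if (any(category_mix < 0) || any(era_mix < 0) ||
      sum(category_mix) == 0 || sum(era_mix) == 0)
    stop("infeasible mix")
  if (any(rates$annual_rate < 0)) stop("negative annual rate")
  structure(list(
    n_workers = n_workers, category_mix = category_mix, era_mix = era_mix,
    age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
    latency_mean = latency_mean, latency_sd = latency_sd,
    latency_min = latency_min,
    duration_mean = duration_mean, duration_sd = duration_sd,
    rates = rates, onset = onset, cde_onset_pars = cde_onset_pars,
    life_expectancy = life_expectancy, study_end = as.Date(study_end),
    entry_range = entry_range, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# truncated-normal sampler (vectorized rejection)
#' @keywords internal
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Sample a dust concentration measurement
#'
#' Lognormal draw around the decade-block geometric mean for the given
#' area and calendar year, with sdlog = log(gsd) where the geometric SD is
#' back-solved from the +1/-1 SD monitoring columns. With `noise = FALSE`
#' the geometric mean itself is returned.
#'
#' @param area Work area(s). @param year Calendar year(s).
#' @param conc Concentration table.
#' @param noise Draw lognormal noise? (default TRUE)
#' @return Positive concentration(s) in mg/m3.
#' @export
sample_concentration <- function(area, year,
                                 conc = default_concentration_table(),
                                 noise = TRUE) {
  n <- max(length(area), length(year))
  area <- rep_len(area, n); year <- rep_len(year, n)
  gm <- conc_lookup(conc, area, year)
  if (!noise) return(gm)
  gsd <- rep(NA_real_, n)
  for (i in seq_len(nrow(conc))) {
    hit <- area == conc$area[i] &
      year >= conc$year_start[i] & year <= conc$year_end[i]
    gsd[hit] <- conc$gsd[i]
  }
  if (anyNA(gsd)) gsd[is.na(gsd)] <- 1
  stats::rlnorm(n, meanlog = log(gm), sdlog = log(gsd))
}

#' Generate a synthetic cohort with ground truth
#'
#' Each worker receives an entry era and occupational category from the
#' configured mixes, an entry date uniform within the era, a birth year
#' from the age-at-entry distribution, and a job-spell history constructed
#' so that the classification cascade genuinely returns the assigned
#' category. CWP conversion follows the configured onset model at the
#' worker's subgroup rate over the exposed years; converted workers are
#' diagnosed at entry + latency (or at the exponential event time) if that
#' falls before study end, otherwise censored as non-cases.
#'
#' @param spec A [cohort_spec()].
#' @return list with `cohort` (a [cwp_cohort()]), `truth` (data.frame:
#'   `worker_id`, `era`, `category`, `true_rate`, `exposed_years`,
#'   `converted`, `cwp_status`) and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_workers
  id <- sprintf("W%06d", seq_len(n))
  era <- sample(names(spec$era_mix), n, replace = TRUE, prob = spec$era_mix)
  category <- sample(names(spec$category_mix), n, replace = TRUE,
                     prob = spec$category_mix)

  if (is.null(spec$entry_range)) {
    lo <- as.Date(c("1970-" = "1970-01-01", "1980-" = "1980-01-01",
                    "1990-" = "1990-01-01")[era])
    hi <- as.Date(c("1970-" = "1979-12-31", "1980-" = "1989-12-31",
                    "1990-" = "2010-12-31")[era])
  } else {
    lo <- rep(as.Date(spec$entry_range[1]), n)
    hi <- rep(as.Date(spec$entry_range[2]), n)
  }
  entry <- lo + floor(stats::runif(n) * (as.numeric(hi - lo) + 1))
  era <- era_of_year(year_of(entry))

  age <- rtnorm(n, spec$age_mean, spec$age_sd,
                spec$age_bounds[1], spec$age_bounds[2])
  birth_year <- year_of(entry) - as.integer(round(age))

  follow <- interval_years(entry, spec$study_end)
  dur <- pmax(1.001, pmin(stats::rnorm(n, spec$duration_mean,
                                       spec$duration_sd), follow))

  seg <- build_career_segments(id, category, entry, dur)

  # subgroup rate lookup
  key <- paste(era, category)
  rkey <- paste(spec$rates$era, spec$rates$category)
  rate <- spec$rates$annual_rate[match(key, rkey)]
  if (anyNA(rate))
    stop("no configured rate for subgroup(s): ",
         paste(unique(key[is.na(rate)]), collapse = ", "))

  u <- stats::runif(n)
  latency <- rtnorm(n, spec$latency_mean, spec$latency_sd,
                    lower = spec$latency_min)
  if (spec$onset == "linear") {
    converted <- u < pmin(1, rate * dur)
    evt_time <- latency
  } else if (spec$onset == "exponential") {
    evt_time <- ifelse(rate > 0, -log(u) / rate, Inf)
    converted <- evt_time <= dur
  } else { # cde dose-response
    cde <- as.numeric(cde_by_worker(seg, default_concentration_table())[id])
    p <- stats::plogis(spec$cde_onset_pars[["intercept"]] +
                         spec$cde_onset_pars[["slope"]] * log10(cde + 1))
    converted <- u < p
    evt_time <- latency
  }
  is_case <- converted & evt_time <= follow
  diag_date <- entry + pmax(1, floor(evt_time * 365.25))
  diag_date[!is_case] <- NA

  workers <- data.frame(
    worker_id = id, birth_year = birth_year, first_exposure_date = entry,
    cwp_status = is_case, diagnosis_date = as.Date(diag_date),
    censor_date = as.Date(ifelse(is_case, NA, as.character(spec$study_end))),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    worker_id = id, era = era, category = category, true_rate = rate,
    exposed_years = dur, converted = converted, cwp_status = is_case,
    stringsAsFactors = FALSE
  )
  list(cohort = cwp_cohort(workers, seg), truth = truth, spec = spec)
}

# Build job-spell tables whose classification matches the assigned
# category by construction (with margins so day-rounding cannot flip a
# boundary rule).
#' @keywords internal
build_career_segments <- function(id, category, entry, dur) {
  n <- length(id)
  d1 <- d2 <- d3 <- numeric(n)
  a1 <- a2 <- a3 <- rep(NA_character_, n)
  u_single <- stats::runif(n)

  i <- category == "tunneling"
  single <- u_single[i] < 0.3 | dur[i] < 3
  f <- stats::runif(sum(i), 0.55, 0.95)
  d1[i] <- ifelse(single, dur[i], f * dur[i]); a1[i] <- "tunneling"
  d2[i] <- ifelse(single, 0, (1 - f) * dur[i]); a2[i] <- "helping"

  i <- category == "mining"
  single <- u_single[i] < 0.3 | dur[i] < 3
  t <- ifelse(single, 0, stats::runif(sum(i)) * pmin(1.5, 0.2 * dur[i]))
  h <- ifelse(single, 0, stats::runif(sum(i)) * 0.2 * dur[i])
  d1[i] <- t; a1[i] <- "tunneling"
  d2[i] <- dur[i] - t - h; a2[i] <- "mining"
  d3[i] <- h; a3[i] <- "helping"

  i <- category == "combining"
  single <- u_single[i] < 0.3 | dur[i] < 4.5
  hi <- pmax(pmin(dur[i] / 2, 8), 2.2)
  t <- ifelse(single, 0, stats::runif(sum(i), 2.1, hi))
  d1[i] <- t; a1[i] <- "tunneling"
  d2[i] <- dur[i] - t; a2[i] <- "combining"

  i <- category == "helping"
  single <- u_single[i] < 0.7 | dur[i] < 3
  t <- ifelse(single, 0, stats::runif(sum(i)) * pmin(1.5, 0.15 * dur[i]))
  m <- ifelse(single, 0, stats::runif(sum(i), 0.1, 0.45) * dur[i])
  d1[i] <- t; a1[i] <- "tunneling"
  d2[i] <- m; a2[i] <- "mining"
  d3[i] <- dur[i] - t - m; a3[i] <- "helping"

  # melt to long form, dropping empty spells (< ~1 week)
  all_d <- cbind(d1, d2, d3)
  all_a <- cbind(a1, a2, a3)
  keep <- all_d > 0.02
  ord <- rep(1:3, each = n)
  wid <- rep(seq_len(n), 3)
  keep_v <- as.vector(keep)
  wid <- wid[keep_v]; dv <- as.vector(all_d)[keep_v]
  av <- as.vector(all_a)[keep_v]; ov <- ord[keep_v]
  o <- order(wid, ov)
  wid <- wid[o]; dv <- dv[o]; av <- av[o]
  # consecutive spans from entry, in whole days
  end_cum <- stats::ave(dv, wid, FUN = cumsum)
  start_cum <- end_cum - dv
  data.frame(
    worker_id = id[wid],
    area = av,
    start_date = entry[wid] + round(start_cum * 365.25),
    end_date = entry[wid] + round(end_cum * 365.25),
    stringsAsFactors = FALSE
  )
}

#' Small deterministic test cohorts
#'
#' Hand-constructed cohorts (no sampling) exercising every classifier
#' branch and both outcomes:
#' * `"tiny"` — 50 workers cycling through all categories and eras, with
#'   CWP cases in the 1970- and 1980- eras;
#' * `"mixed-careers"` — multi-spell careers hitting each rule of the
#'   classification cascade, including the mining (tunneling < 2 y) and
#'   combining (tunneling >= 2 y, <= half) branches;
#' * `"no-cases"` — 24 workers, none with CWP.
#'
#' @param name One of `"tiny"`, `"mixed-careers"`, `"no-cases"`.
#' @return A [cwp_cohort()].
#' @export
make_fixture <- function(name = c("tiny", "mixed-careers", "no-cases")) {
  name <- match.arg(name)
  study_end <- as.Date("2011-12-31")
  if (name == "tiny" || name == "no-cases") {
    n <- if (name == "tiny") 50L else 24L
    cats <- rep(cwp_categories(), length.out = n)
    eras <- rep(c("1970-", "1980-", "1990-"), length.out = n)
    entry <- as.Date(c("1970-" = "1972-07-01", "1980-" = "1983-07-01",
                       "1990-" = "1994-07-01")[eras]) + (seq_len(n) * 17) %% 300
    dur <- pmin(20 + (seq_len(n) %% 7), interval_years(entry, study_end) - 0.1)
    id <- sprintf("T%03d", seq_len(n))
    is_case <- if (name == "tiny") {
      seq_len(n) %% 5 == 0 & eras != "1990-"
    } else rep(FALSE, n)
    lat <- ifelse(eras == "1980-", 20 + seq_len(n) %% 4,
                  24 + seq_len(n) %% 6)
    diag <- entry + round(lat * 365.25)
    diag[!is_case] <- NA
    workers <- data.frame(
      worker_id = id, birth_year = year_of(entry) - 22L,
      first_exposure_date = entry, cwp_status = is_case,
      diagnosis_date = as.Date(diag),
      censor_date = as.Date(ifelse(is_case, NA, as.character(study_end))),
      stringsAsFactors = FALSE)
    segments <- data.frame(
      worker_id = id, area = cats, start_date = entry,
      end_date = entry + round(dur * 365.25), stringsAsFactors = FALSE)
    return(cwp_cohort(workers, segments))
  }
  # mixed-careers: one worker per classifier branch, plus single-area ones
  mk <- function(id, entry, spells, case = FALSE, lat = NA) {
    ent <- as.Date(entry)
    ends <- ent + round(cumsum(spells$dur) * 365.25)
    starts <- c(ent, ends[-length(ends)])
    list(
      w = data.frame(worker_id = id, birth_year = year_of(ent) - 21L,
                     first_exposure_date = ent, cwp_status = case,
                     diagnosis_date = if (case)
                       ent + round(lat * 365.25) else as.Date(NA),
                     censor_date = if (case) as.Date(NA) else study_end,
                     stringsAsFactors = FALSE),
      s = data.frame(worker_id = id, area = spells$area,
                     start_date = starts, end_date = ends,
                     stringsAsFactors = FALSE))
  }
  lst <- list(
    # rule 1: consistent single area
    mk("M01", "1975-03-01", data.frame(area = "tunneling", dur = 30)),
    mk("M02", "1976-03-01", data.frame(area = "mining", dur = 28),
       case = TRUE, lat = 26),
    mk("M03", "1977-03-01", data.frame(area = "combining", dur = 25)),
    mk("M04", "1978-03-01", data.frame(area = "helping", dur = 30)),
    # rule 2: tunneling > half
    mk("M05", "1980-06-01", data.frame(area = c("tunneling", "helping"),
                                       dur = c(12, 8)), case = TRUE, lat = 27),
    # rule 3: tunneling < 2 y, mining > half
    mk("M06", "1981-06-01", data.frame(area = c("tunneling", "mining",
                                                "helping"),
                                       dur = c(1, 12, 7))),
    # rule 4: tunneling >= 2 y and <= half
    mk("M07", "1982-06-01", data.frame(area = c("tunneling", "mining",
                                                "helping"),
                                       dur = c(3, 15, 2))),
    # rule 5 fallback: multi-area, none of the above
    mk("M08", "1983-06-01", data.frame(area = c("tunneling", "mining",
                                                "helping"),
                                       dur = c(1, 5, 14))),
    mk("M09", "1992-06-01", data.frame(area = c("mining", "helping"),
                                       dur = c(4, 12))),
    mk("M10", "1995-06-01", data.frame(area = "helping", dur = 14))
  )
  cwp_cohort(do.call(rbind, lapply(lst, `[[`, "w")),
             do.call(rbind, lapply(lst, `[[`, "s")))
}
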