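# Cohort data model: worker records, job-spell (segment) histories, the
# area-by-year dust concentration table, occupational classification and
# derived exposure quantities (durations, CDE, observation windows).

#' Occupational categories of underground coal work
#'
#' Work areas, in the conventional order: tunneling (rock drilling/blasting,
#' highest silica), mining (coal face), combining (mixed rock/coal layers),
#' helping (maintenance/transport, no direct dust generation).
#'
#' @return Character vector of the four category labels.
#' @export
cwp_categories <- function() c("tunneling", "mining", "combining", "helping")

#' Eras of first dust exposure
#'
#' Entry decades used for subgroup stratification: 1970-, 1980-, 1990-
#' (the last spans 1990 onwards).
#'
#' @return Character vector of era labels.
#' @export
cwp_eras <- function() c("1970-", "1980-", "1990-")

#' @keywords internal
era_of_year <- function(year) {
  out <- rep(NA_character_, length(year))
  out[year >= 1970 & year < 1980] <- "1970-"
  out[year >= 1980 & year < 1990] <- "1980-"
  out[year >= 1990] <- "1990-"
  out
}

#' @keywords internal
year_of <- function(date) as.integer(format(date, "%Y"))

#' Default area-by-decade dust concentration table
#'
#' Geometric-mean total dust concentrations (mg/m3) measured in the four
#' working areas, by decade block. The geometric standard deviation (gsd) of
#' each cell is back-solved from the +1 SD / -1 SD columns of the monitoring
#' summary as sqrt(upper/lower). Calendar years resolve to their decade
#' block; the final block extends through the end of follow-up (2011).
#'
#' @return A data.frame with columns `area`, `year_start`, `year_end`,
#'   `geometric_mean_mg_m3`, `gsd`.
#' @export
default_concentration_table <- function() {
  blocks <- data.frame(
    year_start = rep(c(1970L, 1980L, 1990L, 2000L), each = 4),
    year_end   = rep(c(1979L, 1989L, 1999L, 2011L), each = 4),
    area       = rep(cwp_categories(), 4),
    stringsAsFactors = FALSE
  )
  gm <- c(72.6, 82.1, 51.1, 0.8,
          47.2, 64.0, 47.6, 0.7,
          44.4, 36.0, 26.8, 0.4,
          23.5, 23.9, 15.8, 0.2)
  up <- c(218.4, 200.9, 106.3, 1.1,
          89.9, 126.1, 66.3, 0.8,
          94.4, 65.4, 42.9, 0.5,
          40.2, 29.4, 35.7, 0.5)
  lo <- c(24.2, 33.5, 24.6, 0.6,
          24.8, 32.5, 34.2, 0.6,
          20.8, 19.8, 16.8, 0.3,
          13.8, 19.4, 7.0, 0.2)
  blocks$geometric_mean_mg_m3 <- gm
  blocks$gsd <- sqrt(up / lo)
  blocks[, c("area", "year_start", "year_end", "geometric_mean_mg_m3", "gsd")]
}

#' Read a concentration table from delimited text
#'
#' @param path CSV file with columns `area`, `year_start`, `year_end`,
#'   `geometric_mean_mg_m3` and optionally `gsd`.
#' @return A concentration table data.frame.
#' @export
read_concentration_table <- function(path) {
  conc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area", "year_start", "year_end", "geometric_mean_mg_m3")
  miss <- setdiff(need, names(conc))
  if (length(miss))
    stop("concentration table is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(conc$gsd)) conc$gsd <- NA_real_
  if (any(conc$geometric_mean_mg_m3 <= 0))
    stop("concentrations must be positive")
  conc
}

# Resolve (area, calendar year) pairs to geometric-mean concentrations.
# Unresolvable cells raise an error naming every missing (area, year).
#' @keywords internal
conc_lookup <- function(conc, area, year) {
  gm <- rep(NA_real_, length(area))
  for (i in seq_len(nrow(conc))) {
    hit <- area == conc$area[i] &
      year >= conc$year_start[i] & year <= conc$year_end[i]
    gm[hit] <- conc$geometric_mean_mg_m3[i]
  }
  if (anyNA(gm)) {
    bad <- unique(paste0("(", area[is.na(gm)], ", ", year[is.na(gm)], ")"))
    stop("no concentration for cell(s): ", paste(bad, collapse = ", "))
  }
  gm
}

#' Duration of a date interval in years
#'
#' Intervals are half-open `[start, end)`; durations use days/365.25.
#'
#' @param start,end Date vectors.
#' @return Numeric years.
#' @export
interval_years <- function(start, end) as.numeric(end - start) / 365.25

#' Classify a worker's occupational category from the job-spell history
#'
#' Applies the rule cascade used in occupational dust cohorts: (1) a worker
#' engaged consistently in one area takes that area's label; (2) tunneling
#' duration more than half the total exposure duration -> tunneling;
#' (3) tunneling under 2 years and mining more than half -> mining;
#' (4) tunneling at least 2 years but not more than half -> combining;
#' (5) otherwise helping. A duration of exactly half the total is not "more
#' than half"; exactly 2 years of tunneling is combining-eligible.
#'
#' @param area Character vector of work areas, one per job spell.
#' @param duration Numeric vector of spell durations in years (positive).
#' @param worker_id Optional id used in error messages.
#' @return One of `cwp_categories()`.
#' @export
classify_occupation <- function(area, duration, worker_id = NULL) {
  who <- if (is.null(worker_id)) "" else paste0(" (worker ", worker_id, ")")
  if (length(area) == 0L)
    stop("empty segment list", who)
  if (length(area) != length(duration))
    stop("area and duration lengths differ", who)
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("non-positive segment duration", who)
  bad <- setdiff(unique(area), cwp_categories())
  if (length(bad))
    stop("unknown work area(s): ", paste(bad, collapse = ", "), who)
  if (length(unique(area)) == 1L) return(area[[1L]])
  total <- sum(duration)
  tun <- sum(duration[area == "tunneling"])
  min_ <- sum(duration[area == "mining"])
  if (tun > total / 2) return("tunneling")
  if (tun < 2 && min_ > total / 2) return("mining")
  if (tun >= 2 && tun <= total / 2) return("combining")
  "helping"
}

#' Cumulative dust exposure from job spells and a concentration table
#'
#' CDE is the sum over job spells, and over the calendar years each spell
#' overlaps, of the fraction of the year inside the spell (days/365.25)
#' times the area's geometric-mean concentration for that year. Units are
#' mg/m3-years (printed "mg-years" in reports).
#'
#' @param segments data.frame with columns `area`, `start_date`, `end_date`
#'   (Dates) for one worker; an empty frame gives 0.
#' @param conc Concentration table (see [default_concentration_table()]).
#' @return CDE in mg/m3-years.
#' @export
compute_cde <- function(segments, conc = default_concentration_table()) {
  if (nrow(segments) == 0L) return(0)
  segments$worker_id <- "w"
  as.numeric(cde_by_worker(segments, conc))
}

# Vectorized CDE over a multi-worker segment table; returns a named vector
# of CDE per worker_id. One row per (segment x overlapped calendar year).
#' @keywords internal
cde_by_worker <- function(segments, conc) {
  stopifnot(all(c("worker_id", "area", "start_date", "end_date") %in%
                  names(segments)))
  if (any(segments$end_date <= segments$start_date))
    stop("segment with end_date <= start_date")
  sy <- year_of(segments$start_date)
  # last calendar year touched by the half-open interval
  ey <- year_of(segments$end_date - 1L)
  ny <- ey - sy + 1L
  idx <- rep(seq_len(nrow(segments)), ny)
  year <- sy[idx] + sequence(ny) - 1L
  y0 <- as.Date(paste0(year, "-01-01"))
  y1 <- as.Date(paste0(year + 1L, "-01-01"))
  ov_start <- pmax(segments$start_date[idx], y0)
  ov_end <- pmin(segments$end_date[idx], y1)
  frac <- as.numeric(ov_end - ov_start) / 365.25
  gm <- conc_lookup(conc, segments$area[idx], year)
  contrib <- frac * gm
  tapply(contrib, segments$worker_id[idx], sum)
}

#' Observation window of each worker in years
#'
#' Follow-up runs from the first day of dust exposure to the diagnosis date
#' for CWP cases (this equals the latency period) and to the censor date
#' (loss to follow-up or study end) for workers without CWP.
#'
#' @param workers data.frame with `first_exposure_date`, `cwp_status`,
#'   `diagnosis_date`, `censor_date`.
#' @return Numeric vector of observed years (strictly positive).
#' @export
observation_window <- function(workers) {
  status <- as.logical(workers$cwp_status)
  end <- as.Date(ifelse(status,
                        as.character(workers$diagnosis_date),
                        as.character(workers$censor_date)))
  if (any(status & is.na(workers$diagnosis_date)))
    stop("CWP case without diagnosis_date: ",
         paste(workers$worker_id[status & is.na(workers$diagnosis_date)],
               collapse = ", "))
  if (any(!status & is.na(workers$censor_date)))
    stop("non-case without censor_date: ",
         paste(workers$worker_id[!status & is.na(workers$censor_date)],
               collapse = ", "))
  yrs <- interval_years(workers$first_exposure_date, end)
  if (any(yrs <= 0))
    stop("non-positive observation window for worker(s): ",
         paste(workers$worker_id[yrs <= 0], collapse = ", "))
  yrs
}

#' Construct and validate a cohort object
#'
#' A cohort couples a worker table (one row per subject) with a segment
#' table (one row per job spell). Validation enforces the record
#' invariants: unique ids, every worker has at least one spell with
#' positive duration, spells of a worker do not overlap,
#' `first_exposure_date` equals the earliest spell start, cases carry a
#' diagnosis date after first exposure, non-cases carry a censor date, and
#' total exposure duration is at least 1 year (the cohort inclusion rule).
#'
#' @param workers data.frame: `worker_id`, `birth_year`,
#'   `first_exposure_date`, `cwp_status` (logical or 0/1),
#'   `diagnosis_date`, `censor_date`.
#' @param segments data.frame: `worker_id`, `area`, `start_date`, `end_date`.
#' @return An object of class `cwp_cohort` (a list with `workers` and
#'   `segments`).
#' @export
cwp_cohort <- function(workers, segments) {
  for (col in c("first_exposure_date", "diagnosis_date", "censor_date"))
    workers[[col]] <- as.Date(workers[[col]])
  for (col in c("start_date", "end_date"))
    segments[[col]] <- as.Date(segments[[col]])
  workers$cwp_status <- as.logical(workers$cwp_status)
  obj <- structure(list(workers = workers, segments = segments),
                   class = "cwp_cohort")
  validate_cohort(obj)
  obj
}

#' @keywords internal
validate_cohort <- function(cohort) {
  w <- cohort$workers
  s <- cohort$segments
  need_w <- c("worker_id", "birth_year", "first_exposure_date", "cwp_status",
              "diagnosis_date", "censor_date")
  need_s <- c("worker_id", "area", "start_date", "end_date")
  miss <- c(setdiff(need_w, names(w)), setdiff(need_s, names(s)))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(w) == 0L) {
    if (nrow(s) > 0L) stop("segments present for an empty worker table")
    return(invisible(TRUE))
  }
  if (anyDuplicated(w$worker_id))
    stop("duplicate worker_id: ",
         paste(unique(w$worker_id[duplicated(w$worker_id)]), collapse = ", "))
  orphan <- setdiff(s$worker_id, w$worker_id)
  if (length(orphan))
    stop("segments for unknown worker_id: ", paste(orphan, collapse = ", "))
  no_seg <- setdiff(w$worker_id, s$worker_id)
  if (length(no_seg))
    stop("worker(s) with no segments: ", paste(no_seg, collapse = ", "))
  if (any(s$end_date <= s$start_date))
    stop("segment with end_date <= start_date for worker(s): ",
         paste(unique(s$worker_id[s$end_date <= s$start_date]),
               collapse = ", "))
  bad_area <- setdiff(unique(s$area), cwp_categories())
  if (length(bad_area))
    stop("unknown work area(s): ", paste(bad_area, collapse = ", "))
  # overlapping spells of one worker are rejected, not merged
  o <- order(s$worker_id, s$start_date)
  so <- s[o, ]
  same <- so$worker_id[-1L] == so$worker_id[-nrow(so)]
  overl <- same & (so$start_date[-1L] < so$end_date[-nrow(so)])
  if (any(overl))
    stop("overlapping segments for worker(s): ",
         paste(unique(so$worker_id[-1L][overl]), collapse = ", "))
  first_seg <- tapply(as.numeric(s$start_date), s$worker_id, min)
  fe <- as.numeric(w$first_exposure_date)
  names(fe) <- w$worker_id
  mismatch <- abs(fe[names(first_seg)] - first_seg) > 0
  if (any(mismatch))
    stop("first_exposure_date does not equal earliest segment start for: ",
         paste(names(first_seg)[mismatch], collapse = ", "))
  dur <- tapply(interval_years(s$start_date, s$end_date), s$worker_id, sum)
  if (any(dur < 1 - 1e-9))
    stop("total exposure under 1 year (inclusion rule) for: ",
         paste(names(dur)[dur < 1 - 1e-9], collapse = ", "))
  st <- as.logical(w$cwp_status)
  if (any(st & is.na(w$diagnosis_date)))
    stop("CWP case without diagnosis_date: ",
         paste(w$worker_id[st & is.na(w$diagnosis_date)], collapse = ", "))
  if (any(st & !is.na(w$diagnosis_date) &
            w$diagnosis_date <= w$first_exposure_date))
    stop("diagnosis_date not after first exposure for: ",
         paste(w$worker_id[st & !is.na(w$diagnosis_date) &
                             w$diagnosis_date <= w$first_exposure_date],
               collapse = ", "))
  if (any(!st & is.na(w$censor_date)))
    stop("non-case without censor_date: ",
         paste(w$worker_id[!st & is.na(w$censor_date)], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.cwp_cohort <- function(x, ...) {
  cat("cwp_cohort:", nrow(x$workers), "workers,",
      nrow(x$segments), "segments,",
      sum(x$workers$cwp_status), "CWP cases\n")
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' @param workers_path CSV with columns `worker_id`, `birth_year`,
#'   `first_exposure_date`, `cwp_status`, `diagnosis_date`, `censor_date`
#'   (ISO 8601 dates; empty fields for absent dates).
#' @param segments_path CSV sidecar with columns `worker_id`, `area`,
#'   `start_date`, `end_date`, one row per job spell.
#' @return A [cwp_cohort()] object. A header-only worker file yields an
#'   empty cohort with a warning.
#' @export
read_cohort <- function(workers_path, segments_path) {
  w <- utils::read.csv(workers_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  s <- utils::read.csv(segments_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need_w <- c("worker_id", "birth_year", "first_exposure_date", "cwp_status",
              "diagnosis_date", "censor_date")
  miss <- setdiff(need_w, names(w))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(w) == 0L) {
    warning("cohort file has a header but no records; returning empty cohort")
    w2 <- data.frame(worker_id = character(), birth_year = integer(),
                     first_exposure_date = as.Date(character()),
                     cwp_status = logical(),
                     diagnosis_date = as.Date(character()),
                     censor_date = as.Date(character()))
    s2 <- data.frame(worker_id = character(), area = character(),
                     start_date = as.Date(character()),
                     end_date = as.Date(character()))
    return(cwp_cohort(w2, s2))
  }
  parse_date <- function(x, col, file) {
    x[x == ""] <- NA_character_
    d <- as.Date(x, format = "%Y-%m-%d")
    bad <- !is.na(x) & is.na(d)
    if (any(bad))
      stop("unparseable ", col, " at line(s) ",
           paste(which(bad) + 1L, collapse = ", "), " of ", file)
    d
  }
  w$birth_year <- as.integer(w$birth_year)
  w$first_exposure_date <- parse_date(w$first_exposure_date,
                                      "first_exposure_date", workers_path)
  w$diagnosis_date <- parse_date(w$diagnosis_date, "diagnosis_date",
                                 workers_path)
  w$censor_date <- parse_date(w$censor_date, "censor_date", workers_path)
  w$cwp_status <- as.integer(w$cwp_status) == 1L
  s$start_date <- parse_date(s$start_date, "start_date", segments_path)
  s$end_date <- parse_date(s$end_date, "end_date", segments_path)
  cwp_cohort(w, s)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: round-trips a valid cohort identically.
#'
#' @param cohort A `cwp_cohort`.
#' @param workers_path,segments_path Output CSV paths.
#' @export
write_cohort <- function(cohort, workers_path, segments_path) {
  w <- cohort$workers
  w$cwp_status <- as.integer(w$cwp_status)
  for (col in c("first_exposure_date", "diagnosis_date", "censor_date"))
    w[[col]] <- ifelse(is.na(w[[col]]), "", as.character(w[[col]]))
  utils::write.csv(w, workers_path, row.names = FALSE, quote = FALSE)
  s <- cohort$segments
  s$start_date <- as.character(s$start_date)
  s$end_date <- as.character(s$end_date)
  utils::write.csv(s, segments_path, row.names = FALSE, quote = FALSE)
  invisible(c(workers_path, segments_path))
}

#' Derive per-worker exposure and observation quantities
#'
#' For every worker: occupational category by the classification cascade,
#' total and per-area exposure durations, cumulative dust exposure (CDE),
#' observed years (first exposure to diagnosis or censoring), latency
#' (defined for cases only, where it equals the observed years), era of
#' first dust exposure, and current age at `as_of`.
#'
#' @param cohort A [cwp_cohort()].
#' @param conc Concentration table; defaults to the shipped decade-block
#'   table.
#' @param as_of Date at which `current_age` is evaluated (study end).
#' @return data.frame, one row per worker.
#' @export
derive_exposures <- function(cohort, conc = default_concentration_table(),
                             as_of = as.Date("2011-12-31")) {
  w <- cohort$workers
  s <- cohort$segments
  if (nrow(w) == 0L)
    return(data.frame(worker_id = character()))
  s$dur <- interval_years(s$start_date, s$end_date)
  dur_area <- function(a) {
    d <- tapply(s$dur * (s$area == a), s$worker_id, sum)
    out <- as.numeric(d[w$worker_id])
    out[is.na(out)] <- 0
    out
  }
  tun <- dur_area("tunneling"); mng <- dur_area("mining")
  cmb <- dur_area("combining"); hlp <- dur_area("helping")
  total <- tun + mng + cmb + hlp
  by_w <- split(s[, c("area", "dur")], s$worker_id)
  cat_by_id <- vapply(names(by_w), function(id) {
    classify_occupation(by_w[[id]]$area, by_w[[id]]$dur, worker_id = id)
  }, character(1))
  cde_v <- cde_by_worker(s, conc)
  obs <- observation_window(w)
  data.frame(
    worker_id = w$worker_id,
    category = factor(unname(cat_by_id[w$worker_id]),
                      levels = cwp_categories()),
    era = factor(era_of_year(year_of(w$first_exposure_date)),
                 levels = cwp_eras()),
    total_duration = total,
    tunneling_duration = tun,
    mining_duration = mng,
    combining_duration = cmb,
    helping_duration = hlp,
    cde = as.numeric(cde_v[w$worker_id]),
    observed_years = obs,
    latency = ifelse(w$cwp_status, obs, NA_real_),
    cwp_status = w$cwp_status,
    current_age = year_of(as_of) - w$birth_year,
    stringsAsFactors = FALSE
  )
}
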