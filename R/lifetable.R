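# Actuarial life-table cumulative incidence, annual average incidence,
# Peto log-rank curve comparison, and Pearson chi-square contingency tests.

#' Build an actuarial life table
#'
#' Time is years since first dust exposure on 1-year intervals
#' `[k, k+1)`. Events (CWP diagnoses) and withdrawals (censorings) fall in
#' the interval containing their observed time; the effective denominator
#' half-weights withdrawals, `n'_k = n_k - w_k/2`, the standard actuarial
#' correction. Conditional incidence is `q_k = d_k / n'_k` and cumulative
#' incidence `CI(t) = 1 - prod_{k<t} (1 - q_k)`.
#'
#' @param time Numeric observed years, or a data.frame with columns
#'   `observed_years` and `cwp_status` (e.g. from [derive_exposures()]).
#' @param event Logical/0-1 event indicator (ignored when `time` is a
#'   data.frame).
#' @param width Interval width in years (default 1).
#' @return data.frame of class `cwp_lifetable` with columns `interval`
#'   (start of interval, in units of `width`), `n`, `d`, `w`, `n_eff`,
#'   `q`, `ci` (cumulative incidence at the interval's end).
#' @export
build_life_table <- function(time, event = NULL, width = 1) {
  if (is.data.frame(time)) {
    event <- time$cwp_status
    time <- time$observed_years
  }
  if (length(time) == 0L) stop("empty worker list")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("observation window must be positive for every worker")
  event <- as.logical(event)
  k <- floor(time / width)
  K <- max(k)
  d <- tabulate(k[event] + 1L, nbins = K + 1L)
  w <- tabulate(k[!event] + 1L, nbins = K + 1L)
  n <- length(time) - cumsum(c(0, (d + w)[-(K + 1L)]))
  n_eff <- n - w / 2
  q <- ifelse(n_eff > 0, d / n_eff, 0)
  q <- pmin(pmax(q, 0), 1)
  out <- data.frame(interval = (0:K) * width, n = n, d = d, w = w,
                    n_eff = n_eff, q = q,
                    ci = 1 - cumprod(1 - q))
  class(out) <- c("cwp_lifetable", "data.frame")
  out
}

#' Cumulative incidence curve from a life table
#'
#' @param lt A [build_life_table()] result.
#' @return data.frame `(t, ci)` with `ci(0) = 0`, non-decreasing, in
#'   `[0, 1]`; one point per interval boundary.
#' @export
cumulative_incidence_curve <- function(lt) {
  stopifnot(inherits(lt, "cwp_lifetable"))
  width <- if (nrow(lt) > 1) diff(lt$interval[1:2]) else 1
  data.frame(t = c(lt$interval, lt$interval[nrow(lt)] + width),
             ci = c(0, lt$ci))
}

#' Cumulative incidence at a time point
#'
#' @param lt A `cwp_lifetable`. @param t Years since first exposure (an
#'   interval boundary).
#' @return `CI(t)`.
#' @export
ci_at <- function(lt, t) {
  stopifnot(inherits(lt, "cwp_lifetable"))
  width <- if (nrow(lt) > 1) diff(lt$interval[1:2]) else 1
  span <- lt$interval[nrow(lt)] + width
  if (t > span + 1e-9) stop("t = ", t, " exceeds the table span (", span, ")")
  if (t <= 0) return(0)
  1 - prod(1 - lt$q[lt$interval < t - 1e-9])
}

#' Annual average incidence rate
#'
#' The constant-rate summary of a life table: cumulative incidence at the
#' follow-up horizon divided by the follow-up time (per-year probability;
#' multiply by 1000 for per-mille).
#'
#' @param lt A `cwp_lifetable`. @param follow_up Follow-up horizon (years).
#' @return Per-year rate `CI(follow_up) / follow_up`.
#' @export
annual_average_incidence <- function(lt, follow_up) {
  if (follow_up <= 0) stop("follow_up must be positive")
  ci_at(lt, follow_up) / follow_up
}

#' Two-sample weighted (Peto) log-rank test
#'
#' Compares the incidence experience of two groups. At each distinct event
#' time the observed minus expected events in group A and the
#' hypergeometric variance are accumulated with weights; the Peto-Peto
#' weight is the pooled product-limit survival estimate at the event time
#' (computed from the pooled risk set, no +1 correction). With
#' `weights = "unit"` the classic (unweighted) log-rank test is obtained.
#' The statistic `(sum w (O - E))^2 / sum w^2 V` is referred to
#' chi-square with 1 df.
#'
#' @param a,b data.frames with `observed_years` and `cwp_status` (or
#'   vectors of times with `event_a`/`event_b`).
#' @param event_a,event_b Event indicators when `a`/`b` are numeric.
#' @param weights `"peto"` (default) or `"unit"`.
#' @return list of class `cwp_curvecmp`: `statistic`, `df`, `p_value`.
#' @export
peto_logrank <- function(a, b, event_a = NULL, event_b = NULL,
                         weights = c("peto", "unit")) {
  weights <- match.arg(weights)
  if (is.data.frame(a)) { event_a <- a$cwp_status; a <- a$observed_years }
  if (is.data.frame(b)) { event_b <- b$cwp_status; b <- b$observed_years }
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  if (sum(a) <= 0 || sum(b) <= 0) stop("group with zero observation time")
  time <- c(a, b)
  event <- as.logical(c(event_a, event_b))
  grp <- rep(1:2, c(length(a), length(b)))
  et <- sort(unique(time[event]))
  if (length(et) == 0L)
    return(structure(list(statistic = 0, df = 1L, p_value = 1),
                     class = "cwp_curvecmp"))
  num <- den <- 0
  surv <- 1
  for (t in et) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    dead <- event & time == t
    d_j <- sum(dead)
    d1 <- sum(dead & grp == 1L)
    e1 <- d_j * n1 / n_j
    v1 <- if (n_j > 1)
      d_j * (n1 / n_j) * (1 - n1 / n_j) * (n_j - d_j) / (n_j - 1) else 0
    surv <- surv * (1 - d_j / n_j)   # pooled survival through t
    w <- if (weights == "peto") surv else 1
    num <- num + w * (d1 - e1)
    den <- den + w^2 * v1
  }
  stat <- if (den > 0) num^2 / den else 0
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1L, lower.tail = FALSE)),
            class = "cwp_curvecmp")
}

#' @export
print.cwp_curvecmp <- function(x, ...) {
  p <- if (x$p_value < 0.001) "<0.001" else sprintf("%.3f", x$p_value)
  cat(sprintf("chi-square = %.1f, df = %d, P %s%s\n", x$statistic, x$df,
              if (x$p_value < 0.001) "" else "= ", p))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic `sum (O - E)^2 / E` without continuity correction,
#' `df = (r - 1)(c - 1)`.
#'
#' @param tab An r x c matrix of counts (at least 2 x 2).
#' @return list of class `cwp_curvecmp`: `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column total")
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value)),
            class = "cwp_curvecmp")
}

#' Estimate annual average incidence per subgroup
#'
#' Builds a life table for every observed (era x category) subgroup and
#' summarises it as cumulative incidence at the subgroup's follow-up
#' horizon divided by that horizon — the per-subgroup constant annual
#' rate used for projection.
#'
#' @param derived A [derive_exposures()] data.frame (columns `era`,
#'   `category`, `observed_years`, `cwp_status`).
#' @param follow_up Follow-up horizon in years; default is each
#'   subgroup's `floor(max(observed_years))`.
#' @return data.frame: `era`, `category`, `n`, `cases`, `follow_up`,
#'   `ci_at_followup`, `annual_rate` (per year).
#' @export
estimate_subgroup_rates <- function(derived, follow_up = NULL) {
  sub <- split(derived, list(derived$era, derived$category), drop = TRUE,
               sep = "|")
  rows <- lapply(names(sub), function(nm) {
    d <- sub[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    fu <- if (is.null(follow_up)) floor(max(d$observed_years)) else follow_up
    if (fu < 1) fu <- 1
    lt <- build_life_table(d)
    fu <- min(fu, lt$interval[nrow(lt)] + 1)
    ci <- ci_at(lt, fu)
    data.frame(era = parts[1], category = parts[2], n = nrow(d),
               cases = sum(d$cwp_status), follow_up = fu,
               ci_at_followup = ci, annual_rate = ci / fu,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(match(out$era, cwp_eras()),
            match(out$category, cwp_categories())), , drop = FALSE]
}
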