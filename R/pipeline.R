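# End-to-end pipeline: generate/load -> derive exposures -> life tables &
# curve comparisons -> baseline table -> subgroup rates -> projection ->
# risk perceptron -> threshold calibration -> risk report. One seeded,
# reproducible run writing delimited outputs plus a resolved config.

#' Build a pipeline run configuration
#'
#' A fully serializable description of one run: either a synthetic-cohort
#' size (with onset model), a named fixture, or input file paths; plus
#' seed and stage options. Re-running a persisted config reproduces the
#' outputs byte for byte.
#'
#' @param out_dir Output directory.
#' @param n_workers Synthetic cohort size (ignored when `fixture` or
#'   files are given).
#' @param seed Integer seed for all randomness in the run.
#' @param fixture Optional fixture name (see [make_fixture()]).
#' @param workers_file,segments_file Optional cohort input files.
#' @param concentration_file Optional concentration table (default: the
#'   shipped decade-block table).
#' @param onset Synthetic onset model (see [cohort_spec()]).
#' @param hidden_units,split_ratio,cutoff Risk-model options.
#' @param life_expectancy Years, for the projection stage.
#' @param follow_up Optional fixed follow-up horizon for subgroup rates.
#' @return list of class `cwp_runconfig`.
#' @export
run_config <- function(out_dir,
                       n_workers = 2000L, seed = 1L,
                       fixture = NULL,
                       workers_file = NULL, segments_file = NULL,
                       concentration_file = NULL,
                       onset = "linear",
                       hidden_units = 9L, split_ratio = 0.7, cutoff = 0.2,
                       life_expectancy = 74, follow_up = NULL) {
  structure(list(out_dir = out_dir, n_workers = as.integer(n_workers),
                 seed = as.integer(seed), fixture = fixture,
                 workers_file = workers_file, segments_file = segments_file,
                 concentration_file = concentration_file, onset = onset,
                 hidden_units = as.integer(hidden_units),
                 split_ratio = split_ratio, cutoff = cutoff,
                 life_expectancy = life_expectancy, follow_up = follow_up),
            class = "cwp_runconfig")
}

#' @keywords internal
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Baseline characteristics table with chi-square tests
#'
#' Cross-classifies workers with and without CWP over the reporting
#' strata (occupational category; era of first exposure; duration
#' <10/10-/20-/30- years; CDE <100/100-/1000- mg-years) with column
#' percentages and a Pearson chi-square per characteristic. With zero
#' cases the chi-square is reported as NA.
#'
#' @param derived A [derive_exposures()] data.frame.
#' @param duration_breaks,cde_breaks Stratum boundaries.
#' @return list of data.frames (one per characteristic) with columns
#'   `stratum`, `with_cwp`, `with_pct`, `without_cwp`, `without_pct`,
#'   `chi2`, `df`, `p_value` (test values on the first row).
#' @export
report_table2 <- function(derived,
                          duration_breaks = c(0, 10, 20, 30, Inf),
                          cde_breaks = c(0, 100, 1000, Inf)) {
  strata <- list(
    occupational_category = factor(as.character(derived$category),
                                   levels = cwp_categories()),
    era_of_first_exposure = factor(as.character(derived$era),
                                   levels = cwp_eras()),
    duration_years = cut(derived$total_duration, duration_breaks,
                         right = FALSE, labels = c("<10", "10-", "20-", "30-")),
    cde_mg_years = cut(derived$cde, cde_breaks, right = FALSE,
                       labels = c("<100", "100-", "1000-"))
  )
  status <- derived$cwp_status
  lapply(strata, function(s) {
    if (all(is.na(s)) || length(levels(droplevels(s[!is.na(s)]))) == 0)
      stop("empty stratum set")
    with_n <- as.integer(table(s[status]))
    without_n <- as.integer(table(s[!status]))
    chi <- df <- p <- NA_real_
    tab <- rbind(with_n, without_n)
    keep <- colSums(tab) > 0
    if (sum(status) > 0 && sum(!status) > 0 && sum(keep) >= 2) {
      ct <- pearson_chi2(tab[, keep, drop = FALSE])
      chi <- ct$statistic; df <- ct$df; p <- ct$p_value
    }
    out <- data.frame(
      stratum = levels(s),
      with_cwp = with_n,
      with_pct = round(100 * with_n / max(sum(with_n), 1), 1),
      without_cwp = without_n,
      without_pct = round(100 * without_n / max(sum(without_n), 1), 1),
      chi2 = NA_real_, df = NA_real_, p_value = NA_real_,
      stringsAsFactors = FALSE)
    out$chi2[1] <- chi; out$df[1] <- df; out$p_value[1] <- p
    out
  })
}

#' Cumulative-incidence curves per group
#'
#' Builds a life table for each level of a grouping factor over the same
#' worker frame and stacks the incidence curves in long form.
#'
#' @param derived A [derive_exposures()] data.frame.
#' @param group Factor (or vector) with one level per curve.
#' @return data.frame with columns `group`, `t`, `ci`.
#' @export
group_curves <- function(derived, group) {
  grp <- droplevels(factor(group))
  do.call(rbind, lapply(levels(grp), function(g) {
    lt <- build_life_table(derived[grp == g & !is.na(grp), , drop = FALSE])
    cv <- cumulative_incidence_curve(lt)
    cbind(group = g, cv)
  }))
}

#' Pairwise Peto log-rank comparisons for a grouping factor
#'
#' Runs [peto_logrank()] for every pair of group levels (df = 1 each,
#' no multiplicity adjustment).
#'
#' @inheritParams group_curves
#' @return data.frame `groupA`, `groupB`, `chi2`, `df`, `p_value`, or
#'   NULL with fewer than two levels.
#' @export
pairwise_peto <- function(derived, group) {
  grp <- droplevels(factor(group))
  lv <- levels(grp)
  if (length(lv) < 2) return(NULL)
  pairs <- utils::combn(lv, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- derived[grp == pairs[1, j] & !is.na(grp), , drop = FALSE]
    b <- derived[grp == pairs[2, j] & !is.na(grp), , drop = FALSE]
    cmp <- peto_logrank(a, b)
    data.frame(groupA = pairs[1, j], groupB = pairs[2, j],
               chi2 = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full pipeline
#'
#' Executes every stage of the analysis on a synthetic, fixture or file
#' cohort and writes delimited reports to the output directory: the
#' cohort and ground truth (when synthetic), cumulative-incidence curves
#' and pairwise Peto comparisons for the category/duration/CDE groupings,
#' the baseline characteristics table with chi-squares, per-subgroup
#' annual rates, the age-band and future-window projection tables, the
#' risk-model metrics and variable importances, the calibrated cutoffs,
#' the per-worker risk report and its per-stratum summary, a plain-text
#' run summary, and the resolved config as YAML. Stage errors propagate
#' with the stage name. If threshold calibration is infeasible on the
#' cohort, the conventional cutoffs 0.1/0.2 are used and a warning is
#' recorded.
#'
#' @param config A [run_config()].
#' @return (invisibly) list with the main in-memory results and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cwp_runconfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  truth <- NULL
  cohort <- run_stage("load_cohort", {
    if (!is.null(config$fixture)) {
      make_fixture(config$fixture)
    } else if (!is.null(config$workers_file)) {
      read_cohort(config$workers_file, config$segments_file)
    } else {
      g <- generate_cohort(cohort_spec(n_workers = config$n_workers,
                                       onset = config$onset,
                                       seed = config$seed))
      truth <- g$truth
      g$cohort
    }
  })
  note("cohort: ", nrow(cohort$workers), " workers, ",
       sum(cohort$workers$cwp_status), " CWP cases")
  write_cohort(cohort, out("cohort.csv"), out("segments.csv"))
  if (!is.null(truth))
    utils::write.csv(truth, out("ground_truth.csv"), row.names = FALSE)

  conc <- run_stage("cohort_model.compute_cde (concentration table)", {
    if (is.null(config$concentration_file)) default_concentration_table()
    else read_concentration_table(config$concentration_file)
  })
  derived <- run_stage("cohort_model.compute_cde (derive_exposures)",
                       derive_exposures(cohort, conc))
  utils::write.csv(derived, out("derived_exposures.csv"), row.names = FALSE)
  note("derived exposures for ", nrow(derived), " workers")

  run_stage("lifetable_stats", {
    groupings <- list(
      category = derived$category,
      duration = cut(derived$total_duration, c(0, 20, Inf), right = FALSE,
                     labels = c("<20", "20-")),
      cde = cut(derived$cde, c(0, 100, 1000, Inf), right = FALSE,
                labels = c("<100", "100-", "1000-")))
    curves <- do.call(rbind, lapply(names(groupings), function(nm)
      cbind(grouping = nm, group_curves(derived, groupings[[nm]]))))
    utils::write.csv(curves, out("incidence_curves.csv"), row.names = FALSE)
    cmps <- do.call(rbind, lapply(names(groupings), function(nm) {
      pp <- pairwise_peto(derived, groupings[[nm]])
      if (is.null(pp)) NULL else cbind(grouping = nm, pp)
    }))
    if (!is.null(cmps))
      utils::write.csv(cmps, out("curve_comparisons.csv"), row.names = FALSE)
  })

  t2 <- run_stage("report_table2", report_table2(derived))
  t2_flat <- do.call(rbind, Map(cbind, characteristic = names(t2), t2))
  utils::write.csv(t2_flat, out("table2.csv"), row.names = FALSE)

  rates <- run_stage("estimate_subgroup_rates",
                     estimate_subgroup_rates(derived,
                                             follow_up = config$follow_up))
  utils::write.csv(rates, out("subgroup_rates.csv"), row.names = FALSE)

  noncases <- derived[!derived$cwp_status, , drop = FALSE]
  proj <- run_stage("project_cases",
                    project_cases(noncases, rates,
                                  life_expectancy = config$life_expectancy))
  by_age_sum <- summarize_projection(
    proj$by_age, pmax(colSums(proj$n_by_age), 1))
  by_win_sum <- summarize_projection(proj$by_window, nrow(noncases))
  utils::write.csv(cbind(rbind(proj$by_age, Total = colSums(proj$by_age)),
                         Total = c(rowSums(proj$by_age),
                                   sum(proj$by_age))),
                   out("projection_by_age.csv"))
  utils::write.csv(cbind(rbind(proj$by_window,
                               Total = colSums(proj$by_window)),
                         Total = c(rowSums(proj$by_window),
                                   sum(proj$by_window))),
                   out("projection_by_window.csv"))
  note(sprintf("projected new CWP cases: %.1f (%.1f%% of %d non-cases)",
               proj$total, by_win_sum$grand_percent, nrow(noncases)))

  split <- run_stage("split_data",
                     split_data(derived, config$split_ratio, config$seed))
  model <- run_stage("train_model",
                     train_model(split$train, config$hidden_units,
                                 seed = config$seed))
  val_p <- run_stage("predict_risk", predict_risk(model, split$validation))
  all_p <- run_stage("predict_risk", predict_risk(model, derived))
  met_val <- confusion_metrics(val_p$probability,
                               split$validation$cwp_status, config$cutoff)
  met_all <- confusion_metrics(all_p$probability, derived$cwp_status,
                               config$cutoff)
  met <- rbind(data.frame(set = "validation", n = met_val$n,
                          accuracy = met_val$accuracy,
                          sensitivity = met_val$sensitivity,
                          specificity = met_val$specificity),
               data.frame(set = "all", n = met_all$n,
                          accuracy = met_all$accuracy,
                          sensitivity = met_all$sensitivity,
                          specificity = met_all$specificity))
  utils::write.csv(met, out("model_metrics.csv"), row.names = FALSE)
  imp <- run_stage("variable_importance",
                   variable_importance(model, derived, seed = config$seed))
  utils::write.csv(data.frame(variable = names(imp),
                              importance = as.numeric(imp)),
                   out("variable_importance.csv"), row.names = FALSE)

  nc_p <- all_p[!derived$cwp_status, , drop = FALSE]
  low_pool <- sum(noncases$category == "helping" &
                    noncases$era %in% c("1980-", "1990-"))
  thr <- run_stage("calibrate_thresholds", {
    tryCatch(calibrate_thresholds(nc_p$probability, max(proj$total, 1e-9),
                                  low_pool),
             error = function(e) {
               warning("calibration infeasible (", conditionMessage(e),
                       "); using cutoffs 0.1/0.2")
               note("calibration infeasible; fell back to cutoffs 0.1/0.2")
               list(c_low = 0.1, c_high = 0.2,
                    target_high = round(max(proj$total, 0) * 1.5),
                    n_high = NA_integer_, n_low = NA_integer_)
             })
  })
  classified <- run_stage("classify_risk",
                          classify_risk(nc_p, thr$c_low, thr$c_high))
  utils::write.csv(classified, out("risk_report.csv"), row.names = FALSE)
  t5 <- run_stage("stratified_risk_report",
                  stratified_risk_report(classified, noncases))
  t5_flat <- do.call(rbind, Map(cbind, characteristic = names(t5), t5))
  utils::write.csv(t5_flat, out("table5.csv"), row.names = FALSE)
  note(sprintf("risk classes (cutoffs %.2f/%.2f): low %d, middle %d, high %d",
               thr$c_low, thr$c_high, sum(classified$risk_class == "low"),
               sum(classified$risk_class == "middle"),
               sum(classified$risk_class == "high")))

  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, out("config.yaml"))
  writeLines(log_lines, out("run_summary.txt"))

  invisible(list(out_dir = config$out_dir, cohort = cohort, truth = truth,
                 derived = derived, rates = rates, projection = proj,
                 model = model, metrics = list(validation = met_val,
                                               all = met_all),
                 importance = imp, thresholds = thr,
                 classified = classified, table2 = t2, table5 = t5))
}
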