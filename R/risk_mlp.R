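# MLP risk model: feature encoding, 7:3 split, single-hidden-layer
# perceptron fit, confusion metrics, permutation importance, threshold
# calibration and low/middle/high risk classification.

# Encode the four inputs (occupational category, era of first exposure,
# duration, CDE) into the model matrix: treatment dummies for the two
# categoricals, standardized continuous columns (CDE optionally
# log1p-transformed first). `meta` carries levels and scaling so that
# prediction re-applies the training encoding exactly.
#' @keywords internal
encode_features <- function(data, meta = NULL, log_cde = FALSE) {
  cat_lv <- cwp_categories(); era_lv <- cwp_eras()
  cat_f <- factor(as.character(data$category), levels = cat_lv)
  era_f <- factor(as.character(data$era), levels = era_lv)
  if (anyNA(cat_f)) stop("unseen occupational category level")
  if (anyNA(era_f)) stop("unseen era level")
  if (!is.null(meta)) log_cde <- meta$log_cde
  cde <- if (log_cde) log1p(data$cde) else data$cde
  num <- cbind(duration = data$total_duration, cde = cde)
  if (any(!is.finite(num))) stop("non-finite features")
  if (is.null(meta)) {
    ctr <- colMeans(num)
    scl <- apply(num, 2, stats::sd)
    scl[scl == 0] <- 1
    meta <- list(center = ctr, scale = scl, log_cde = log_cde)
  }
  num <- sweep(sweep(num, 2, meta$center), 2, meta$scale, "/")
  dummies <- function(f, lv) {
    m <- sapply(lv[-1], function(l) as.numeric(f == l))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    colnames(m) <- lv[-1]
    m
  }
  x <- cbind(dummies(cat_f, cat_lv), dummies(era_f, era_lv), num)
  list(x = x, meta = meta,
       groups = list(
         occupational_category = cat_lv[-1],
         era_of_first_exposure = era_lv[-1],
         duration_of_exposure = "duration",
         cde = "cde"))
}

#' Split records into training and validation sets
#'
#' Random, disjoint, exhaustive split reproducible by seed; sizes are
#' within one record of the requested ratio.
#'
#' @param data data.frame of records. @param ratio Training fraction in
#'   (0, 1); default 0.7 (the 7:3 split). @param seed Integer seed.
#' @return list: `train`, `validation`, `train_idx`.
#' @export
split_data <- function(data, ratio = 0.7, seed = 1L) {
  n <- nrow(data)
  if (n < 10L) stop("fewer than 10 records")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  set.seed(seed)
  idx <- sample.int(n, round(n * ratio))
  list(train = data[idx, , drop = FALSE],
       validation = data[-idx, , drop = FALSE],
       train_idx = sort(idx))
}

#' Train the risk perceptron
#'
#' Fits a three-layer perceptron (inputs -> one hidden layer -> one
#' logistic output trained on cross-entropy) on the encoded features,
#' with small weight decay for stability. Training is reproducible by
#' seed (the seed fixes the random initial weights; the optimizer is
#' deterministic).
#'
#' @param data Training records: a [derive_exposures()]-style data.frame
#'   with `category`, `era`, `total_duration`, `cde`, `cwp_status`.
#' @param hidden_units Hidden-layer size (default 9).
#' @param seed Integer seed.
#' @param decay Weight decay. @param maxit Optimizer iteration cap.
#' @param log_cde log1p-transform CDE before standardizing?
#' @return list of class `cwp_riskmodel`: the fitted `net`, encoding
#'   `meta`, `hidden_units`, `seed`, training deviance.
#' @export
train_model <- function(data, hidden_units = 9L, seed = 1L,
                        decay = 1e-3, maxit = 400, log_cde = FALSE) {
  y <- as.numeric(data$cwp_status)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  enc <- encode_features(data, log_cde = log_cde)
  set.seed(seed)
  net <- nnet::nnet(enc$x, y, size = hidden_units, decay = decay,
                    maxit = maxit, entropy = TRUE, trace = FALSE,
                    MaxNWts = 10000)
  structure(list(net = net, meta = enc$meta, groups = enc$groups,
                 hidden_units = hidden_units, seed = seed,
                 n_train = nrow(data), deviance = net$value),
            class = "cwp_riskmodel")
}

#' @export
print.cwp_riskmodel <- function(x, ...) {
  cat(sprintf(
    "perceptron %d-%d-1 (%d weights), trained on %d records, seed %d\n",
    x$net$n[1], x$net$n[2], length(x$net$wts), x$n_train, x$seed))
  invisible(x)
}

#' Predict per-worker CWP risk probabilities
#'
#' @param model A [train_model()] fit. @param data Records to score.
#' @return data.frame `worker_id`, `probability` (in `[0, 1]`).
#' @export
predict_risk <- function(model, data) {
  enc <- encode_features(data, meta = model$meta)
  p <- as.numeric(stats::predict(model$net, enc$x))
  data.frame(worker_id = data$worker_id, probability = pmin(pmax(p, 0), 1),
             stringsAsFactors = FALSE)
}

#' Confusion metrics at a probability cutoff
#'
#' Probabilities at or above the cutoff predict the positive (CWP) class.
#'
#' @param probabilities Predicted probabilities. @param labels True 0/1 or
#'   logical labels. @param cutoff Cutoff in (0, 1), default 0.2.
#' @return list: `accuracy`, `sensitivity`, `specificity` (percent), with
#'   numerators/denominators (`tp`, `tn`, `p`, `n_neg`, `n`), and `cutoff`.
#' @export
confusion_metrics <- function(probabilities, labels, cutoff = 0.2) {
  if (length(labels) == 0L) stop("empty label vector")
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  y <- as.logical(labels)
  pred <- probabilities >= cutoff
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  p <- sum(y); n_neg <- sum(!y); n <- length(y)
  list(accuracy = 100 * (tp + tn) / n,
       sensitivity = if (p > 0) 100 * tp / p else NA_real_,
       specificity = if (n_neg > 0) 100 * tn / n_neg else NA_real_,
       tp = tp, tn = tn, p = p, n_neg = n_neg, n = n, cutoff = cutoff)
}

#' Permutation importance of the four input variables
#'
#' Importance of each input (occupational category, era of first
#' exposure, duration, CDE) is the increase in cross-entropy loss when
#' that variable's encoded columns are jointly permuted, averaged over
#' permutations, floored at 0 and normalized to sum to 1. A constant
#' column cannot change the loss and gets importance 0.
#'
#' @param model A [train_model()] fit. @param data Labelled records.
#' @param n_perm Permutations per variable. @param seed Integer seed.
#' @return Named numeric vector over the four inputs, summing to 1.
#' @export
variable_importance <- function(model, data, n_perm = 5L, seed = 1L) {
  enc <- encode_features(data, meta = model$meta)
  y <- as.numeric(data$cwp_status)
  loss <- function(x) {
    p <- pmin(pmax(as.numeric(stats::predict(model$net, x)), 1e-12),
              1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  base <- loss(enc$x)
  set.seed(seed)
  delta <- vapply(enc$groups, function(cols) {
    if (all(apply(enc$x[, cols, drop = FALSE], 2,
                  function(v) length(unique(v)) == 1L))) {
      warning("constant input variable; importance set to 0")
      return(0)
    }
    mean(vapply(seq_len(n_perm), function(i) {
      xp <- enc$x
      perm <- sample.int(nrow(xp))
      xp[, cols] <- xp[perm, cols, drop = FALSE]
      loss(xp) - base
    }, numeric(1)))
  }, numeric(1))
  imp <- pmax(delta, 0)
  if (sum(imp) == 0) {
    warning("no variable changes the loss; returning zeros")
    return(imp)
  }
  imp / sum(imp)
}

#' Calibrate the low/high risk-probability cutoffs
#'
#' The high cutoff is chosen on the grid so that the number of workers at
#' or above it best matches the protected-pool target, defined as the
#' projected future case total increased by 50% (round(total * 1.5)).
#' The low cutoff best matches a designated low-risk pool size (workers
#' strictly below it).
#'
#' @param probabilities Predicted probabilities of workers without CWP.
#' @param projected_total Projected number of future cases.
#' @param low_pool_size Size of the designated low-risk pool.
#' @param grid Candidate cutoffs (default 0.01 steps).
#' @return list: `c_low`, `c_high`, `target_high`, `n_high`, `n_low`.
#' @export
calibrate_thresholds <- function(probabilities, projected_total,
                                 low_pool_size,
                                 grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(probabilities) == 0L) stop("no probabilities")
  if (projected_total <= 0) stop("projected_total must be positive")
  target_high <- round(projected_total * 1.5)
  n_ge <- vapply(grid, function(c) sum(probabilities >= c), numeric(1))
  c_high <- grid[which.min(abs(n_ge - target_high))]
  if (sum(probabilities >= c_high) == 0 && target_high > 0)
    stop("no cutoff on the grid reaches the high-risk target")
  n_lt <- vapply(grid, function(c) sum(probabilities < c), numeric(1))
  c_low <- grid[which.min(abs(n_lt - low_pool_size))]
  if (!(c_low < c_high))
    stop("no grid values satisfy c_low < c_high (got ", c_low, " >= ",
         c_high, ")")
  list(c_low = c_low, c_high = c_high, target_high = target_high,
       n_high = sum(probabilities >= c_high),
       n_low = sum(probabilities < c_low))
}

#' Classify workers into low/middle/high risk
#'
#' Boundary convention: a probability at or above a cutoff falls in the
#' upper class (`p < c_low` -> low; `p >= c_high` -> high; otherwise
#' middle). The three classes partition the input.
#'
#' @param assessments data.frame `worker_id`, `probability` (from
#'   [predict_risk()]).
#' @param c_low,c_high Cutoffs with `c_low < c_high` (e.g. 0.1 and 0.2).
#' @return The input with a `risk_class` factor (`low`/`middle`/`high`)
#'   and the cutoffs as attributes `c_low`, `c_high`.
#' @export
classify_risk <- function(assessments, c_low = 0.1, c_high = 0.2) {
  if (!(c_low < c_high)) stop("c_low must be below c_high")
  p <- assessments$probability
  cls <- ifelse(p < c_low, "low", ifelse(p >= c_high, "high", "middle"))
  assessments$risk_class <- factor(cls, levels = c("low", "middle", "high"))
  attr(assessments, "c_low") <- c_low
  attr(assessments, "c_high") <- c_high
  assessments
}

#' Risk-class rates per worker stratum
#'
#' Cross-tabulates risk classes against the reporting strata
#' (occupational category, era of first exposure, duration and CDE bands)
#' with row percentages — the per-stratum surveillance report.
#'
#' @param classified [classify_risk()] output.
#' @param derived Matching [derive_exposures()] rows (same workers).
#' @param duration_breaks,cde_breaks Stratum boundaries.
#' @return list of data.frames, one per characteristic, with counts and
#'   row percentages per class.
#' @export
stratified_risk_report <- function(classified, derived,
                                   duration_breaks = c(0, 10, 20, 30, Inf),
                                   cde_breaks = c(0, 100, 1000, Inf)) {
  m <- merge(classified, derived, by = "worker_id")
  strata <- list(
    occupational_category = factor(as.character(m$category),
                                   levels = cwp_categories()),
    era_of_first_exposure = factor(as.character(m$era), levels = cwp_eras()),
    duration_years = cut(m$total_duration, duration_breaks, right = FALSE,
                         labels = c("<10", "10-", "20-", "30-")),
    cde_mg_years = cut(m$cde, cde_breaks, right = FALSE,
                       labels = c("<100", "100-", "1000-"))
  )
  lapply(strata, function(s) {
    tab <- table(stratum = s, class = m$risk_class)
    pct <- 100 * prop.table(tab + 0, margin = 1)
    pct[is.nan(pct)] <- 0
    df <- as.data.frame.matrix(tab)
    names(df) <- paste0("n_", names(df))
    cbind(stratum = rownames(df), n = rowSums(tab), df,
          as.data.frame.matrix(round(pct, 1))[,
            c("low", "middle", "high"), drop = FALSE] |>
            stats::setNames(c("pct_low", "pct_middle", "pct_high")),
          row.names = NULL)
  })
}
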