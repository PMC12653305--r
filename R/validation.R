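#' Binarization rule for satellite vs field agreement
#'
#' The damage classification and the defoliation categories are compared on
#' a common damaged/healthy axis. By default the satellite side is positive
#' for classes \{severe damage, damage\} (codes 0, 1) and the field side for
#' categories \{Medium, Severe, Dead\} (defoliation > 25 percent). The rule
#' is fully configurable and is serialized into every agreement report for
#' audit, since the class-to-category mapping is a methodological choice.
#'
#' @param sat_positive_classes Integer class codes counted as damaged.
#' @param field_positive_categories Category labels counted as damaged.
#' @return List of class `binarization_rule`.
#' @export
binarization_rule <- function(sat_positive_classes = c(0L, 1L),
                              field_positive_categories =
                                c("Medium", "Severe", "Dead")) {
  stopifnot(all(sat_positive_classes %in% 0:4),
            all(field_positive_categories %in% defoliation_category_labels()))
  structure(list(sat_positive_classes = as.integer(sat_positive_classes),
                 field_positive_categories = field_positive_categories),
            class = "binarization_rule")
}

#' Binarize a satellite class / field category pair
#'
#' @param sat_class Integer damage class codes 0--4.
#' @param field_category Defoliation category labels or factor.
#' @param rule A [binarization_rule()].
#' @return Data frame with logical columns `sat_positive`, `field_positive`.
#' @export
binarize <- function(sat_class, field_category, rule = binarization_rule()) {
  stopifnot(length(sat_class) == length(field_category))
  data.frame(
    sat_positive = sat_class %in% rule$sat_positive_classes & !is.na(sat_class),
    field_positive = as.character(field_category) %in%
      rule$field_positive_categories & !is.na(field_category))
}

#' Confusion tally of predicted vs reference positives
#'
#' Tallies TP/FP/FN/TN from paired logicals (prediction = satellite,
#' reference = field). Counts can be normalized by the reference
#' positive/negative totals or by the grand total.
#'
#' @param sat_positive,field_positive Logical vectors of equal length >= 1.
#' @param normalize `"none"` (raw counts), `"reference"` (TP and FN divided
#'   by reference positives, FP and TN by reference negatives), or `"total"`.
#' @return List of class `confusion_stats` with `tp`, `fp`, `fn`, `tn`,
#'   `n`, `normalize`.
#' @export
confusion <- function(sat_positive, field_positive,
                      normalize = c("none", "reference", "total")) {
  normalize <- match.arg(normalize)
  stopifnot(length(sat_positive) == length(field_positive),
            length(sat_positive) >= 1)
  tp <- sum(sat_positive & field_positive)
  fp <- sum(sat_positive & !field_positive)
  fn <- sum(!sat_positive & field_positive)
  tn <- sum(!sat_positive & !field_positive)
  n <- length(sat_positive)
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (normalize == "reference") {
    pos <- tp + fn; neg <- fp + tn
    cells <- c(tp = if (pos > 0) tp / pos else NA_real_,
               fp = if (neg > 0) fp / neg else NA_real_,
               fn = if (pos > 0) fn / pos else NA_real_,
               tn = if (neg > 0) tn / neg else NA_real_)
  } else if (normalize == "total") {
    cells <- cells / n
  }
  structure(c(as.list(cells), list(n = n, normalize = normalize)),
            class = "confusion_stats")
}

#' Derived confusion-matrix metrics
#'
#' Computes precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, total accuracy `(TP+TN)/(TP+TN+FP+FN)` and
#' `F1 = 2TP/(2TP+FP+FN)` from the four cells. A metric whose denominator is
#' zero is undefined and reported as `NA` (an explicit marker, never a
#' silent 0). Works on raw counts or normalized rates alike, since the
#' formulas are scale-invariant.
#'
#' @param x A `confusion_stats` object from [confusion()], or a numeric with
#'   named elements `tp`, `fp`, `fn`, `tn`.
#' @return The input cells plus `precision`, `sensitivity`, `specificity`,
#'   `total_accuracy`, `f1`, as a `confusion_stats` list.
#' @export
agreement_metrics <- function(x) {
  cells <- if (inherits(x, "confusion_stats")) x else as.list(x)
  tp <- cells$tp; fp <- cells$fp; fn <- cells$fn; tn <- cells$tn
  safe <- function(num, den) if (is.na(den) || den <= 0) NA_real_ else num / den
  out <- c(list(tp = tp, fp = fp, fn = fn, tn = tn),
           list(precision = safe(tp, tp + fp),
                sensitivity = safe(tp, tp + fn),
                specificity = safe(tn, tn + fp),
                total_accuracy = safe(tp + tn, tp + tn + fp + fn),
                f1 = safe(2 * tp, 2 * tp + fp + fn)))
  out$n <- cells$n; out$normalize <- cells$normalize
  structure(out, class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("<confusion tp=%.3g fp=%.3g fn=%.3g tn=%.3g", x$tp, x$fp, x$fn, x$tn))
  if (!is.null(x$precision))
    cat(sprintf("  P=%.2f Se=%.2f Sp=%.2f TA=%.2f F1=%.2f",
                x$precision, x$sensitivity, x$specificity,
                x$total_accuracy, x$f1))
  cat(">\n")
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `k = (p_o - p_e) / (1 - p_e)` between two
#' categorical labelings, where `p_o` is the observed agreement and `p_e`
#' the chance agreement from the marginal products. Supports the binary and
#' the general K-category case. When `p_e = 1` exactly (both raters
#' constant), kappa is undefined and `NA` is returned.
#'
#' @param x Either a vector of labels (with `y` the second rater) or a
#'   square contingency matrix of joint counts (rows = rater 1, columns =
#'   rater 2, identical category order).
#' @param y Second label vector; ignored when `x` is a matrix.
#' @return Kappa in \[-1, 1\], or `NA` if undefined.
#' @examples
#' cohens_kappa(c(1, 1, 0), c(1, 1, 0))  # 1
#' @export
cohens_kappa <- function(x, y = NULL) {
  if (is.matrix(x)) {
    tab <- x
    if (nrow(tab) != ncol(tab)) stop("contingency matrix must be square")
  } else {
    stopifnot(!is.null(y), length(x) == length(y), length(x) >= 1)
    ok <- !is.na(x) & !is.na(y)
    x <- as.character(x[ok]); y <- as.character(y[ok])
    if (length(x) == 0) return(NA_real_)
    lev <- sort(unique(c(x, y)))
    tab <- table(factor(x, lev), factor(y, lev))
  }
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Regression agreement between plot anomalies and field defoliation
#'
#' OLS of field defoliation percentage on the plot-level anomaly value
#' (optionally sign-flipped so that larger predictor means more damage),
#' reporting `R^2` and RMSE in defoliation-percent units.
#'
#' @param sat_values Plot-level z (or class codes), the predictor.
#' @param field_defoliation_pct Field defoliation percentages, the response.
#' @param sign Multiplier applied to the predictor, default -1 (damage is
#'   negative z, so -z increases with damage). R^2 and RMSE are invariant to
#'   the choice.
#' @return `regression_result` (see [fit_tpf_vs_z()]).
#' @export
regression_agreement <- function(sat_values, field_defoliation_pct, sign = -1) {
  ok <- !is.na(sat_values) & !is.na(field_defoliation_pct)
  x <- sign * sat_values[ok]; y <- field_defoliation_pct[ok]
  if (length(x) < 3) stop("need at least 3 pairs")
  ols_fit(x, y)
}

#' Stratified agreement reports
#'
#' Runs the full agreement battery (confusion cells, the derived metrics,
#' binary Cohen's kappa, and R^2/RMSE of defoliation on z) per stratum plus
#' a grand pooled row. Plot-years with a missing satellite value are
#' excluded from the statistics and counted per stratum. Strata with fewer
#' pairs than needed get `NA` metrics (with the reason retained in
#' `n_missing`/`n_used`).
#'
#' @param data Data frame with columns `plot_id`, `level`, `year`, `z`,
#'   `class`, `defoliation_pct` (e.g. [extract_plot_z()] joined with the
#'   plot records on plot_id and year).
#' @param strata `"year"`, `"plot"` or `"level"`.
#' @param rule A [binarization_rule()].
#' @param normalize Normalization mode passed to [confusion()].
#' @return Data frame, one row per stratum plus `"pooled"`, with the
#'   confusion cells, derived metrics, kappa, r_squared, rmse, n_used,
#'   n_missing. The rule is attached as attribute `rule`.
#' @export
pooled_report <- function(data, strata = c("year", "plot", "level"),
                          rule = binarization_rule(),
                          normalize = "none") {
  strata <- match.arg(strata)
  key <- switch(strata, year = data$year, plot = data$plot_id,
                level = data$level)
  groups <- c(split(data, key), list(pooled = data))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    miss <- is.na(d$class) | is.na(d$defoliation_pct)
    d <- d[!miss, ]
    base <- data.frame(stratum = g, n_used = nrow(d), n_missing = sum(miss))
    if (nrow(d) == 0) {
      met <- rep(NA_real_, 11)
      names(met) <- c("tp", "fp", "fn", "tn", "precision", "sensitivity",
                      "specificity", "total_accuracy", "f1", "kappa",
                      "r_squared")
      return(cbind(base, as.data.frame(as.list(met)), rmse = NA_real_))
    }
    b <- binarize(d$class, categorize_defoliation(d$defoliation_pct), rule)
    m <- agreement_metrics(confusion(b$sat_positive, b$field_positive,
                                     normalize = normalize))
    kap <- cohens_kappa(b$sat_positive, b$field_positive)
    reg <- if (nrow(d) >= 3 && stats::var(d$z, na.rm = TRUE) > 0)
      regression_agreement(d$z, d$defoliation_pct)
    else list(r_squared = NA_real_, rmse = NA_real_)
    cbind(base, data.frame(tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
                           precision = m$precision, sensitivity = m$sensitivity,
                           specificity = m$specificity,
                           total_accuracy = m$total_accuracy, f1 = m$f1,
                           kappa = kap, r_squared = reg$r_squared,
                           rmse = reg$rmse))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rule") <- rule
  attr(out, "normalize") <- normalize
  out
}
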