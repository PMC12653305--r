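#' Temperature-Precipitation Factor (TPF)
#'
#' Drought index of the growing season:
#' `TPF = 100 * mean(monthly mean temperature) / sum(monthly precipitation)`
#' over March--August. The "average temperature" is the unweighted mean of
#' the six monthly means. Higher values indicate a more drought-stressed
#' season. All six months must be present and total precipitation positive.
#'
#' @param climate Data frame with columns `site_id`, `year`, `month`,
#'   `tmean_c`, `precip_mm` (e.g. from [simulate_climate()] or
#'   [read_climate_csv()]).
#' @param site,year Optional filters; if omitted, TPF is computed for every
#'   site-year present.
#' @return Data frame `site_id`, `year`, `tpf`; a single numeric value when
#'   both `site` and `year` are given.
#' @examples
#' cl <- data.frame(site_id = "a", year = 2020, month = 3:8,
#'                  tmean_c = 15, precip_mm = 50)
#' tpf(cl)  # 100 * 15 / 300 = 5
#' @export
tpf <- function(climate, site = NULL, year = NULL) {
  if (!is.null(site)) climate <- climate[climate$site_id %in% site, ]
  if (!is.null(year)) climate <- climate[climate$year %in% year, ]
  climate <- climate[climate$month %in% 3:8, ]
  if (any(climate$precip_mm < 0, na.rm = TRUE))
    stop("negative precipitation")
  key <- interaction(climate$site_id, climate$year, drop = TRUE)
  res <- do.call(rbind, lapply(split(climate, key), function(d) {
    if (!setequal(d$month, 3:8) || anyNA(d$tmean_c) || anyNA(d$precip_mm))
      stop(sprintf("site %s year %s: months March-August incomplete",
                   d$site_id[1], d$year[1]))
    p <- sum(d$precip_mm)
    if (p <= 0) stop(sprintf("site %s year %s: zero total precipitation",
                             d$site_id[1], d$year[1]))
    data.frame(site_id = d$site_id[1], year = d$year[1],
               tpf = 100 * mean(d$tmean_c) / p)
  }))
  rownames(res) <- NULL
  res <- res[order(res$site_id, res$year), ]
  if (!is.null(site) && !is.null(year) && nrow(res) == 1) return(res$tpf)
  res
}

#' Ordinary least-squares fit of plot anomalies on TPF
#'
#' Regresses a plot-level Z NDVI response on the site's yearly TPF with an
#' intercept: `R^2 = 1 - RSS/TSS`, `RMSE = sqrt(mean squared residual)`.
#' Pairs with missing values are dropped. The response is the continuous
#' plot mean z by default; pass the ordinal class codes to reproduce the
#' class-code variant.
#'
#' @param tpf_by_year Numeric predictor (one value per year).
#' @param z_by_year Numeric response, same length.
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `rmse`, `n`.
#' @export
fit_tpf_vs_z <- function(tpf_by_year, z_by_year) {
  stopifnot(length(tpf_by_year) == length(z_by_year))
  ok <- !is.na(tpf_by_year) & !is.na(z_by_year)
  x <- tpf_by_year[ok]; y <- z_by_year[ok]
  if (length(x) < 3) stop("need at least 3 paired years")
  if (stats::var(x) == 0) stop("zero variance in predictor")
  ols_fit(x, y)
}

# Shared OLS-with-intercept summary used by the climate and validation sides.
ols_fit <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 rmse = sqrt(mean(res^2)), n = length(y)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<ols  y = %.4g + %.4g x  R2 = %.3f  RMSE = %.3f  n = %d>\n",
              x$intercept, x$slope, x$r_squared, x$rmse, x$n))
  invisible(x)
}
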