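#' Normalised Difference Vegetation Index
#'
#' Per pixel `(NIR - RED) / (NIR + RED)`. Pixels with a zero band sum are
#' invalid (`NA`), not an error.
#'
#' @param red,nir Numeric vectors, matrices or arrays of equal shape.
#' @return NDVI values with the shape of the inputs.
#' @examples
#' ndvi(red = 0.1, nir = 0.4)  # 0.6
#' @export
ndvi <- function(red, nir) {
  if (!identical(dim(red), dim(nir)) || length(red) != length(nir))
    stop("red and nir grids must share shape")
  s <- nir + red
  out <- (nir - red) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Standardized NDVI anomaly (Z NDVI)
#'
#' Per pixel, standardizes each year's growing-season NDVI against the mean
#' and standard deviation over the baseline years:
#' `z_y = (NDVI_y - mean) / sd`. The baseline includes the evaluated year
#' (the reference period is the full analysed span). Pixels whose baseline
#' SD falls below `eps` are degenerate: they get `z = 0` in every year and
#' are flagged. A pixel's z is defined only where the pixel is valid in
#' every baseline year and in the year itself.
#'
#' @param ndvi_by_year Named list (names = year labels) of NDVI matrices of
#'   equal shape, or a list of [median_composite()] results.
#' @param baseline_years Year labels of the reference period; at least 2,
#'   all present in `ndvi_by_year`. Default: all years.
#' @param sd_type `"population"` (divide by N, default) or `"sample"` (N-1).
#'   With a 7-year baseline the choice is material, so it is echoed in the
#'   result.
#' @param eps Degeneracy threshold on the baseline SD, NDVI units.
#' @return Object of class `anomaly_set`: `years`, `ndvi` (list), `ndvi_mean`,
#'   `ndvi_sd`, `z` (list of matrices), `classes` (list of integer matrices),
#'   `degenerate` (logical matrix), `n_degenerate`, `sd_type`.
#' @export
z_ndvi <- function(ndvi_by_year, baseline_years = NULL,
                   sd_type = c("population", "sample"), eps = 1e-6) {
  sd_type <- match.arg(sd_type)
  grids <- lapply(ndvi_by_year, function(x)
    if (inherits(x, "annual_composite")) x$ndvi else x)
  if (is.null(names(grids)) || any(names(grids) == ""))
    stop("ndvi_by_year must be a named list (names are year labels)")
  years <- names(grids)
  if (is.null(baseline_years)) baseline_years <- years
  baseline_years <- as.character(baseline_years)
  if (length(baseline_years) < 2) stop("need at least 2 baseline years")
  if (!all(baseline_years %in% years))
    stop("baseline_years must be a subset of the available years")
  dm <- dim(grids[[1]])
  stopifnot(all(vapply(grids, function(g) identical(dim(g), dm), logical(1))))

  base <- grids[baseline_years]
  nb <- length(base)
  valid_base <- Reduce(`&`, lapply(base, function(g) !is.na(g)))
  m <- Reduce(`+`, lapply(base, function(g) ifelse(is.na(g), 0, g))) / nb
  ss <- Reduce(`+`, lapply(base, function(g) ifelse(is.na(g), 0, (g - m)^2)))
  v <- if (sd_type == "population") ss / nb else ss / (nb - 1)
  s <- sqrt(v)
  m[!valid_base] <- NA_real_
  s[!valid_base] <- NA_real_
  degenerate <- valid_base & s < eps
  z <- lapply(grids, function(g) {
    zz <- (g - m) / s
    zz[degenerate] <- 0
    zz[is.na(g) | !valid_base] <- NA_real_
    zz
  })
  structure(list(years = years, ndvi = grids, ndvi_mean = m, ndvi_sd = s,
                 z = z, classes = lapply(z, classify_z),
                 degenerate = degenerate, n_degenerate = sum(degenerate),
                 sd_type = sd_type, baseline_years = baseline_years),
            class = "anomaly_set")
}

#' @export
print.anomaly_set <- function(x, ...) {
  cat(sprintf("<anomaly_set %d years (%s..%s)  %dx%d px  %d degenerate  %s SD>\n",
              length(x$years), x$years[1], x$years[length(x$years)],
              nrow(x$ndvi_mean), ncol(x$ndvi_mean), x$n_degenerate, x$sd_type))
  invisible(x)
}

#' Damage class distribution of a classified grid
#'
#' Percent of classified pixels per damage class; unclassified (`NA`) pixels
#' are excluded from the denominator.
#'
#' @param class_grid Integer matrix of class codes 0--4 (see [classify_z()]).
#' @param year Optional year label carried into the output.
#' @return Data frame with columns `year`, `class`, `label`, `percent`,
#'   `n_pixels` (one row per class; `n_pixels` is the per-class count, the
#'   classified total is the attribute `n_classified`).
#' @export
class_distribution <- function(class_grid, year = NA) {
  n <- sum(!is.na(class_grid))
  if (n == 0) stop("no classified pixels")
  counts <- vapply(0:4, function(k) sum(class_grid == k, na.rm = TRUE), 0L)
  out <- data.frame(year = year, class = 0:4, label = damage_class_labels(),
                    percent = 100 * counts / n, n_pixels = counts)
  attr(out, "n_classified") <- n
  out
}
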