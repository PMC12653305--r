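#' Extract plot-level Z NDVI series from an anomaly set
#'
#' For each plot and year, aggregates z over a square window of radius
#' `radius` pixels (default 1, i.e. a 3x3 window, about 30 m at 10 m pixels,
#' matching the scale of a monitoring plot) centred on the plot pixel,
#' clipped at the grid edge and intersected with valid pixels. The class is
#' derived from the aggregated z with the same intervals as [classify_z()]
#' (mode `"mean"`), or as the modal member-pixel class (mode `"modal"`).
#' Plot-years with zero valid pixels get `NA` (a missing marker), not an
#' error.
#'
#' @param anoms An [z_ndvi()] `anomaly_set`.
#' @param plots Data frame with columns `plot_id`, `level`, `row`, `col`
#'   (one row per plot; extra columns ignored, duplicated plot ids collapsed).
#' @param radius Non-negative integer window radius in pixels.
#' @param agg `"mean"` (default) or `"modal"`.
#' @return Data frame of class series: `plot_id`, `level`, `year`, `z`,
#'   `class`, `n_valid`.
#' @export
extract_plot_z <- function(anoms, plots, radius = 1, agg = c("mean", "modal")) {
  agg <- match.arg(agg)
  stopifnot(inherits(anoms, "anomaly_set"), radius >= 0)
  plots <- unique(plots[, c("plot_id", "level", "row", "col")])
  nr <- nrow(anoms$ndvi_mean); nc <- ncol(anoms$ndvi_mean)
  bad <- plots$row < 1 | plots$row > nr | plots$col < 1 | plots$col > nc
  if (any(bad))
    stop("plots outside the grid: ", paste(plots$plot_id[bad], collapse = ", "))
  out <- expand.grid(plot_id = plots$plot_id, year = anoms$years,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$level <- plots$level[match(out$plot_id, plots$plot_id)]
  out$z <- NA_real_; out$class <- NA_integer_; out$n_valid <- 0L
  for (i in seq_len(nrow(out))) {
    p <- plots[match(out$plot_id[i], plots$plot_id), ]
    zg <- anoms$z[[out$year[i]]]
    rows <- max(1, p$row - radius):min(nr, p$row + radius)
    cols <- max(1, p$col - radius):min(nc, p$col + radius)
    zw <- zg[rows, cols, drop = FALSE]
    zv <- zw[!is.na(zw)]
    out$n_valid[i] <- length(zv)
    if (length(zv) > 0) {
      if (agg == "mean") {
        out$z[i] <- mean(zv)
        out$class[i] <- classify_z(out$z[i])
      } else {
        cl <- classify_z(zv)
        tab <- tabulate(cl + 1L, nbins = 5L)
        out$class[i] <- which.max(tab) - 1L  # ties toward the worse class
        out$z[i] <- mean(zv)
      }
    }
  }
  out[, c("plot_id", "level", "year", "z", "class", "n_valid")]
}

#' Plot-network class-count table
#'
#' Counts plots per damage class and year from a plot series; missing
#' plot-years (NA class) are excluded from the counts and reported in a
#' `missing` column, so `rowSums(counts) + missing` equals the number of
#' plots for every year.
#'
#' @param series Output of [extract_plot_z()] (optionally pre-filtered to
#'   one level).
#' @return Data frame with one row per year: `year`, one column per class
#'   label, `missing`.
#' @export
level_table <- function(series) {
  stopifnot(nrow(series) >= 1)
  years <- sort(unique(series$year))
  labs <- damage_class_labels()
  out <- data.frame(year = years)
  for (k in 0:4)
    out[[labs[k + 1]]] <- vapply(years, function(y)
      sum(series$year == y & series$class == k, na.rm = TRUE), 0L)
  out$missing <- vapply(years, function(y)
    sum(series$year == y & is.na(series$class)), 0L)
  out
}
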