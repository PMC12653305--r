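#' Plain-text grid serialization
#'
#' Rasters are carried as plain numeric matrices and persisted as
#' tab-separated text grids (one row per pixel row, `NA` for invalid
#' pixels), which keeps every artifact human-readable and diff-able.
#'
#' @param grid Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly (`write_grid_tsv`); the matrix
#'   (`read_grid_tsv`).
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Read a plot table
#'
#' Expects at least `plot_id`, `level`, `row`, `col`, `year`,
#' `defoliation_pct`; extra columns (dieback, discolouration, notes) pass
#' through untouched.
#'
#' @param path CSV file path.
#' @return Data frame with a `defoliation_category` column added when absent.
#' @export
read_plots_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "level", "row", "col", "year", "defoliation_pct")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("plot CSV is missing columns: ", paste(missing, collapse = ", "))
  if (is.null(d$defoliation_category))
    d$defoliation_category <- categorize_defoliation(d$defoliation_pct)
  d
}

#' Read a monthly climate table
#'
#' Expects columns `site_id`, `year`, `month`, `tmean_c`, `precip_mm`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_climate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "month", "tmean_c", "precip_mm")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("climate CSV is missing columns: ", paste(missing, collapse = ", "))
  d
}
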