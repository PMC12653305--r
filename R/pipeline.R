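#' Pipeline configuration
#'
#' Bundles every stage's parameters into one reproducible object. All
#' randomness is governed by the simulation seed; the same configuration
#' always produces bit-identical outputs.
#'
#' @param sim A [simulation_config()] (the pipeline's input world), or `NULL`
#'   when `scenes`/`plots`/`climate` are supplied to [run_pipeline()]
#'   directly.
#' @param mask A [mask_config()].
#' @param baseline_years Years of the standardization baseline (default all).
#' @param sd_type SD convention for [z_ndvi()].
#' @param stat_on Compositing mode for [median_composite()].
#' @param radius Plot extraction window radius for [extract_plot_z()].
#' @param agg Plot aggregation mode (`"mean"` or `"modal"`).
#' @param rule A [binarization_rule()].
#' @param normalize Confusion normalization mode.
#' @param clip_mask Optional logical matrix; pixels outside it are dropped
#'   before standardization (the study-area clipping step).
#' @param out_dir Optional output directory; when given, all tables, grids
#'   and a JSON run manifest are written there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            mask = mask_config(),
                            baseline_years = NULL,
                            sd_type = "population",
                            stat_on = "bands",
                            radius = 1,
                            agg = "mean",
                            rule = binarization_rule(),
                            normalize = "none",
                            clip_mask = NULL,
                            out_dir = NULL) {
  structure(list(sim = sim, mask = mask, baseline_years = baseline_years,
                 sd_type = sd_type, stat_on = stat_on, radius = radius,
                 agg = agg, rule = rule, normalize = normalize,
                 clip_mask = clip_mask, out_dir = out_dir),
            class = "pipeline_config")
}

#' Clip a grid to a study-area mask
#'
#' Invalidates (sets `NA`) every pixel outside the mask; grid geometry is
#' preserved. An all-false mask is allowed but warns.
#'
#' @param grid Numeric matrix.
#' @param mask Logical matrix of the same shape (`TRUE` = keep).
#' @return The clipped grid.
#' @export
clip_to_mask <- function(grid, mask) {
  if (!identical(dim(grid), dim(mask)))
    stop("mask extent does not match the grid")
  if (!any(mask)) warning("clip mask is empty; all pixels invalidated")
  grid[!mask] <- NA_real_
  grid
}

#' Run the full anomaly-and-validation pipeline
#'
#' Executes simulate (optional) -> scene prefilter -> pixel masking ->
#' median composite -> NDVI -> Z NDVI -> classification -> class
#' distributions -> plot extraction -> level tables -> TPF -> agreement
#' reports, and writes a machine-readable JSON manifest recording the
#' configuration, seed, per-stage counts and output-file checksums.
#'
#' @param cfg A [pipeline_config()].
#' @param scenes,plots,climate Optional pre-built inputs (as produced by the
#'   simulator or read from files); when omitted they are simulated from
#'   `cfg$sim`.
#' @return List with `composites`, `anomalies`, `distributions`,
#'   `plot_series`, `level_tables`, `tpf`, `reports`, `tpf_regressions`,
#'   `manifest` (and `truth` when simulated). Written to `cfg$out_dir` when
#'   set.
#' @export
run_pipeline <- function(cfg = pipeline_config(), scenes = NULL,
                         plots = NULL, climate = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  truth <- NULL
  if (is.null(scenes)) {
    if (is.null(cfg$sim)) stop("no scenes supplied and no simulation config")
    sim <- simulate_scenes(cfg$sim)
    scenes <- sim$scenes
    truth <- sim$truth
    if (is.null(plots)) plots <- simulate_plots(cfg$sim, truth)
    if (is.null(climate)) climate <- simulate_climate(cfg$sim)
  }
  log_stage <- function(...) message("[zndvi] ", sprintf(...))

  # preprocess: prefilter, mask, composite per year
  composites <- list()
  n_in <- 0L; n_kept <- 0L
  for (y in names(scenes)) {
    sc <- scenes[[y]]
    n_in <- n_in + length(sc)
    kept <- withCallingHandlers(prefilter_scenes(sc, cfg$mask),
                                warning = function(w) invokeRestart("muffleWarning"))
    n_kept <- n_kept + length(kept)
    if (length(kept) == 0) {
      log_stage("year %s: no scenes survive the prefilter", y)
      dm <- dim(sc[[1]]$red)
      composites[[y]] <- structure(
        list(year = y, red = matrix(NA_real_, dm[1], dm[2]),
             nir = matrix(NA_real_, dm[1], dm[2]),
             ndvi = matrix(NA_real_, dm[1], dm[2]),
             n_obs = matrix(0L, dm[1], dm[2]),
             valid = matrix(FALSE, dm[1], dm[2]), stat_on = cfg$stat_on),
        class = "annual_composite")
      next
    }
    kept <- lapply(kept, mask_pixels, cfg = cfg$mask)
    composites[[y]] <- median_composite(kept, y, stat_on = cfg$stat_on)
  }
  log_stage("prefilter kept %d of %d scenes (QA preset '%s')",
            n_kept, n_in, cfg$mask$preset)

  ndvi_by_year <- lapply(composites, function(cp) cp$ndvi)
  if (!is.null(cfg$clip_mask))
    ndvi_by_year <- lapply(ndvi_by_year, clip_to_mask, mask = cfg$clip_mask)

  anoms <- z_ndvi(ndvi_by_year, baseline_years = cfg$baseline_years,
                  sd_type = cfg$sd_type)
  log_stage("standardized %d years; %d degenerate pixels",
            length(anoms$years), anoms$n_degenerate)

  distributions <- do.call(rbind, lapply(anoms$years, function(y)
    class_distribution(anoms$classes[[y]], year = y)))

  result <- list(composites = composites, anomalies = anoms,
                 distributions = distributions, truth = truth)

  if (!is.null(plots)) {
    series <- extract_plot_z(anoms, plots, radius = cfg$radius, agg = cfg$agg)
    level_tables <- lapply(split(series, series$level), level_table)
    joined <- merge(series,
                    plots[, c("plot_id", "year", "defoliation_pct")],
                    by = c("plot_id", "year"))
    reports <- list(year = pooled_report(joined, "year", cfg$rule, cfg$normalize),
                    plot = pooled_report(joined, "plot", cfg$rule, cfg$normalize),
                    level = pooled_report(joined, "level", cfg$rule, cfg$normalize))
    result$plot_series <- series
    result$level_tables <- level_tables
    result$reports <- reports
    log_stage("extracted %d plot-year values (%d missing)", nrow(series),
              sum(is.na(series$class)))
  } else {
    log_stage("no plot table supplied; stopping after class distributions")
  }

  if (!is.null(climate) && !is.null(plots)) {
    tpf_tab <- tpf(climate)
    sites <- unique(tpf_tab$site_id)
    l2 <- result$plot_series[result$plot_series$level == "II", ]
    regs <- list()
    for (i in seq_along(sites)) {
      pid <- sort(unique(l2$plot_id))[i]
      if (is.na(pid)) next
      zi <- l2[l2$plot_id == pid, ]
      ti <- tpf_tab[tpf_tab$site_id == sites[i], ]
      m <- merge(zi, ti, by = "year")
      regs[[pid]] <- tryCatch(fit_tpf_vs_z(m$tpf, m$z), error = function(e) NULL)
    }
    result$tpf <- tpf_tab
    result$tpf_regressions <- regs
  }

  result$manifest <- build_manifest(cfg, result)
  if (!is.null(cfg$out_dir)) write_outputs(cfg, result)
  invisible(result)
}

build_manifest <- function(cfg, result) {
  cfg_json <- jsonlite::toJSON(rapply(unclass(cfg), unclass, how = "replace"),
                               auto_unbox = TRUE, null = "null", digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  list(package = as.character(utils::packageVersion("zndvi")),
       seed = if (!is.null(cfg$sim)) cfg$sim$seed else NA,
       config_hash = unname(tools::md5sum(tf)),
       config = jsonlite::fromJSON(cfg_json),
       counts = list(
         years = length(result$composites),
         pixels = length(result$composites[[1]]$ndvi),
         degenerate_pixels = result$anomalies$n_degenerate,
         plot_years = if (!is.null(result$plot_series)) nrow(result$plot_series) else 0L,
         missing_plot_years = if (!is.null(result$plot_series))
           sum(is.na(result$plot_series$class)) else 0L))
}

write_outputs <- function(cfg, result) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(cfg$out_dir, ...)
  utils::write.csv(result$distributions, p("class_distribution.csv"),
                   row.names = FALSE)
  for (y in result$anomalies$years) {
    write_grid_tsv(result$anomalies$z[[y]], p(sprintf("z_%s.tsv", y)))
    write_grid_tsv(result$anomalies$classes[[y]], p(sprintf("classes_%s.tsv", y)))
  }
  if (!is.null(result$plot_series)) {
    utils::write.csv(result$plot_series, p("plot_series.csv"), row.names = FALSE)
    for (lv in names(result$level_tables))
      utils::write.csv(result$level_tables[[lv]],
                       p(sprintf("level_table_%s.csv", lv)), row.names = FALSE)
    for (st in names(result$reports)) {
      rep_out <- result$reports[[st]]
      num <- vapply(rep_out, is.numeric, logical(1))
      rep_out[num] <- lapply(rep_out[num], round, digits = 2)
      utils::write.csv(rep_out, p(sprintf("agreement_%s.csv", st)),
                       row.names = FALSE)
    }
  }
  if (!is.null(result$tpf))
    utils::write.csv(result$tpf, p("tpf.csv"), row.names = FALSE)
  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  result$manifest$files <- lapply(stats::setNames(tools::md5sum(files),
                                                  basename(files)), unname)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(cfg$out_dir)
}
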