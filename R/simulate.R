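#' Configuration for the synthetic forest scene simulator
#'
#' Builds and validates the configuration of the synthetic world: a small
#' Sentinel-2-like tile observed several times per growing season over a run
#' of years, with injected disturbance events, cloud/shadow contamination, a
#' two-tier plot network with defoliation responses, and site-level monthly
#' climate.
#'
#' The simulated world is deliberately simple but *stated*: the healthy NDVI
#' surface is a fixed smooth spatial field around `baseline_ndvi`; interannual
#' variability is a fixed zero-mean "year quality" signal shared by all
#' pixels and scaled to `interannual_sd` (a common climate signal, not i.i.d.
#' pixel noise -- per-pixel standardization is scale-invariant, so a purely
#' i.i.d. interannual world would flag a constant fraction of healthy pixels
#' as damaged no matter how small the noise); disturbance events subtract
#' `drop` NDVI units inside their footprint in their year; per-scene
#' observation noise has SD `noise_sd`.
#'
#' @param years Integer vector of consecutive year labels.
#' @param grid_rows,grid_cols Pixel counts of the tile.
#' @param pixel_size Pixel edge length in metres.
#' @param scenes_per_year Number of acquisitions inside each growing season.
#' @param baseline_ndvi Mean healthy NDVI, in (0, 1).
#' @param spatial_sd Amplitude of the fixed spatial NDVI field (NDVI units).
#' @param interannual_sd Standard deviation of the shared year-quality signal
#'   (NDVI units). Zero gives a constant baseline (degenerate pixels).
#' @param disturbance_events List of events, each a list with elements
#'   `year`, `drop` (NDVI units, >= 0) and either `fraction` (of tile area,
#'   realized as the first pixels in row-major order) or `footprint`
#'   (logical matrix of tile shape).
#' @param cloud_fraction Per-scene probability that a cloud block is
#'   contaminated, in \[0, 1\].
#' @param cloud_block Edge length (pixels) of the square cloud blocks.
#' @param n_plots_level1,n_plots_level2 Plot counts of the two network tiers.
#' @param defoliation_base Baseline defoliation percent of healthy plots.
#' @param defoliation_gain Percent defoliation per unit of local NDVI drop.
#' @param noise_sd Observation noise SD on per-scene NDVI; defoliation
#'   observation noise is `100 * noise_sd` percent.
#' @param drought_coupling If `TRUE`, disturbance years get hotter, drier
#'   March--August climate so the TPF drought factor co-varies with damage.
#' @param drought_precip_factor Multiplier on precipitation in drought years.
#' @param drought_temp_delta Additive temperature offset (degrees C) in
#'   drought years.
#' @param climate_noise_sd SD of additive monthly temperature noise (degrees
#'   C); precipitation gets a lognormal multiplier with sdlog 0.05.
#' @param seed Integer master seed. All randomness flows from it through four
#'   sub-streams drawn in a fixed order (scenes, clouds, plots, climate), so
#'   e.g. the climate series does not depend on whether scenes were generated.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(years = 2017:2023,
                              grid_rows = 20, grid_cols = 20,
                              pixel_size = 10,
                              scenes_per_year = 8,
                              baseline_ndvi = 0.8,
                              spatial_sd = 0.05,
                              interannual_sd = 0.05,
                              disturbance_events = list(
                                list(year = 2022, fraction = 0.4, drop = 0.3)),
                              cloud_fraction = 0.05,
                              cloud_block = 4,
                              n_plots_level1 = 78,
                              n_plots_level2 = 7,
                              defoliation_base = 5,
                              defoliation_gain = 100,
                              noise_sd = 0.02,
                              drought_coupling = TRUE,
                              drought_precip_factor = 0.6,
                              drought_temp_delta = 1.5,
                              climate_noise_sd = 0.3,
                              seed = 1L) {
  cfg <- list(years = as.integer(years), grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols), pixel_size = pixel_size,
              scenes_per_year = as.integer(scenes_per_year),
              baseline_ndvi = baseline_ndvi, spatial_sd = spatial_sd,
              interannual_sd = interannual_sd,
              disturbance_events = disturbance_events,
              cloud_fraction = cloud_fraction,
              cloud_block = as.integer(cloud_block),
              n_plots_level1 = as.integer(n_plots_level1),
              n_plots_level2 = as.integer(n_plots_level2),
              defoliation_base = defoliation_base,
              defoliation_gain = defoliation_gain,
              noise_sd = noise_sd,
              drought_coupling = isTRUE(drought_coupling),
              drought_precip_factor = drought_precip_factor,
              drought_temp_delta = drought_temp_delta,
              climate_noise_sd = climate_noise_sd,
              seed = as.integer(seed))
  stopifnot(length(cfg$years) >= 2, !anyDuplicated(cfg$years),
            cfg$grid_rows >= 1, cfg$grid_cols >= 1,
            cfg$scenes_per_year >= 1,
            cfg$baseline_ndvi > 0, cfg$baseline_ndvi < 1,
            cfg$spatial_sd >= 0, cfg$interannual_sd >= 0,
            cfg$cloud_fraction >= 0, cfg$cloud_fraction <= 1,
            cfg$cloud_block >= 1,
            cfg$n_plots_level1 >= 1, cfg$n_plots_level2 >= 1,
            cfg$noise_sd >= 0, cfg$climate_noise_sd >= 0,
            cfg$drought_precip_factor > 0)
  for (ev in cfg$disturbance_events) {
    if (is.null(ev$year) || !(ev$year %in% cfg$years))
      stop("disturbance event year must be one of the simulated years")
    if (is.null(ev$drop) || ev$drop < 0)
      stop("disturbance ndvi drop must be >= 0")
    if (!is.null(ev$footprint)) {
      if (!is.logical(ev$footprint) ||
          !identical(dim(ev$footprint), c(cfg$grid_rows, cfg$grid_cols)))
        stop("disturbance footprint must be a logical grid_rows x grid_cols matrix")
    } else if (is.null(ev$fraction) || ev$fraction <= 0 || ev$fraction > 1) {
      stop("disturbance event needs a footprint matrix or a fraction in (0, 1]")
    }
    if (cfg$baseline_ndvi - cfg$spatial_sd * 1.5 - ev$drop <= -1)
      stop("disturbance drop would push NDVI below -1")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Four independent sub-seeds derived from the master seed in a fixed order.
stream_seeds <- function(config) {
  set.seed(config$seed)
  stats::setNames(sample.int(2147483646L, 4),
                  c("scenes", "clouds", "plots", "climate"))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fixed smooth spatial NDVI field: deterministic, so it cancels exactly in
# per-pixel standardization and consumes no RNG.
pixel_baseline <- function(config) {
  r <- seq_len(config$grid_rows) / config$grid_rows
  c_ <- seq_len(config$grid_cols) / config$grid_cols
  surf <- outer(sin(2 * pi * r), cos(2 * pi * c_)) / sqrt(0.5)
  clamp(config$baseline_ndvi + config$spatial_sd * surf, 0.02, 0.98)
}

# Shared year-quality signal, scaled to population SD = interannual_sd over
# the simulated years. Shape: the first year is an exceptionally favourable
# reference season and later years sit slightly below the long-term mean
# (standardized values sqrt(n-1) and -1/sqrt(n-1)), so no healthy year falls
# into a damage class on its own; damage classes are driven by the injected
# disturbance events alone.
year_effects <- function(config) {
  n <- length(config$years)
  p <- c(n - 1, rep(-1, n - 1))
  s <- sqrt(mean(p^2))
  eff <- if (config$interannual_sd > 0) p / s * config$interannual_sd
         else rep(0, n)
  stats::setNames(eff, config$years)
}

event_footprint <- function(ev, config) {
  if (!is.null(ev$footprint)) return(ev$footprint)
  k <- round(ev$fraction * config$grid_rows * config$grid_cols)
  matrix(seq_len(config$grid_rows * config$grid_cols) <= k,
         nrow = config$grid_rows, byrow = TRUE)
}

# True (pre-noise, pre-cloud) NDVI per pixel and year, plus footprints.
true_ndvi_field <- function(config) {
  base <- pixel_baseline(config)
  eff <- year_effects(config)
  yrs <- as.character(config$years)
  truth <- array(NA_real_,
                 dim = c(config$grid_rows, config$grid_cols, length(yrs)),
                 dimnames = list(NULL, NULL, yrs))
  footprints <- list()
  for (j in seq_along(yrs)) truth[, , j] <- base + eff[j]
  for (ev in config$disturbance_events) {
    fp <- event_footprint(ev, config)
    y <- as.character(ev$year)
    layer <- truth[, , y]
    layer[fp] <- layer[fp] - ev$drop
    if (any(layer < -1)) stop("disturbance drop would push NDVI below -1")
    truth[, , y] <- layer
    footprints[[y]] <- if (is.null(footprints[[y]])) fp else footprints[[y]] | fp
  }
  list(true_ndvi = truth, footprints = footprints,
       pixel_base = base, year_effect = eff)
}

#' Simulate Sentinel-2-like scene stacks with ground truth
#'
#' Generates `scenes_per_year` acquisitions per year on dates spread evenly
#' through the April--October growing season. Each scene carries RED and NIR
#' reflectance grids built by inverting the NDVI definition with the pair sum
#' fixed at 0.5 (so `NIR = 0.25 (1 + NDVI)`, `RED = 0.25 (1 - NDVI)`), a QA
#' bitmask grid with cloud/cirrus bits set on contaminated pixels, a scene
#' classification grid (vegetation 4, cloud shadow 3, cloud probability 8/9)
#' and a cloud-percentage metadata value equal to the realized contaminated
#' fraction. Clouds arrive as square blocks of edge `cloud_block` so that the
#' scene-level 5 percent prefilter is exercised realistically; contaminated
#' pixels get depressed NDVI so unmasked contamination visibly biases
#' composites.
#'
#' @param config A [simulation_config()].
#' @return List with `scenes` (a list per year, each a list of
#'   `scene_stack` objects) and `truth` (true NDVI array
#'   rows x cols x years, disturbance footprints, pixel baseline, year
#'   effects).
#' @export
simulate_scenes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- stream_seeds(config)
  tr <- true_ndvi_field(config)
  nr <- config$grid_rows; nc <- config$grid_cols
  nper <- config$scenes_per_year
  yrs <- as.character(config$years)

  set.seed(seeds[["scenes"]])
  noise <- lapply(seq_len(length(yrs) * nper), function(i)
    if (config$noise_sd > 0) matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    else matrix(0, nr, nc))

  set.seed(seeds[["clouds"]])
  rb <- ceiling(nr / config$cloud_block)
  cb <- ceiling(nc / config$cloud_block)
  masks <- lapply(seq_len(length(yrs) * nper), function(i) {
    cloudy <- matrix(stats::runif(rb * cb) < config$cloud_fraction, rb, cb)
    shadow <- matrix(stats::runif(rb * cb) < 0.3, rb, cb)  # contamination type
    cirrus <- matrix(stats::runif(rb * cb) < 0.2, rb, cb)
    grow <- function(m) m[rep(seq_len(rb), each = config$cloud_block)[seq_len(nr)],
                          rep(seq_len(cb), each = config$cloud_block)[seq_len(nc)],
                          drop = FALSE]
    list(contaminated = grow(cloudy), shadow = grow(cloudy & shadow),
         cirrus = grow(cloudy & cirrus & !shadow))
  })

  scenes <- stats::setNames(vector("list", length(yrs)), yrs)
  k <- 0L
  for (j in seq_along(yrs)) {
    year <- config$years[j]
    dates <- as.Date(sprintf("%d-04-01", year)) +
      round(seq(0, 213, length.out = nper))
    scenes[[j]] <- vector("list", nper)
    for (s in seq_len(nper)) {
      k <- k + 1L
      nd <- clamp(tr$true_ndvi[, , j] + noise[[k]], -0.999, 0.999)
      m <- masks[[k]]
      nd[m$contaminated & !m$shadow] <- 0.05  # bright cloud, low NDVI
      nd[m$shadow] <- 0.15                    # dark shadow, depressed NDVI
      qa <- matrix(0L, nr, nc)
      cloud_px <- m$contaminated & !m$shadow
      qa[cloud_px & !m$cirrus] <- bitwShiftL(1L, 10L)  # opaque cloud
      qa[cloud_px & m$cirrus] <- bitwShiftL(1L, 11L)   # cirrus
      scl <- matrix(4L, nr, nc)                        # vegetation
      scl[cloud_px] <- ifelse(m$cirrus[cloud_px], 8L, 9L)
      scl[m$shadow] <- 3L                              # cloud shadow
      scenes[[j]][[s]] <- scene_stack(
        red = 0.25 * (1 - nd), nir = 0.25 * (1 + nd),
        qa_bits = qa, scene_class = scl, date = dates[s],
        cloud_pct = 100 * mean(m$contaminated), year = year)
    }
  }
  list(scenes = scenes, truth = tr)
}

#' Construct a scene stack
#'
#' One satellite acquisition: co-registered RED/NIR reflectance grids, a QA
#' bitmask grid, a scene-classification grid, the acquisition date and the
#' scene-level cloud-percentage metadata.
#'
#' @param red,nir Numeric reflectance matrices of equal shape.
#' @param qa_bits Integer bitmask matrix.
#' @param scene_class Integer scene-classification matrix.
#' @param date Acquisition `Date`.
#' @param cloud_pct Scene cloud percentage in \[0, 100\].
#' @param year Year label (defaults to the date's year).
#' @return Object of class `scene_stack`.
#' @export
scene_stack <- function(red, nir, qa_bits, scene_class, date, cloud_pct,
                        year = as.integer(format(date, "%Y"))) {
  stopifnot(is.matrix(red), identical(dim(red), dim(nir)),
            identical(dim(red), dim(qa_bits)),
            identical(dim(red), dim(scene_class)),
            cloud_pct >= 0, cloud_pct <= 100)
  structure(list(red = red, nir = nir, qa_bits = qa_bits,
                 scene_class = scene_class, date = as.Date(date),
                 cloud_pct = cloud_pct, year = as.integer(year)),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("<scene_stack %s  %dx%d px  cloud %.1f%%>\n",
              format(x$date), nrow(x$red), ncol(x$red), x$cloud_pct))
  invisible(x)
}

#' Simulate the monitoring plot network and its defoliation responses
#'
#' Places the Level I and Level II plots on jittered regular grids (a toy
#' analogue of the 16 x 16 km systematic design) and derives a defoliation
#' record per plot and year: `clamp(base + gain * local NDVI drop + noise,
#' 0, 100)`, where the local drop is the disturbance-event drop at the plot
#' pixel in that year. Plots inside footprints in disturbance years therefore
#' have systematically higher defoliation.
#'
#' @param config A [simulation_config()].
#' @param truth The `truth` element returned by [simulate_scenes()].
#' @return Data frame with one row per plot-year: `plot_id`, `level`, `row`,
#'   `col`, `x`, `y`, `year`, `defoliation_pct`, `defoliation_category`,
#'   `true_defoliation_pct`.
#' @export
simulate_plots <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- stream_seeds(config)
  set.seed(seeds[["plots"]])

  place <- function(n, prefix) {
    g <- ceiling(sqrt(n))
    centers_r <- (seq_len(g) - 0.5) / g * config$grid_rows
    centers_c <- (seq_len(g) - 0.5) / g * config$grid_cols
    grid <- expand.grid(r = centers_r, c = centers_c)[seq_len(n), ]
    jr <- stats::runif(n, -0.3, 0.3) * config$grid_rows / g
    jc <- stats::runif(n, -0.3, 0.3) * config$grid_cols / g
    # nearest pixel center, ties toward smaller indices
    row <- clamp(floor(grid$r + jr) + 1L, 1L, config$grid_rows)
    col <- clamp(floor(grid$c + jc) + 1L, 1L, config$grid_cols)
    data.frame(plot_id = sprintf("%s-%03d", prefix, seq_len(n)),
               row = as.integer(row), col = as.integer(col))
  }
  p1 <- place(config$n_plots_level1, "L1"); p1$level <- "I"
  p2 <- place(config$n_plots_level2, "L2"); p2$level <- "II"
  plots <- rbind(p1, p2)
  plots$x <- (plots$col - 0.5) * config$pixel_size
  plots$y <- (plots$row - 0.5) * config$pixel_size

  yrs <- config$years
  recs <- plots[rep(seq_len(nrow(plots)), each = length(yrs)), ]
  recs$year <- rep(yrs, times = nrow(plots))
  drop_at <- function(row, col, year) {
    d <- 0
    for (ev in config$disturbance_events) {
      if (ev$year == year) {
        fp <- event_footprint(ev, config)
        if (fp[row, col]) d <- d + ev$drop
      }
    }
    d
  }
  local_drop <- mapply(drop_at, recs$row, recs$col, recs$year)
  recs$true_defoliation_pct <- clamp(
    config$defoliation_base + config$defoliation_gain * local_drop, 0, 100)
  noise <- if (config$noise_sd > 0)
    stats::rnorm(nrow(recs), 0, 100 * config$noise_sd) else 0
  recs$defoliation_pct <- clamp(recs$true_defoliation_pct + noise, 0, 100)
  recs$defoliation_category <- categorize_defoliation(recs$defoliation_pct)
  rownames(recs) <- NULL
  recs[, c("plot_id", "level", "row", "col", "x", "y", "year",
           "defoliation_pct", "defoliation_category", "true_defoliation_pct")]
}

#' Simulate monthly site climate with optional drought coupling
#'
#' One site per Level II plot. Each site shares a fixed temperate-continental
#' monthly climatology; in disturbance years (when `drought_coupling` is on)
#' precipitation is multiplied by `drought_precip_factor` and temperature
#' raised by `drought_temp_delta`, so the March--August TPF is strictly
#' higher in drought years. Monthly noise is additive on temperature and a
#' lognormal multiplier on precipitation.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `site_id`, `year`, `month`, `tmean_c`,
#'   `precip_mm`.
#' @export
simulate_climate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- stream_seeds(config)
  set.seed(seeds[["climate"]])
  clim_t <- c(-1, 1, 6, 12, 17, 20, 22, 21, 17, 11, 5, 0)
  clim_p <- c(35, 32, 33, 45, 60, 70, 65, 55, 50, 40, 45, 40)
  drought_years <- if (config$drought_coupling)
    unique(vapply(config$disturbance_events, `[[`, 0, "year")) else integer()
  sites <- sprintf("L2-%03d", seq_len(config$n_plots_level2))
  out <- expand.grid(month = 1:12, year = config$years, site_id = sites,
                     stringsAsFactors = FALSE)[, c("site_id", "year", "month")]
  dr <- out$year %in% drought_years
  t_noise <- if (config$climate_noise_sd > 0)
    stats::rnorm(nrow(out), 0, config$climate_noise_sd) else 0
  p_mult <- if (config$climate_noise_sd > 0)
    exp(stats::rnorm(nrow(out), 0, 0.05)) else 1
  out$tmean_c <- clim_t[out$month] + ifelse(dr, config$drought_temp_delta, 0) + t_noise
  out$precip_mm <- clim_p[out$month] *
    ifelse(dr, config$drought_precip_factor, 1) * p_mult
  out
}

#' Simulate the complete synthetic dataset
#'
#' Convenience wrapper running [simulate_scenes()], [simulate_plots()] and
#' [simulate_climate()] off one configuration.
#'
#' @param config A [simulation_config()].
#' @return List with `scenes`, `truth`, `plots`, `climate` and the `config`.
#' @export
simulate_forest <- function(config = simulation_config()) {
  sc <- simulate_scenes(config)
  plots <- simulate_plots(config, sc$truth)
  climate <- simulate_climate(config)
  list(scenes = sc$scenes, truth = sc$truth, plots = plots,
       climate = climate, config = config)
}
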