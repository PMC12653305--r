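#' Masking and compositing configuration
#'
#' Parameters of the three-stage cloud screening: a scene-level cloud
#' percentage prefilter, a QA bitmask test, and a scene-classification (SCL)
#' exclusion list, plus the growing-season window for compositing.
#'
#' Two named presets are shipped for the QA bit list. The method text targets
#' bits 9, 10 and 11, but the standard Sentinel-2 QA60 layout defines only
#' bit 10 (opaque cloud) and bit 11 (cirrus), leaving bit 9 unused; preset
#' `"extended"` is \{9, 10, 11\} and preset `"qa60-standard"` is \{10, 11\}. The
#' active preset is recorded in the returned object so downstream metadata
#' can echo it.
#'
#' @param max_cloud_pct Scenes with metadata cloud percentage strictly above
#'   this are dropped ("more than 5 percent" excluded, so the boundary is
#'   kept). Default 5.
#' @param preset QA bit preset name, `"extended"` or `"qa60-standard"`.
#' @param qa_cloud_bits Integer bit indices (< 16) overriding the preset.
#' @param scl_excluded SCL class codes treated as contaminated. Default
#'   \{3, 7, 8, 9\} (cloud shadow and cloud-probability classes).
#' @param season_start,season_end Inclusive month-day bounds (`"MM-DD"`) of
#'   the compositing season, compared within each scene's own calendar year.
#'   Default April 1 -- October 31.
#' @return List of class `mask_config`.
#' @export
mask_config <- function(max_cloud_pct = 5,
                        preset = c("extended", "qa60-standard"),
                        qa_cloud_bits = NULL,
                        scl_excluded = c(3L, 7L, 8L, 9L),
                        season_start = "04-01", season_end = "10-31") {
  preset <- match.arg(preset)
  if (is.null(qa_cloud_bits))
    qa_cloud_bits <- if (preset == "extended") c(9L, 10L, 11L) else c(10L, 11L)
  stopifnot(max_cloud_pct >= 0, max_cloud_pct <= 100,
            all(qa_cloud_bits >= 0), all(qa_cloud_bits < 16),
            all(scl_excluded >= 0))
  structure(list(max_cloud_pct = max_cloud_pct, preset = preset,
                 qa_cloud_bits = as.integer(qa_cloud_bits),
                 scl_excluded = as.integer(scl_excluded),
                 season_start = season_start, season_end = season_end),
            class = "mask_config")
}

in_season <- function(dates, cfg) {
  md <- format(as.Date(dates), "%m-%d")
  md >= cfg$season_start & md <= cfg$season_end
}

#' Scene-level prefilter on cloud metadata and season
#'
#' Keeps exactly the scenes whose metadata cloud percentage is at most
#' `max_cloud_pct` and whose date lies inside the growing-season window
#' (inclusive on both ends); order is preserved. An empty result is allowed
#' but raises a warning with the number of scenes dropped.
#'
#' @param scenes Non-empty list of [scene_stack()] objects.
#' @param cfg A [mask_config()].
#' @return The retained sub-list of `scenes`.
#' @export
prefilter_scenes <- function(scenes, cfg = mask_config()) {
  if (length(scenes) == 0) stop("no scenes supplied")
  keep <- vapply(scenes, function(s)
    s$cloud_pct <= cfg$max_cloud_pct && in_season(s$date, cfg), logical(1))
  if (!any(keep))
    warning(sprintf("prefilter removed all %d scenes", length(scenes)))
  scenes[keep]
}

#' Per-pixel quality masking
#'
#' A pixel is invalid iff any configured QA bit is set in its bitmask word
#' OR its scene-classification code is in the exclusion list. Reflectance is
#' untouched; the validity is attached as a logical `valid` matrix on the
#' returned scene. Masking is idempotent.
#'
#' @param scene A [scene_stack()]; must carry `qa_bits` and `scene_class`.
#' @param cfg A [mask_config()].
#' @return The scene with a `valid` logical matrix element.
#' @export
mask_pixels <- function(scene, cfg = mask_config()) {
  if (is.null(scene$qa_bits)) stop("scene is missing the quality band 'qa_bits'")
  if (is.null(scene$scene_class)) stop("scene is missing the quality band 'scene_class'")
  bitmask <- sum(bitwShiftL(1L, cfg$qa_cloud_bits))
  qa_bad <- bitwAnd(scene$qa_bits, bitmask) != 0L
  scl_bad <- matrix(scene$scene_class %in% cfg$scl_excluded,
                    nrow(scene$scene_class), ncol(scene$scene_class))
  scene$valid <- !(qa_bad | scl_bad)
  scene
}

#' Growing-season median composite
#'
#' Per pixel and per band, the median over valid observations of all supplied
#' scenes; the even-count median is the arithmetic mean of the two central
#' values. Pixels with zero valid observations are invalid in the result's
#' `valid` mask (not an error); per-pixel observation counts are recorded.
#'
#' @param scenes Non-empty list of scenes, normally already passed through
#'   [prefilter_scenes()] and [mask_pixels()]. Scenes without a `valid`
#'   element are treated as fully valid.
#' @param year Year label for the composite.
#' @param stat_on `"bands"` (default): median RED and NIR, then NDVI from the
#'   composited bands. `"ndvi"`: NDVI per scene first, then the median of the
#'   per-scene NDVI (band medians are still reported).
#' @return Object of class `annual_composite` with elements `year`, `red`,
#'   `nir`, `ndvi`, `n_obs`, `valid`, `stat_on`.
#' @export
median_composite <- function(scenes, year, stat_on = c("bands", "ndvi")) {
  stat_on <- match.arg(stat_on)
  if (length(scenes) == 0) stop("cannot composite zero scenes")
  dm <- dim(scenes[[1]]$red)
  stack_band <- function(get) {
    arr <- array(NA_real_, c(dm, length(scenes)))
    for (i in seq_along(scenes)) {
      s <- scenes[[i]]
      b <- get(s)
      if (!is.null(s$valid)) b[!s$valid] <- NA_real_
      arr[, , i] <- b
    }
    arr
  }
  med <- function(arr) apply(arr, c(1, 2), stats::median, na.rm = TRUE)
  red_a <- stack_band(function(s) s$red)
  nir_a <- stack_band(function(s) s$nir)
  n_obs <- apply(!is.na(red_a), c(1, 2), sum)
  red_m <- med(red_a); nir_m <- med(nir_a)
  red_m[n_obs == 0] <- NA_real_; nir_m[n_obs == 0] <- NA_real_
  nd <- if (stat_on == "bands") ndvi(red_m, nir_m)
        else med(ndvi(red_a, nir_a))
  structure(list(year = year, red = red_m, nir = nir_m, ndvi = nd,
                 n_obs = n_obs, valid = n_obs > 0, stat_on = stat_on),
            class = "annual_composite")
}

#' @export
print.annual_composite <- function(x, ...) {
  cat(sprintf("<annual_composite %s  %dx%d px  %.1f%% valid  (%s median)>\n",
              x$year, nrow(x$ndvi), ncol(x$ndvi), 100 * mean(x$valid),
              x$stat_on))
  invisible(x)
}
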