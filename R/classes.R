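#' Damage class codes and labels
#'
#' The five Z NDVI damage classes used throughout the package, coded as
#' integers 0--4 from worst to best condition:
#'
#' | code | label               | Z NDVI interval |
#' |------|---------------------|-----------------|
#' | 0    | severe damage       | (-Inf, -2)      |
#' | 1    | damage              | \[-2, -1)       |
#' | 2    | moderate            | \[-1, 0)        |
#' | 3    | regeneration        | \[0, 1)         |
#' | 4    | strong regeneration | \[1, Inf)       |
#'
#' Bins are lower-inclusive half-open so they cover the real line totally and
#' disjointly; z = 1 falls in "strong regeneration".
#'
#' @return Named integer vector mapping class labels to codes.
#' @export
damage_classes <- function() {
  stats::setNames(0:4, c("severe damage", "damage", "moderate",
                         "regeneration", "strong regeneration"))
}

#' @rdname damage_classes
#' @export
damage_class_labels <- function() names(damage_classes())

#' Classify standardized NDVI anomalies into damage classes
#'
#' Maps each z value to one of the five damage class codes (see
#' [damage_classes()]). `NA` values propagate.
#'
#' @param z Numeric vector or matrix of Z NDVI values.
#' @return Integer vector/matrix of class codes 0--4, same shape as `z`.
#' @examples
#' classify_z(c(-2.5, -1.5, -0.5, 0.5, 3))  # 0 1 2 3 4
#' @export
classify_z <- function(z) {
  cls <- findInterval(z, c(-2, -1, 0, 1))
  if (is.matrix(z)) dim(cls) <- dim(z)
  cls
}

#' Defoliation categories of crown-condition surveys
#'
#' Bins a defoliation percentage into the standard five crown-condition
#' categories: None 0--10, Weak >10--25, Medium >25--60, Severe >60--99,
#' Dead 100 (anything above 99). Boundaries 10, 25, 60, 99 belong to the
#' lower category; 100 is Dead.
#'
#' @param pct Numeric vector of defoliation percentages in \[0, 100\].
#' @return Factor with levels None, Weak, Medium, Severe, Dead.
#' @examples
#' categorize_defoliation(c(5, 10, 11, 25, 62, 100))
#' @export
categorize_defoliation <- function(pct) {
  if (any(!is.na(pct) & (pct < 0 | pct > 100)))
    stop("defoliation percentages must lie in [0, 100]")
  idx <- 1L + (pct > 10) + (pct > 25) + (pct > 60) + (pct > 99)
  factor(defoliation_category_labels()[idx],
         levels = defoliation_category_labels())
}

#' @rdname categorize_defoliation
#' @export
defoliation_category_labels <- function() {
  c("None", "Weak", "Medium", "Severe", "Dead")
}
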