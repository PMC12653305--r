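# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and textbook formulas only.

oracle_ndvi <- function(red, nir) {
  out <- matrix(NA_real_, nrow(red), ncol(red))
  for (i in seq_len(nrow(red))) for (j in seq_len(ncol(red))) {
    s <- nir[i, j] + red[i, j]
    if (!is.na(s) && s != 0) out[i, j] <- (nir[i, j] - red[i, j]) / s
  }
  out
}

# pixelwise median over a list of matrices with per-scene validity masks
oracle_median <- function(grids, valids = NULL) {
  nr <- nrow(grids[[1]]); nc <- ncol(grids[[1]])
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (k in seq_along(grids)) {
      ok <- if (is.null(valids)) TRUE else valids[[k]][i, j]
      if (ok && !is.na(grids[[k]][i, j])) vals <- c(vals, grids[[k]][i, j])
    }
    if (length(vals) > 0) {
      vals <- sort(vals)
      m <- length(vals)
      out[i, j] <- if (m %% 2 == 1) vals[(m + 1) / 2]
                   else (vals[m / 2] + vals[m / 2 + 1]) / 2
    }
  }
  out
}

# value-by-value standardization over a list of year grids
oracle_z <- function(grids, sd_type = "population", eps = 1e-6) {
  nr <- nrow(grids[[1]]); nc <- ncol(grids[[1]])
  ny <- length(grids)
  z <- lapply(grids, function(g) matrix(NA_real_, nr, nc))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- vapply(grids, function(g) g[i, j], 0)
    if (anyNA(vals)) next
    mu <- sum(vals) / ny
    ss <- sum((vals - mu)^2)
    sd <- sqrt(if (sd_type == "population") ss / ny else ss / (ny - 1))
    for (y in seq_len(ny))
      z[[y]][i, j] <- if (sd < eps) 0 else (vals[y] - mu) / sd
  }
  z
}

oracle_classify <- function(z) {
  out <- z
  for (k in seq_along(z)) {
    v <- z[k]
    out[k] <- if (is.na(v)) NA_integer_
    else if (v < -2) 0 else if (v < -1) 1 else if (v < 0) 2
    else if (v < 1) 3 else 4
  }
  out
}

oracle_confusion <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0
  for (k in seq_along(pred)) {
    if (pred[k] && ref[k]) tp <- tp + 1
    else if (pred[k] && !ref[k]) fp <- fp + 1
    else if (!pred[k] && ref[k]) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_kappa <- function(x, y) {
  lev <- sort(unique(c(x, y)))
  n <- length(x)
  po <- sum(x == y) / n
  pe <- 0
  for (l in lev) pe <- pe + (sum(x == l) / n) * (sum(y == l) / n)
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

# OLS with intercept via explicit normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = 1 - rss / tss, rmse = sqrt(mean(res^2)))
}

# small scene builder for preprocess tests
make_scene <- function(ndvi_grid, date = as.Date("2020-06-15"), cloud_pct = 0,
                       qa = NULL, scl = NULL) {
  nr <- nrow(ndvi_grid); nc <- ncol(ndvi_grid)
  scene_stack(red = 0.25 * (1 - ndvi_grid), nir = 0.25 * (1 + ndvi_grid),
              qa_bits = if (is.null(qa)) matrix(0L, nr, nc) else qa,
              scene_class = if (is.null(scl)) matrix(4L, nr, nc) else scl,
              date = date, cloud_pct = cloud_pct)
}
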