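# Independent oracles, deliberately implemented apart from the package code
# paths they check.

# Brute-force maximum Feret: largest pairwise distance over a point set.
feret_brute_force <- function(points) {
  max(dist(points))
}

# Mid-crack boundary points of a logical mask, recomputed from first
# principles (shift comparisons), in physical units.
mask_boundary_points <- function(mask, pixel_scale) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  pts <- NULL
  shifts <- list(up = c(-1L, 0L), down = c(1L, 0L),
                 left = c(0L, -1L), right = c(0L, 1L))
  for (d in names(shifts)) {
    sh <- shifts[[d]]
    nb <- pad[2:(nr + 1L) + sh[1], 2:(nc + 1L) + sh[2]]
    exposed <- which(mask & !nb)
    if (!length(exposed)) next
    ij <- arrayInd(exposed, dim(mask))
    x <- (ij[, 2] - 0.5) * pixel_scale + sh[2] * 0.5 * pixel_scale
    y <- (ij[, 1] - 0.5) * pixel_scale + sh[1] * 0.5 * pixel_scale
    pts <- rbind(pts, cbind(x, y))
  }
  pts
}

# Closed-form OLS via the normal equations, with classical t-based p-values.
ols_normal_equations <- function(X, y) {
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  res <- y - Xi %*% beta
  df <- nrow(Xi) - ncol(Xi)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(t(Xi) %*% Xi)) * s2)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], coefficients = beta[-1],
       p_values = p[-1], r_squared = r2)
}

# Closed-form pooled two-sample t-test p-value.
pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tval), nx + ny - 2)
}
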