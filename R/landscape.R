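#' Generate a synthetic landscape of smooth environmental surfaces
#'
#' Builds a rectangular planar region carrying `n_covariates` continuous
#' environmental surfaces, each a low-frequency random cosine field. The
#' surfaces play the role of gridded environmental layers (elevation, land
#' cover, precipitation, ...) in a real analysis: smooth enough that spline
#' recovery of covariate effects is meaningful, finite everywhere, and
#' evaluable at arbitrary coordinates.
#'
#' @param n_covariates number of surfaces (>= 1).
#' @param seed integer seed; the landscape is fully determined by
#'   `(n_covariates, seed, bounds)`.
#' @param bounds numeric length-4 vector `c(xmin, xmax, ymin, ymax)` in
#'   meters; must be non-degenerate.
#' @param n_components number of cosine components per surface; more
#'   components give rougher (but still smooth, bounded-gradient) fields.
#' @return an object of class `occufuse_landscape`.
#' @export
generate_landscape <- function(n_covariates, seed,
                               bounds = c(0, 10000, 0, 10000),
                               n_components = 6) {
  if (!is_count(n_covariates) || n_covariates < 1)
    stop_param("`n_covariates` must be a positive integer")
  if (!is.numeric(bounds) || length(bounds) != 4 || any(!is.finite(bounds)) ||
      bounds[2] <= bounds[1] || bounds[4] <= bounds[3])
    stop_param("`bounds` must be c(xmin, xmax, ymin, ymax) with xmax > xmin and ymax > ymin")

  fields <- with_seed(seed, lapply(seq_len(n_covariates), function(j) {
    list(
      amp   = rnorm(n_components, 0, 1) / sqrt(n_components),
      # frequencies in cycles per domain length; kept low so gradients stay bounded
      fx    = runif(n_components, 0.3, 2.5) * sample(c(-1, 1), n_components, replace = TRUE),
      fy    = runif(n_components, 0.3, 2.5) * sample(c(-1, 1), n_components, replace = TRUE),
      phase = runif(n_components, 0, 2 * pi)
    )
  }))

  structure(
    list(bounds = as.numeric(bounds), n_covariates = as.integer(n_covariates),
         fields = fields, seed = as.integer(seed)),
    class = "occufuse_landscape"
  )
}

#' Evaluate landscape covariate surfaces at planar points
#'
#' @param landscape an `occufuse_landscape`.
#' @param xy two-column matrix or data frame of planar coordinates (meters).
#' @return numeric matrix, one row per point, one (raw, unstandardized)
#'   column per covariate, named `cov1`, `cov2`, ...
#' @export
landscape_covariates <- function(landscape, xy) {
  stopifnot(inherits(landscape, "occufuse_landscape"))
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  b <- landscape$bounds
  u <- (xy[, 1] - b[1]) / (b[2] - b[1])
  v <- (xy[, 2] - b[3]) / (b[4] - b[3])
  out <- vapply(landscape$fields, function(f) {
    val <- numeric(length(u))
    for (k in seq_along(f$amp))
      val <- val + f$amp[k] * cos(2 * pi * (f$fx[k] * u + f$fy[k] * v) + f$phase[k])
    val
  }, numeric(length(u)))
  out <- matrix(out, nrow = length(u), ncol = landscape$n_covariates)
  colnames(out) <- paste0("cov", seq_len(landscape$n_covariates))
  out
}

points_in_bounds <- function(xy, bounds) {
  xy <- as.matrix(xy)
  xy[, 1] >= bounds[1] & xy[, 1] <= bounds[2] &
    xy[, 2] >= bounds[3] & xy[, 2] <= bounds[4]
}

#' @export
print.occufuse_landscape <- function(x, ...) {
  cat(sprintf("<occufuse_landscape> %d covariate surface(s) on [%g, %g] x [%g, %g] m (seed %d)\n",
              x$n_covariates, x$bounds[1], x$bounds[2], x$bounds[3], x$bounds[4], x$seed))
  invisible(x)
}

## Shared internals: build a latent occupancy process at `sites` using given
## standardization statistics (so several site sets can share one
## parameterization of the truth).
process_at <- function(landscape, beta_true, sites, center, scale, seed) {
  sites <- as.matrix(sites)[, 1:2, drop = FALSE]
  if (!all(points_in_bounds(sites, landscape$bounds)))
    stop_param("all sites must lie inside the landscape bounds")
  Xraw <- landscape_covariates(landscape, sites)
  Xstd <- standardize_cols(Xraw, center, scale)
  eta <- as.numeric(cbind(rep(1, nrow(Xstd)), Xstd) %*% beta_true)
  psi <- plogis(eta)
  z <- with_seed(seed, rbinom(length(psi), 1L, psi))
  psi_fn <- function(xy) {
    xy <- as.matrix(xy)[, 1:2, drop = FALSE]
    Xs <- standardize_cols(landscape_covariates(landscape, xy), center, scale)
    as.numeric(plogis(cbind(rep(1, nrow(Xs)), Xs) %*% beta_true))
  }
  structure(
    list(landscape = landscape, sites = sites, X_raw = Xraw,
         X_std = Xstd, center = attr(Xstd, "center"), scale = attr(Xstd, "scale"),
         beta_true = beta_true, psi = psi, z = z, psi_fn = psi_fn,
         seed = as.integer(seed)),
    class = "occufuse_process"
  )
}

#' Simulate a latent occupancy process over a set of sites
#'
#' Computes occupancy probability psi at each site by the inverse-logit of a
#' linear predictor in the standardized landscape covariates
#' (`logit(psi) = beta %*% c(1, X)`), then draws the latent presence state
#' `z ~ Bernoulli(psi)` once per site. Covariates are standardized over the
#' supplied sites unless explicit statistics are given.
#'
#' @param landscape an `occufuse_landscape`.
#' @param beta_true numeric vector of length `n_covariates + 1` (intercept
#'   first), on the standardized-covariate scale.
#' @param sites two-column matrix of planar coordinates; must be inside
#'   bounds.
#' @param seed integer seed for the presence draws.
#' @param center,scale optional standardization statistics (one per
#'   covariate) to use instead of the sample statistics of `sites`.
#' @return an `occufuse_process` carrying psi, z, the standardized design,
#'   the standardization statistics, and `psi_fn`, a function evaluating the
#'   true occupancy probability at arbitrary in-bounds coordinates.
#' @export
simulate_occupancy <- function(landscape, beta_true, sites, seed,
                               center = NULL, scale = NULL) {
  stopifnot(inherits(landscape, "occufuse_landscape"))
  beta_true <- as.numeric(beta_true)
  if (length(beta_true) != landscape$n_covariates + 1)
    stop_param("`beta_true` must have length n_covariates + 1 (intercept first)")
  sites <- as.matrix(sites)[, 1:2, drop = FALSE]
  if (!all(points_in_bounds(sites, landscape$bounds)))
    stop_param("all sites must lie inside the landscape bounds")
  if (is.null(center) || is.null(scale)) {
    Xraw <- landscape_covariates(landscape, sites)
    Xs <- standardize_cols(Xraw)
    center <- center %||% attr(Xs, "center")
    scale <- scale %||% attr(Xs, "scale")
  }
  process_at(landscape, beta_true, sites, center, scale, seed)
}

#' @export
print.occufuse_process <- function(x, ...) {
  cat(sprintf("<occufuse_process> %d sites; mean psi = %.3f; mean z = %.3f\n",
              nrow(x$sites), mean(x$psi), mean(x$z)))
  invisible(x)
}
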