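# NLCD-style legend used throughout the package
.legend <- c(
  developed_open = 21L, developed_low = 22L, developed_med = 23L,
  developed_high = 24L, barren = 31L, deciduous = 41L, evergreen = 42L,
  mixed = 43L, pasture = 81L, crops = 82L
)

#' Land-cover class code sets
#'
#' Convenience accessors for the class legend used by the synthetic
#' landscapes: four developed intensity classes, three forest classes and
#' two agriculture classes, mirroring the NLCD groupings.
#'
#' @return Named integer vector of class codes.
#' @export
landcover_legend <- function() .legend

#' @rdname landcover_legend
#' @export
forest_classes <- function() unname(.legend[c("deciduous", "evergreen", "mixed")])

#' @rdname landcover_legend
#' @export
developed_classes <- function() unname(.legend[c("developed_open", "developed_low",
                                                 "developed_med", "developed_high")])

#' @rdname landcover_legend
#' @export
agriculture_classes <- function() unname(.legend[c("pasture", "crops")])

# FFT frequencies for a length-n axis (cycles per cell)
.fftfreq <- function(n) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, -rev(seq_len(floor(n / 2))))
  k / n
}

#' Spatially autocorrelated Gaussian random field
#'
#' Spectral (FFT) synthesis of a standardized Gaussian field on a grid.
#' The spectral filter 1/(|k|^2 + k0^2)^(e/2) with k0 = 1/range yields
#' fields with correlation length of roughly `range` cells while retaining
#' power across scales (exponent < 2), which is what multi-radius buffer
#' analyses need: distinct landscape composition at distinct radii.
#'
#' @param nrow,ncol grid dimensions.
#' @param range correlation range in cells.
#' @param exponent spectral decay exponent.
#' @return A standardized (mean 0, sd 1) `nrow` x `ncol` matrix.
#' @export
gaussian_field <- function(nrow, ncol, range = 10, exponent = 1.8) {
  white <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  kx <- matrix(.fftfreq(ncol), nrow, ncol, byrow = TRUE)
  ky <- matrix(.fftfreq(nrow), nrow, ncol)
  k2 <- kx^2 + ky^2
  filt <- (k2 + (1 / range)^2)^(-exponent / 2)
  filt[1, 1] <- 0  # remove mean component
  z <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / (nrow * ncol)
  (z - mean(z)) / stats::sd(z)
}

.new_landscape <- function(landcover, pop, housing, elevation, cell_size, origin) {
  stopifnot(
    identical(dim(landcover), dim(pop)),
    identical(dim(landcover), dim(housing)),
    identical(dim(landcover), dim(elevation)),
    all(pop >= 0), all(housing >= 0)
  )
  structure(
    list(landcover = landcover, pop_density = pop, housing_density = housing,
         elevation = elevation, cell_size = cell_size, origin = origin,
         legend = .legend),
    class = "LandscapeStack"
  )
}

#' @export
print.LandscapeStack <- function(x, ...) {
  d <- dim(x$landcover)
  cat("LandscapeStack:", d[1], "x", d[2], "cells @", x$cell_size, "m\n")
  cat("  extent:", d[2] * x$cell_size / 1000, "x", d[1] * x$cell_size / 1000, "km\n")
  tab <- table(x$landcover)
  cat("  cover fractions:\n")
  print(round(tab / sum(tab), 3))
  invisible(x)
}

#' Generate a synthetic landscape stack
#'
#' Builds co-registered land-cover, population-density, housing-density and
#' elevation grids emulating a forest-dominated region with an urbanization
#' gradient. Developed cells, population density and housing density are all
#' increasing functions of one latent urbanization surface (a planar ramp
#' blended with an autocorrelated field), so that a PCA of developed-cover
#' proportions and the two densities has a dominant first component. Forest
#' forms autocorrelated patches from a thresholded Gaussian random field.
#'
#' @param extent side length of the square landscape in meters.
#' @param cell_size cell size in meters.
#' @param urban_strength gradient strength in `[0, 1]`; the developed cover
#'   fraction is `0.25 * urban_strength`, and 0 yields no developed cells and
#'   zero densities.
#' @param forest_frac target fraction of all cells in forest classes.
#' @param agri_frac target fraction of all cells in agriculture classes
#'   (capped by what developed and forest leave available).
#' @param max_radius optional largest analysis radius (m); the extent must be
#'   at least twice this value.
#' @param autocorr_range correlation range of the random fields, in cells.
#' @param spectral_exponent spectral decay of the urbanization field; values
#'   below 2 leave substantial variance at fine scales, so that buffer
#'   composition differs genuinely across radii (development in real
#'   regions is multi-scale: scattered exurban parcels within broad
#'   metropolitan gradients).
#' @param ramp_weight variance share of the planar regional gradient in the
#'   latent urbanization surface.
#' @param seed integer seed; identical configuration and seed give
#'   bit-identical grids.
#' @return A `LandscapeStack`.
#' @export
generate_landscape <- function(extent = 20000, cell_size = 100,
                               urban_strength = 0.5, forest_frac = 0.58,
                               agri_frac = 0.20, max_radius = NULL,
                               autocorr_range = 10, spectral_exponent = 1.0,
                               ramp_weight = 0.05, seed = 1) {
  if (!is.null(max_radius) && extent < 2 * max_radius)
    stop("configuration error: extent (", extent, " m) must be at least twice ",
         "the largest analysis radius (", max_radius, " m)")
  if (forest_frac <= 0 || forest_frac > 1)
    stop("forest_frac must be in (0, 1]")
  if (urban_strength < 0 || urban_strength > 1)
    stop("urban_strength must be in [0, 1]")
  dev_frac <- 0.25 * urban_strength
  if (dev_frac + forest_frac > 1 + 1e-12)
    stop("forest_frac + developed fraction exceed 1; lower one of them")

  n <- as.integer(round(extent / cell_size))
  set.seed(seed)

  ramp <- matrix(seq(-1, 1, length.out = n), n, n, byrow = TRUE)
  ramp <- (ramp - mean(ramp)) / stats::sd(ramp)
  urb_lat <- sqrt(ramp_weight) * ramp +
    sqrt(1 - ramp_weight) * gaussian_field(n, n, autocorr_range,
                                           exponent = spectral_exponent)
  forest_lat <- gaussian_field(n, n, autocorr_range)
  type_lat <- gaussian_field(n, n, autocorr_range)
  elev_lat <- gaussian_field(n, n, max(autocorr_range * 3, 20), exponent = 2.5)

  ncell <- n * n
  lc <- matrix(.legend[["barren"]], n, n)

  n_dev <- round(dev_frac * ncell)
  if (n_dev > 0) {
    ord <- order(urb_lat, decreasing = TRUE)
    dev_idx <- ord[seq_len(n_dev)]
    # higher latent urbanization -> higher development intensity
    q <- ceiling(4 * seq_len(n_dev) / n_dev)
    lc[dev_idx] <- developed_classes()[5L - q]
  } else dev_idx <- integer(0)

  free <- setdiff(seq_len(ncell), dev_idx)
  n_forest <- round(forest_frac * ncell)
  if (n_forest > length(free)) n_forest <- length(free)
  f_ord <- free[order(forest_lat[free], decreasing = TRUE)]
  forest_idx <- f_ord[seq_len(n_forest)]
  ft <- type_lat[forest_idx]
  qs <- stats::quantile(ft, c(0.6, 0.8))
  lc[forest_idx] <- ifelse(ft <= qs[1], .legend[["deciduous"]],
                           ifelse(ft <= qs[2], .legend[["evergreen"]], .legend[["mixed"]]))

  rest <- setdiff(free, forest_idx)
  n_agri <- min(round(agri_frac * ncell), length(rest))
  if (n_agri > 0) {
    a_idx <- rest[order(forest_lat[rest], decreasing = TRUE)][seq_len(n_agri)]
    lc[a_idx] <- ifelse(type_lat[a_idx] > 0, .legend[["pasture"]], .legend[["crops"]])
  }

  # densities: increasing in the urbanization latent, noisy, non-negative
  u_rank <- matrix(rank(urb_lat) / ncell, n, n)
  pop <- urban_strength * 1500 * u_rank^4 * exp(0.3 * matrix(stats::rnorm(ncell), n, n))
  housing <- pop / 2.4 * exp(0.2 * matrix(stats::rnorm(ncell), n, n))
  elev <- 350 + 120 * elev_lat

  .new_landscape(lc, pop, housing, elev, cell_size, origin = c(0, 0))
}

# cell-center coordinates; row 1 is the bottom row
.cell_centers <- function(stack) {
  n <- nrow(stack$landcover)
  m <- ncol(stack$landcover)
  cs <- stack$cell_size
  list(x = stack$origin[1] + (seq_len(m) - 0.5) * cs,
       y = stack$origin[2] + (seq_len(n) - 0.5) * cs)
}
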