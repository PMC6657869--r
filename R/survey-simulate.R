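# forest proportion within `radius` m of every cell whose disc fits the grid;
# returns a matrix with NA outside the admissible border
.forest_prop_grid <- function(stack, radius) {
  cs <- stack$cell_size
  n <- nrow(stack$landcover); m <- ncol(stack$landcover)
  r_cells <- floor(radius / cs)
  off <- expand.grid(di = -r_cells:r_cells, dj = -r_cells:r_cells)
  off <- off[(off$di^2 + off$dj^2) * cs^2 < radius^2, , drop = FALSE]
  fmask <- matrix(as.numeric(stack$landcover %in% forest_classes()), n, m)
  acc <- matrix(0, n, m)
  for (k in seq_len(nrow(off))) {
    di <- off$di[k]; dj <- off$dj[k]
    src_i <- (1 + max(0, di)):(n + min(0, di))
    src_j <- (1 + max(0, dj)):(m + min(0, dj))
    acc[src_i - di, src_j - dj] <- acc[src_i - di, src_j - dj] + fmask[src_i, src_j]
  }
  prop <- acc / nrow(off)
  # discs extending beyond the grid are not admissible
  bi <- ceiling(radius / cs)
  out <- matrix(NA_real_, n, m)
  if (n > 2 * bi && m > 2 * bi)
    out[(bi + 1):(n - bi), (bi + 1):(m - bi)] <-
      prop[(bi + 1):(n - bi), (bi + 1):(m - bi)]
  out
}

#' Place point-count locations on a landscape
#'
#' Samples survey locations subject to the two design rules: all pairwise
#' distances at least `min_dist` (400 m) and more than `forest_min` (50\%)
#' forest cover within a `forest_radius` (0.2 km) buffer of each point.
#' Per-location detectability covariates (observer, start time, Julian date,
#' year) and local habitat covariates (land-use-change flag, dominant forest
#' habitat) are drawn from simple survey-like distributions.
#'
#' @param stack a `LandscapeStack`.
#' @param n number of locations.
#' @param seed integer seed.
#' @param min_dist minimum pairwise distance (m).
#' @param forest_radius radius of the local forest rule (m).
#' @param forest_min minimum forest proportion within `forest_radius`
#'   (strictly greater than).
#' @param n_observers number of observers to simulate.
#' @param margin keep locations at least this far (m) from every grid edge,
#'   so buffers up to `margin` stay complete; 0 disables.
#' @return A `SurveyDesign` data frame (id, x, y, observer, start_time,
#'   julian_date, year, landuse_change, dominant_habitat).
#' @export
place_count_locations <- function(stack, n, seed = 1, min_dist = 400,
                                  forest_radius = 200, forest_min = 0.5,
                                  n_observers = 8, margin = 0) {
  stopifnot(n >= 1)
  set.seed(seed)
  prop <- .forest_prop_grid(stack, forest_radius)
  if (margin > 0) {
    cc0 <- .cell_centers(stack)
    xmax <- stack$origin[1] + ncol(stack$landcover) * stack$cell_size
    ymax <- stack$origin[2] + nrow(stack$landcover) * stack$cell_size
    bad_j <- cc0$x - margin < stack$origin[1] | cc0$x + margin > xmax
    bad_i <- cc0$y - margin < stack$origin[2] | cc0$y + margin > ymax
    prop[bad_i, ] <- NA
    prop[, bad_j] <- NA
  }
  cand <- which(!is.na(prop) & prop > forest_min)
  if (length(cand) == 0)
    stop("infeasible: no candidate site passes the >", forest_min * 100,
         "% forest rule within ", forest_radius, " m")
  cc <- .cell_centers(stack)
  nr <- nrow(stack$landcover)
  ci <- ((cand - 1) %% nr) + 1
  cj <- ((cand - 1) %/% nr) + 1
  ord <- sample(length(cand))
  xs <- cc$x[cj][ord]; ys <- cc$y[ci][ord]; cells <- cand[ord]
  keep_x <- numeric(0); keep_y <- numeric(0); keep_cell <- integer(0)
  for (k in seq_along(xs)) {
    if (length(keep_x) == 0 ||
        min((keep_x - xs[k])^2 + (keep_y - ys[k])^2) >= min_dist^2) {
      keep_x <- c(keep_x, xs[k]); keep_y <- c(keep_y, ys[k])
      keep_cell <- c(keep_cell, cells[k])
      if (length(keep_x) == n) break
    }
  }
  if (length(keep_x) < n)
    stop("infeasible: only ", length(keep_x), " of ", n, " sites satisfy the ",
         min_dist, " m minimum spacing among forest-rule candidates")

  # dominant local forest habitat from the landscape at the point
  lc_at <- stack$landcover[keep_cell]
  dom <- names(.legend)[match(lc_at, .legend)]
  dom[!lc_at %in% forest_classes()] <- "mixed"

  design <- data.frame(
    id = seq_len(n),
    x = keep_x, y = keep_y,
    observer = factor(sample(paste0("obs", seq_len(n_observers)), n, replace = TRUE)),
    start_time = round(runif(n, 300, 600)),
    julian_date = sample(145:185, n, replace = TRUE),
    year = sample(2004:2009, n, replace = TRUE),
    landuse_change = rbinom(n, 1, 0.1),
    dominant_habitat = factor(dom)
  )
  attr(design, "min_dist") <- min_dist
  attr(design, "forest_radius") <- forest_radius
  attr(design, "forest_min") <- forest_min
  class(design) <- c("SurveyDesign", "data.frame")
  design
}

#' Validate a survey design against its landscape
#'
#' Re-checks the pairwise spacing rule and, by independent recount of buffer
#' cells, the local forest rule.
#'
#' @param design a `SurveyDesign`.
#' @param stack the `LandscapeStack` it was placed on.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_design <- function(design, stack) {
  md <- attr(design, "min_dist") %||% 400
  fr <- attr(design, "forest_radius") %||% 200
  fm <- attr(design, "forest_min") %||% 0.5
  d <- as.matrix(stats::dist(design[, c("x", "y")]))
  diag(d) <- Inf
  if (any(d < md)) stop("spacing rule violated")
  for (i in seq_len(nrow(design))) {
    b <- extract_buffer(stack, c(design$x[i], design$y[i]), fr)
    if (proportional_cover(b, stack, forest_classes()) <= fm)
      stop("forest rule violated at location ", design$id[i])
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate species detections at survey locations
#'
#' Detection probability at a location is
#' `plogis(alpha + beta_true * U(s_true) + sum(gamma_j x_j))` where `U(s)` is
#' the location's standardized urbanization score at the species' true scale
#' of effect and `x_j` are standardized nuisance covariates named in
#' `gamma`. Draws are independent Bernoulli; a positive count is attached to
#' each detection so count-weighted analyses have data.
#'
#' @param design a `SurveyDesign`.
#' @param metrics metric table from [assemble_metrics()] covering every
#'   species' `s_true`.
#' @param truth a `TruthRecord` data frame (columns `species_id`,
#'   `beta_true`, `s_true`, `alpha`) as built by [generate_traits_and_tree()]
#'   or by hand. Optional attribute `gamma`: named vector of nuisance
#'   coefficients over metric columns.
#' @param seed integer seed.
#' @param urb_col metric column holding the urbanization score.
#' @return A `DetectionTable` data frame (species_id, location_id, detected,
#'   count).
#' @export
simulate_occurrences <- function(design, metrics, truth, seed = 1,
                                 urb_col = "urb") {
  set.seed(seed)
  gamma <- attr(truth, "gamma")
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    s <- truth$s_true[i]
    mt <- metrics[metrics$radius_km == s, , drop = FALSE]
    mt <- mt[match(design$id, mt$location_id), , drop = FALSE]
    if (any(is.na(mt$location_id)) || !nrow(mt))
      stop("no metrics available at s_true = ", s, " km for species ",
           truth$species_id[i])
    u <- as.numeric(scale(mt[[urb_col]]))
    eta <- truth$alpha[i] + truth$beta_true[i] * u
    if (!is.null(gamma))
      for (nm in names(gamma))
        eta <- eta + gamma[[nm]] * as.numeric(scale(mt[[nm]]))
    det <- rbinom(nrow(design), 1, plogis(eta))
    out[[i]] <- data.frame(
      species_id = truth$species_id[i],
      location_id = design$id,
      detected = det,
      count = ifelse(det == 1, 1 + rpois(nrow(design), 0.7), 0L)
    )
  }
  res <- do.call(rbind, out)
  class(res) <- c("DetectionTable", "data.frame")
  res
}
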