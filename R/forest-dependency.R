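#' Species eligibility filter
#'
#' Drops species detected at fewer than `min_locations` count locations, and
#' species flagged in an optional attribute table as hybrid, irregular
#' breeder, raptor, waterfowl or nocturnal.
#'
#' @param species_summary data frame with `species_id` and `n_locations`
#'   (number of locations with a detection).
#' @param flags optional data frame with `species_id` and logical columns
#'   among `hybrid`, `irregular`, `raptor`, `waterfowl`, `nocturnal`. When
#'   absent only the count filter is applied (a message notes this).
#' @param min_locations minimum number of occupied locations.
#' @return Data frame with `species_id`, `keep`, `reason`.
#' @export
eligibility_filter <- function(species_summary, flags = NULL, min_locations = 30) {
  out <- data.frame(species_id = species_summary$species_id,
                    keep = TRUE, reason = "", stringsAsFactors = FALSE)
  flag_cols <- c("hybrid", "irregular", "raptor", "waterfowl", "nocturnal")
  if (is.null(flags)) {
    message("no species-attribute flag file supplied; applying only the ",
            "minimum-occurrence filter")
  } else {
    for (fc in intersect(flag_cols, names(flags))) {
      bad <- flags$species_id[which(flags[[fc]])]
      hit <- out$species_id %in% bad & out$keep
      out$keep[hit] <- FALSE
      out$reason[hit] <- fc
    }
  }
  low <- species_summary$n_locations < min_locations & out$keep
  out$keep[low] <- FALSE
  out$reason[low] <- "min occurrence"
  out
}

#' Cumulative count and forest-amount curves
#'
#' Orders locations by ascending forest amount and accumulates both the
#' species' counts and the forest amounts along that ordering, as fractions
#' of their totals. Locations with equal forest amount are pooled so the
#' curves (and the max-gap statistic) are invariant to relabeling ties.
#'
#' @param counts per-location counts of the species.
#' @param forest per-location forest amount.
#' @return List with `count_cdf`, `forest_cdf` (evaluated at the upper edge
#'   of each distinct forest value) and `forest_values`.
#' @export
cumulative_curves <- function(counts, forest) {
  stopifnot(length(counts) == length(forest))
  if (sum(counts) <= 0) stop("zero total count; cannot form the count CDF")
  agg_c <- tapply(counts, forest, sum)
  agg_f <- tapply(forest, forest, sum)
  fv <- as.numeric(names(agg_c))
  o <- order(fv)
  list(count_cdf = cumsum(agg_c[o]) / sum(counts),
       forest_cdf = cumsum(agg_f[o]) / sum(forest),
       forest_values = fv[o])
}

# max-gap statistic between the two curves plus its signed deviation:
# negative gap at the argmax (counts lagging forest) means individuals are
# concentrated in the most-forested landscapes
.max_gap <- function(curves) {
  d <- curves$count_cdf - curves$forest_cdf
  i <- which.max(abs(d))
  list(D = abs(d[i]), direction = sign(d[i]))
}

#' Forest-dependency classification
#'
#' Reconstruction of a Kolmogorov-Smirnov-style comparison of the cumulative
#' distribution of a species' counts to the cumulative distribution of
#' forest amount: at each radius the weighted one-ordering max-gap statistic
#' D is tested by permutation of counts over locations. A radius votes
#' forest-dependent when the test does not reject (counts accumulate with
#' forest) or when it rejects with the deviation toward high-forest
#' landscapes; it votes forest-independent when counts concentrate in the
#' least-forested landscapes. The final label is the majority vote across
#' radii, ties going to forest-dependent.
#'
#' @param counts per-location counts of one species.
#' @param forest_by_radius data frame or matrix, one column per radius
#'   (named by radius), of per-location forest amounts.
#' @param alpha significance level of the permutation test.
#' @param n_perm number of count permutations.
#' @param seed integer seed for the permutation null.
#' @return A `DependencyResult`: data frame with one row per radius
#'   (radius, D, p, direction, vote) plus attributes `classification` and
#'   `species votes`.
#' @export
ks_classify <- function(counts, forest_by_radius, alpha = 0.05,
                        n_perm = 1000, seed = 1) {
  set.seed(seed)
  forest_by_radius <- as.data.frame(forest_by_radius)
  res <- lapply(names(forest_by_radius), function(rn) {
    forest <- forest_by_radius[[rn]]
    obs <- .max_gap(cumulative_curves(counts, forest))
    perm_D <- replicate(n_perm, {
      .max_gap(cumulative_curves(sample(counts), forest))$D
    })
    p <- (sum(perm_D >= obs$D) + 1) / (n_perm + 1)
    vote <- if (p >= alpha || obs$direction <= 0) "forest-dependent"
            else "forest-independent"
    data.frame(radius = rn, D = obs$D, p = p, direction = obs$direction,
               vote = vote, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  n_dep <- sum(res$vote == "forest-dependent")
  cls <- if (n_dep >= nrow(res) / 2) "forest-dependent" else "forest-independent"
  attr(res, "classification") <- cls
  class(res) <- c("DependencyResult", "data.frame")
  res
}

#' Classify every species in a detection table
#'
#' @param detections a `DetectionTable`.
#' @param metrics a `MetricVector` table with a `forest` column.
#' @param radii radii (km) to use; default all in `metrics`.
#' @inheritParams ks_classify
#' @return Data frame with one row per species: `species_id`,
#'   `classification`, `n_dependent_votes`, `n_radii`.
#' @export
classify_forest_dependency <- function(detections, metrics, radii = NULL,
                                       alpha = 0.05, n_perm = 1000, seed = 1) {
  if (is.null(radii)) radii <- sort(unique(metrics$radius_km))
  loc <- sort(unique(metrics$location_id))
  fbr <- sapply(radii, function(r) {
    m <- metrics[metrics$radius_km == r, ]
    m$forest[match(loc, m$location_id)]
  })
  colnames(fbr) <- radii
  keep_loc <- stats::complete.cases(fbr)
  fbr <- fbr[keep_loc, , drop = FALSE]
  loc <- loc[keep_loc]
  sp <- unique(detections$species_id)
  rows <- lapply(sp, function(s) {
    d <- detections[detections$species_id == s, ]
    counts <- d$count[match(loc, d$location_id)]
    counts[is.na(counts)] <- 0
    dr <- ks_classify(counts, fbr, alpha = alpha, n_perm = n_perm, seed = seed)
    data.frame(species_id = s, classification = attr(dr, "classification"),
               n_dependent_votes = sum(dr$vote == "forest-dependent"),
               n_radii = nrow(dr), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
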