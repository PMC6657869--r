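#' Assemble per-location, per-radius explanatory variables
#'
#' For every survey location and every analysis radius, computes the
#' urbanization-index inputs (four developed-class proportions, mean
#' population and housing density), runs the PCA index per radius across
#' landscapes, and adds the heterogeneity covariates: forest amount, forest
#' patch density, forest clumpiness, agriculture amount, elevation mean and
#' range, and Shannon diversity. Location-level habitat and detectability
#' covariates are carried through. Buffers extending beyond the grid
#' (incomplete) are dropped.
#'
#' Forest columns are computed once per entry of `forest_sets`; the default
#' single set `total` uses all three forest classes, the fallback for
#' generalist species or species without a mapped habitat affinity.
#' Species-specific class sets (e.g. `deciduous = 41`) add suffixed columns.
#'
#' @param stack a `LandscapeStack`.
#' @param design a `SurveyDesign`.
#' @param radii analysis radii in km.
#' @param forest_sets named list of class-code vectors for forest
#'   amount/configuration; first entry is the total-forest fallback.
#' @return A `MetricVector` data frame, one row per complete
#'   (location, radius) pair, with the per-radius `PCAIndex` objects in
#'   attribute `pca` and dropped (incomplete) pairs in attribute `dropped`.
#' @export
assemble_metrics <- function(stack, design, radii,
                             forest_sets = list(total = forest_classes())) {
  dev_cls <- developed_classes()
  rows <- list()
  dropped <- list()
  pca_by_radius <- list()
  for (r in radii) {
    rad_m <- r * 1000
    recs <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      b <- extract_buffer(stack, c(design$x[i], design$y[i]), rad_m)
      if (b$incomplete || b$n == 0) {
        dropped[[length(dropped) + 1]] <- data.frame(
          location_id = design$id[i], radius_km = r, reason = "incomplete buffer")
        next
      }
      rec <- list(location_id = design$id[i], radius_km = r)
      for (k in seq_along(dev_cls))
        rec[[paste0("dev", k)]] <- proportional_cover(b, stack, dev_cls[k])
      rec$pop <- area_weighted_mean(b, stack$pop_density)
      rec$housing <- area_weighted_mean(b, stack$housing_density)
      for (nm in names(forest_sets)) {
        suf <- if (nm == names(forest_sets)[1]) "" else paste0("_", nm)
        rec[[paste0("forest", suf)]] <- proportional_cover(b, stack, forest_sets[[nm]])
        rec[[paste0("pdens", suf)]] <- patch_density(b, stack, forest_sets[[nm]])
        rec[[paste0("clumpy", suf)]] <- clumpiness(b, stack, forest_sets[[nm]])
      }
      rec$agri <- proportional_cover(b, stack, agriculture_classes())
      rec$elev_mean <- area_weighted_mean(b, stack$elevation)
      rec$elev_range <- surface_range(b, stack$elevation)
      rec$shannon <- shannon_diversity(b, stack)
      recs[[i]] <- as.data.frame(rec)
    }
    recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    if (is.null(recs) || nrow(recs) == 0) next
    uvars <- as.matrix(recs[, c(paste0("dev", seq_along(dev_cls)), "pop", "housing")])
    # classes absent at this radius yield constant zero columns carrying no
    # information; drop them rather than fail the whole index
    const <- apply(uvars, 2, sd) == 0
    if (any(const) && sum(!const) >= 2) {
      message("radius ", r, " km: dropping constant urbanization variable(s) ",
              paste(colnames(uvars)[const], collapse = ", "))
      uvars <- uvars[, !const, drop = FALSE]
    }
    pca <- tryCatch(urbanization_pca(uvars, housing_col = "housing"),
                    error = function(e) e)
    if (inherits(pca, "error")) {
      warning("PCA failed at radius ", r, " km: ", conditionMessage(pca),
              "; urbanization score set to NA")
      recs$urb <- NA_real_
    } else {
      recs$urb <- as.numeric(pca$scores[, 1])
      if (ncol(pca$scores) > 1) recs$urb2 <- as.numeric(pca$scores[, 2])
      pca_by_radius[[as.character(r)]] <- pca
    }
    rows[[as.character(r)]] <- recs
  }
  # radii with a retained second component carry urb2; align columns with NA
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(d) {
    for (cn in setdiff(all_cols, names(d))) d[[cn]] <- NA_real_
    d[, all_cols]
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no complete buffers at any radius")
  rownames(out) <- NULL
  # carry location covariates through
  loc_cols <- setdiff(names(design), c("x", "y"))
  out <- merge(out, design[, loc_cols], by.x = "location_id", by.y = "id",
               sort = FALSE)
  out <- out[order(out$radius_km, out$location_id), ]
  rownames(out) <- NULL
  attr(out, "pca") <- pca_by_radius
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  class(out) <- c("MetricVector", "data.frame")
  out
}
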