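#' Urbanization-intensity PCA index
#'
#' Principal component analysis on the correlation matrix of the
#' urbanization variables measured over landscapes at one radius (canonical
#' six: four developed-class proportions, area-weighted population density
#' and housing density). Components with eigenvalue > 1 are retained; each
#' retained component is oriented so that its correlation with housing
#' density is non-negative, so higher scores always mean more urban.
#'
#' @param x numeric matrix or data frame, one row per landscape, at least
#'   two non-constant columns.
#' @param housing_col column (name or index) used for the sign convention.
#' @return A `PCAIndex`: list with `loadings`, `eigenvalues`, `retained`
#'   (component indices), `scores` (n x retained, zero-mean columns), and
#'   `prop_var`.
#' @export
urbanization_pca <- function(x, housing_col = "housing") {
  x <- as.matrix(x)
  if (nrow(x) < 7) stop("need at least 7 landscapes for the PCA index")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant variable(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  retained <- which(ev > 1)
  if (length(retained) == 0) {
    warning("no eigenvalue exceeds 1; retaining the first component")
    retained <- 1L
  }
  load <- eig$vectors[, retained, drop = FALSE]
  rownames(load) <- colnames(x)
  scores <- z %*% load
  hc <- if (is.character(housing_col)) match(housing_col, colnames(x)) else housing_col
  if (!is.na(hc)) {
    for (k in seq_along(retained)) {
      r <- stats::cor(scores[, k], x[, hc])
      if (!is.na(r) && r < 0) {
        load[, k] <- -load[, k]
        scores[, k] <- -scores[, k]
      }
    }
  }
  colnames(scores) <- colnames(load) <- paste0("U", seq_along(retained))
  structure(list(loadings = load, eigenvalues = ev, retained = retained,
                 scores = scores, prop_var = ev / length(ev)),
            class = "PCAIndex")
}

#' @export
print.PCAIndex <- function(x, ...) {
  cat("PCAIndex:", length(x$retained), "component(s) retained (eigenvalue > 1)\n")
  cat("  eigenvalues:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  cat("  variance explained by retained:",
      paste0(round(100 * x$prop_var[x$retained], 1), "%", collapse = ", "), "\n")
  invisible(x)
}
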