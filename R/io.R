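#' Write and read a landscape stack as plain-text grids
#'
#' Each surface is written as a whitespace-delimited matrix
#' (`<prefix>_<surface>.tsv`) alongside a JSON header
#' (`<prefix>_header.json`) holding cell size, origin and the class legend.
#'
#' @param stack a `LandscapeStack`.
#' @param prefix file path prefix (directory must exist).
#' @return `write_landscape`: the header path, invisibly.
#'   `read_landscape`: the reconstructed `LandscapeStack`.
#' @export
write_landscape <- function(stack, prefix) {
  surfaces <- c("landcover", "pop_density", "housing_density", "elevation")
  for (s in surfaces)
    utils::write.table(stack[[s]], paste0(prefix, "_", s, ".tsv"),
                       row.names = FALSE, col.names = FALSE)
  hdr <- list(cell_size = stack$cell_size, origin = stack$origin,
              dim = dim(stack$landcover), legend = as.list(stack$legend))
  path <- paste0(prefix, "_header.json")
  jsonlite::write_json(hdr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, "_header.json"), simplifyVector = TRUE)
  rd <- function(s, mode) {
    m <- as.matrix(utils::read.table(paste0(prefix, "_", s, ".tsv")))
    dimnames(m) <- NULL
    storage.mode(m) <- mode
    m
  }
  .new_landscape(rd("landcover", "integer"), rd("pop_density", "double"),
                 rd("housing_density", "double"), rd("elevation", "double"),
                 cell_size = hdr$cell_size, origin = hdr$origin)
}

#' Round-trip survey designs and detection tables as CSV
#'
#' @param x a `SurveyDesign` or `DetectionTable`.
#' @param path CSV path.
#' @return Reader functions return the reconstructed object.
#' @export
write_design <- function(x, path) {
  df <- as.data.frame(x)
  for (a in c("min_dist", "forest_radius", "forest_min"))
    if (!is.null(attr(x, a))) df[[paste0(".", a)]] <- attr(x, a)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = TRUE)
  for (a in c("min_dist", "forest_radius", "forest_min")) {
    col <- paste0(".", a)
    if (col %in% names(df)) {
      attr(df, a) <- df[[col]][1]
      df[[col]] <- NULL
    }
  }
  class(df) <- c("SurveyDesign", "data.frame")
  df
}

#' @rdname write_design
#' @export
write_detections <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("DetectionTable", "data.frame")
  df
}
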