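#' Extract a circular buffer from a landscape stack
#'
#' Membership follows the cell-center rule: a cell belongs to the buffer iff
#' its center lies strictly within `radius` of `center`. The buffer is
#' flagged incomplete when any part of the disc extends beyond the grid;
#' downstream assembly drops incomplete buffers, mirroring the exclusion of
#' landscapes overlapping the study-region border.
#'
#' @param stack a `LandscapeStack`.
#' @param center numeric `(x, y)` in meters.
#' @param radius buffer radius in meters (> 0).
#' @return A `Buffer`: list with `center`, `radius`, `cells` (linear indices
#'   into the grids), `n`, and `incomplete` flag.
#' @export
extract_buffer <- function(stack, center, radius) {
  stopifnot(radius > 0, length(center) == 2)
  cs <- stack$cell_size
  nr <- nrow(stack$landcover); nc <- ncol(stack$landcover)
  xmax <- stack$origin[1] + nc * cs
  ymax <- stack$origin[2] + nr * cs
  if (center[1] < stack$origin[1] || center[1] > xmax ||
      center[2] < stack$origin[2] || center[2] > ymax)
    stop("buffer center (", center[1], ", ", center[2], ") is off the grid")
  incomplete <- center[1] - radius < stack$origin[1] ||
    center[1] + radius > xmax ||
    center[2] - radius < stack$origin[2] ||
    center[2] + radius > ymax

  cc <- .cell_centers(stack)
  jr <- which(abs(cc$x - center[1]) < radius)
  ir <- which(abs(cc$y - center[2]) < radius)
  if (length(jr) == 0 || length(ir) == 0) {
    cells <- integer(0)
  } else {
    dx2 <- (cc$x[jr] - center[1])^2
    dy2 <- (cc$y[ir] - center[2])^2
    inside <- outer(dy2, dx2, `+`) < radius^2
    ii <- ir[row(inside)[inside]]
    jj <- jr[col(inside)[inside]]
    cells <- ii + (jj - 1L) * nr
  }
  structure(list(center = center, radius = radius, cells = cells,
                 n = length(cells), incomplete = incomplete,
                 dim = c(nr, nc), cell_size = cs),
            class = "Buffer")
}

#' Proportional cover of a class set within a buffer
#'
#' @param buffer a `Buffer`.
#' @param stack the `LandscapeStack`.
#' @param classes integer class codes (non-empty).
#' @return Proportion of member cells whose class is in `classes`.
#' @export
proportional_cover <- function(buffer, stack, classes) {
  if (length(classes) == 0) stop("empty class set")
  if (buffer$n == 0) stop("empty buffer")
  mean(stack$landcover[buffer$cells] %in% classes)
}

#' Mean of a surface over a buffer
#'
#' Cells are equal-area, so the area-weighted average of a density surface
#' over the buffer is the plain mean of member cells.
#'
#' @param buffer a `Buffer`.
#' @param surface numeric grid co-registered with the buffer's stack.
#' @param ignore_missing drop NA cells instead of erroring.
#' @return Mean surface value.
#' @export
area_weighted_mean <- function(buffer, surface, ignore_missing = FALSE) {
  if (buffer$n == 0) stop("empty buffer")
  v <- surface[buffer$cells]
  if (anyNA(v)) {
    if (!ignore_missing) stop("NA cells in buffer; set ignore_missing = TRUE to drop them")
    v <- v[!is.na(v)]
  }
  mean(v)
}

#' Range (max minus min) of a surface over a buffer
#' @inheritParams area_weighted_mean
#' @export
surface_range <- function(buffer, surface, ignore_missing = FALSE) {
  if (buffer$n == 0) stop("empty buffer")
  v <- surface[buffer$cells]
  if (anyNA(v)) {
    if (!ignore_missing) stop("NA cells in buffer")
    v <- v[!is.na(v)]
  }
  max(v) - min(v)
}
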