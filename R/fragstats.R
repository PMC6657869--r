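# connected components of `mask` (logical matrix) under 8- or 4-neighbor
# connectivity; iterative flood fill, returns component count
.n_components <- function(mask, eight = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (eight) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1); dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    di <- c(-1, 1, 0, 0); dj <- c(0, 0, -1, 1)
  }
  count <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (seen[start]) next
    count <- count + 1L
    stack_ <- start
    seen[start] <- TRUE
    while (length(stack_)) {
      cur <- stack_[length(stack_)]
      stack_ <- stack_[-length(stack_)]
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      ni <- i + di; nj <- j + dj
      ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
      idx <- ni[ok] + (nj[ok] - 1L) * nr
      idx <- idx[mask[idx] & !seen[idx]]
      if (length(idx)) {
        seen[idx] <- TRUE
        stack_ <- c(stack_, idx)
      }
    }
  }
  count
}

# logical masks for a buffer, cropped to its bounding box: in-buffer
# membership and in-buffer class membership
.buffer_masks <- function(buffer, stack, class) {
  nr <- buffer$dim[1]
  gi <- ((buffer$cells - 1L) %% nr) + 1L
  gj <- ((buffer$cells - 1L) %/% nr) + 1L
  i0 <- min(gi); j0 <- min(gj)
  bi <- gi - i0 + 1L; bj <- gj - j0 + 1L
  bnr <- max(bi); bnc <- max(bj)
  idx <- bi + (bj - 1L) * bnr
  inb <- matrix(FALSE, bnr, bnc)
  inb[idx] <- TRUE
  cls <- matrix(FALSE, bnr, bnc)
  cls[idx] <- stack$landcover[buffer$cells] %in% class
  list(inb = inb, cls = cls)
}

#' Patch density of a class within a buffer
#'
#' Number of connected patches (8-neighbor connectivity) of the class among
#' buffer member cells, per 100 hectares of buffer area.
#'
#' @param buffer a `Buffer`.
#' @param stack the `LandscapeStack`.
#' @param class integer class code(s) treated as one cover type.
#' @return Patches per 100 ha (0 when the class is absent).
#' @export
patch_density <- function(buffer, stack, class) {
  if (buffer$n == 0) stop("empty buffer")
  m <- .buffer_masks(buffer, stack, class)
  n_patch <- .n_components(m$cls, eight = TRUE)
  area_ha <- buffer$n * buffer$cell_size^2 / 1e4
  n_patch / area_ha * 100
}

# minimum perimeter (in cell-edge units) of a maximally compact patch of a
# cells; standard FRAGSTATS construction
.min_perimeter <- function(a) {
  n <- floor(sqrt(a))
  m <- a - n^2
  if (m == 0) 4 * n
  else if (a <= n * (n + 1)) 4 * n + 2
  else 4 * n + 4
}

# rook adjacency tallies within the buffer (double-count convention):
# g_ii = ordered like-class pairs, g_i. = ordered pairs with a class cell first
.adjacency_tally <- function(inb, cls) {
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  nr <- nrow(inb); nc <- ncol(inb)
  g_ii <- 0; g_i_dot <- 0
  for (s in shifts) {
    di <- s[1]; dj <- s[2]
    src_i <- (1 + max(0, di)):(nr + min(0, di))
    src_j <- (1 + max(0, dj)):(nc + min(0, dj))
    a_cls <- cls[src_i - di, src_j - dj, drop = FALSE]
    b_in  <- inb[src_i, src_j, drop = FALSE]
    b_cls <- cls[src_i, src_j, drop = FALSE]
    g_i_dot <- g_i_dot + sum(a_cls & b_in)
    g_ii <- g_ii + sum(a_cls & b_cls)
  }
  list(g_ii = g_ii, g_i_dot = g_i_dot)
}

#' Clumpiness (CLUMPY) of a class within a buffer
#'
#' Adjacency-based aggregation index in `[-1, 1]`: -1 for a maximally
#' disaggregated (checkerboard) class, 0 for a random arrangement, 1 for a
#' single maximally compact patch. Computed from the like-adjacency
#' proportion `G = g_ii / (g_i. - min_e)` using rook (4-neighbor)
#' adjacencies between cell pairs that both lie inside the buffer
#' (double-count convention), where `min_e` is the minimum possible
#' perimeter of the class, and the class proportion `P`:
#' `(G - P) / P` when `G < P` and `P < 0.5`, else `(G - P) / (1 - P)`.
#'
#' @inheritParams patch_density
#' @return Clumpiness value, or `NA` when the class is absent from the
#'   buffer.
#' @export
clumpiness <- function(buffer, stack, class) {
  if (buffer$n == 0) stop("empty buffer")
  m <- .buffer_masks(buffer, stack, class)
  a <- sum(m$cls)
  if (a == 0) return(NA_real_)
  P <- a / buffer$n
  if (P >= 1) return(1)
  tal <- .adjacency_tally(m$inb, m$cls)
  denom <- tal$g_i_dot - .min_perimeter(a)
  G <- if (denom <= 0) 1 else tal$g_ii / denom
  G <- min(max(G, 0), 1)
  if (G < P && P < 0.5) (G - P) / P else (G - P) / (1 - P)
}

#' Shannon diversity of land-cover classes within a buffer
#'
#' `H = -sum(p_k * log(p_k))` (natural log) over classes present in the
#' buffer.
#'
#' @inheritParams patch_density
#' @return H in nats (0 when a single class fills the buffer).
#' @export
shannon_diversity <- function(buffer, stack) {
  if (buffer$n == 0) stop("empty buffer")
  p <- table(stack$landcover[buffer$cells])
  p <- as.numeric(p) / buffer$n
  p <- p[p > 0]
  -sum(p * log(p))
}
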