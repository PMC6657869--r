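# -- fixture builders ---------------------------------------------------------

# landscape stack from an explicit land-cover matrix; flat densities/elevation
# unless supplied
make_stack <- function(landcover, cell_size = 100, pop = NULL, housing = NULL,
                       elevation = NULL) {
  landcover <- as.matrix(landcover)
  storage.mode(landcover) <- "integer"
  z <- matrix(0, nrow(landcover), ncol(landcover))
  urbanscape:::.new_landscape(
    landcover,
    if (is.null(pop)) z else pop,
    if (is.null(housing)) z else housing,
    if (is.null(elevation)) z + 350 else elevation,
    cell_size = cell_size, origin = c(0, 0))
}

uniform_stack <- function(n, class = 41L, cell_size = 100) {
  make_stack(matrix(class, n, n), cell_size = cell_size)
}

# a buffer covering every cell of a square stack (centered, generous radius)
whole_grid_buffer <- function(stack) {
  n <- nrow(stack$landcover)
  cs <- stack$cell_size
  extract_buffer(stack, c(n * cs / 2, n * cs / 2), radius = n * cs)
}

# two-column matrix whose sample correlation is exactly r
exact_cor_matrix <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- scale(rnorm(n))
  e <- scale(residuals(lm(rnorm(n) ~ x)))
  cbind(a = as.numeric(x), b = as.numeric(r * x + sqrt(1 - r^2) * e))
}

# -- independent oracles ------------------------------------------------------

# connected-component count via igraph on the adjacency graph
igraph_components <- function(mask, eight = TRUE) {
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  nr <- nrow(mask)
  i <- ((idx - 1L) %% nr) + 1L
  j <- ((idx - 1L) %/% nr) + 1L
  id <- seq_along(idx)
  key <- setNames(id, paste(i, j))
  offs <- if (eight) rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
          else rbind(c(-1, 0), c(0, -1))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nk <- unname(key[paste(i + offs[k, 1], j + offs[k, 2])])
    ok <- !is.na(nk)
    from <- c(from, id[ok]); to <- c(to, nk[ok])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, as.vector(rbind(from, to)))
  igraph::components(g)$no
}

# clumpiness by explicit O(n^2) tally of all rook-adjacent cell pairs
clumpiness_oracle <- function(landcover, class, in_buffer = NULL) {
  nr <- nrow(landcover); nc <- ncol(landcover)
  if (is.null(in_buffer)) in_buffer <- matrix(TRUE, nr, nc)
  cells <- which(in_buffer)
  total <- length(cells)
  is_cls <- landcover %in% class & in_buffer
  a <- sum(is_cls)
  if (a == 0) return(NA_real_)
  P <- a / total
  if (P >= 1) return(1)
  g_ii <- 0; g_idot <- 0
  ci <- ((cells - 1) %% nr) + 1
  cj <- ((cells - 1) %/% nr) + 1
  for (u in seq_along(cells)) {
    for (v in seq_along(cells)) {
      if (u == v) next
      if (abs(ci[u] - ci[v]) + abs(cj[u] - cj[v]) == 1) {
        if (is_cls[cells[u]]) {
          g_idot <- g_idot + 1
          if (is_cls[cells[v]]) g_ii <- g_ii + 1
        }
      }
    }
  }
  nside <- floor(sqrt(a))
  m <- a - nside^2
  min_e <- if (m == 0) 4 * nside
           else if (a <= nside * (nside + 1)) 4 * nside + 2
           else 4 * nside + 4
  G <- if (g_idot - min_e <= 0) 1 else g_ii / (g_idot - min_e)
  G <- min(max(G, 0), 1)
  if (G < P && P < 0.5) (G - P) / P else (G - P) / (1 - P)
}

# full model-averaging arithmetic, spreadsheet style
model_average_oracle <- function(delta, beta, v, delta_max = 2) {
  keep <- delta <= delta_max
  d <- delta[keep]; b <- beta[keep]; vv <- v[keep]
  w <- exp(-d / 2); w <- w / sum(w)
  bb <- sum(w * b)
  list(beta = bb, se = sum(w * sqrt(vv + (b - bb)^2)))
}

# max absolute gap between count and forest CDFs, direct implementation on
# the pooled-by-forest-value ordering
max_gap_oracle <- function(counts, forest) {
  o <- order(forest)
  counts <- counts[o]; forest <- forest[o]
  # pool tied forest values
  grp <- cumsum(!duplicated(forest))
  cc <- tapply(counts, grp, sum)
  ff <- tapply(forest, grp, sum)
  max(abs(cumsum(cc) / sum(cc) - cumsum(ff) / sum(ff)))
}
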