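test_that("buffer membership follows the cell-center rule", {
  st <- uniform_stack(30)
  # degenerate disc: radius below half a cell keeps only the containing cell
  b <- extract_buffer(st, c(1050, 1050), 40)
  expect_equal(b$n, 1L)
  expect_false(b$incomplete)
  # member count approximates the disc area for a 1 km disc on 30 m cells
  st30 <- uniform_stack(100, cell_size = 30)
  b2 <- extract_buffer(st30, c(1500, 1500), 1000)
  expect_lt(abs(b2$n - pi * 1000^2 / 30^2) / (pi * 1000^2 / 30^2), 0.01)
  # a disc leaving the grid is flagged incomplete
  b3 <- extract_buffer(st, c(150, 150), 400)
  expect_true(b3$incomplete)
  expect_error(extract_buffer(st, c(-10, 500), 100), "off the grid")
})

test_that("proportional cover counts member cells exactly", {
  st <- uniform_stack(20)
  b <- whole_grid_buffer(st)
  expect_equal(proportional_cover(b, st, forest_classes()), 1.0)
  expect_equal(proportional_cover(b, st, 99L), 0.0)
  expect_error(proportional_cover(b, st, integer(0)), "empty class set")
  # checkerboard: half in each class up to one-cell parity
  n <- 40
  cb <- matrix(ifelse((row(diag(n)) + col(diag(n))) %% 2 == 0, 41L, 82L), n, n)
  stc <- make_stack(cb)
  bc <- extract_buffer(stc, c(2000, 2000), 1500)
  expect_lt(abs(proportional_cover(bc, stc, 41L) - 0.5), 1 / bc$n * 2)
})

test_that("area-weighted mean and range reduce correctly over buffers", {
  n <- 50
  st <- uniform_stack(n)
  b <- extract_buffer(st, c(2500, 2500), 1200)
  const <- matrix(7.5, n, n)
  expect_equal(area_weighted_mean(b, const), 7.5)
  half <- matrix(rep(c(0, 100), each = n * n / 2), n, n)
  bb <- whole_grid_buffer(st)
  expect_equal(area_weighted_mean(bb, half), 50)
  expect_equal(surface_range(bb, half), 100)
  # linear ramp: the disc mean equals the ramp value at the disc center
  cc <- urbanscape:::.cell_centers(st)
  ramp <- outer(cc$y, cc$x, function(y, x) 0.003 * x + 0.001 * y + 2)
  expect_lt(abs(area_weighted_mean(b, ramp) - (0.003 * 2500 + 0.001 * 2500 + 2)) /
              (0.003 * 2500 + 0.001 * 2500 + 2), 0.01)
  withNA <- const; withNA[3, 3] <- NA
  expect_error(area_weighted_mean(bb, withNA), "NA")
  expect_equal(area_weighted_mean(bb, withNA, ignore_missing = TRUE), 7.5)
})

test_that("patch density counts 8-connected components per 100 ha", {
  n <- 30
  lc <- matrix(82L, n, n)
  lc[5:10, 5:10] <- 41L            # one solid blob
  st <- make_stack(lc)
  b <- whole_grid_buffer(st)
  area_ha <- b$n * 100^2 / 1e4
  expect_equal(patch_density(b, st, 41L), 1 / area_ha * 100)
  lc2 <- lc; lc2[20:24, 20:24] <- 41L  # second blob far away
  st2 <- make_stack(lc2)
  expect_equal(patch_density(b, st2, 41L), 2 / area_ha * 100)
  expect_equal(patch_density(b, st, 99L), 0)
})

test_that("patch counts match the igraph flood-fill oracle on random grids", {
  set.seed(42)
  for (rep in 1:20) {
    mask <- matrix(runif(900) < runif(1, 0.2, 0.7), 30, 30)
    ours <- urbanscape:::.n_components(mask, eight = TRUE)
    expect_equal(ours, igraph_components(mask, eight = TRUE),
                 ignore_attr = TRUE)
  }
})

test_that("clumpiness hits its analytic anchors", {
  n <- 20
  cb <- matrix(ifelse((row(diag(n)) + col(diag(n))) %% 2 == 0, 41L, 82L), n, n)
  st <- make_stack(cb)
  b <- whole_grid_buffer(st)
  expect_identical(clumpiness(b, st, 41L), -1)   # perfect checkerboard at P = 0.5
  solid <- uniform_stack(n)
  expect_identical(clumpiness(whole_grid_buffer(solid), solid, 41L), 1)
  expect_true(is.na(clumpiness(b, st, 99L)))     # absent class undefined
})

test_that("clumpiness matches the brute-force adjacency oracle on random grids", {
  set.seed(7)
  for (rep in 1:25) {
    lc <- matrix(sample(c(41L, 82L), 144, replace = TRUE,
                        prob = c(runif(1, 0.2, 0.8), 1)), 12, 12)
    st <- make_stack(lc)
    b <- whole_grid_buffer(st)
    o <- clumpiness_oracle(lc, 41L)
    ours <- clumpiness(b, st, 41L)
    if (is.na(o)) expect_true(is.na(ours))
    else expect_equal(ours, o, tolerance = 1e-12)
  }
})

test_that("clumpiness respects buffer boundaries, not the full grid", {
  lc <- matrix(82L, 15, 15)
  lc[6:9, 6:9] <- 41L
  st <- make_stack(lc)
  b <- extract_buffer(st, c(750, 750), 420)
  nr <- 15
  inb <- matrix(FALSE, nr, nr); inb[b$cells] <- TRUE
  expect_equal(clumpiness(b, st, 41L), clumpiness_oracle(lc, 41L, inb),
               tolerance = 1e-12)
})

test_that("shannon diversity evaluates -sum p log p", {
  st <- uniform_stack(10)
  b <- whole_grid_buffer(st)
  expect_equal(shannon_diversity(b, st), 0)
  n <- 20
  two <- matrix(rep(c(41L, 82L), each = n * n / 2), n, n)
  st2 <- make_stack(two)
  expect_equal(shannon_diversity(whole_grid_buffer(st2), st2), log(2),
               tolerance = 1e-12)
  # proportions (0.5, 0.3, 0.2)
  v <- c(rep(41L, 50), rep(82L, 30), rep(22L, 20))
  st3 <- make_stack(matrix(v, 10, 10))
  expect_equal(shannon_diversity(whole_grid_buffer(st3), st3),
               -sum(c(.5, .3, .2) * log(c(.5, .3, .2))), tolerance = 1e-12)
  expect_equal(shannon_diversity(whole_grid_buffer(st3), st3), 1.0297,
               tolerance = 1e-4)
})

test_that("class proportions over the legend sum to one per buffer", {
  st <- generate_landscape(extent = 5000, cell_size = 100,
                           urban_strength = 0.7, forest_frac = 0.5, seed = 31)
  b <- extract_buffer(st, c(2500, 2500), 1000)
  tot <- sum(vapply(landcover_legend(),
                    function(cl) proportional_cover(b, st, cl), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("urbanization PCA retains eigenvalue > 1 components with a stable sign", {
  # two variables correlated at 0.5: eigenvalues 1 +/- r
  xy <- exact_cor_matrix(200, 0.5, seed = 2)
  colnames(xy) <- c("housing", "pop")
  p <- urbanization_pca(xy, housing_col = "housing")
  expect_equal(p$eigenvalues, c(1.5, 0.5), tolerance = 1e-10)
  expect_equal(p$retained, 1L)
  expect_gte(cor(p$scores[, 1], xy[, "housing"]), 0)
  # perfectly correlated pair: rank 1, eigenvalues (2, 0)
  xx <- cbind(housing = rnorm(50))
  xx <- cbind(xx, other = 2 * xx[, 1] + 3)
  p2 <- urbanization_pca(xx)
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(length(p2$retained), 1L)
  # independent standard normals: all eigenvalues near 1 (the largest sample
  # eigenvalue of a correlation matrix always exceeds 1, so at least one
  # component is retained by the > 1 rule)
  set.seed(3)
  z6 <- matrix(rnorm(6 * 4000), ncol = 6,
               dimnames = list(NULL, c(paste0("v", 1:5), "housing")))
  p3 <- urbanization_pca(z6)
  expect_lt(max(abs(p3$eigenvalues - 1)), 0.15)
  expect_gte(length(p3$retained), 1)
  # errors
  expect_error(urbanization_pca(xy[1:5, ]), "at least 7")
  bad <- xy; bad[, 2] <- 1
  expect_error(urbanization_pca(bad), "constant")
})

test_that("PCA scores reproduce the correlation-matrix eigendecomposition", {
  set.seed(9)
  x <- matrix(rnorm(300), 50, 6)
  x[, 2] <- x[, 1] * 0.8 + rnorm(50, sd = 0.4)
  colnames(x) <- c("dev1", "dev2", "dev3", "dev4", "pop", "housing")
  p <- urbanization_pca(x)
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  for (k in seq_along(p$retained))
    expect_equal(var(p$scores[, k]), p$eigenvalues[p$retained[k]],
                 tolerance = 1e-10)
  expect_equal(colMeans(p$scores), rep(0, ncol(p$scores)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
})

test_that("assembled metrics are internally consistent and recountable", {
  st <- generate_landscape(extent = 7000, cell_size = 100,
                           urban_strength = 0.6, forest_frac = 0.55, seed = 41)
  d <- place_count_locations(st, 25, seed = 42, margin = 500)
  radii <- c(0.2, 0.5)
  m <- suppressWarnings(suppressMessages(assemble_metrics(st, d, radii)))
  expect_equal(nrow(m), 25 * 2)
  expect_true(all(m$forest >= 0 & m$forest <= 1))
  expect_true(all(m$elev_range >= 0))
  expect_true(all(m$shannon >= 0))
  expect_true(all(m$clumpy >= -1 & m$clumpy <= 1, na.rm = TRUE))
  # independent recount of one row's forest amount
  row <- m[m$radius_km == 0.5, ][4, ]
  loc <- d[d$id == row$location_id, ]
  b <- extract_buffer(st, c(loc$x, loc$y), 500)
  recount <- mean(st$landcover[b$cells] %in% forest_classes())
  expect_equal(row$forest, recount, tolerance = 1e-12)
  # border-overlapping buffers are dropped, not silently kept
  d_edge <- place_count_locations(st, 25, seed = 43)
  m2 <- suppressWarnings(suppressMessages(assemble_metrics(st, d_edge, 2)))
  dropped <- attr(m2, "dropped")
  expect_equal(nrow(m2) + sum(dropped$radius_km == 2), 25)
})

test_that("species-specific forest class sets add suffixed columns", {
  st <- generate_landscape(extent = 5000, cell_size = 100,
                           urban_strength = 0.5, forest_frac = 0.6, seed = 51)
  d <- place_count_locations(st, 12, seed = 52, margin = 300)
  m <- suppressWarnings(suppressMessages(
    assemble_metrics(st, d, 0.2,
                     forest_sets = list(total = forest_classes(),
                                        deciduous = 41L))))
  expect_true(all(c("forest", "forest_deciduous", "clumpy_deciduous") %in%
                    names(m)))
  expect_true(all(m$forest_deciduous <= m$forest + 1e-12))
})
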