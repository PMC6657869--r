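test_that("response preparation computes inverse-variance weights", {
  resp <- data.frame(species_id = c("a", "b"), effect = c(0.1, -0.2),
                     se = c(0.5, 0.05), scale_km = c(1, 2))
  pr <- prepare_responses(resp)
  expect_equal(pr$effect$weight, c(4, 400))
  expect_equal(pr$effect$weight[2] / pr$effect$weight[1], 100)
  resp$se[1] <- 0
  expect_error(prepare_responses(resp), "a")
  # the published per-species table yields 58 finite positive weights
  t1 <- read_table1_fixture()
  w <- 1 / t1$se^2
  expect_equal(length(w), 58)
  expect_true(all(is.finite(w) & w > 0))
})

test_that("univariate screen reproduces closed-form adjusted R-squared", {
  # noise-free proportional response: adjusted R2 = 1
  tr <- 1:10
  s <- suppressWarnings(univariate_screen(tr, 2 * tr + 3))
  expect_equal(s$adj_r2, 1, tolerance = 1e-12)
  expect_true(s$admitted)
  # hand-computable six-point set
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 11.9)
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  expect_equal(univariate_screen(x, y)$adj_r2, 1 - (1 - r2) * 5 / 4,
               tolerance = 1e-12)
  # independent response: adjusted R2 typically non-positive at large n
  set.seed(4)
  neg <- replicate(40, univariate_screen(rnorm(200), rnorm(200))$adj_r2 <= 0.01)
  expect_gt(mean(neg), 0.7)
  expect_false(univariate_screen(rep(1, 10), rnorm(10))$admitted)
  expect_error(univariate_screen(c(1, 2, NA, NA, NA, NA), rnorm(6)), "fewer than 5")
})

test_that("group construction separates screened and complete-trait sets", {
  set.seed(5)
  n <- 40
  traits <- data.frame(
    species_id = sprintf("s%02d", 1:n),
    good = rnorm(n),           # drives the response
    noisy = rnorm(n),          # unrelated
    gappy = rnorm(n))          # unrelated and 20% missing
  traits$gappy[sample(n, 8)] <- NA
  resp <- data.frame(species_id = traits$species_id,
                     value = 0.8 * traits$good + rnorm(n, 0, 0.3))
  g <- build_groups(traits, resp)
  expect_true("good" %in% g$screened$traits)
  expect_true(all(c("good", "noisy") %in% g$complete$traits))
  expect_false("gappy" %in% g$complete$traits)
  # complete-case N of the screened group matches an independent row scan
  scan_n <- sum(stats::complete.cases(traits[, g$screened$traits, drop = FALSE]))
  expect_equal(g$screened$n, scan_n)
  # with no missing data the two groups share the full species set
  traits2 <- traits; traits2$gappy <- rnorm(n)
  g2 <- build_groups(traits2, resp)
  expect_equal(g2$screened$n, n)
  expect_equal(g2$complete$n, n)
})

test_that("correlated trait pairs are flagged and retained", {
  set.seed(6)
  n <- 50
  base <- rnorm(n)
  traits <- data.frame(species_id = sprintf("s%02d", 1:n),
                       t1 = base, t2 = 0.72 * base +
                         sqrt(1 - 0.72^2) * rnorm(n))
  resp <- data.frame(species_id = traits$species_id,
                     value = traits$t1 + rnorm(n, 0, 0.2))
  w <- capture_warnings(g <- build_groups(traits, resp))
  expect_true(any(grepl("0.70", w)))
  expect_true(all(c("t1", "t2") %in% g$complete$traits))
})

test_that("trait model averaging counts parameters like the published tables", {
  set.seed(7)
  n <- 30
  tr <- data.frame(t1 = rnorm(n))
  y <- 0.5 * tr$t1 + rnorm(n, 0, 0.5)
  fit <- trait_model_average(y, tr)
  # a single-trait group has 2 candidate models; the best-model table lists
  # those within delta <= 2
  expect_lte(nrow(fit$table), 2)
  one_trait <- fit$table[fit$table$Model == "t1", ]
  expect_equal(one_trait$K, 3)  # slope + intercept + error SD
  icpt <- fit$table[fit$table$Model == "(intercept only)", ]
  if (nrow(icpt)) expect_equal(icpt$K, 2)
  expect_equal(fit$table$delta[1], 0)
  expect_equal(sum(fit$table$w), 1, tolerance = 1e-12)
  # delta column re-fed to akaike_weights reproduces the weight column
  expect_equal(akaike_weights(fit$table$delta), fit$table$w, tolerance = 1e-12)
})

test_that("equal weights reduce the weighted fit to the unweighted fit", {
  set.seed(8)
  n <- 45
  traits <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 0.6 * traits$a + rnorm(n, 0, 0.4)
  fw <- trait_model_average(y, traits, weights = rep(2.5, n))
  fu <- trait_model_average(y, traits, weights = NULL)
  expect_equal(fw$effects$estimate, fu$effects$estimate, tolerance = 1e-10)
  expect_equal(fw$table$delta, fu$table$delta, tolerance = 1e-10)
})

test_that("cross-group combination reports the larger-magnitude estimate", {
  s <- data.frame(trait = c("a", "b"), estimate = c(0.5, 0.1),
                  se = c(0.1, 0.1), in_best_set = c(TRUE, TRUE))
  c_ <- data.frame(trait = c("a", "c"), estimate = c(-0.8, 0.3),
                   se = c(0.2, 0.1), in_best_set = c(TRUE, TRUE))
  out <- combine_trait_effects(s, c_)
  expect_equal(out$estimate[out$trait == "a"], -0.8)  # larger magnitude wins
  expect_equal(out$group[out$trait == "a"], "complete")
  expect_equal(sort(out$trait), c("a", "b", "c"))
})

test_that("full stage 2 runs end to end on synthetic responses", {
  set.seed(9)
  n <- 50
  g <- generate_traits_and_tree(n, beta_weights = c(granivory = 0.6),
                                beta_noise_sd = 0.1, seed = 10)
  resp <- data.frame(species_id = g$truth$species_id,
                     effect = g$truth$beta_true + rnorm(n, 0, 0.1),
                     se = runif(n, 0.08, 0.2),
                     scale_km = g$truth$s_true)
  fit <- fit_trait_effects(resp, g$traits, "effect",
                           trait_cols = c("clutch_size", "wingspan",
                                          "granivory", "frugivory"))
  expect_s3_class(fit$effects, "TraitEffect")
  gran <- fit$effects[fit$effects$trait == "granivory", ]
  expect_gt(gran$estimate, 0)
})

test_that("PGLS lambda behaves at its boundaries and under independence", {
  # star phylogeny: lambda unidentified, reported 0, estimates equal OLS
  star <- ape::stree(16, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  tv <- setNames(rnorm(16), star$tip.label)
  rv <- setNames(2 + 0.5 * tv + rnorm(16, 0, 0.3), star$tip.label)
  fit <- pgls_lambda(tv, rv, star)
  expect_equal(fit$lambda, 0)
  expect_equal(fit$p, 1)
  ols <- coef(lm(rv ~ tv))
  expect_equal(unname(fit$coef), unname(ols), tolerance = 1e-8)
  # independent data on a real tree: lambda near 0, LRT rarely significant
  set.seed(11)
  tree <- ape::rphylo(60, 1, 0)
  t2 <- setNames(rnorm(60), tree$tip.label)
  r2 <- setNames(rnorm(60), tree$tip.label)
  fit2 <- pgls_lambda(t2, r2, tree)
  expect_lt(fit2$lambda, 0.35)
  expect_error(pgls_lambda(t2[1:3], r2[1:3], tree), "fewer than 5")
})

test_that("PGLS lambda agrees with the nlme/ape oracle on Brownian data", {
  skip_if_not_installed("nlme")
  set.seed(12)
  tree <- ape::rphylo(48, 1, 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  V <- ape::vcv(tree)
  L <- t(chol(V + diag(1e-10, 48)))
  tv <- setNames(rnorm(48), tree$tip.label)
  rv <- setNames(0.4 * tv + as.numeric(L %*% rnorm(48)), tree$tip.label)
  ours <- pgls_lambda(tv, rv, tree)
  dat <- data.frame(tv = tv, rv = rv, species = names(tv))
  ref <- nlme::gls(rv ~ tv, data = dat,
                   correlation = ape::corPagel(0.8, tree, form = ~ species),
                   method = "ML")
  lam_ref <- unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(ours$lambda, lam_ref, tolerance = 0.05)
  expect_equal(unname(ours$coef[2]), unname(coef(ref)[2]), tolerance = 0.05)
})

test_that("the phylogenetic screen summarizes every trait", {
  set.seed(13)
  g <- generate_traits_and_tree(40, lambda_true = 0, seed = 14)
  resp <- setNames(rnorm(40), g$traits$species_id)
  out <- phylo_signal_screen(g$traits, resp, g$tree,
                             trait_cols = c("wingspan", "clutch_size"))
  expect_equal(nrow(out), 2)
  expect_true(all(out$lambda >= 0 & out$lambda <= 1))
})
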