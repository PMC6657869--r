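# default trait roster: continuous traits on plausible field-guide scales,
# binary traits by thresholding a latent evolving on the same tree
.default_traits <- list(
  continuous = c(wingspan = 8, body_mass = 25, clutch_size = 1.2,
                 fledglings = 1, duration_nest = 4, flock_size = 6,
                 lifespan = 3, foraging_height = 4),
  cont_mean = c(wingspan = 25, body_mass = 40, clutch_size = 4.5,
                fledglings = 3, duration_nest = 14, flock_size = 8,
                lifespan = 8, foraging_height = 8),
  binary = c(granivory = 0.35, frugivory = 0.30, omnivory = 0.35,
             cavity_nesting = 0.30, resident = 0.45)
)

# lambda-scaled Brownian covariance: off-diagonal multiplied by lambda
.lambda_vcv <- function(tree, lambda) {
  V <- ape::vcv(tree)
  Vl <- lambda * V
  diag(Vl) <- diag(V)
  Vl
}

#' Generate species traits, a phylogeny and ground-truth responses
#'
#' Simulates a Yule phylogeny, evolves continuous traits under
#' lambda-scaled Brownian motion (Pagel's lambda transform of the Brownian
#' covariance), derives binary traits by thresholding latent Brownian
#' variables at configurable prevalences, and constructs each species' true
#' urbanization coefficient and true scale of effect as linear combinations
#' of the standardized traits plus Gaussian noise. The true scale is snapped
#' (on the log scale) to the nearest radius in `radii`, so scale recovery is
#' a classification task with an exact answer.
#'
#' @param n_species number of tips.
#' @param lambda_true phylogenetic signal in `[0, 1]` for trait evolution.
#' @param beta_weights named vector: per-SD contribution of traits to the
#'   true urbanization coefficient.
#' @param scale_weights named vector: per-SD contribution of traits to the
#'   log true scale of effect.
#' @param beta_mean intercept of the true coefficient (log-odds per SD of
#'   urbanization score).
#' @param beta_noise_sd,scale_noise_sd SD of the Gaussian noise added to the
#'   coefficient and to the log scale.
#' @param radii analysis radii (km) the true scale is snapped to.
#' @param alpha logistic intercept (baseline occurrence log-odds).
#' @param missing_rate per-trait probability that a trait value is set
#'   missing (missing completely at random).
#' @param seed integer seed.
#' @return List with `traits` (data frame, one row per species), `tree`
#'   (`ape::phylo`), and `truth` (`TruthRecord` data frame with columns
#'   species_id, beta_true, s_true, alpha; the weights used are attached as
#'   attributes `beta_weights` / `scale_weights`).
#' @export
generate_traits_and_tree <- function(n_species, lambda_true = 0,
                                     beta_weights = NULL, scale_weights = NULL,
                                     beta_mean = -0.36, beta_noise_sd = 0.1,
                                     scale_noise_sd = 0.3,
                                     radii = c(0.2, 0.5, 1, 2, 4, 6, 8, 10, 12, 16),
                                     alpha = 0, missing_rate = 0, seed = 1) {
  if (lambda_true < 0 || lambda_true > 1)
    stop("lambda_true must be in [0, 1]")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))

  Vl <- .lambda_vcv(tree, lambda_true)
  L <- chol(Vl + diag(1e-10, n_species))
  draw <- function() as.numeric(t(L) %*% rnorm(n_species))

  cont <- .default_traits$continuous
  z <- sapply(names(cont), function(nm) draw())
  rownames(z) <- tree$tip.label
  traits_nat <- sweep(sweep(z, 2, cont, `*`), 2,
                      .default_traits$cont_mean[names(cont)], `+`)
  traits_nat <- pmax(traits_nat, 0.1)

  bin <- .default_traits$binary
  zb <- sapply(names(bin), function(nm) draw())
  binary <- sapply(names(bin), function(nm)
    as.integer(zb[, nm] > quantile(zb[, nm], 1 - bin[[nm]])))
  rownames(binary) <- tree$tip.label

  std <- cbind(apply(z, 2, function(v) as.numeric(scale(v))),
               apply(binary, 2, function(v)
                 if (sd(v) > 0) as.numeric(scale(v)) else v * 0))
  rownames(std) <- tree$tip.label

  lin <- function(w) {
    out <- numeric(n_species)
    for (nm in names(w)) {
      if (!nm %in% colnames(std)) stop("unknown trait in weights: ", nm)
      out <- out + w[[nm]] * std[, nm]
    }
    out
  }
  beta_true <- beta_mean + lin(beta_weights) + rnorm(n_species, 0, beta_noise_sd)
  s_lat <- log(2) + lin(scale_weights) + rnorm(n_species, 0, scale_noise_sd)
  s_true <- radii[apply(abs(outer(s_lat, log(radii), `-`)), 1, which.min)]

  traits <- data.frame(species_id = tree$tip.label, traits_nat, binary,
                       row.names = NULL, check.names = FALSE)
  if (missing_rate > 0) {
    tc <- setdiff(names(traits), "species_id")
    for (nm in tc) {
      miss <- runif(n_species) < missing_rate
      traits[[nm]][miss] <- NA
    }
  }

  truth <- data.frame(species_id = tree$tip.label, beta_true = beta_true,
                      s_true = s_true, alpha = alpha)
  attr(truth, "beta_weights") <- beta_weights
  attr(truth, "scale_weights") <- scale_weights
  class(truth) <- c("TruthRecord", "data.frame")
  list(traits = traits, tree = tree, truth = truth)
}
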