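#' Prepare stage-2 response variables
#'
#' Effect sizes are weighted by their inverse sampling variance
#' (`1 / SE^2`) to account for varying estimate precision; scales of effect
#' are carried unweighted on the km scale.
#'
#' @param responses a `SpeciesResponse` data frame with `species_id`,
#'   `effect`, `se`, `scale_km`.
#' @return List with `effect` (data frame species_id, value, weight) and
#'   `scale` (species_id, value).
#' @export
prepare_responses <- function(responses) {
  if (any(responses$se <= 0))
    stop("non-positive SE for species: ",
         paste(responses$species_id[responses$se <= 0], collapse = ", "))
  list(
    effect = data.frame(species_id = responses$species_id,
                        value = responses$effect,
                        weight = 1 / responses$se^2),
    scale = data.frame(species_id = responses$species_id,
                       value = responses$scale_km)
  )
}

#' Univariate screening regression
#'
#' Weighted simple linear regression of the response on one trait; the
#' trait is admitted to the screened group when the adjusted R-squared,
#' `1 - (1 - R2) * (n - 1) / (n - 2)`, is positive.
#'
#' @param trait numeric trait values (NA allowed).
#' @param response numeric response values.
#' @param weights optional positive weights.
#' @return List with `adj_r2`, `n`, `admitted`.
#' @export
univariate_screen <- function(trait, response, weights = NULL) {
  ok <- !is.na(trait) & !is.na(response)
  if (sum(ok) < 5) stop("fewer than 5 non-missing trait/response pairs")
  tr <- trait[ok]; y <- response[ok]
  w <- if (is.null(weights)) rep(1, sum(ok)) else weights[ok]
  if (sd(tr) == 0)
    return(list(adj_r2 = NA_real_, n = sum(ok), admitted = FALSE,
                reason = "constant trait"))
  fit <- lm(y ~ tr, weights = w)
  r2 <- summary(fit)$r.squared
  n <- sum(ok)
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(adj_r2 = adj, n = n, admitted = adj > 0)
}

#' Build the two stage-2 trait groups
#'
#' Group 1 holds the traits passing the univariate screen (positive
#' adjusted R-squared), analyzed on the complete-case species subset for
#' those traits. Group 2 holds the traits observed for every species,
#' analyzed on all species. Trait pairs with `|r| >= 0.70` are flagged (and
#' kept) in attribute `collinear`.
#'
#' @param traits trait data frame with `species_id`.
#' @param response data frame with `species_id`, `value` (and optional
#'   `weight`), as from [prepare_responses()].
#' @param trait_cols candidate trait columns (default: all but
#'   `species_id`).
#' @param weights optional per-species weights aligned with `response`.
#' @return List of two groups, each with `traits` (character), `data`
#'   (complete-case rows incl. response/weight), `screen` (group 1 only).
#' @export
build_groups <- function(traits, response, trait_cols = NULL, weights = NULL) {
  if (is.null(trait_cols)) trait_cols <- setdiff(names(traits), "species_id")
  dat <- merge(response, traits, by = "species_id", sort = FALSE)
  w <- if ("weight" %in% names(dat)) dat$weight else weights

  screen <- lapply(trait_cols, function(tc)
    tryCatch(univariate_screen(dat[[tc]], dat$value, w),
             error = function(e) list(adj_r2 = NA, n = 0, admitted = FALSE,
                                      reason = conditionMessage(e))))
  names(screen) <- trait_cols
  g1_traits <- trait_cols[vapply(screen, `[[`, logical(1), "admitted")]
  g2_traits <- trait_cols[colSums(is.na(traits[, trait_cols, drop = FALSE])) == 0]
  if (length(g1_traits) == 0) stop("empty screened group: no trait has positive adjusted R2")
  if (length(g2_traits) == 0) stop("empty complete-trait group")

  mk <- function(tc) {
    cc <- stats::complete.cases(dat[, c("value", tc), drop = FALSE])
    d <- dat[cc, , drop = FALSE]
    cr <- if (length(tc) > 1) stats::cor(d[, tc]) else matrix(1, 1, 1)
    hi <- which(abs(cr) >= 0.70 & upper.tri(cr), arr.ind = TRUE)
    coll <- if (length(tc) > 1 && nrow(hi))
      data.frame(trait1 = tc[hi[, 1]], trait2 = tc[hi[, 2]],
                 r = cr[hi], stringsAsFactors = FALSE)
    else NULL
    structure(list(traits = tc, data = d, n = nrow(d)), collinear = coll)
  }
  g1 <- mk(g1_traits); g1$screen <- screen
  g2 <- mk(g2_traits)
  for (g in list(g1, g2))
    if (!is.null(attr(g, "collinear")))
      warning("trait pair(s) with |r| >= 0.70 retained: ",
              paste(attr(g, "collinear")$trait1, attr(g, "collinear")$trait2,
                    sep = "~", collapse = ", "))
  list(screened = g1, complete = g2)
}

#' All-subsets trait model averaging
#'
#' Fits weighted Gaussian linear models for every trait subset (traits
#' partial-SD standardized first, like the stage-1 predictors), ranks them
#' by AIC with `K` counting slope coefficients, the intercept and the error
#' SD (an intercept-only model has K = 2, a one-trait model K = 3), and
#' full-averages each trait's coefficient with its unconditional SE over
#' the delta AIC <= 2 best-model set.
#'
#' @param response numeric response vector.
#' @param traits data frame/matrix of trait values (no missing values).
#' @param weights optional positive observation weights.
#' @param delta_max averaging threshold.
#' @return List with `effects` (a `TraitEffect` data frame: trait,
#'   estimate, se, in_best_set) and `table` (model-selection table:
#'   Model, K, AIC, delta, w over the delta <= `delta_max` set).
#' @export
trait_model_average <- function(response, traits, weights = NULL,
                                delta_max = 2) {
  X <- as.matrix(traits)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) stop("need more species than traits + 2 (n = ", n, ", p = ", p, ")")
  if (anyNA(X)) stop("missing trait values; build groups first")
  sd_ <- standardize(X)
  z <- as.data.frame(sd_$z)
  w <- if (is.null(weights)) rep(1, n) else weights
  terms <- colnames(z)

  n_mod <- 2^p
  fits <- vector("list", n_mod)
  rows <- vector("list", n_mod)
  dat <- cbind(y = response, z)
  for (m in seq_len(n_mod) - 1L) {
    sel <- terms[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0]
    fml <- if (length(sel)) stats::reformulate(sel, "y") else y ~ 1
    fit <- lm(fml, data = dat, weights = w)
    fits[[m + 1L]] <- fit
    rows[[m + 1L]] <- data.frame(
      model = if (length(sel)) paste(sel, collapse = " + ") else "(intercept only)",
      K = length(sel) + 2L, AIC = AIC(fit), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AIC - min(tab$AIC)
  ord <- order(tab$AIC)
  tab <- tab[ord, ]; fits <- fits[ord]
  best <- tab$delta <= delta_max
  bt <- tab[best, ]
  bt$w <- akaike_weights(bt$delta)
  bfits <- fits[best]

  effects <- lapply(terms, function(tr) {
    b <- vapply(bfits, function(f) {
      cf <- coef(f)
      if (tr %in% names(cf)) cf[[tr]] else 0
    }, numeric(1))
    v <- vapply(bfits, function(f) {
      vc <- vcov(f)
      if (tr %in% rownames(vc)) vc[tr, tr] else 0
    }, numeric(1))
    bb <- sum(bt$w * b)
    se <- sum(bt$w * sqrt(v + (b - bb)^2))
    data.frame(trait = tr, estimate = bb, se = se,
               in_best_set = any(b != 0), stringsAsFactors = FALSE)
  })
  effects <- do.call(rbind, effects)
  class(effects) <- c("TraitEffect", "data.frame")
  names(bt) <- c("Model", "K", "AIC", "delta", "w")
  rownames(bt) <- NULL
  list(effects = effects, table = bt)
}

#' Combine trait effects across the two groups
#'
#' When a trait appears in the best-model sets of both groups, the final
#' reported effect is the larger-magnitude of the two model-averaged
#' coefficients.
#'
#' @param screened,complete `effects` tables from [trait_model_average()]
#'   for the screened and complete-trait groups.
#' @return A `TraitEffect` data frame with `group` marking the origin of
#'   each final estimate.
#' @export
combine_trait_effects <- function(screened, complete) {
  all_tr <- union(screened$trait[screened$in_best_set],
                  complete$trait[complete$in_best_set])
  rows <- lapply(all_tr, function(tr) {
    s <- screened[screened$trait == tr & screened$in_best_set, ]
    c_ <- complete[complete$trait == tr & complete$in_best_set, ]
    if (nrow(s) && nrow(c_)) {
      pick <- if (abs(s$estimate) >= abs(c_$estimate)) cbind(s, group = "screened")
              else cbind(c_, group = "complete")
    } else if (nrow(s)) pick <- cbind(s, group = "screened")
    else pick <- cbind(c_, group = "complete")
    pick
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("TraitEffect", "data.frame")
  out
}

#' Stage 2: trait effects on effect sizes and scales of effect
#'
#' Runs the full second stage for one response (effect size, inverse-
#' variance weighted, or scale of effect, unweighted): univariate screen,
#' group construction, all-subsets AIC averaging in both groups, and
#' cross-group combination.
#'
#' @param responses a `SpeciesResponse` table.
#' @param traits trait data frame with `species_id`.
#' @param response which response to model.
#' @param trait_cols candidate trait columns.
#' @param delta_max averaging threshold.
#' @return List with `groups`, per-group `fits`, and combined `effects`.
#' @export
fit_trait_effects <- function(responses, traits,
                              response = c("effect", "scale"),
                              trait_cols = NULL, delta_max = 2) {
  response <- match.arg(response)
  prep <- prepare_responses(responses)
  resp <- prep[[response]]
  groups <- build_groups(traits, resp, trait_cols = trait_cols)
  fits <- lapply(groups, function(g) {
    w <- if ("weight" %in% names(g$data)) g$data$weight else NULL
    trait_model_average(g$data$value, g$data[, g$traits, drop = FALSE],
                        weights = w, delta_max = delta_max)
  })
  effects <- combine_trait_effects(fits$screened$effects, fits$complete$effects)
  list(groups = groups, fits = fits, effects = effects)
}
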