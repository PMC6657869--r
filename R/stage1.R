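#' Partial standard deviation of a predictor
#'
#' `s*_j = s_j * sqrt(1 / VIF_j) * sqrt((n - 1) / (n - p))`, where `VIF_j =
#' 1 / (1 - R2_j)` comes from regressing column `j` on all other predictors.
#' Dividing predictors by their partial SDs makes standardized coefficients
#' comparable when averaging across models that hold different predictor
#' subsets.
#'
#' @param x numeric predictor matrix (n x p).
#' @param j column index or name.
#' @return List with `psd`, `sd`, `vif`.
#' @export
partial_sd <- function(x, j) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1) stop("need n > p + 1 for partial standard deviations")
  if (is.character(j)) j <- match(j, colnames(x))
  s <- sd(x[, j])
  if (s == 0) stop("constant column: ", colnames(x)[j] %||% j)
  if (p == 1) {
    vif <- 1
  } else {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / ((n - 1) * s^2)
    if (r2 > 1 - 1e-10) {
      partners <- colnames(x)[-j][which.max(abs(stats::cor(x[, -j, drop = FALSE],
                                                           x[, j])))]
      stop("perfect collinearity between '", colnames(x)[j] %||% j,
           "' and '", partners %||% "another predictor", "'")
    }
    vif <- 1 / (1 - r2)
  }
  list(psd = s * sqrt(1 / vif) * sqrt((n - 1) / (n - p)), sd = s, vif = vif)
}

#' Standardize a design matrix by partial SDs
#'
#' Divides each column by its partial standard deviation, then centers and
#' scales to unit variance, storing all transformation parameters so the
#' transform can be inverted. Pairwise predictor correlations with absolute
#' value at or above `cor_warn` trigger a collinearity warning (predictors
#' are kept).
#'
#' @param x numeric predictor matrix with column names.
#' @param cor_warn collinearity warning threshold on |r|.
#' @return A `StandardizedDesign`: list with `z` (standardized matrix),
#'   `psd`, `vif`, `center`, `scale`, `n`, `p`.
#' @export
standardize <- function(x, cor_warn = 0.70) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (p > 1) {
    cr <- stats::cor(x)
    hi <- which(abs(cr) >= cor_warn & upper.tri(cr), arr.ind = TRUE)
    if (nrow(hi))
      warning("predictor correlation |r| >= ", cor_warn, ": ",
              paste(colnames(x)[hi[, 1]], colnames(x)[hi[, 2]],
                    sep = "~", collapse = ", "))
  }
  info <- lapply(seq_len(p), function(j) partial_sd(x, j))
  psd <- vapply(info, `[[`, numeric(1), "psd")
  vif <- vapply(info, `[[`, numeric(1), "vif")
  xs <- sweep(x, 2, psd, `/`)
  ctr <- colMeans(xs)
  scl <- apply(xs, 2, sd)
  z <- sweep(sweep(xs, 2, ctr, `-`), 2, scl, `/`)
  structure(list(z = z, psd = setNames(psd, colnames(x)),
                 vif = setNames(vif, colnames(x)),
                 center = ctr, scale = scl, n = nrow(x), p = p),
            class = "StandardizedDesign")
}

#' Invert a standardization
#' @param sd_obj a `StandardizedDesign`.
#' @param z standardized matrix (defaults to the stored one).
#' @return The original-scale matrix.
#' @export
unstandardize <- function(sd_obj, z = sd_obj$z) {
  xs <- sweep(sweep(z, 2, sd_obj$scale, `*`), 2, sd_obj$center, `+`)
  sweep(xs, 2, sd_obj$psd, `*`)
}

#' Maximum-likelihood logistic regression
#'
#' Thin wrapper around iteratively reweighted least squares
#' (`stats::glm.fit`) returning coefficients, their covariance, the
#' log-likelihood and `AIC = -2 * logLik + 2 * K` with `K` counting the
#' intercept and slope coefficients. Complete separation (non-convergence or
#' divergent coefficients) is flagged rather than silently returned, so the
#' model can be excluded from candidate sets.
#'
#' @param y 0/1 response with both classes present.
#' @param x predictor matrix (may have zero columns for the intercept-only
#'   model).
#' @return List with `coef`, `vcov`, `logLik`, `aic`, `k`, `separation`.
#' @export
fit_logistic <- function(y, x = NULL) {
  if (length(unique(y)) < 2) stop("response has a single class")
  X <- if (is.null(x) || NCOL(x) == 0) matrix(1, length(y), 1)
       else cbind(`(Intercept)` = 1, as.matrix(x))
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)",
                     if (ncol(X) > 1) paste0("x", seq_len(ncol(X) - 1)))
  colnames(X)[1] <- "(Intercept)"
  if (length(y) <= ncol(X)) stop("need n > number of coefficients")
  fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  ll <- sum(dbinom(y, 1, mu, log = TRUE))
  k <- ncol(X)
  w <- mu * (1 - mu)
  xtwx <- crossprod(X * sqrt(w))
  vc <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
  sep <- !fit$converged || max(abs(fit$coefficients)) > 15 || is.null(vc)
  if (!is.null(vc)) dimnames(vc) <- list(colnames(X), colnames(X))
  list(coef = setNames(fit$coefficients, colnames(X)), vcov = vc,
       logLik = ll, aic = -2 * ll + 2 * k, k = k, separation = sep)
}

#' All-subsets logistic candidate models
#'
#' Fits every subset of the standardized predictors (including the
#' intercept-only model) and records, for each candidate, its AIC, delta,
#' Akaike weight over the retained set, and the urbanization coefficient
#' and its sampling variance (0 when the term is absent, as full model
#' averaging requires). Models with complete separation are excluded from
#' the candidate set.
#'
#' @param y 0/1 response.
#' @param sdesign a `StandardizedDesign` (or plain matrix).
#' @param urb_col name of the urbanization-score column.
#' @param cap maximum number of predictors (2^p models are fitted).
#' @return A `CandidateModel` data frame sorted by AIC: columns `model`,
#'   `K`, `AIC`, `delta`, `w`, `beta_urb`, `var_urb`. Excluded models are
#'   listed in attribute `excluded`.
#' @export
all_subsets <- function(y, sdesign, urb_col = "urb", cap = 15) {
  z <- if (inherits(sdesign, "StandardizedDesign")) sdesign$z else as.matrix(sdesign)
  p <- ncol(z)
  if (p > cap)
    stop("p = ", p, " exceeds the subset cap (", cap,
         "); reduce predictors or raise `cap`")
  terms <- colnames(z)
  n_mod <- 2^p
  rows <- vector("list", n_mod)
  excluded <- character(0)
  for (m in seq_len(n_mod) - 1L) {
    sel <- terms[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0]
    fit <- fit_logistic(y, z[, sel, drop = FALSE])
    label <- if (length(sel)) paste(sel, collapse = " + ") else "(intercept only)"
    if (fit$separation) {
      excluded <- c(excluded, label)
      next
    }
    has_urb <- urb_col %in% sel
    rows[[m + 1L]] <- data.frame(
      model = label, K = fit$k, AIC = fit$aic,
      beta_urb = if (has_urb) fit$coef[[urb_col]] else 0,
      var_urb = if (has_urb) fit$vcov[urb_col, urb_col] else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop("all candidate models were separated")
  out <- out[order(out$AIC), ]
  out$delta <- out$AIC - min(out$AIC)
  out$w <- akaike_weights(out$delta)
  rownames(out) <- NULL
  out <- out[, c("model", "K", "AIC", "delta", "w", "beta_urb", "var_urb")]
  attr(out, "excluded") <- excluded
  class(out) <- c("CandidateModel", "data.frame")
  out
}

#' Akaike weights from AIC differences
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` over the supplied
#' candidate set.
#'
#' @param delta non-negative AIC differences (min must be 0).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(delta) {
  if (length(delta) == 0) stop("empty candidate set")
  if (any(delta < 0)) stop("negative delta")
  u <- exp(-delta / 2)
  u / sum(u)
}

# single local maximum in the weighted kernel density of the coefficient
# values (Gaussian kernel, Silverman bandwidth); sets of <= 2 models are
# unimodal by definition, as are sets whose total spread lies within the
# within-model sampling noise (mode counting on sub-noise wiggles would
# flag estimates that differ only by sampling error)
.is_unimodal <- function(beta, w, sampling_sd = 0) {
  if (length(beta) <= 2) return(TRUE)
  if (sd(beta) == 0) return(TRUE)
  if (diff(range(beta)) <= 2 * sampling_sd) return(TRUE)
  d <- suppressWarnings(stats::density(beta, weights = w / sum(w), bw = "nrd0"))
  y <- d$y
  n_max <- sum(diff(sign(diff(y))) == -2)
  n_max <= 1
}

#' Full model averaging over the delta <= 2 candidate set
#'
#' Renormalizes Akaike weights over candidates with `delta <= delta_max`,
#' averages the urbanization coefficient over that set with the coefficient
#' set to 0 in models lacking the term (full averaging), and reports the
#' unconditional standard error
#' `sum(w_i * sqrt(var_i + (beta_i - beta_bar)^2))`, which adds
#' between-model spread to within-model sampling variance. A unimodality
#' flag on the candidate coefficients is attached; non-unimodal
#' (species, radius) cases are excluded downstream.
#'
#' @param candidates a `CandidateModel` table.
#' @param delta_max inclusion threshold on delta.
#' @return List with `beta`, `se`, `unimodal`, `n_models`, `weights`.
#' @export
model_average <- function(candidates, delta_max = 2) {
  keep <- candidates[candidates$delta <= delta_max, , drop = FALSE]
  w <- akaike_weights(keep$delta)
  beta_bar <- sum(w * keep$beta_urb)
  se <- sum(w * sqrt(keep$var_urb + (keep$beta_urb - beta_bar)^2))
  # unimodality is a property of the estimates from models that contain the
  # term; the structural zeros of term-free models are not estimates
  has_term <- keep$var_urb > 0
  noise <- if (any(has_term)) sqrt(max(keep$var_urb[has_term])) else 0
  list(beta = beta_bar, se = se,
       unimodal = .is_unimodal(keep$beta_urb[has_term], w[has_term],
                               sampling_sd = noise),
       n_models = nrow(keep), weights = w)
}

#' Scale of effect from per-radius averaged coefficients
#'
#' The scale of effect is the radius at which the model-averaged
#' urbanization coefficient has the largest absolute value, among radii with
#' unimodal candidate sets; ties go to the smallest radius.
#'
#' @param per_radius data frame with columns `radius_km`, `beta`, `se`,
#'   `unimodal`.
#' @return List with `scale_km`, `beta`, `se`, or `NULL` when every radius
#'   is excluded as non-unimodal.
#' @export
scale_of_effect <- function(per_radius) {
  ok <- per_radius[!is.na(per_radius$beta) & per_radius$unimodal, , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  ok <- ok[order(ok$radius_km), ]
  i <- which.max(abs(ok$beta))  # which.max takes the first: smallest radius on ties
  list(scale_km = ok$radius_km[i], beta = ok$beta[i], se = ok$se[i])
}

#' Stage 1: species responses to urbanization across scales
#'
#' For each species and radius: builds the predictor matrix from the metric
#' table, standardizes it by partial SDs, fits all predictor subsets,
#' averages the urbanization coefficient over the delta AIC <= 2 set, and
#' finally selects each species' scale of effect.
#'
#' @param detections a `DetectionTable`.
#' @param metrics a `MetricVector` table.
#' @param predictors metric columns used as candidate predictors (must
#'   include `urb_col`).
#' @param urb_col urbanization-score column.
#' @param radii radii to analyze (default: all in `metrics`).
#' @param delta_max averaging threshold.
#' @param cap subset cap passed to [all_subsets()].
#' @return A `SpeciesResponse` data frame: one row per species with
#'   `species_id`, `n`, `effect`, `se`, `scale_km`; the per-radius table is
#'   in attribute `per_radius`, dropped species in attribute `dropped`.
#' @export
fit_species_responses <- function(detections, metrics,
                                  predictors = c("urb", "forest", "agri",
                                                 "elev_mean"),
                                  urb_col = "urb", radii = NULL,
                                  delta_max = 2, cap = 15) {
  if (is.null(radii)) radii <- sort(unique(metrics$radius_km))
  stopifnot(urb_col %in% predictors)
  sp <- unique(detections$species_id)
  per_radius_all <- list()
  rows <- list()
  dropped <- character(0)
  for (s in sp) {
    det <- detections[detections$species_id == s, ]
    pr <- lapply(radii, function(r) {
      m <- metrics[metrics$radius_km == r, , drop = FALSE]
      y <- det$detected[match(m$location_id, det$location_id)]
      ok <- !is.na(y) & stats::complete.cases(m[, predictors, drop = FALSE])
      m <- m[ok, , drop = FALSE]; y <- y[ok]
      if (length(unique(y)) < 2 || nrow(m) <= length(predictors) + 1)
        return(data.frame(radius_km = r, beta = NA_real_, se = NA_real_,
                          unimodal = NA, n = nrow(m)))
      sd_ <- standardize(as.matrix(m[, predictors, drop = FALSE]))
      cand <- all_subsets(y, sd_, urb_col = urb_col, cap = cap)
      avg <- model_average(cand, delta_max = delta_max)
      data.frame(radius_km = r, beta = avg$beta, se = avg$se,
                 unimodal = avg$unimodal, n = length(y))
    })
    pr <- do.call(rbind, pr)
    pr$species_id <- s
    per_radius_all[[s]] <- pr
    sel <- scale_of_effect(pr)
    if (is.null(sel)) {
      dropped <- c(dropped, s)
      next
    }
    rows[[s]] <- data.frame(species_id = s,
                            n = pr$n[pr$radius_km == sel$scale_km],
                            effect = sel$beta, se = sel$se,
                            scale_km = sel$scale_km,
                            stringsAsFactors = FALSE)
  }
  if (length(dropped))
    message("species dropped (no unimodal radius): ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_radius") <- do.call(rbind, per_radius_all)
  attr(out, "dropped") <- dropped
  class(out) <- c("SpeciesResponse", "data.frame")
  out
}
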