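# profile log-likelihood of a GLS regression under Sigma = sigma2 * V
.gls_loglik <- function(y, X, V) {
  n <- length(y)
  ch <- chol(V)
  logdet <- 2 * sum(log(diag(ch)))
  Li <- backsolve(ch, diag(n), transpose = TRUE)  # Li %*% t(Li) = V^-1 (via L')
  yt <- Li %*% y
  Xt <- Li %*% X
  fit <- stats::lm.fit(Xt, yt)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(logLik = ll, coef = fit$coefficients, sigma2 = sigma2)
}

#' Univariate PGLS with Pagel's lambda
#'
#' Generalized least-squares regression of a response on one trait under
#' the phylogenetic covariance `V(lambda)`, equal to the Brownian-motion
#' covariance with off-diagonal entries multiplied by `lambda` (diagonal
#' unchanged). `lambda` is estimated by maximum likelihood on `[0, 1]` and
#' tested against `lambda = 0` with a likelihood-ratio test whose
#' chi-squared(1) p-value is halved because 0 lies on the boundary of the
#' parameter space. On a star phylogeny `V(lambda)` is diagonal for every
#' `lambda`, the estimates equal ordinary least squares and `lambda` is
#' unidentified (reported as 0).
#'
#' @param trait numeric trait values named by tip label (NA dropped).
#' @param response numeric response values named by tip label.
#' @param tree an `ape::phylo` with branch lengths.
#' @return A `PhyloSignalResult`: list with `lambda`, `logLik`,
#'   `logLik0`, `LR`, `p`, `coef`, `n`.
#' @export
pgls_lambda <- function(trait, response, tree) {
  sp <- intersect(names(trait)[!is.na(trait)], names(response)[!is.na(response)])
  sp <- intersect(sp, tree$tip.label)
  if (length(sp) < 5) stop("fewer than 5 usable tips")
  tr <- ape::keep.tip(tree, sp)
  V <- ape::vcv(tr)[sp, sp]
  y <- response[sp]
  X <- cbind(1, trait[sp])

  star <- max(abs(V[upper.tri(V)])) < 1e-12 * max(diag(V))
  mk <- function(lambda) {
    Vl <- lambda * V
    diag(Vl) <- diag(V)
    Vl
  }
  ll0 <- .gls_loglik(y, X, mk(0))
  if (star) {
    res <- structure(list(lambda = 0, logLik = ll0$logLik, logLik0 = ll0$logLik,
                          LR = 0, p = 1, coef = ll0$coef, n = length(sp),
                          note = "star phylogeny: lambda unidentified"),
                     class = "PhyloSignalResult")
    return(res)
  }
  f <- function(l) .gls_loglik(y, X, mk(l))$logLik
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
  # the optimum may sit at either boundary; check both ends explicitly
  cands <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll0$logLik, f(1))
  best <- which.max(lls)
  lambda <- cands[best]
  llb <- .gls_loglik(y, X, mk(lambda))
  LR <- max(0, 2 * (llb$logLik - ll0$logLik))
  p <- if (LR == 0) 1 else 0.5 * pchisq(LR, df = 1, lower.tail = FALSE)
  structure(list(lambda = lambda, logLik = llb$logLik, logLik0 = ll0$logLik,
                 LR = LR, p = p, coef = llb$coef, n = length(sp)),
            class = "PhyloSignalResult")
}

#' @export
print.PhyloSignalResult <- function(x, ...) {
  cat("Pagel's lambda =", round(x$lambda, 3),
      " LR =", round(x$LR, 3), " p =", signif(x$p, 3), " n =", x$n, "\n")
  invisible(x)
}

#' Phylogenetic-signal screen over a trait table
#'
#' Runs [pgls_lambda()] for every trait against one response and reports
#' whether any trait shows lambda significantly greater than 0 (in which
#' case stage 2 should be interpreted with care; the pipeline warns and
#' proceeds non-phylogenetically either way).
#'
#' @param traits trait data frame with `species_id`.
#' @param response named numeric vector (names are species ids).
#' @param tree an `ape::phylo`.
#' @param trait_cols trait columns to screen.
#' @param alpha significance level.
#' @return Data frame: trait, lambda, LR, p, n, significant.
#' @export
phylo_signal_screen <- function(traits, response, tree, trait_cols = NULL,
                                alpha = 0.05) {
  if (is.null(trait_cols)) trait_cols <- setdiff(names(traits), "species_id")
  rows <- lapply(trait_cols, function(tc) {
    tv <- setNames(traits[[tc]], traits$species_id)
    res <- tryCatch(pgls_lambda(tv, response, tree), error = function(e) NULL)
    if (is.null(res))
      return(data.frame(trait = tc, lambda = NA, LR = NA, p = NA, n = NA,
                        significant = NA))
    data.frame(trait = tc, lambda = res$lambda, LR = res$LR, p = res$p,
               n = res$n, significant = res$p < alpha)
  })
  out <- do.call(rbind, rows)
  if (any(out$significant %in% TRUE))
    warning("phylogenetic signal detected for: ",
            paste(out$trait[out$significant %in% TRUE], collapse = ", "),
            "; stage 2 proceeds non-phylogenetically")
  out
}
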