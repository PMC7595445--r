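#' Ridge-penalized multinomial logistic regression
#'
#' Fits a multinomial logistic model by Newton-Raphson on the penalized
#' log-likelihood. The ridge penalty (`lambda/2 * sum(slopes^2)`) is applied
#' to slope coefficients only, never to intercepts, so the fit stays bounded
#' under perfect separation (the typical situation at inversion-diagnostic
#' SNPs) while class base rates remain unshrunken.
#'
#' @param x numeric predictor matrix (one row per observation, no intercept
#'   column; the intercept is added internally).
#' @param y response: integer/factor with `G >= 2` observed classes.
#' @param lambda ridge penalty on slopes; default `1e-3`.
#' @param init_intercepts optional numeric vector of length `G` of initial
#'   intercepts on the log-probability scale (e.g. log class frequencies);
#'   slopes always start at zero.
#' @return list with `coefficients` ((1+ncol(x)) x (G-1) matrix, baseline =
#'   last class), `penalized_loglik`, `loglik`, `classes` (class values in
#'   model order), `converged`, `iterations`.
#' @keywords internal
fit_multinom_ridge <- function(x, y, lambda = 1e-3, init_intercepts = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  classes <- sort(unique(y))
  G <- length(classes)
  if (G < 2) {
    abort("multinomial fit requires at least 2 observed classes")
  }
  yi <- match(y, classes) - 1L
  X <- cbind(1, x)
  penalize <- c(0, rep(1, ncol(x)))
  init <- matrix(0, nrow = ncol(X), ncol = G - 1L)
  if (!is.null(init_intercepts)) {
    stopifnot(length(init_intercepts) == G)
    init[1, ] <- init_intercepts[-G] - init_intercepts[G]
  } else {
    freq <- tabulate(yi + 1L, nbins = G) / length(yi)
    init[1, ] <- log(pmax(freq[-G], 1e-12)) - log(pmax(freq[G], 1e-12))
  }
  fit <- .multinom_ridge_cpp(X, yi, G, lambda, penalize, init)
  fit$classes <- classes
  fit
}

#' Likelihood-ratio test of a multinomial model against intercept-only
#'
#' The null model (intercepts only, no penalty applies since there are no
#' slopes) has the closed-form maximum `sum(n_g * log(n_g / n))`. The
#' statistic compares penalized log-likelihoods of the nested models under
#' the same `lambda`, and is clamped at zero (the penalized full-model
#' optimum can fall a hair below the null under heavy shrinkage).
#'
#' @inheritParams fit_multinom_ridge
#' @param df chi-square degrees of freedom.
#' @return list with `statistic`, `df`, `p_value` (floored at 1e-300).
#' @keywords internal
multinom_lrt <- function(x, y, df, lambda = 1e-3, init_intercepts = NULL) {
  fit <- fit_multinom_ridge(x, y, lambda = lambda,
                            init_intercepts = init_intercepts)
  counts <- table(y)
  ll_null <- sum(counts * log(counts / length(y)))
  stat <- max(0, 2 * (fit$penalized_loglik - ll_null))
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = max(p, 1e-300),
       converged = fit$converged)
}
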