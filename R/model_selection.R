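# Per-feature AIC comparison of the five component-specific regression
# models and the winning-model rule (lowest AIC wins only if it beats the
# runner-up by more than 2).

#' Gaussian-likelihood AIC from a residual sum of squares
#'
#' `AIC = n * ln(rss / n) + 2 * (k + 1)`: the Gaussian maximum-likelihood
#' form with the error variance counted as a parameter and constant terms
#' omitted (only AIC differences are ever used).
#'
#' @param rss Residual sum of squares (> 0; a perfect fit is degenerate).
#' @param n Number of observations.
#' @param k Number of regression parameters (1 <= k < n).
#' @return The AIC value (vectorised over `rss` and `k`).
#' @export
gaussian_aic <- function(rss, n, k) {
  if (any(rss <= 0)) {
    abort("rss must be positive (a perfect fit has no finite Gaussian AIC)")
  }
  if (any(k < 1) || any(n <= k)) abort("need n > k >= 1")
  n * log(rss / n) + 2 * (k + 1)
}

#' Winning-model rule over per-feature AIC values
#'
#' The component whose model has the lowest AIC is the winner only if the
#' second-lowest AIC exceeds it by more than `threshold` (default 2);
#' otherwise the winner is `"none"`. Exact ties give `delta = 0` and
#' therefore no winner.
#'
#' @param aics Numeric matrix, features x 5 models, columns named after the
#'   components.
#' @param threshold AIC margin the winner must clear (default 2).
#' @return An `aic_table` tibble: `feature` (if rownames present), the five
#'   AIC columns, `winner` and `delta` (second-lowest minus lowest AIC).
#' @export
winning_component <- function(aics, threshold = 2) {
  aics <- as.matrix(aics)
  if (ncol(aics) != 5) abort("aics must have five columns (one per component)")
  if (is.null(colnames(aics))) colnames(aics) <- mets_components()
  n_finite <- rowSums(is.finite(aics))
  if (any(n_finite < 2)) {
    abort("each feature needs at least two finite AIC values")
  }
  winner <- character(nrow(aics))
  delta <- numeric(nrow(aics))
  for (i in seq_len(nrow(aics))) {
    a <- aics[i, ]
    ord <- order(a)
    delta[i] <- a[ord[2]] - a[ord[1]]
    winner[i] <- if (delta[i] > threshold) colnames(aics)[ord[1]] else "none"
  }
  out <- dplyr::bind_cols(
    if (!is.null(rownames(aics))) tibble::tibble(feature = rownames(aics)) else NULL,
    tibble::as_tibble(aics)
  )
  out$winner <- winner
  out$delta <- delta
  class(out) <- c("aic_table", class(out))
  out
}

#' AIC winning-model map over all morphology features
#'
#' Fits, for every feature, the five single-component regression models and
#' applies the winning-model rule. In the default `"full"` mode each model is
#' `feature ~ component + covariates`, so the five AICs share a common
#' dependent variable and are strictly comparable. The `"two_step"` mode
#' instead scores the step-2 models of the unique-effect procedure (step-1
#' residual ~ component + covariates); its dependent variable differs across
#' models, which is surfaced in the methods vignette.
#'
#' @inheritParams unique_effect_scan
#' @param mode `"full"` (default) or `"two_step"`.
#' @param threshold Winning-model AIC margin (default 2).
#' @return An `aic_table` tibble: feature metadata, the five AIC values,
#'   `winner` and `delta`.
#' @export
winner_map <- function(data, morph, features,
                       covariates = mets_covariates(),
                       mode = c("full", "two_step"),
                       threshold = 2,
                       hypertension = c("binary", "sbp")) {
  mode <- match.arg(mode)
  hypertension <- match.arg(hypertension)
  data <- .drop_unevaluable(data)
  ali <- .align_scan_inputs(data, morph, features)
  data <- ali$data
  Y <- ali$Y
  n <- nrow(data)
  cov_design <- build_design(data, covariates, intercept = TRUE)
  comps <- mets_components()

  aics <- matrix(NA_real_, nrow(features), 5,
                 dimnames = list(features$feature, comps))
  for (cc in comps) {
    x <- component_predictor(data, cc, hypertension)
    if (mode == "full") {
      X <- cbind(component = x, cov_design)
      dep <- Y
    } else {
      others <- setdiff(comps, cc)
      X1 <- cbind(
        `(Intercept)` = 1,
        vapply(others, function(o) component_predictor(data, o, hypertension),
               numeric(n))
      )
      dep <- residualize(Y, X1)
      X <- cbind(component = x, cov_design)
    }
    stats <- .ols_scan(dep, X, term = 1L)
    aics[, cc] <- gaussian_aic(stats$rss, n, stats$k)
  }
  out <- winning_component(aics, threshold = threshold)
  out <- dplyr::bind_cols(
    features[c("feature", "measure_kind", "region", "hemisphere")],
    out[setdiff(names(out), "feature")]
  )
  class(out) <- c("aic_table", class(out))
  attr(out, "mode") <- mode
  attr(out, "threshold") <- threshold
  attr(out, "n") <- n
  out
}
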