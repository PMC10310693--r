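# PLS brain-age prediction: feature selection from the association scans,
# cross-validated SIMPLS age regression, age-bias-corrected brain-age gaps,
# and application of the frozen model to external (disease) cohorts.

# SIMPLS (de Jong 1993) for a univariate response. X must be column-centered
# (typically standardized), y centered. Returns the cumulative coefficient
# path B[, a] mapping X to y using the first a latent components; at
# a = rank(X) the coefficients coincide with OLS.
.simpls <- function(X, y, ncomp) {
  p <- ncol(X)
  S <- crossprod(X, y)
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t <- X %*% r
    normt <- sqrt(sum(t^2))
    if (!is.finite(normt) || normt < 1e-12) break
    t <- t / normt
    r <- r / normt
    pv <- crossprod(X, t)
    Q[a] <- drop(crossprod(y, t))
    v <- pv
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    V[, a] <- v
    a_used <- a
  }
  B <- matrix(0, p, max(a_used, 1L))
  acc <- numeric(p)
  for (a in seq_len(a_used)) {
    acc <- acc + R[, a] * Q[a]
    B[, a] <- acc
  }
  list(coef_path = B, ncomp = a_used)
}

.standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  list(center = ctr, scale = scl)
}

.standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

# Inner K-fold CV RMSE path over 1..ncomp_max components (used to pick the
# number of latent components without touching held-out data).
.pls_cv_rmse <- function(X, y, ncomp_max, folds = 5, seed = 1) {
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  sse <- numeric(ncomp_max)
  for (k in seq_len(folds)) {
    tr <- fold != k
    std <- .standardize_fit(X[tr, , drop = FALSE])
    std$scale <- pmax(std$scale, 1e-12)
    Xtr <- .standardize_apply(X[tr, , drop = FALSE], std)
    Xte <- .standardize_apply(X[!tr, , drop = FALSE], std)
    mu <- mean(y[tr])
    fit <- .simpls(Xtr, y[tr] - mu, ncomp_max)
    a_max <- fit$ncomp
    pred <- mu + Xte %*% fit$coef_path   # n_te x a_used
    err2 <- (pred - y[!tr])^2
    path <- colSums(err2)
    if (a_max < ncomp_max) path <- c(path, rep(path[a_max], ncomp_max - a_max))
    sse <- sse + path
  }
  sqrt(sse / n)
}

#' Select MetS-associated features for the brain-age model
#'
#' The union of features significant (after correction) in at least one of
#' the supplied association scans, in the feature order of the first scan.
#'
#' @param scans A list of `mets_assoc` results (typically the five
#'   unique-effect scans), or a single result.
#' @return Character vector of feature ids.
#' @export
select_features <- function(scans) {
  if (inherits(scans, "mets_assoc")) scans <- list(scans)
  sig <- unique(unlist(lapply(scans, function(s) s$feature[s$significant])))
  keep <- scans[[1]]$feature[scans[[1]]$feature %in% sig]
  if (length(keep) == 0) {
    abort(paste0(
      "no feature is significant in any scan; ",
      "consider a larger sample or a less stringent level"
    ))
  }
  keep
}

#' Fit the PLS brain-age model with K-fold cross-validation
#'
#' Chronological age is regressed on the standardized morphology features by
#' SIMPLS partial least squares. Features are z-scored with training-fold
#' statistics inside each fold (no leakage); out-of-fold predictions give the
#' reported fit metrics and the raw brain-age gaps; the age-bias line (raw
#' gap regressed on age, out-of-fold) is stored in the model; the deployable
#' model is refit on all data.
#'
#' @param data Participant tibble with `id` and `age`.
#' @param morph Wide morphology tibble.
#' @param feature_ids Features to use (e.g. from [select_features()]);
#'   default all morphology columns.
#' @param folds Number of CV folds (default 10).
#' @param ncomp Number of latent components; `NULL` (default) selects it by
#'   inner 5-fold CV minimizing RMSE over `1..min(max_ncomp, p, n)`.
#' @param max_ncomp Upper bound of the component search (default 30).
#' @param seed Seed fixing fold assignment and the inner CV split.
#' @return A list of class `pls_age_fit`: `model` (`pls_age_model`),
#'   `result` (per-participant tibble with `brain_age`, `gap_raw`,
#'   `gap_corrected`, `fold`), `metrics` (one-row tibble with out-of-fold
#'   `r`, `rmse`, `mae` and their in-sample counterparts).
#' @export
fit_pls_age <- function(data, morph, feature_ids = NULL, folds = 10,
                        ncomp = NULL, max_ncomp = 30, seed = 1) {
  check_columns(data, c("id", "age"))
  feature_ids <- feature_ids %||% setdiff(names(morph), "id")
  morph <- morph[match(data$id, morph$id), , drop = FALSE]
  X <- morph_matrix(morph, feature_ids)
  y <- data$age
  n <- nrow(X)
  if (n < folds * 2) abort("need at least 2 participants per fold")

  const <- apply(X, 2, sd) < 1e-12
  if (any(const)) {
    warn(sprintf("dropping %d constant feature(s)", sum(const)))
    X <- X[, !const, drop = FALSE]
    feature_ids <- feature_ids[!const]
  }
  p <- ncol(X)
  cap <- min(max_ncomp, p, n - ceiling(n / folds) - 1)
  if (!is.null(ncomp)) {
    if (ncomp < 1 || ncomp > min(p, n - 1)) {
      abort("ncomp must lie in 1..min(feature count, n - 1)")
    }
  }

  set.seed(stage_seed(seed, "folds"))
  fold <- sample(rep(seq_len(folds), length.out = n))
  oof <- numeric(n)
  per_fold_ncomp <- integer(folds)
  for (k in seq_len(folds)) {
    tr <- fold != k
    std <- .standardize_fit(X[tr, , drop = FALSE])
    std$scale <- pmax(std$scale, 1e-12)
    Xtr <- .standardize_apply(X[tr, , drop = FALSE], std)
    Xte <- .standardize_apply(X[!tr, , drop = FALSE], std)
    mu <- mean(y[tr])
    nc <- ncomp
    if (is.null(nc)) {
      rmse_path <- .pls_cv_rmse(X[tr, , drop = FALSE], y[tr], cap,
                                seed = stage_seed(seed, "folds") + 7L + k)
      nc <- which.min(rmse_path)
    }
    fit <- .simpls(Xtr, y[tr] - mu, nc)
    per_fold_ncomp[k] <- fit$ncomp
    oof[!tr] <- mu + Xte %*% fit$coef_path[, fit$ncomp]
  }

  gap_raw <- oof - y
  bias_fit <- lm(gap_raw ~ y)
  bias <- c(intercept = unname(coef(bias_fit)[1]),
            slope = unname(coef(bias_fit)[2]))
  gap_corrected <- gap_raw - (bias[["intercept"]] + bias[["slope"]] * y)

  # Deployable model refit on all data.
  std_all <- .standardize_fit(X)
  std_all$scale <- pmax(std_all$scale, 1e-12)
  Xs <- .standardize_apply(X, std_all)
  nc_final <- ncomp
  if (is.null(nc_final)) {
    rmse_path <- .pls_cv_rmse(X, y, min(max_ncomp, p, n - 1),
                              seed = stage_seed(seed, "folds") + 99L)
    nc_final <- which.min(rmse_path)
  }
  fit_all <- .simpls(Xs, y - mean(y), nc_final)
  model <- structure(
    list(
      schema = 1L,
      features = feature_ids,
      center = setNames(as.numeric(std_all$center), feature_ids),
      scale = setNames(as.numeric(std_all$scale), feature_ids),
      coef = setNames(as.numeric(fit_all$coef_path[, fit_all$ncomp]),
                      feature_ids),
      intercept = mean(y),
      ncomp = fit_all$ncomp,
      bias = bias,
      cv = list(folds = folds, seed = seed, assignment = fold,
                per_fold_ncomp = per_fold_ncomp)
    ),
    class = "pls_age_model"
  )

  insample <- model$intercept + Xs %*% model$coef
  result <- tibble::tibble(
    id = data$id,
    age = y,
    brain_age = oof,
    gap_raw = gap_raw,
    gap_corrected = gap_corrected,
    cohort = if ("group" %in% names(data)) data$group else "aging",
    fold = fold
  )
  metrics <- tibble::tibble(
    r = cor(oof, y),
    rmse = sqrt(mean((oof - y)^2)),
    mae = mean(abs(oof - y)),
    r_insample = cor(drop(insample), y),
    rmse_insample = sqrt(mean((insample - y)^2)),
    mae_insample = mean(abs(insample - y)),
    n = n,
    p = p,
    ncomp = fit_all$ncomp
  )
  structure(list(model = model, result = result, metrics = metrics),
            class = "pls_age_fit")
}

#' Age-bias correction of brain-age gaps
#'
#' Subtracts the fitted age-bias line from the raw gaps:
#' `corrected = raw - (slope * age + intercept)`. With `refit = TRUE` the
#' line is re-estimated on this cohort (making the corrected gaps exactly
#' uncorrelated with age there); otherwise the line stored in the model --
#' fitted on the aging training cohort -- is applied, which is required when
#' scoring disease cohorts against the aging reference.
#'
#' @param result A brain-age result tibble (`age`, `gap_raw`).
#' @param model A `pls_age_model` supplying the stored line.
#' @param refit Re-estimate the line on this cohort (needs n >= 10).
#' @return The result tibble with `gap_corrected` recomputed; the line used
#'   is attached as attribute `bias`.
#' @export
bias_correct <- function(result, model, refit = FALSE) {
  check_columns(result, c("age", "gap_raw"), "brain-age result")
  if (refit) {
    if (nrow(result) < 10) {
      abort("refitting the bias line needs at least 10 participants")
    }
    fit <- lm(gap_raw ~ age, data = result)
    bias <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  } else {
    bias <- model$bias
  }
  result$gap_corrected <- result$gap_raw -
    (bias[["intercept"]] + bias[["slope"]] * result$age)
  attr(result, "bias") <- bias
  result
}

#' Apply a frozen brain-age model to a cohort
#'
#' Features are standardized with the model's stored training means and SDs
#' (never the new cohort's), ages are predicted, and raw and corrected gaps
#' are computed with the stored bias line.
#'
#' @param model A `pls_age_model`.
#' @param data Participant tibble with `id`, `age` (and optionally `group`).
#' @param morph Wide morphology tibble containing every model feature.
#' @return A brain-age result tibble (`id`, `age`, `brain_age`, `gap_raw`,
#'   `gap_corrected`, `cohort`).
#' @export
apply_pls_age <- function(model, data, morph) {
  stopifnot(inherits(model, "pls_age_model"))
  check_columns(data, c("id", "age"))
  missing <- setdiff(model$features, names(morph))
  if (length(missing) > 0) {
    abort(paste0(
      "morphology table is missing model feature(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  morph <- morph[match(data$id, morph$id), , drop = FALSE]
  X <- morph_matrix(morph, model$features)
  Xs <- .standardize_apply(X, list(center = model$center, scale = model$scale))
  pred <- drop(model$intercept + Xs %*% model$coef)
  gap_raw <- pred - data$age
  tibble::tibble(
    id = data$id,
    age = data$age,
    brain_age = pred,
    gap_raw = gap_raw,
    gap_corrected = gap_raw -
      (model$bias[["intercept"]] + model$bias[["slope"]] * data$age),
    cohort = if ("group" %in% names(data)) data$group else "unknown"
  )
}

#' @export
predict.pls_age_model <- function(object, data, morph, ...) {
  apply_pls_age(object, data, morph)
}

#' Serialize a brain-age model to JSON
#'
#' All arrays inline, full numeric precision; [read_pls_model()] restores a
#' model whose predictions are bit-identical to the original's.
#'
#' @param model A `pls_age_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_age_model"))
  payload <- list(
    schema = model$schema,
    features = model$features,
    center = unname(model$center),
    scale = unname(model$scale),
    coef = unname(model$coef),
    intercept = model$intercept,
    ncomp = model$ncomp,
    bias = as.list(model$bias),
    cv = model$cv
  )
  # 17 significant digits uniquely identify a double: the round-trip is exact
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a brain-age model from JSON
#'
#' @param path Path written by [write_pls_model()].
#' @return A `pls_age_model`.
#' @export
read_pls_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      schema = as.integer(x$schema),
      features = x$features,
      center = setNames(as.numeric(x$center), x$features),
      scale = setNames(as.numeric(x$scale), x$features),
      coef = setNames(as.numeric(x$coef), x$features),
      intercept = as.numeric(x$intercept),
      ncomp = as.integer(x$ncomp),
      bias = c(intercept = as.numeric(x$bias$intercept),
               slope = as.numeric(x$bias$slope)),
      cv = list(folds = as.integer(x$cv$folds), seed = as.integer(x$cv$seed),
                assignment = as.integer(x$cv$assignment),
                per_fold_ncomp = as.integer(x$cv$per_fold_ncomp))
    ),
    class = "pls_age_model"
  )
}
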