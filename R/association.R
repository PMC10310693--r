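# Mass-univariate association of morphology features with MetS components or
# the severity score: two-step unique-effect regression, BH-FDR or maxT
# permutation correction applied separately within each measure kind.

#' Residualize a feature matrix on a design matrix
#'
#' Returns `Y - X (X'X)^-1 X' Y` column by column; the residuals are
#' orthogonal to every column of `X`.
#'
#' @param Y Numeric matrix (participants x features) or a wide morphology
#'   tibble with an `id` column.
#' @param X Full-rank numeric design matrix with matching rows.
#' @return Numeric matrix of residuals with the dimensions of `Y`.
#' @export
residualize <- function(Y, X) {
  if (is.data.frame(Y)) Y <- morph_matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) abort("Y and X must have the same number of rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("design matrix is rank deficient; cannot residualize")
  }
  qr.resid(qrX, Y)
}

# Vectorised OLS of every column of Y on X, reporting the coefficient of
# X's `term`-th column for each feature.
.ols_scan <- function(Y, X, term = 1L) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    abort(sprintf(
      "fewer participants (%d) than model parameters (%d)", n, p
    ))
  }
  qrX <- qr(X)
  if (qrX$rank < p) abort("scan design matrix is rank deficient")
  beta_all <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  rss <- colSums(res^2)
  df <- n - p
  sigma2 <- rss / df
  cterm <- chol2inv(qr.R(qrX))[term, term]
  beta <- beta_all[term, ]
  se <- sqrt(sigma2 * cterm)
  tstat <- beta / se
  list(
    beta = unname(beta), se = unname(se), t = unname(tstat),
    p = unname(2 * pt(-abs(tstat), df)), df = df, rss = unname(rss), k = p
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; a feature is
#' significant when its adjusted value is at or below `level`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param level FDR level (default 0.01, the level used for the association
#'   scans).
#' @return A tibble with columns `p`, `q` and `significant`.
#' @export
fdr_adjust <- function(p, level = 0.01) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  q <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = q <= level)
}

#' maxT permutation adjustment (Freedman-Lane style)
#'
#' Controls the familywise error rate over a feature set: the predictor is
#' residualized on the covariates, permuted `n_perm` times, and each
#' feature's adjusted p-value is the proportion of permutations whose maximum
#' |t| across features reaches its observed |t| (with the add-one
#' correction).
#'
#' @param Y Feature matrix (participants x features) or wide morphology
#'   tibble.
#' @param predictor Numeric predictor vector.
#' @param covariates Numeric covariate design matrix (including intercept).
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return Numeric vector of adjusted p-values, one per feature.
#' @export
maxt_adjust <- function(Y, predictor, covariates, n_perm = 1000, seed = 1) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  if (is.data.frame(Y)) Y <- morph_matrix(Y)
  Z <- as.matrix(covariates)
  n <- nrow(Y)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) abort("covariate matrix is rank deficient")
  xt <- qr.resid(qrZ, as.numeric(predictor))
  Yt <- qr.resid(qrZ, Y)
  xss <- sum(xt^2)
  if (xss < .Machine$double.eps * n) abort("predictor is constant given covariates")
  yss <- colSums(Yt^2)
  df <- n - ncol(Z) - 1

  t_obs <- {
    cross <- drop(crossprod(xt, Yt))
    rss <- pmax(yss - cross^2 / xss, .Machine$double.eps)
    (cross / xss) * sqrt(xss * df / rss)
  }

  set.seed(seed)
  P <- t(vapply(seq_len(n_perm), function(i) xt[sample.int(n)], numeric(n)))
  cross_p <- P %*% Yt                       # n_perm x features
  rss_p <- pmax(rep(yss, each = n_perm) - cross_p^2 / xss,
                .Machine$double.eps)
  t_p <- (cross_p / xss) * sqrt(xss * df / rss_p)
  max_t <- apply(abs(t_p), 1, max)
  vapply(abs(t_obs), function(t0) (1 + sum(max_t >= t0)) / (1 + n_perm),
         numeric(1))
}

.assoc_result <- function(features, stats, predictor, correction, level,
                          n, adj) {
  out <- tibble::tibble(
    feature = features$feature,
    measure_kind = features$measure_kind,
    region = features$region,
    hemisphere = features$hemisphere,
    beta = stats$beta,
    se = stats$se,
    t = stats$t,
    df = stats$df,
    p = stats$p,
    q = adj$q,
    significant = adj$significant
  )
  attr(out, "predictor") <- predictor
  attr(out, "correction") <- correction
  attr(out, "level") <- level
  attr(out, "n") <- n
  class(out) <- c("mets_assoc", class(out))
  out
}

# Apply the configured multiple-testing correction separately within each
# measure kind (area, thickness, volume get their own families).
.correct_by_kind <- function(stats, features, correction, level,
                             maxt_args = NULL) {
  m <- length(stats$p)
  q <- numeric(m)
  sig <- logical(m)
  for (kd in unique(features$measure_kind)) {
    idx <- which(features$measure_kind == kd)
    if (correction == "fdr") {
      adj <- fdr_adjust(stats$p[idx], level = level)
      q[idx] <- adj$q
      sig[idx] <- adj$significant
    } else {
      padj <- maxt_adjust(
        maxt_args$Y[, idx, drop = FALSE], maxt_args$predictor,
        maxt_args$covariates, n_perm = maxt_args$n_perm,
        seed = maxt_args$seed
      )
      q[idx] <- padj
      sig[idx] <- padj <= level
    }
  }
  list(q = q, significant = sig)
}

.align_scan_inputs <- function(data, morph, features) {
  check_columns(data, "id")
  check_columns(morph, "id", "morphology table")
  if (!all(data$id %in% morph$id)) {
    abort("some participant ids are missing from the morphology table")
  }
  morph <- morph[match(data$id, morph$id), , drop = FALSE]
  Y <- morph_matrix(morph, features$feature)
  list(data = data, Y = Y)
}

.drop_unevaluable <- function(data) {
  fl <- mets_flags(data)
  if (any(!fl$evaluable)) {
    inform(sprintf(
      "excluding %d participant(s) with unevaluable MetS components",
      sum(!fl$evaluable)
    ))
    data <- data[fl$evaluable, , drop = FALSE]
  }
  data
}

#' Unique-effect association scan of one MetS component
#'
#' Two-step regression per morphology feature. Step 1 regresses the feature
#' on the other four MetS components (plus intercept; optionally also the
#' covariates). Step 2 regresses the step-1 residuals on the component of
#' interest while controlling for the demographic, socioeconomic and
#' lifestyle covariates, and reports that component's coefficient.
#' Multiple-testing correction is applied separately within each measure
#' kind. Degrees of freedom are those of the step-2 model (step-1 estimation
#' is not propagated; see the methods vignette).
#'
#' @param data Participant tibble (evaluable MetS rows are used; others are
#'   excluded with a message).
#' @param morph Wide morphology tibble (`id` + feature columns).
#' @param features Feature metadata tibble (`feature`, `measure_kind`,
#'   `region`, `hemisphere`).
#' @param component One of `"waist"`, `"triglyceride"`, `"hdl"`,
#'   `"hypertension"`, `"hba1c"`.
#' @param covariates Covariate scheme for step 2; default [mets_covariates()].
#' @param step1_covariates Also include the covariates in step 1 (sensitivity
#'   toggle; default FALSE).
#' @param correction `"fdr"` (Benjamini-Hochberg, default) or `"maxT"`
#'   (permutation familywise correction).
#' @param level Significance level for the corrected values (default 0.01).
#' @param hypertension How the hypertension component enters: the binary
#'   criterion flag (default) or raw systolic BP.
#' @param n_perm,seed Permutation settings when `correction = "maxT"`.
#' @return A `mets_assoc` tibble: one row per feature with `beta`, `se`,
#'   `t`, `df`, `p`, `q`, `significant` plus feature metadata; attributes
#'   record predictor, correction, level and sample size.
#' @export
unique_effect_scan <- function(data, morph, features, component,
                               covariates = mets_covariates(),
                               step1_covariates = FALSE,
                               correction = c("fdr", "maxT"),
                               level = 0.01,
                               hypertension = c("binary", "sbp"),
                               n_perm = 1000, seed = 1) {
  correction <- match.arg(correction)
  hypertension <- match.arg(hypertension)
  comps <- mets_components()
  if (!component %in% comps) {
    abort(paste0("component must be one of: ", paste(comps, collapse = ", ")))
  }
  data <- .drop_unevaluable(data)
  ali <- .align_scan_inputs(data, morph, features)
  data <- ali$data
  Y <- ali$Y

  x <- component_predictor(data, component, hypertension)
  if (sd(x) < .Machine$double.eps) {
    abort(paste0("component '", component, "' is constant across participants"))
  }
  others <- setdiff(comps, component)
  X1 <- cbind(
    `(Intercept)` = 1,
    vapply(others, function(cc) component_predictor(data, cc, hypertension),
           numeric(nrow(data)))
  )
  cov_design <- build_design(data, covariates, intercept = TRUE)
  if (step1_covariates) X1 <- cbind(X1, cov_design[, -1, drop = FALSE])
  R1 <- residualize(Y, X1)

  X2 <- cbind(component = x, cov_design)
  stats <- .ols_scan(R1, X2, term = 1L)
  adj <- .correct_by_kind(
    stats, features, correction, level,
    maxt_args = list(Y = R1, predictor = x, covariates = cov_design,
                     n_perm = n_perm, seed = seed)
  )
  .assoc_result(features, stats, component, correction, level, nrow(data), adj)
}

#' Association scan of the MetS severity score
#'
#' Single-step mass-univariate regression: each morphology feature on the
#' severity score (0-5) plus the covariates; reports the severity
#' coefficient with correction within measure kind.
#'
#' @inheritParams unique_effect_scan
#' @return A `mets_assoc` tibble (predictor `"severity"`).
#' @export
severity_scan <- function(data, morph, features,
                          covariates = mets_covariates(),
                          correction = c("fdr", "maxT"),
                          level = 0.01, n_perm = 1000, seed = 1) {
  correction <- match.arg(correction)
  data <- .drop_unevaluable(data)
  ali <- .align_scan_inputs(data, morph, features)
  data <- ali$data
  Y <- ali$Y

  sev <- as.numeric(mets_flags(data)$severity)
  if (sd(sev) < .Machine$double.eps) {
    abort("severity is constant across participants")
  }
  cov_design <- build_design(data, covariates, intercept = TRUE)
  X <- cbind(severity = sev, cov_design)
  stats <- .ols_scan(Y, X, term = 1L)
  adj <- .correct_by_kind(
    stats, features, correction, level,
    maxt_args = list(Y = Y, predictor = sev, covariates = cov_design,
                     n_perm = n_perm, seed = seed)
  )
  .assoc_result(features, stats, "severity", correction, level, nrow(data), adj)
}

#' Write an association result as delimited text
#'
#' One row per feature with all statistics and metadata columns; a compact
#' JSON manifest alongside records predictor, correction, level and sample
#' size.
#'
#' @param result A `mets_assoc` tibble.
#' @param path CSV output path (`<path>.json` gets the manifest).
#' @return Invisibly, `path`.
#' @export
write_association <- function(result, path) {
  write.csv(as.data.frame(result), path, row.names = FALSE)
  jsonlite::write_json(
    list(
      predictor = attr(result, "predictor"),
      correction = attr(result, "correction"),
      level = attr(result, "level"),
      n = attr(result, "n")
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
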