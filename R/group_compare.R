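# Distributional comparison of brain-age gaps across severity levels and
# disease groups (two-sample KS tests with BH-FDR), and covariate-matched
# cohort comparisons (logit-propensity greedy matching + t-tests).

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over the pooled support of the absolute difference of
#' the two empirical distribution functions; the p-value comes from the
#' asymptotic two-sample Kolmogorov distribution by default, or from the
#' exact distribution when `exact = TRUE` (offered for small samples).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param exact Use the exact p-value computation (default FALSE,
#'   asymptotic).
#' @return A one-row tibble with `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    abort("both samples must contain at least 2 observations")
  }
  kt <- suppressWarnings(ks.test(a, b, exact = exact))
  tibble::tibble(
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    n_a = length(a),
    n_b = length(b)
  )
}

.gap_contrast_table <- function(contrasts, level) {
  if (nrow(contrasts) == 0) return(contrasts)
  adj <- fdr_adjust(contrasts$p, level = level)
  contrasts$q <- adj$q
  contrasts$significant <- adj$significant
  contrasts
}

#' KS contrasts of brain-age gaps between adjacent severity levels
#'
#' Compares the corrected brain-age gap distribution between adjacent MetS
#' severity levels (0 vs 1, ..., 4 vs 5; or all pairs), with BH-FDR across
#' the performed contrasts at `level`. Per-level means and SDs are attached
#' as the `"levels"` attribute. Levels with fewer than 2 participants are
#' skipped with a message.
#'
#' @param result Brain-age result tibble with `id` and `gap_corrected`.
#' @param severity Severity tibble from [mets_severity()] (`id`,
#'   `severity`).
#' @param scheme `"adjacent"` (default) or `"all_pairs"`.
#' @param level FDR level (default 0.05).
#' @param exact Passed to [ks_two_sample()].
#' @return A `gap_contrasts` tibble: one row per contrast with group labels,
#'   sizes, means, direction, `D`, `p`, `q`, `significant`.
#' @export
severity_gap_contrasts <- function(result, severity,
                                   scheme = c("adjacent", "all_pairs"),
                                   level = 0.05, exact = FALSE) {
  scheme <- match.arg(scheme)
  check_columns(result, c("id", "gap_corrected"), "brain-age result")
  check_columns(severity, c("id", "severity"), "severity table")
  joined <- dplyr::inner_join(
    result[c("id", "gap_corrected")],
    severity[c("id", "severity")],
    by = "id"
  )
  joined <- joined[!is.na(joined$severity), , drop = FALSE]
  level_stats <- joined |>
    dplyr::group_by(severity) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_gap = mean(gap_corrected),
      sd_gap = sd(gap_corrected),
      .groups = "drop"
    ) |>
    dplyr::arrange(severity)

  pairs <- if (scheme == "adjacent") {
    lapply(0:4, function(s) c(s, s + 1))
  } else {
    utils::combn(0:5, 2, simplify = FALSE)
  }
  rows <- list()
  for (pr in pairs) {
    g1 <- joined$gap_corrected[joined$severity == pr[1]]
    g2 <- joined$gap_corrected[joined$severity == pr[2]]
    if (length(g1) < 2 || length(g2) < 2) {
      inform(sprintf(
        "skipping severity contrast %d vs %d (fewer than 2 per level)",
        pr[1], pr[2]
      ))
      next
    }
    ks <- ks_two_sample(g1, g2, exact = exact)
    rows[[length(rows) + 1]] <- tibble::tibble(
      contrast = sprintf("%d vs %d", pr[1], pr[2]),
      group1 = as.character(pr[1]), group2 = as.character(pr[2]),
      n1 = length(g1), n2 = length(g2),
      mean1 = mean(g1), mean2 = mean(g2),
      direction = ifelse(mean(g2) > mean(g1), "increasing", "decreasing"),
      D = ks$statistic, p = ks$p_value
    )
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble()
  if (nrow(out) == 0) {
    inform("no severity contrast could be evaluated")
    out <- tibble::tibble(
      contrast = character(), group1 = character(), group2 = character(),
      n1 = integer(), n2 = integer(), mean1 = numeric(), mean2 = numeric(),
      direction = character(), D = numeric(), p = numeric(),
      q = numeric(), significant = logical()
    )
  } else {
    out <- .gap_contrast_table(out, level)
  }
  attr(out, "levels") <- level_stats
  attr(out, "level") <- level
  class(out) <- c("gap_contrasts", class(out))
  out
}

#' KS contrasts of disease-cohort gaps against the aging cohort
#'
#' One KS contrast per disease cohort versus the aging reference, BH-FDR
#' across the contrasts. The gap sets may come from the all-components model
#' or from per-component PLS models.
#'
#' @param aging Brain-age result tibble for the aging cohort.
#' @param diseases Named list of brain-age result tibbles, one per disease.
#' @param level FDR level (default 0.05).
#' @param exact Passed to [ks_two_sample()].
#' @return A `gap_contrasts` tibble, one row per disease.
#' @export
disease_gap_contrasts <- function(aging, diseases, level = 0.05,
                                  exact = FALSE) {
  check_columns(aging, "gap_corrected", "brain-age result")
  if (is.null(names(diseases)) || any(names(diseases) == "")) {
    abort("diseases must be a named list of brain-age results")
  }
  rows <- lapply(names(diseases), function(d) {
    g <- diseases[[d]]$gap_corrected
    if (length(g) < 2) {
      inform(sprintf("skipping disease contrast '%s' (fewer than 2)", d))
      return(NULL)
    }
    ks <- ks_two_sample(aging$gap_corrected, g, exact = exact)
    tibble::tibble(
      contrast = paste0(d, " vs aging"),
      group1 = "aging", group2 = d,
      n1 = nrow(aging), n2 = length(g),
      mean1 = mean(aging$gap_corrected), mean2 = mean(g),
      direction = ifelse(mean(g) > mean(aging$gap_corrected),
                         "increasing", "decreasing"),
      D = ks$statistic, p = ks$p_value
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no disease contrast could be evaluated")
  out <- .gap_contrast_table(out, level)
  attr(out, "level") <- level
  class(out) <- c("gap_contrasts", class(out))
  out
}

#' Propensity-score matching (greedy 1:1 nearest neighbour)
#'
#' Fits a logistic regression of treated-vs-pool membership on the
#' covariates, then matches each treated participant to the nearest unused
#' pool participant on the logit propensity scale, in descending order of
#' treated propensity, optionally within a caliper (a multiple of the SD of
#' the logit propensity). Matching is 1:1 without replacement and
#' deterministic given the inputs.
#'
#' @param treated,pool Participant tibbles (must share `id` and the
#'   covariate columns; ids must not overlap).
#' @param covariates Covariate scheme; default [mets_covariates()].
#' @param caliper Caliper width in SDs of the logit propensity (default
#'   0.2); `NULL` disables it.
#' @param seed Retained for interface stability; matching itself is
#'   deterministic (ties broken by row order).
#' @return A list of class `match_set`: `pairs` (treated id, control id,
#'   logit distance), `scores` (id, treated, propensity, logit),
#'   `covariates`, `caliper`, `n_unmatched`.
#' @export
propensity_match <- function(treated, pool, covariates = mets_covariates(),
                             caliper = 0.2, seed = 1) {
  check_columns(treated, "id", "treated table")
  check_columns(pool, "id", "pool table")
  if (nrow(pool) < nrow(treated)) {
    warn("pool is smaller than the treated group; matching will be partial")
  }
  both <- dplyr::bind_rows(treated, pool)
  z <- c(rep(1L, nrow(treated)), rep(0L, nrow(pool)))
  X <- build_design(both, covariates, intercept = FALSE)
  fit <- suppressWarnings(glm(z ~ X, family = binomial()))
  ps <- fitted(fit)
  if (any(ps > 1 - 1e-8) || any(ps < 1e-8)) {
    abort(paste0(
      "perfect separation in the propensity model; ",
      "covariates fully predict group membership"
    ))
  }
  lg <- qlogis(ps)
  cal_width <- if (is.null(caliper)) Inf else caliper * sd(lg)

  lg_t <- lg[z == 1]
  lg_c <- lg[z == 0]
  ord <- order(lg_t, decreasing = TRUE)
  used <- rep(FALSE, length(lg_c))
  pair_t <- integer(0)
  pair_c <- integer(0)
  dist <- numeric(0)
  for (i in ord) {
    d <- abs(lg_c - lg_t[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= cal_width) {
      used[j] <- TRUE
      pair_t <- c(pair_t, i)
      pair_c <- c(pair_c, j)
      dist <- c(dist, d[j])
    }
  }
  pairs <- tibble::tibble(
    treated_id = treated$id[pair_t],
    control_id = pool$id[pair_c],
    distance = dist
  )
  structure(
    list(
      pairs = pairs,
      scores = tibble::tibble(
        id = both$id, treated = z == 1, propensity = unname(ps),
        logit = unname(lg)
      ),
      covariates = covariates,
      caliper = caliper,
      n_unmatched = nrow(treated) - nrow(pairs)
    ),
    class = "match_set"
  )
}

#' Covariate balance diagnostics for a match set
#'
#' Standardized mean differences (treated minus control over the pooled
#' pre-matching SD) for every covariate column of the design, before and
#' after matching.
#'
#' @param matchset A [propensity_match()] result.
#' @param treated,pool The tibbles that were matched.
#' @return A tibble with `covariate`, `smd_before`, `smd_after`.
#' @export
match_balance <- function(matchset, treated, pool) {
  both <- dplyr::bind_rows(treated, pool)
  X <- build_design(both, matchset$covariates, intercept = FALSE)
  is_t <- c(rep(TRUE, nrow(treated)), rep(FALSE, nrow(pool)))
  sd_pool <- apply(X, 2, function(v) {
    sqrt((var(v[is_t]) + var(v[!is_t])) / 2)
  })
  smd <- function(rows_t, rows_c) {
    (colMeans(X[rows_t, , drop = FALSE]) -
       colMeans(X[rows_c, , drop = FALSE])) / pmax(sd_pool, 1e-12)
  }
  before <- smd(which(is_t), which(!is_t))
  mt <- match(matchset$pairs$treated_id, both$id)
  mc <- match(matchset$pairs$control_id, both$id)
  after <- smd(mt, mc)
  tibble::tibble(
    covariate = colnames(X),
    smd_before = unname(before),
    smd_after = unname(after)
  )
}

#' t-tests on matched groups
#'
#' Two-sample Student's t-test (pooled variance; optionally paired) of each
#' requested variable between the matched treated and matched control
#' participants.
#'
#' @param matchset A [propensity_match()] result.
#' @param data Tibble containing `id` and the variables (typically the
#'   row-bound treated and pool tables with MetS measurements and severity).
#' @param variables Character vector of column names to test.
#' @param paired Use the paired t-test (default FALSE, two-sample).
#' @return A tibble: `variable`, `mean_treated`, `mean_control`, `t`, `df`,
#'   `p`.
#' @export
matched_t_test <- function(matchset, data, variables, paired = FALSE) {
  if (nrow(matchset$pairs) < 2) abort("need at least 2 matched pairs")
  check_columns(data, c("id", variables), "variable table")
  it <- match(matchset$pairs$treated_id, data$id)
  ic <- match(matchset$pairs$control_id, data$id)
  if (anyNA(it) || anyNA(ic)) abort("matched ids are missing from data")
  rows <- lapply(variables, function(v) {
    xt <- as.numeric(data[[v]][it])
    xc <- as.numeric(data[[v]][ic])
    tt <- t.test(xt, xc, var.equal = TRUE, paired = paired)
    tibble::tibble(
      variable = v,
      mean_treated = mean(xt),
      mean_control = mean(xc),
      t = unname(tt$statistic),
      df = unname(tt$parameter),
      p = tt$p.value
    )
  })
  dplyr::bind_rows(rows)
}
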