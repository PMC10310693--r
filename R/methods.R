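# print / tidy / glance methods for the package's result objects.

#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.mets_sim_config <- function(x, ...) {
  cat("<mets_sim_config>\n")
  cat(sprintf("  participants: %d, seed: %d, ages %.1f-%.1f\n",
              x$n_participants, x$seed, x$age_range[1], x$age_range[2]))
  cat(sprintf("  features: %d area, %d thickness, %d volume\n",
              x$n_features[["area"]], x$n_features[["thickness"]],
              x$n_features[["volume"]]))
  cat(sprintf("  disease cohorts: %s\n",
              paste(sprintf("%s (n=%d, +%.2fy)", names(x$disease_n),
                            x$disease_n,
                            x$disease_offsets[names(x$disease_n)]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.pls_age_model <- function(x, ...) {
  cat("<pls_age_model>\n")
  cat(sprintf("  %d features, %d latent component(s)\n",
              length(x$features), x$ncomp))
  cat(sprintf("  bias line: gap = %.3f %+.3f * age\n",
              x$bias[["intercept"]], x$bias[["slope"]]))
  cat(sprintf("  trained with %d-fold CV (seed %d)\n",
              x$cv$folds, x$cv$seed))
  invisible(x)
}

#' @export
print.pls_age_fit <- function(x, ...) {
  cat("<pls_age_fit>\n")
  m <- x$metrics
  cat(sprintf(
    "  out-of-fold: r = %.3f, RMSE = %.2f y, MAE = %.2f y (n = %d, p = %d)\n",
    m$r, m$rmse, m$mae, m$n, m$p
  ))
  cat(sprintf("  %d latent component(s)\n", m$ncomp))
  invisible(x)
}

#' @export
print.match_set <- function(x, ...) {
  cat("<match_set>\n")
  cat(sprintf("  %d pairs matched, %d treated unmatched (caliper %s)\n",
              nrow(x$pairs), x$n_unmatched,
              if (is.null(x$caliper)) "none" else format(x$caliper)))
  invisible(x)
}

#' @rdname tidy.pls_age_fit
#' @export
tidy.pls_age_model <- function(x, ...) {
  tibble::tibble(
    feature = x$features,
    center = unname(x$center),
    scale = unname(x$scale),
    coefficient = unname(x$coef)
  )
}

#' Tidiers for brain-age fits
#'
#' `tidy()` on a `pls_age_fit` returns the per-participant out-of-fold
#' predictions and gaps; on a `pls_age_model` the per-feature
#' standardization parameters and coefficients. `glance()` returns the
#' one-row fit metrics.
#'
#' @param x A `pls_age_fit` or `pls_age_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pls_age_fit <- function(x, ...) x$result

#' @rdname tidy.pls_age_fit
#' @export
glance.pls_age_fit <- function(x, ...) x$metrics

#' Tidiers for match sets
#'
#' `tidy()` returns the matched pairs; `glance()` the pair count, unmatched
#' count and caliper.
#'
#' @param x A `match_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.match_set <- function(x, ...) x$pairs

#' @rdname tidy.match_set
#' @export
glance.match_set <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_unmatched = x$n_unmatched,
    caliper = x$caliper %||% NA_real_,
    max_distance = if (nrow(x$pairs) > 0) max(x$pairs$distance) else NA_real_
  )
}
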