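# MetS component flags, severity score and covariate design matrices.

#' NCEP-ATP III / IDF component flags
#'
#' Evaluates the five metabolic syndrome criteria per participant:
#' \itemize{
#'   \item waist: circumference >= 102 cm (males) / >= 88 cm (females);
#'   \item triglyceride: >= 1.7 mmol/L, or on triglyceride medication;
#'   \item hdl: < 1.0 mmol/L (males) / < 1.3 mmol/L (females), or on HDL
#'     medication;
#'   \item hypertension: SBP >= 130 mmHg or DBP >= 85 mmHg, or on BP
#'     medication;
#'   \item hba1c: >= 42.0 mmol/mol, or on glucose-lowering treatment.
#' }
#' All thresholds are inclusive as written. A participant whose measurement is
#' missing and whose corresponding medication flag is also missing (or FALSE
#' where no medication can satisfy the criterion, as for waist) cannot be
#' evaluated: the row is kept, flagged `evaluable = FALSE`, and its flags and
#' severity are `NA` so downstream stages can exclude and log it.
#'
#' @param data Participant tibble with columns `sex`, `waist`,
#'   `triglyceride`, `hdl`, `sbp`, `dbp`, `hba1c` and the medication flags
#'   `med_triglyceride`, `med_hdl`, `med_bp`, `med_glucose`.
#' @return A tibble: `id` (if present), the five logical flags
#'   `flag_waist` ... `flag_hba1c`, `severity` (0-5 integer) and `evaluable`.
#' @export
mets_flags <- function(data) {
  check_columns(data, c("sex", "waist", "triglyceride", "hdl", "sbp", "dbp",
                        "hba1c", "med_triglyceride", "med_hdl", "med_bp",
                        "med_glucose"))
  male <- data$sex == "male"

  # Criterion met if the measurement passes the threshold OR the medication
  # flag overrides; three-valued OR keeps an NA measurement decidable when
  # the medication flag is TRUE.
  or_med <- function(meas_flag, med) meas_flag | med
  flag_waist <- ifelse(male, data$waist >= 102, data$waist >= 88)
  flag_triglyceride <- or_med(data$triglyceride >= 1.7, data$med_triglyceride)
  flag_hdl <- or_med(
    ifelse(male, data$hdl < 1.0, data$hdl < 1.3), data$med_hdl
  )
  bp_meas <- data$sbp >= 130 | data$dbp >= 85
  # one known-elevated reading decides even if the other is missing
  bp_meas[is.na(bp_meas) &
            ((!is.na(data$sbp) & data$sbp >= 130) |
             (!is.na(data$dbp) & data$dbp >= 85))] <- TRUE
  flag_hypertension <- or_med(bp_meas, data$med_bp)
  flag_hba1c <- or_med(data$hba1c >= 42.0, data$med_glucose)

  flags <- tibble::tibble(
    flag_waist = flag_waist,
    flag_triglyceride = flag_triglyceride,
    flag_hdl = flag_hdl,
    flag_hypertension = flag_hypertension,
    flag_hba1c = flag_hba1c
  )
  evaluable <- stats::complete.cases(flags)
  severity <- ifelse(evaluable, rowSums(flags), NA_integer_)
  out <- dplyr::bind_cols(
    if ("id" %in% names(data)) tibble::tibble(id = data$id) else NULL,
    flags
  )
  out$severity <- as.integer(severity)
  out$evaluable <- evaluable
  out
}

#' MetS severity score
#'
#' The severity is the number of the five NCEP-ATP III/IDF criteria a
#' participant meets (0-5); medication use counts as meeting the criterion.
#' Identical to [mets_flags()] with the flag columns retained.
#'
#' @inheritParams mets_flags
#' @return A tibble as from [mets_flags()].
#' @export
mets_severity <- function(data) {
  mets_flags(data)
}

.education_map <- c(
  "College or University Degree" = 16,
  "A levels/AS levels or equivalent" = 13,
  "O levels/GCSEs or equivalent" = 11,
  "CSEs or equivalent" = 11,
  "NVQ or HND or HNC or equivalent" = 10,
  "Other professional qualifications" = 10,
  "Never attend school" = 0
)

#' Map education qualifications to years of education
#'
#' Qualification labels are converted to years of full-time education:
#' a college or university degree is 16 years; A/AS levels 13; O levels,
#' GCSEs or CSEs 11; NVQ/HND/HNC and other professional qualifications 10;
#' never attended school 0. Numeric input (years already) passes through
#' unchanged.
#'
#' @param x Numeric years or character qualification labels (vectorised).
#' @return Numeric years of education.
#' @export
education_years <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) && !is.factor(x)) {
    abort("education must be numeric years or a qualification label")
  }
  x <- as.character(x)
  out <- unname(.education_map[x])
  unknown <- unique(x[is.na(out) & !is.na(x)])
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown education qualification(s): ",
      paste(unknown, collapse = "; "),
      ". Valid labels: ", paste(names(.education_map), collapse = "; ")
    ))
  }
  out
}

# Default covariate scheme and reference levels. Handedness is deliberately
# not in the default scheme (available via `covariates=`).
.covariate_levels <- list(
  sex = c("female", "male"),
  ethnicity = c("white", "non-white"),
  handedness = c("right", "left", "ambidextrous"),
  smoking = c("never", "former", "current"),
  employment = c("working", "unemployed", "retired", "others"),
  site = c("cheadle", "reading", "newcastle")
)

#' Default covariate scheme for the association and matching models
#'
#' Age at the MRI visit, sex, Townsend deprivation index, ethnicity, years of
#' education, smoking status, alcohol consumption frequency, employment
#' status, brain size, and imaging site.
#'
#' @return Character vector of covariate names.
#' @export
mets_covariates <- function() {
  c("age", "sex", "townsend", "ethnicity", "education", "smoking",
    "alcohol_freq", "employment", "brain_size", "site")
}

#' Build a covariate design matrix
#'
#' Numeric covariates enter as-is; categorical covariates are dummy-coded
#' against fixed reference levels (sex = female, ethnicity = white,
#' smoking = never, employment = working, site = cheadle,
#' handedness = right). Education given as qualification labels is converted
#' via [education_years()]. Column order is deterministic; an intercept
#' column is always first.
#'
#' @param data Participant tibble.
#' @param covariates Character vector of covariate names; defaults to
#'   [mets_covariates()].
#' @param intercept Include an intercept column (default TRUE).
#' @return A numeric matrix with an `encoding` attribute mapping each
#'   categorical covariate to its dummy columns and reference level.
#' @export
build_design <- function(data, covariates = mets_covariates(),
                         intercept = TRUE) {
  unknown <- setdiff(covariates, names(data))
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown covariate(s) not in data: ", paste(unknown, collapse = ", ")
    ))
  }
  n <- nrow(data)
  cols <- list()
  encoding <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, n)
  for (cv in covariates) {
    x <- data[[cv]]
    if (cv == "education" && !is.numeric(x)) x <- education_years(x)
    if (is.numeric(x) || is.logical(x)) {
      cols[[cv]] <- as.numeric(x)
    } else {
      levs <- .covariate_levels[[cv]] %||% sort(unique(as.character(x)))
      x <- as.character(x)
      bad <- setdiff(unique(x), levs)
      if (length(bad) > 0) {
        abort(paste0(
          "covariate '", cv, "' has unexpected level(s): ",
          paste(bad, collapse = ", ")
        ))
      }
      dummies <- levs[-1]
      present <- dummies[dummies %in% x]
      for (lv in present) {
        cols[[paste0(cv, "_", lv)]] <- as.numeric(x == lv)
      }
      encoding[[cv]] <- list(reference = levs[1], dummy_levels = present,
                             columns = paste0(cv, "_", present))
    }
  }
  X <- do.call(cbind, cols)
  rk <- qr(X)$rank
  if (rk < ncol(X)) {
    qrX <- qr(X)
    dropped <- colnames(X)[qrX$pivot[seq(rk + 1, ncol(X))]]
    abort(paste0(
      "design matrix is rank deficient; collinear column(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  attr(X, "encoding") <- encoding
  X
}

#' Decode a design matrix's categorical encoding
#'
#' Recovers the original categorical labels from the dummy columns of a
#' [build_design()] matrix.
#'
#' @param X Design matrix with an `encoding` attribute.
#' @return A tibble with one column per encoded categorical covariate.
#' @export
decode_design <- function(X) {
  enc <- attr(X, "encoding")
  if (is.null(enc)) abort("design matrix carries no encoding attribute")
  out <- lapply(names(enc), function(cv) {
    e <- enc[[cv]]
    lab <- rep(e$reference, nrow(X))
    for (i in seq_along(e$columns)) {
      lab[X[, e$columns[i]] == 1] <- e$dummy_levels[i]
    }
    lab
  })
  names(out) <- names(enc)
  tibble::as_tibble(out)
}

# Predictor-of-interest values for the scans: raw measurements for waist,
# triglyceride, hdl and hba1c; the binary criterion flag for hypertension by
# default (as tabulated), or raw systolic BP.
component_predictor <- function(data, component,
                                hypertension = c("binary", "sbp")) {
  hypertension <- match.arg(hypertension)
  comps <- mets_components()
  if (!component %in% comps) {
    abort(paste0(
      "component must be one of: ", paste(comps, collapse = ", ")
    ))
  }
  if (component == "hypertension") {
    if (hypertension == "sbp") return(as.numeric(data$sbp))
    flags <- mets_flags(data)
    return(as.numeric(flags$flag_hypertension))
  }
  as.numeric(data[[component]])
}
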