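#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats coef cor lm pnorm pt qnorm quantile rbinom rnorm runif sd
#'   setNames p.adjust ks.test t.test glm binomial predict resid var
#'   complete.cases fitted qlogis
#' @importFrom utils write.csv read.csv
NULL

# Canonical component and measure-kind orderings used across all modules.
mets_components <- function() {
  c("waist", "triglyceride", "hdl", "hypertension", "hba1c")
}

measure_kinds <- function() c("area", "thickness", "volume")

# Deterministic per-stage RNG substreams derived from one global seed, so
# stages can be re-run independently without coupling their draws.
stage_seed <- function(seed, stage) {
  stages <- c(
    "config", "participants", "morphology", "disease", "folds",
    "perm", "match", "pipeline"
  )
  i <- match(stage, stages)
  if (is.na(i)) abort(paste0("unknown RNG stage '", stage, "'"))
  (as.integer(seed) %% 20000000L) * 100L + i
}

# MD5 of the canonical JSON serialisation of a config; stamped on artifacts
# so outputs from different configs cannot be silently mixed.
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

check_columns <- function(data, cols, what = "participant table") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Morphology tables are wide tibbles: id column + one column per feature.
morph_matrix <- function(morph, feature_ids = NULL) {
  check_columns(morph, "id", "morphology table")
  feature_ids <- feature_ids %||% setdiff(names(morph), "id")
  missing <- setdiff(feature_ids, names(morph))
  if (length(missing) > 0) {
    abort(paste0(
      "morphology table is missing feature(s): ",
      paste(utils::head(missing, 10), collapse = ", "),
      if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10) else ""
    ))
  }
  Y <- as.matrix(morph[feature_ids])
  rownames(Y) <- morph$id
  storage.mode(Y) <- "double"
  Y
}
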