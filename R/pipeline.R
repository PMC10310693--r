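# End-to-end orchestration: simulate (or read) -> exclusion filter ->
# severity -> association scans -> winner map -> feature selection ->
# brain age -> disease scoring -> group contrasts, with persisted artifacts
# and a JSON run manifest.

#' Exclusion filter and cohort split
#'
#' Drops participants whose MetS components cannot be evaluated (missing
#' measurement with no medication override) and participants missing any
#' covariate of the scheme, in that order, logging the count removed per
#' reason. The remainder is split by group label into the aging cohort and
#' the disease cohorts, which never enter the aging training set.
#'
#' @param data Participant tibble with a `group` column.
#' @param covariates Covariate scheme checked for missingness; default
#'   [mets_covariates()].
#' @return A list: `aging` (tibble), `diseases` (named list of tibbles),
#'   `log` (tibble with `step`, `reason`, `n_removed`).
#' @export
exclusion_filter <- function(data, covariates = mets_covariates()) {
  check_columns(data, c("id", "group"))
  log <- list()

  fl <- mets_flags(data)
  drop_mets <- !fl$evaluable
  log[[1]] <- tibble::tibble(step = 1L, reason = "missing MetS",
                             n_removed = sum(drop_mets))
  data <- data[!drop_mets, , drop = FALSE]

  present <- intersect(covariates, names(data))
  drop_cov <- if (length(present) > 0) {
    !stats::complete.cases(data[present])
  } else {
    rep(FALSE, nrow(data))
  }
  log[[2]] <- tibble::tibble(step = 2L, reason = "missing covariate",
                             n_removed = sum(drop_cov))
  data <- data[!drop_cov, , drop = FALSE]

  if (nrow(data) == 0) abort("no participant survives the exclusion filter")
  aging <- data[data$group == "aging", , drop = FALSE]
  disease_labels <- setdiff(unique(data$group), "aging")
  diseases <- lapply(setNames(disease_labels, disease_labels), function(d) {
    data[data$group == d, , drop = FALSE]
  })
  list(aging = aging, diseases = diseases, log = dplyr::bind_rows(log))
}

#' Pipeline configuration
#'
#' Either a `simulation` block (a [sim_config()] or a list of its arguments)
#' or the three input paths must be given.
#'
#' @param simulation Optional [sim_config()] or argument list for one.
#' @param participants,morphology,features Optional CSV paths (used when no
#'   simulation block is given).
#' @param covariates Covariate scheme.
#' @param assoc_level FDR level of the association scans (default 0.01).
#' @param ks_level FDR level of the KS contrasts (default 0.05).
#' @param correction `"fdr"` or `"maxT"` for the scans.
#' @param folds,ncomp,max_ncomp PLS settings (defaults 10 folds, component
#'   count chosen by inner CV up to 30).
#' @param contrast_scheme `"adjacent"` or `"all_pairs"` severity contrasts.
#' @param seed Global seed.
#' @return A list of class `mets_pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            participants = NULL, morphology = NULL,
                            features = NULL,
                            covariates = mets_covariates(),
                            assoc_level = 0.01, ks_level = 0.05,
                            correction = c("fdr", "maxT"),
                            folds = 10, ncomp = NULL, max_ncomp = 30,
                            contrast_scheme = c("adjacent", "all_pairs"),
                            seed = 1) {
  correction <- match.arg(correction)
  contrast_scheme <- match.arg(contrast_scheme)
  if (is.null(simulation)) {
    for (field in c("participants", "morphology", "features")) {
      path <- get(field)
      if (is.null(path)) {
        abort(paste0(
          "config field '", field,
          "' is required when no simulation block is given"
        ))
      }
      if (!file.exists(path)) {
        abort(paste0("config field '", field, "': file not found: ", path))
      }
    }
  } else if (!inherits(simulation, "mets_sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  if (assoc_level <= 0 || assoc_level >= 1 || ks_level <= 0 || ks_level >= 1) {
    abort("significance levels must lie in (0, 1)")
  }
  structure(
    list(
      simulation = simulation,
      participants = participants, morphology = morphology,
      features = features,
      covariates = covariates,
      assoc_level = assoc_level, ks_level = ks_level,
      correction = correction,
      folds = as.integer(folds),
      ncomp = if (!is.null(ncomp)) as.integer(ncomp),
      max_ncomp = as.integer(max_ncomp),
      contrast_scheme = contrast_scheme,
      seed = as.integer(seed)
    ),
    class = "mets_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#'   (the `simulation` block, if present, mirrors [sim_config()] arguments).
#' @return A `mets_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    for (f in c("component_correlation", "effect_sizes")) {
      if (!is.null(sim[[f]])) sim[[f]] <- as.matrix(as.data.frame(sim[[f]]))
    }
    raw$simulation <- sim
  }
  do.call(pipeline_config, raw)
}

.write_artifact <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline artifact written by [run_pipeline()]
#'
#' @param path CSV artifact path.
#' @return A tibble; the stamped config hash is attached as attribute
#'   `config_hash`.
#' @export
read_artifact <- function(path) {
  first <- readLines(path, n = 1)
  hash <- sub("^# config_hash: ", "", first)
  out <- tibble::as_tibble(read.csv(path, comment.char = "#"))
  attr(out, "config_hash") <- hash
  out
}

#' Run the full analysis pipeline
#'
#' Executes: phenotype scoring -> five unique-effect scans + severity scan ->
#' AIC winner map -> feature selection -> PLS brain age with bias-corrected
#' gaps -> frozen-model application to each disease cohort -> severity and
#' disease KS contrasts. Every intermediate artifact is persisted under
#' `outdir` (CSV stamped with the config hash; models and the manifest as
#' JSON); a stage failure aborts with the stage name, keeping completed
#' artifacts. Identical config and seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param log_level `"info"` (stage messages to stderr) or `"quiet"`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir, log_level = c("info", "quiet")) {
  stopifnot(inherits(config, "mets_pipeline_config"))
  log_level <- match.arg(log_level)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash_cfg <- unclass(config)
  hash_cfg$simulation <- if (!is.null(config$simulation)) {
    unclass(config$simulation)[setdiff(names(config$simulation), "features")]
  }
  hash <- config_hash(hash_cfg)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(level, stage, msg) {
    writeLines(sprintf("%s [%s] %s", level, stage, msg), log_con)
    if (log_level == "info") {
      message(sprintf("%s %s [%s] %s", format(Sys.time(), "%H:%M:%S"),
                      level, stage, msg))
    }
  }
  stage <- function(name, expr) {
    say("INFO", name, "start")
    res <- tryCatch(expr, error = function(e) {
      say("ERROR", name, conditionMessage(e))
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    say("INFO", name, "done")
    res
  }
  manifest <- list(config_hash = hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("metsage")))

  inputs <- stage("input", {
    if (!is.null(config$simulation)) {
      study <- simulate_study(config$simulation)
      all_part <- dplyr::bind_rows(c(
        list(study$participants),
        unname(lapply(study$diseases, function(d) d$participants))
      ))
      all_morph <- dplyr::bind_rows(c(
        list(study$morphology),
        unname(lapply(study$diseases, function(d) d$morphology))
      ))
      list(participants = all_part, morphology = all_morph,
           features = study$features)
    } else {
      list(
        participants = tibble::as_tibble(read.csv(config$participants)),
        morphology = tibble::as_tibble(read.csv(config$morphology)),
        features = tibble::as_tibble(read.csv(config$features))
      )
    }
  })
  manifest$n_input <- nrow(inputs$participants)
  manifest$n_features <- nrow(inputs$features)

  excl <- stage("exclusion", exclusion_filter(inputs$participants,
                                              config$covariates))
  .write_artifact(excl$log, file.path(outdir, "exclusion_log.csv"), hash)
  manifest$exclusions <- as.list(setNames(excl$log$n_removed, excl$log$reason))
  manifest$n_aging <- nrow(excl$aging)
  manifest$n_disease <- lapply(excl$diseases, nrow)

  aging <- excl$aging
  severity <- stage("severity", mets_severity(aging))
  .write_artifact(severity, file.path(outdir, "severity.csv"), hash)

  scans <- stage("association", {
    lapply(setNames(mets_components(), mets_components()), function(cc) {
      res <- unique_effect_scan(
        aging, inputs$morphology, inputs$features, cc,
        covariates = config$covariates, correction = config$correction,
        level = config$assoc_level, seed = config$seed
      )
      .write_artifact(res, file.path(outdir, paste0("assoc_", cc, ".csv")),
                      hash)
      res
    })
  })
  sev_scan <- stage("severity_scan", {
    res <- severity_scan(
      aging, inputs$morphology, inputs$features,
      covariates = config$covariates, correction = config$correction,
      level = config$assoc_level, seed = config$seed
    )
    .write_artifact(res, file.path(outdir, "assoc_severity.csv"), hash)
    res
  })
  manifest$n_significant <- lapply(scans, function(s) sum(s$significant))
  manifest$n_significant$severity <- sum(sev_scan$significant)

  winners <- stage("winner_map", {
    res <- winner_map(aging, inputs$morphology, inputs$features,
                      covariates = config$covariates)
    .write_artifact(res, file.path(outdir, "winner_map.csv"), hash)
    res
  })
  manifest$winner_counts <- as.list(table(winners$winner))

  selected <- stage("select_features", select_features(scans))
  .write_artifact(tibble::tibble(feature = selected),
                  file.path(outdir, "selected_features.csv"), hash)
  manifest$n_selected <- length(selected)

  fit <- stage("brain_age", fit_pls_age(
    aging, inputs$morphology, feature_ids = selected,
    folds = config$folds, ncomp = config$ncomp,
    max_ncomp = config$max_ncomp, seed = config$seed
  ))
  write_pls_model(fit$model, file.path(outdir, "pls_model.json"))
  .write_artifact(fit$result, file.path(outdir, "brainage_aging.csv"), hash)
  .write_artifact(fit$metrics, file.path(outdir, "fit_metrics.csv"), hash)
  manifest$fit <- as.list(fit$metrics)

  disease_results <- stage("apply_disease", {
    lapply(excl$diseases, function(dd) {
      res <- apply_pls_age(fit$model, dd, inputs$morphology)
      .write_artifact(
        res, file.path(outdir, paste0("brainage_", dd$group[1], ".csv")), hash
      )
      res
    })
  })

  sev_contrasts <- stage("severity_contrasts", severity_gap_contrasts(
    fit$result, severity, scheme = config$contrast_scheme,
    level = config$ks_level
  ))
  .write_artifact(sev_contrasts, file.path(outdir, "contrasts_severity.csv"),
                  hash)
  if (length(disease_results) > 0) {
    dis_contrasts <- stage("disease_contrasts", disease_gap_contrasts(
      fit$result, disease_results, level = config$ks_level
    ))
    .write_artifact(dis_contrasts, file.path(outdir, "contrasts_disease.csv"),
                    hash)
    manifest$disease_mean_gap <- as.list(setNames(
      dis_contrasts$mean2, dis_contrasts$group2
    ))
  }
  manifest$severity_mean_gap <- as.list(setNames(
    attr(sev_contrasts, "levels")$mean_gap,
    paste0("severity_", attr(sev_contrasts, "levels")$severity)
  ))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("INFO", "pipeline", "complete")
  invisible(manifest)
}
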