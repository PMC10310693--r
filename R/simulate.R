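# Synthetic cohort generator with planted ground truth.
#
# The study design it emulates is a population-based aging cohort: one row per
# participant with demographics, socioeconomics, lifestyle, the five metabolic
# syndrome (MetS) measurements and medication flags, plus a wide morphology
# table (cortical surface area and thickness per region, subcortical volumes).
# All distributional choices are stand-ins for restricted cohort data; planted
# coefficients are recorded so downstream stages can be tested for recovery.

# Measurement marginals (means / SDs on natural units) and physiologic floors.
.mets_marginals <- function() {
  tibble::tribble(
    ~component,     ~column,  ~mean,  ~sd,  ~floor,
    "waist",        "waist",   87.4, 12.4,   55,
    "triglyceride", "triglyceride", 1.62, 0.94, 0.2,
    "hdl",          "hdl",     1.49, 0.37,  0.4,
    "hypertension", "sbp",    138.0, 18.0,  85,
    "hba1c",        "hba1c",   34.8, 4.95,  20
  )
}

.cortical_regions <- c(
  "superiorfrontal", "precentral", "postcentral", "supramarginal",
  "middletemporal", "insula", "posteriorcingulate", "lateraloccipital",
  "lateralorbitofrontal", "precuneus", "parahippocampal", "entorhinal",
  "superiorparietal", "inferiorparietal", "fusiform", "rostralmiddlefrontal",
  "caudalmiddlefrontal", "superiortemporal", "inferiortemporal", "cuneus"
)

.subcortical_regions <- c(
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus",
  "amygdala", "accumbens"
)

#' Default correlation among the five MetS components
#'
#' Moderate positive correlation between all pairs, with a stronger
#' waist-triglyceride link and the expected negative triglyceride-HDL link.
#' Values are configuration, not empirical claims.
#'
#' @return A symmetric positive-definite 5x5 matrix with unit diagonal,
#'   rows/columns ordered waist, triglyceride, hdl, hypertension, hba1c.
#' @export
default_component_correlation <- function() {
  comps <- mets_components()
  R <- matrix(0.3, 5, 5, dimnames = list(comps, comps))
  diag(R) <- 1
  R["waist", "triglyceride"] <- R["triglyceride", "waist"] <- 0.45
  R["triglyceride", "hdl"] <- R["hdl", "triglyceride"] <- -0.45
  R["hdl", "waist"] <- R["waist", "hdl"] <- -0.3
  R["hdl", "hypertension"] <- R["hypertension", "hdl"] <- -0.15
  R["hdl", "hba1c"] <- R["hba1c", "hdl"] <- -0.15
  R
}

#' Default standardized effect sizes of MetS burden on morphology
#'
#' Slopes are in units of the feature's noise SD per 1 SD of component burden
#' ("burden" is oriented so that worse metabolic health is positive; for HDL
#' this flips the sign of the standardized measurement). Direction convention:
#' worse MetS increases cortical surface area, decreases cortical thickness,
#' and decreases subcortical volume; abdominal obesity (waist) gets the
#' strongest effects.
#'
#' @return A 5x3 numeric matrix, components by measure kinds.
#' @export
default_effect_sizes <- function() {
  es <- matrix(
    rep(c(0.10, -0.25, -0.20), each = 5), 5, 3,
    dimnames = list(mets_components(), measure_kinds())
  )
  es["waist", ] <- es["waist", ] * 1.5
  es
}

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_participants()], [simulate_morphology()] and
#' [simulate_disease_cohort()]. Feature metadata, default affected sets and
#' per-feature age slopes are derived deterministically from `seed`, so two
#' configs built with identical arguments are identical.
#'
#' @param n_participants Number of participants in the aging cohort (>= 2).
#' @param seed Integer seed; all stage-level randomness is derived from it.
#' @param age_range Numeric length-2, low/high of the uniform age
#'   distribution in years.
#' @param component_correlation 5x5 correlation matrix of the Gaussian copula
#'   over the five MetS components (waist, triglyceride, hdl, hypertension,
#'   hba1c). Must be symmetric, unit-diagonal and positive semi-definite.
#' @param n_features Named counts of morphology features per measure kind
#'   (`area`, `thickness`, `volume`), each >= 1.
#' @param affected_fraction Fraction of all features planted as affected by
#'   each component when `affected_sets` is not supplied.
#' @param affected_sets Optional named list (one entry per component) of
#'   integer feature indices carrying that component's planted effect.
#' @param effect_sizes 5x3 matrix of standardized slopes (components x measure
#'   kinds), in feature-noise-SD units per SD of component burden. Area
#'   entries must be >= 0 and thickness entries <= 0 (worse MetS expands
#'   area and thins cortex); volume entries may take either sign.
#' @param age_slopes Optional numeric vector, one slope (feature units per
#'   year) per feature; defaults are drawn around kind-level means
#'   (area -2 mm^2/y, thickness -0.004 mm/y, volume -15 mm^3/y).
#' @param noise_sd Named per-kind residual SDs (> 0).
#' @param baselines Named per-kind baseline feature values.
#' @param med_rates Bernoulli rates for the medication flags.
#' @param disease_offsets Named added years of brain aging per disease label.
#' @param disease_n Named cohort sizes per disease label.
#' @return A list of class `mets_sim_config`.
#' @export
sim_config <- function(n_participants = 1000,
                       seed = 1,
                       age_range = c(47, 79),
                       component_correlation = default_component_correlation(),
                       n_features = c(area = 40, thickness = 40, volume = 14),
                       affected_fraction = 0.25,
                       affected_sets = NULL,
                       effect_sizes = default_effect_sizes(),
                       age_slopes = NULL,
                       noise_sd = c(area = 60, thickness = 0.08, volume = 250),
                       baselines = c(area = 2500, thickness = 2.5, volume = 4000),
                       med_rates = c(triglyceride = 0.15, hdl = 0.15,
                                     bp = 0.21, glucose = 0.05),
                       disease_offsets = c(stroke = 0.47, parkinson = 1.28,
                                           multiple_sclerosis = 1.94,
                                           dementia = 2.44),
                       disease_n = c(stroke = 500, parkinson = 100,
                                     multiple_sclerosis = 200,
                                     dementia = 100)) {
  comps <- mets_components()
  kinds <- measure_kinds()

  # tolerate list inputs (e.g. from YAML) and unnamed per-kind vectors
  name_kinds <- function(x) {
    x <- unlist(x)
    if (is.null(names(x)) && length(x) == 3) names(x) <- kinds
    x
  }
  n_features <- name_kinds(n_features)
  noise_sd <- name_kinds(noise_sd)
  baselines <- name_kinds(baselines)
  med_rates <- unlist(med_rates)
  disease_offsets <- unlist(disease_offsets)
  disease_n <- unlist(disease_n)
  if (is.list(age_range)) age_range <- unlist(age_range)

  if (!is.numeric(n_participants) || n_participants < 2) {
    abort("n_participants must be at least 2")
  }
  if (length(age_range) != 2 || diff(age_range) < 0) {
    abort("age_range must be (low, high) with low <= high")
  }
  R <- component_correlation
  if (!is.matrix(R) || !all(dim(R) == 5)) {
    abort("component_correlation must be a 5x5 matrix")
  }
  if (max(abs(R - t(R))) > 1e-8) abort("component_correlation must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) abort("component_correlation must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(paste0(
      "component_correlation is not positive semi-definite ",
      "(smallest eigenvalue ", signif(min(ev), 3), ")"
    ))
  }
  dimnames(R) <- list(comps, comps)

  n_features <- n_features[kinds]
  if (anyNA(n_features) || any(n_features < 1)) {
    abort("n_features must name area, thickness and volume counts, each >= 1")
  }
  if (any(noise_sd[kinds] <= 0) || anyNA(noise_sd[kinds])) {
    abort("noise_sd must be positive for every measure kind")
  }

  es <- effect_sizes
  if (!is.matrix(es) || nrow(es) != 5 || ncol(es) != 3) {
    abort("effect_sizes must be a 5x3 matrix (components x measure kinds)")
  }
  dimnames(es) <- list(comps, kinds)
  if (any(es[, "area"] < 0)) {
    abort("effect_sizes for area must be >= 0 (worse MetS increases surface area)")
  }
  if (any(es[, "thickness"] > 0)) {
    abort("effect_sizes for thickness must be <= 0 (worse MetS thins cortex)")
  }

  features <- .make_feature_meta(n_features)
  p <- nrow(features)

  # Config-level randomness (affected sets, age-slope variation) uses its own
  # substream so participant/morphology draws are untouched by these choices.
  set.seed(stage_seed(seed, "config"))
  if (is.null(affected_sets)) {
    n_aff <- max(1L, ceiling(affected_fraction * p))
    affected_sets <- lapply(setNames(comps, comps), function(cc) {
      sort(sample.int(p, n_aff))
    })
  } else {
    affected_sets <- lapply(affected_sets, function(s) sort(as.integer(s)))
    bad <- vapply(affected_sets, function(s) any(s < 0 | s > p), logical(1))
    if (length(affected_sets) != 5 || is.null(names(affected_sets)) ||
        !setequal(names(affected_sets), comps) || any(bad)) {
      abort("affected_sets must name all five components with feature indices in range")
    }
    affected_sets <- affected_sets[comps]
  }
  if (is.null(age_slopes)) {
    base <- c(area = -2.0, thickness = -0.004, volume = -15)
    age_slopes <- base[features$measure_kind] * runif(p, 0.6, 1.4)
  }
  if (length(age_slopes) != p) {
    abort("age_slopes must have one entry per feature")
  }
  age_slopes <- unname(as.numeric(age_slopes))

  structure(
    list(
      n_participants = as.integer(n_participants),
      seed = as.integer(seed),
      age_range = as.numeric(age_range),
      component_correlation = R,
      n_features = n_features,
      features = features,
      affected_sets = affected_sets,
      effect_sizes = es,
      age_slopes = age_slopes,
      noise_sd = noise_sd[kinds],
      baselines = baselines[kinds],
      med_rates = med_rates,
      disease_offsets = disease_offsets,
      disease_n = disease_n
    ),
    class = "mets_sim_config"
  )
}

.make_feature_meta <- function(n_features) {
  one_kind <- function(kind, n, regions) {
    idx <- seq_len(n)
    region <- regions[((idx - 1) %/% 2) %% length(regions) + 1]
    hemi <- c("left", "right")[(idx - 1) %% 2 + 1]
    tibble::tibble(
      feature = sprintf("%s_%03d", kind, idx),
      measure_kind = kind,
      region = region,
      hemisphere = hemi
    )
  }
  dplyr::bind_rows(
    one_kind("area", n_features[["area"]], .cortical_regions),
    one_kind("thickness", n_features[["thickness"]], .cortical_regions),
    one_kind("volume", n_features[["volume"]], .subcortical_regions)
  )
}

# Standardized component burden: (measurement - marginal mean) / marginal SD,
# oriented so worse metabolic health is positive (HDL flipped). Hypertension
# burden is carried by systolic BP. This is exactly the scale the generator
# multiplies planted effects by, so regression on it recovers the planted
# coefficients.
component_burden <- function(data) {
  marg <- .mets_marginals()
  check_columns(data, marg$column, "participant table")
  B <- vapply(seq_len(nrow(marg)), function(i) {
    (data[[marg$column[i]]] - marg$mean[i]) / marg$sd[i]
  }, numeric(nrow(data)))
  colnames(B) <- marg$component
  B[, "hdl"] <- -B[, "hdl"]
  B
}

.simulate_participants_core <- function(n, config, seed, group, id_prefix) {
  set.seed(seed)
  marg <- .mets_marginals()

  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(runif(n) < 0.463, "male", "female")

  # Gaussian copula over the five components.
  L <- chol(config$component_correlation + diag(1e-12, 5))
  Z <- matrix(rnorm(n * 5), n, 5) %*% L
  colnames(Z) <- mets_components()
  meas <- lapply(seq_len(nrow(marg)), function(i) {
    pmax(marg$mean[i] + marg$sd[i] * Z[, marg$component[i]], marg$floor[i])
  })
  names(meas) <- marg$column
  dbp <- pmax(82 + 10 * (0.7 * Z[, "hypertension"] + sqrt(0.51) * rnorm(n)), 50)

  mr <- config$med_rates
  tibble::tibble(
    id = sprintf("%s%05d", id_prefix, seq_len(n)),
    age = age,
    sex = sex,
    ethnicity = ifelse(runif(n) < 0.969, "white", "non-white"),
    handedness = sample(c("right", "left", "ambidextrous"), n, TRUE,
                        prob = c(0.891, 0.095, 0.014)),
    brain_size = rnorm(n, 1194300, 112400),
    townsend = rnorm(n, -1.90, 2.71),
    education = sample(c(10, 11, 13, 16), n, TRUE,
                       prob = c(0.20, 0.20, 0.15, 0.45)),
    employment = sample(c("working", "unemployed", "retired", "others"), n,
                        TRUE, prob = c(0.725, 0.012, 0.215, 0.048)),
    smoking = sample(c("never", "former", "current"), n, TRUE,
                     prob = c(0.624, 0.315, 0.061)),
    alcohol_freq = sample(0:5, n, TRUE,
                          prob = c(0.05, 0.08, 0.12, 0.25, 0.30, 0.20)),
    site = sample(c("cheadle", "reading", "newcastle"), n, TRUE,
                  prob = c(0.608, 0.133, 0.259)),
    waist = meas$waist,
    triglyceride = meas$triglyceride,
    hdl = meas$hdl,
    sbp = meas$sbp,
    dbp = dbp,
    hba1c = meas$hba1c,
    med_triglyceride = runif(n) < mr[["triglyceride"]],
    med_hdl = runif(n) < mr[["hdl"]],
    med_bp = runif(n) < mr[["bp"]],
    med_glucose = runif(n) < mr[["glucose"]],
    group = group
  )
}

#' Simulate the aging-cohort participant table
#'
#' Ages are uniform over `age_range`; the five MetS measurements come from a
#' Gaussian copula with `component_correlation` mapped to Gaussian marginals
#' truncated at physiologic floors; covariates are drawn from the categorical
#' level sets used throughout the package. Repeated calls with the same
#' config are bit-identical.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per participant (`group = "aging"`).
#' @export
simulate_participants <- function(config) {
  stopifnot(inherits(config, "mets_sim_config"))
  .simulate_participants_core(
    config$n_participants, config,
    seed = stage_seed(config$seed, "participants"),
    group = "aging", id_prefix = "P"
  )
}

.simulate_morphology_core <- function(participants, config, seed,
                                      effective_age = NULL,
                                      disease_offset = 0) {
  marg <- .mets_marginals()
  missing <- setdiff(marg$column, names(participants))
  if (length(missing) > 0) {
    abort(paste0(
      "participant table is missing MetS measurement column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  n <- nrow(participants)
  features <- config$features
  p <- nrow(features)
  kinds <- features$measure_kind

  B <- component_burden(participants)
  age_eff <- effective_age %||% participants$age
  agec <- age_eff - mean(config$age_range)

  # Planted coefficient matrix in feature units: age slope plus, for features
  # in a component's affected set, effect_size * noise_sd of that kind.
  comp_coef <- matrix(0, p, 5, dimnames = list(features$feature, mets_components()))
  for (cc in mets_components()) {
    idx <- config$affected_sets[[cc]]
    comp_coef[idx, cc] <- config$effect_sizes[cc, kinds[idx]] *
      config$noise_sd[kinds[idx]]
  }

  set.seed(seed)
  noise <- matrix(rnorm(n * p), n, p) *
    rep(config$noise_sd[kinds], each = n)
  vals <- rep(config$baselines[kinds], each = n) +
    outer(agec, config$age_slopes) +
    B %*% t(comp_coef) +
    noise
  thick <- kinds == "thickness"
  vals[, thick] <- pmax(vals[, thick], 1e-3)
  colnames(vals) <- features$feature

  morphology <- dplyr::bind_cols(
    tibble::tibble(id = participants$id),
    tibble::as_tibble(vals)
  )
  ground_truth <- list(
    coefficients = dplyr::bind_cols(
      tibble::tibble(feature = features$feature, age = config$age_slopes),
      tibble::as_tibble(comp_coef)
    ),
    affected_sets = config$affected_sets,
    disease_offset = disease_offset,
    seed = seed,
    noise_sd = config$noise_sd
  )
  structure(
    list(morphology = morphology, features = features,
         ground_truth = ground_truth),
    class = "morph_sim"
  )
}

#' Simulate the morphology table for a participant cohort
#'
#' Each feature is `baseline(kind) + age_slope * (age - age midpoint) +`
#' the planted component effects (for features in a component's affected set)
#' `+ Gaussian noise`; thickness is clipped positive. The planted coefficients
#' are returned as ground truth for recovery tests.
#'
#' @param participants Participant tibble from [simulate_participants()] or
#'   any table carrying the five MetS measurement columns.
#' @param config A [sim_config()] object.
#' @param seed RNG seed for the morphology noise; defaults to the config's
#'   morphology substream.
#' @return A list of class `morph_sim` with elements `morphology` (wide
#'   tibble, `id` + one column per feature), `features` (metadata tibble) and
#'   `ground_truth` (planted coefficients, affected sets, seed, noise SDs).
#' @export
simulate_morphology <- function(participants, config,
                                seed = stage_seed(config$seed, "morphology")) {
  stopifnot(inherits(config, "mets_sim_config"))
  .simulate_morphology_core(participants, config, seed = seed)
}

#' Simulate a disease cohort with planted accelerated brain aging
#'
#' Participants are generated as in [simulate_participants()] but morphology
#' is synthesized at an effective age of `age + disease offset`, so a brain-age
#' model trained on the aging cohort should estimate a mean bias-corrected gap
#' close to the planted offset. The group label is set to the disease.
#'
#' @param config A [sim_config()] object (offsets and cohort sizes come from
#'   its `disease_offsets` / `disease_n` fields).
#' @param disease One of `"stroke"`, `"dementia"`, `"parkinson"`,
#'   `"multiple_sclerosis"`.
#' @return A list of class `morph_sim` with an extra `participants` element.
#' @export
simulate_disease_cohort <- function(config, disease) {
  stopifnot(inherits(config, "mets_sim_config"))
  valid <- c("stroke", "dementia", "parkinson", "multiple_sclerosis")
  if (!is.character(disease) || length(disease) != 1 || !disease %in% valid) {
    abort(paste0(
      "unknown disease label '", as.character(disease)[1], "'; valid labels: ",
      paste(valid, collapse = ", ")
    ))
  }
  if (!disease %in% names(config$disease_offsets) ||
      !disease %in% names(config$disease_n)) {
    abort(paste0("config carries no offset/size for disease '", disease, "'"))
  }
  idx <- match(disease, valid)
  n <- config$disease_n[[disease]]
  offset <- config$disease_offsets[[disease]]
  participants <- .simulate_participants_core(
    n, config,
    seed = stage_seed(config$seed, "disease") + 1000L * idx,
    group = disease,
    id_prefix = paste0(toupper(substr(disease, 1, 2)), "_")
  )
  out <- .simulate_morphology_core(
    participants, config,
    seed = stage_seed(config$seed, "disease") + 1000L * idx + 500L,
    effective_age = participants$age + offset,
    disease_offset = offset
  )
  out$participants <- participants
  out
}

#' Simulate the full study (aging cohort plus all disease cohorts)
#'
#' @param config A [sim_config()] object.
#' @param diseases Character vector of disease labels to simulate; defaults
#'   to every label in `config$disease_n`.
#' @return A list with `participants`, `morphology`, `features`,
#'   `ground_truth` for the aging cohort and a named `diseases` list of
#'   [simulate_disease_cohort()] results.
#' @export
simulate_study <- function(config, diseases = names(config$disease_n)) {
  stopifnot(inherits(config, "mets_sim_config"))
  participants <- simulate_participants(config)
  morph <- simulate_morphology(participants, config)
  cohorts <- lapply(setNames(diseases, diseases), function(d) {
    simulate_disease_cohort(config, d)
  })
  list(
    participants = participants,
    morphology = morph$morphology,
    features = morph$features,
    ground_truth = morph$ground_truth,
    diseases = cohorts
  )
}

#' Write a simulated study to delimited text and JSON
#'
#' Participant and morphology tables are written as headered CSV (participant
#' id first), ground truth as JSON, and the config as YAML.
#'
#' @param study Result of [simulate_study()].
#' @param config The [sim_config()] used to generate it.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(study, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    morphology = file.path(dir, "morphology.csv"),
    features = file.path(dir, "features.csv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "sim_config.yaml")
  )
  write.csv(study$participants, paths[["participants"]], row.names = FALSE)
  write.csv(study$morphology, paths[["morphology"]], row.names = FALSE)
  write.csv(study$features, paths[["features"]], row.names = FALSE)
  gt <- study$ground_truth
  jsonlite::write_json(
    list(
      coefficients = gt$coefficients, affected_sets = gt$affected_sets,
      disease_offset = gt$disease_offset, seed = gt$seed,
      noise_sd = as.list(gt$noise_sd)
    ),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA
  )
  cfg <- config
  cfg$component_correlation <- as.data.frame(cfg$component_correlation)
  cfg$effect_sizes <- as.data.frame(cfg$effect_sizes)
  cfg$features <- NULL
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}
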