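test_that("regeneration under an identical config is bit-identical", {
  cfg <- sim_config(n_participants = 100, seed = 1,
                    n_features = c(area = 4, thickness = 4, volume = 3))
  cfg2 <- sim_config(n_participants = 100, seed = 1,
                     n_features = c(area = 4, thickness = 4, volume = 3))
  expect_identical(simulate_participants(cfg), simulate_participants(cfg2))
  p <- simulate_participants(cfg)
  expect_identical(simulate_morphology(p, cfg)$morphology,
                   simulate_morphology(p, cfg2)$morphology)
  d1 <- simulate_disease_cohort(cfg, "dementia")
  d2 <- simulate_disease_cohort(cfg2, "dementia")
  expect_identical(d1$morphology, d2$morphology)
})

test_that("identity copula yields near-independent components", {
  cfg <- sim_config(n_participants = 5000, seed = 2,
                    component_correlation = diag(5),
                    n_features = c(area = 2, thickness = 2, volume = 2))
  pt <- simulate_participants(cfg)
  M <- cbind(pt$waist, pt$triglyceride, pt$hdl, pt$sbp, pt$hba1c)
  R <- cor(M)
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
})

test_that("realized correlations converge to the configured copula", {
  cfg <- sim_config(n_participants = 20000, seed = 7,
                    n_features = c(area = 2, thickness = 2, volume = 2))
  pt <- simulate_participants(cfg)
  M <- cbind(pt$waist, pt$triglyceride, pt$hdl, pt$sbp, pt$hba1c)
  expect_lt(max(abs(cor(M) - cfg$component_correlation)), 0.03)
})

test_that("degenerate age range pins every age to its value", {
  cfg <- sim_config(n_participants = 50, seed = 3, age_range = c(62.8, 62.8),
                    n_features = c(area = 2, thickness = 2, volume = 2))
  expect_true(all(simulate_participants(cfg)$age == 62.8))
})

test_that("noiseless morphology is an exact affine function of age and components", {
  # near-zero noise with effect sizes scaled so planted coefficients stay
  # order-one: OLS on [age, burden] must recover them to 1e-6
  es <- matrix(0, 5, 3, dimnames = list(metsage:::mets_components(),
                                        metsage:::measure_kinds()))
  es["waist", ] <- c(2e7, -2e7, -2e7) * 1e-2  # coef = es * noise_sd = +-2
  sets <- list(waist = 1:6, triglyceride = integer(0), hdl = integer(0),
               hypertension = integer(0), hba1c = integer(0))
  cfg <- sim_config(
    n_participants = 120, seed = 4,
    n_features = c(area = 4, thickness = 4, volume = 4),
    noise_sd = c(area = 1e-8, thickness = 1e-8, volume = 1e-8),
    effect_sizes = es, affected_sets = sets
  )
  pt <- simulate_participants(cfg)
  sim <- simulate_morphology(pt, cfg)
  B <- metsage:::component_burden(pt)
  agec <- pt$age - mean(cfg$age_range)
  Y <- as.matrix(sim$morphology[, -1])
  gt <- sim$ground_truth$coefficients
  for (j in seq_len(ncol(Y))) {
    fit <- lm(Y[, j] ~ agec + B)
    expect_lt(abs(coef(fit)[["agec"]] - gt$age[j]), 1e-6)
    expect_lt(abs(coef(fit)[["Bwaist"]] - gt$waist[j]), 1e-6)
  }
})

test_that("a planted negative thickness effect of waist shows up as negative correlation", {
  sets <- list(waist = 41:50, triglyceride = integer(0), hdl = integer(0),
               hypertension = integer(0), hba1c = integer(0))
  cfg <- sim_config(n_participants = 5000, seed = 5,
                    affected_sets = sets, age_range = c(60, 60))
  pt <- simulate_participants(cfg)
  sim <- simulate_morphology(pt, cfg)
  feat <- sim$features$feature[41]  # thickness feature in the waist set
  expect_identical(sim$features$measure_kind[41], "thickness")
  expect_lt(cor(pt$waist, sim$morphology[[feat]]), 0)
})

test_that("empty affected sets give null component associations", {
  sets <- lapply(setNames(metsage:::mets_components(),
                          metsage:::mets_components()),
                 function(x) integer(0))
  cfg <- sim_config(n_participants = 2000, seed = 6, affected_sets = sets,
                    n_features = c(area = 12, thickness = 12, volume = 6))
  pt <- simulate_participants(cfg)
  sim <- simulate_morphology(pt, cfg)
  B <- metsage:::component_burden(pt)
  agec <- pt$age - mean(cfg$age_range)
  pvals <- unlist(lapply(seq_len(30), function(j) {
    fit <- summary(lm(as.matrix(sim$morphology[, -1])[, j] ~ agec + B))
    fit$coefficients[3:7, 4]
  }))
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
})

test_that("invalid configs and inputs are rejected with clear messages", {
  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(sim_config(component_correlation = bad),
               "positive semi-definite")
  expect_error(sim_config(n_participants = 1), "at least 2")
  expect_error(sim_config(noise_sd = c(area = 0, thickness = 1, volume = 1)),
               "positive")
  es <- default_effect_sizes(); es[1, "thickness"] <- 0.5
  expect_error(sim_config(effect_sizes = es), "thickness")
  cfg <- sim_config(n_participants = 10,
                    n_features = c(area = 2, thickness = 2, volume = 2))
  expect_error(simulate_disease_cohort(cfg, "gout"), "valid labels")
  pt <- simulate_participants(cfg)
  expect_error(simulate_morphology(pt[, setdiff(names(pt), "hdl")], cfg),
               "hdl")
})

test_that("disease cohorts carry their label and an aging offset", {
  cfg <- sim_config(n_participants = 50, seed = 8,
                    n_features = c(area = 3, thickness = 3, volume = 2),
                    disease_n = c(dementia = 40, stroke = 40,
                                  parkinson = 5, multiple_sclerosis = 5))
  d <- simulate_disease_cohort(cfg, "dementia")
  expect_true(all(d$participants$group == "dementia"))
  expect_identical(d$ground_truth$disease_offset,
                   cfg$disease_offsets[["dementia"]])
  a <- simulate_participants(cfg)
  expect_length(intersect(a$id, d$participants$id), 0)
})
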