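test_that("residualize demeans, orthogonalizes and matches normal equations", {
  set.seed(1)
  Y <- matrix(rnorm(20 * 5), 20, 5)

  R0 <- residualize(Y, matrix(1, 20, 1))
  expect_equal(R0, scale(Y, scale = FALSE), ignore_attr = TRUE)

  X <- cbind(1, matrix(rnorm(20 * 3), 20, 3))
  R <- residualize(Y, X)
  expect_lt(max(abs(crossprod(X, R))), 1e-8 * max(abs(Y)))

  oracle <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  expect_equal(R, oracle, tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(residualize(Y, cbind(X, X[, 2])), "rank deficient")
})

test_that("scan statistics match an independent normal-equations oracle", {
  cfg <- sim_config(n_participants = 200, seed = 11,
                    n_features = c(area = 5, thickness = 5, volume = 5))
  st <- simulate_study(cfg, diseases = character(0))
  scan <- unique_effect_scan(st$participants, st$morphology, st$features,
                             "waist")
  # oracle: literal two-step with explicit solves
  data <- st$participants
  Y <- as.matrix(st$morphology[match(data$id, st$morphology$id), -1])
  others <- vapply(c("triglyceride", "hdl", "hba1c"),
                   function(cc) data[[cc]], numeric(nrow(data)))
  fl <- mets_flags(data)
  others <- cbind(others, hypertension = as.numeric(fl$flag_hypertension))
  X1 <- cbind(1, others)
  cov <- build_design(data, mets_covariates())
  X2 <- cbind(data$waist, cov)
  for (j in seq_len(ncol(Y))) {
    r1 <- Y[, j] - X1 %*% solve(crossprod(X1), crossprod(X1, Y[, j]))
    o <- oracle_ols(r1, X2, term = 1)
    expect_lt(abs(scan$beta[j] - o$beta) / abs(o$beta), 1e-8)
    expect_lt(abs(scan$se[j] - o$se) / o$se, 1e-8)
    expect_lt(abs(scan$t[j] - o$t) / abs(o$t), 1e-8)
    expect_identical(scan$df[j], o$df)
  }

  sev_scan <- severity_scan(st$participants, st$morphology, st$features)
  sev <- as.numeric(fl$severity)
  Xs <- cbind(sev, cov)
  for (j in seq_len(ncol(Y))) {
    o <- oracle_ols(Y[, j], Xs, term = 1)
    expect_lt(abs(sev_scan$t[j] - o$t) / max(abs(o$t), 1), 1e-8)
  }
})

test_that("two-step beta equals the full-model beta for an orthogonalized component", {
  cfg <- sim_config(n_participants = 300, seed = 12,
                    n_features = c(area = 4, thickness = 4, volume = 4))
  st <- simulate_study(cfg, diseases = character(0))
  data <- st$participants
  fl <- mets_flags(data)
  others <- cbind(
    triglyceride = data$triglyceride, hdl = data$hdl,
    hypertension = as.numeric(fl$flag_hypertension), hba1c = data$hba1c
  )
  cov <- build_design(data, mets_covariates())
  Z <- cbind(others, cov)
  # replace waist by its in-sample orthogonalization against everything else
  data$waist <- drop(data$waist - Z %*% solve(crossprod(Z), crossprod(Z, data$waist)))

  scan <- unique_effect_scan(data, st$morphology, st$features, "waist")
  Y <- as.matrix(st$morphology[match(data$id, st$morphology$id), -1])
  Xfull <- cbind(data$waist, others, cov)
  for (j in seq_len(ncol(Y))) {
    o <- oracle_ols(Y[, j], Xfull, term = 1)
    expect_lt(abs(scan$beta[j] - o$beta) / max(abs(o$beta), 1e-8), 1e-8)
  }
})

test_that("scan statistics are invariant to covariate rescaling and row order", {
  st <- fix_study()
  data <- st$study$participants
  ref <- unique_effect_scan(data, st$study$morphology, st$study$features,
                            "hba1c")
  data2 <- data
  data2$townsend <- data2$townsend * 10 + 5
  data2$brain_size <- data2$brain_size / 1000
  res2 <- unique_effect_scan(data2, st$study$morphology, st$study$features,
                             "hba1c")
  expect_equal(res2$t, ref$t, tolerance = 1e-8)

  perm <- sample(nrow(data))
  res3 <- unique_effect_scan(data[perm, ], st$study$morphology,
                             st$study$features, "hba1c")
  expect_equal(res3$t, ref$t, tolerance = 1e-8)
  expect_equal(res3$q, ref$q, tolerance = 1e-8)
})

test_that("under the planted null the t statistics follow Student's t", {
  sets <- lapply(setNames(metsage:::mets_components(),
                          metsage:::mets_components()),
                 function(x) integer(0))
  cfg <- sim_config(n_participants = 300, seed = 13, affected_sets = sets,
                    age_slopes = rep(0, 50),
                    n_features = c(area = 20, thickness = 20, volume = 10))
  st <- simulate_study(cfg, diseases = character(0))
  res <- unique_effect_scan(st$participants, st$morphology, st$features,
                            "triglyceride")
  ks <- suppressWarnings(ks.test(res$t, function(q) pt(q, df = res$df[1])))
  expect_lt(unname(ks$statistic), 0.2)  # 50 features; loose bound on D
  expect_lt(mean(res$p < 0.05), 0.2)
})

test_that("planted effects are recovered with correct sign at FDR 0.01", {
  sets <- list(waist = 41:60, triglyceride = integer(0), hdl = integer(0),
               hypertension = integer(0), hba1c = integer(0))
  cfg <- sim_config(n_participants = 2000, seed = 14, affected_sets = sets,
                    n_features = c(area = 40, thickness = 40, volume = 14))
  st <- simulate_study(cfg, diseases = character(0))
  res <- unique_effect_scan(st$participants, st$morphology, st$features,
                            "waist")
  hit <- res[41:60, ]  # planted thickness features
  expect_true(all(hit$beta < 0))
  expect_gte(mean(hit$q <= 0.01), 0.9)
})

test_that("BH adjustment handles the edge cases and orders q with p", {
  expect_identical(fdr_adjust(0.001, level = 0.01)$significant, TRUE)
  expect_identical(fdr_adjust(0.001, level = 0.01)$q, 0.001)
  expect_false(any(fdr_adjust(rep(1, 20))$significant))
  set.seed(1)
  p <- runif(200)
  adj <- fdr_adjust(p)
  expect_true(all(adj$q >= adj$p))
  ord <- order(p)
  expect_true(all(diff(adj$q[ord]) >= -1e-12))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("maxT adjustment is monotone and consistent for a single feature", {
  set.seed(2)
  n <- 60
  Y <- matrix(rnorm(n * 8), n, 8)
  Y[, 1] <- Y[, 1] + rnorm(n, sd = 0.1)
  x <- rnorm(n)
  Z <- matrix(1, n, 1)

  padj <- maxt_adjust(Y, x, Z, n_perm = 300, seed = 9)
  # same seed and n => identical permutation stream, so each feature's own
  # permutation p (from a single-feature family) bounds its maxT p from below
  own <- vapply(seq_len(8), function(j) {
    maxt_adjust(Y[, j, drop = FALSE], x, Z, n_perm = 300, seed = 9)
  }, numeric(1))
  expect_true(all(padj >= own - 1e-12))
  expect_identical(padj[1] >= own[1], TRUE)

  single <- maxt_adjust(Y[, 3, drop = FALSE], x, Z, n_perm = 300, seed = 9)
  expect_identical(single, own[3])

  expect_error(maxt_adjust(Y, x, Z, n_perm = 50), "at least 100")
})

test_that("constant predictors and undersized samples are rejected", {
  st <- fix_study()
  data <- st$study$participants[1:12, ]
  expect_error(
    unique_effect_scan(data, st$study$morphology, st$study$features, "waist"),
    "fewer participants|rank deficient"
  )
  data2 <- st$study$participants
  data2$waist <- 90
  expect_error(
    unique_effect_scan(data2, st$study$morphology, st$study$features, "waist"),
    "constant"
  )
  data3 <- st$study$participants
  data3$sbp <- 200; data3$dbp <- 100  # everyone flagged
  data3$med_bp <- TRUE
  expect_error(
    unique_effect_scan(data3, st$study$morphology, st$study$features,
                       "hypertension"),
    "constant"
  )
})
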