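test_that("the KS statistic equals the brute-force ECDF sup-difference", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5))$statistic,
               oracle_ks_d(c(1, 2, 3), c(1.5, 2.5)))
  set.seed(7)
  for (i in 1:100) {
    a <- rnorm(sample(3:12, 1))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_d(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(1, c(1, 2)), "at least 2")
})

test_that("D is invariant under strictly monotone transforms of both samples", {
  set.seed(8)
  a <- rnorm(40); b <- rnorm(35, 0.3)
  d0 <- ks_two_sample(a, b)$statistic
  expect_equal(ks_two_sample(exp(a), exp(b))$statistic, d0)
  expect_equal(ks_two_sample(a^3 + 2 * a, b^3 + 2 * b)$statistic, d0)
})

test_that("severity contrasts report adjacent shifts and per-level summaries", {
  set.seed(9)
  n <- 3000
  sev <- sample(0:5, n, TRUE, prob = c(0.2, 0.3, 0.25, 0.15, 0.07, 0.03))
  gaps <- tibble::tibble(
    id = as.character(1:n),
    gap_corrected = sev * 0.8 + rnorm(n)
  )
  sev_tab <- tibble::tibble(id = gaps$id, severity = sev)
  gc <- severity_gap_contrasts(gaps, sev_tab)
  expect_identical(nrow(gc), 5L)
  expect_true(all(gc$direction == "increasing"))
  lv <- attr(gc, "levels")
  expect_identical(lv$severity, 0:5)
  expect_true(all(diff(lv$mean_gap) > 0))
  expect_true(all(gc$q >= gc$p - 1e-12))

  # degenerate: everyone at severity 0
  sev0 <- tibble::tibble(id = gaps$id, severity = 0L)
  expect_message(gc0 <- severity_gap_contrasts(gaps, sev0), "skipping|no severity")
  expect_identical(nrow(gc0), 0L)
})

test_that("disease contrasts preserve a planted mean-gap ordering", {
  set.seed(10)
  mk <- function(n, mu, pre) tibble::tibble(
    id = paste0(pre, 1:n), gap_corrected = rnorm(n, mu, 2)
  )
  aging <- mk(2000, 0, "a")
  dis <- list(
    dementia = mk(500, 2.44, "d"), multiple_sclerosis = mk(500, 1.94, "m"),
    parkinson = mk(500, 1.28, "p"), stroke = mk(500, 0.47, "s")
  )
  gc <- disease_gap_contrasts(aging, dis)
  means <- setNames(gc$mean2, gc$group2)
  expect_true(means[["dementia"]] > means[["multiple_sclerosis"]])
  expect_true(means[["multiple_sclerosis"]] > means[["parkinson"]])
  expect_true(means[["parkinson"]] > means[["stroke"]])

  # a zero-offset "disease" drawn from the aging distribution is mostly null
  null_dis <- list(null = mk(500, 0, "n"))
  gcn <- disease_gap_contrasts(aging, null_dis)
  expect_lt(gcn$D, 0.1)
})

test_that("exact covariate duplicates are matched at zero distance", {
  treated <- manual_participants(30, seed = 20)
  pool <- treated
  pool$id <- paste0("c", seq_len(nrow(pool)))
  extra <- manual_participants(30, seed = 21)
  extra$id <- paste0("e", seq_len(nrow(extra)))
  pool <- dplyr::bind_rows(pool, extra)
  ms <- propensity_match(treated, pool, covariates = c("age", "townsend"))
  expect_identical(nrow(ms$pairs), 30L)
  expect_identical(ms$n_unmatched, 0L)
  expect_lt(max(ms$pairs$distance), 1e-8)
})

test_that("a zero caliper with no exact duplicates yields zero pairs", {
  treated <- manual_participants(20, seed = 22)
  pool <- manual_participants(40, seed = 23)
  pool$id <- paste0("c", seq_len(nrow(pool)))
  ms <- propensity_match(treated, pool, covariates = c("age", "townsend"),
                         caliper = 0)
  expect_identical(nrow(ms$pairs), 0L)
  expect_identical(ms$n_unmatched, 20L)
})

test_that("matching balances covariates drawn independently of group", {
  cfg <- sim_config(n_participants = 2000, seed = 24,
                    n_features = c(area = 2, thickness = 2, volume = 2))
  all <- simulate_participants(cfg)
  treated <- all[1:500, ]
  pool <- all[501:2000, ]
  ms <- propensity_match(treated, pool)
  bal <- match_balance(ms, treated, pool)
  expect_true(all(abs(bal$smd_after) < 0.1))
  expect_identical(nrow(ms$pairs), 500L)
})

test_that("matching is deterministic", {
  treated <- manual_participants(25, seed = 25)
  pool <- manual_participants(60, seed = 26)
  pool$id <- paste0("c", seq_len(nrow(pool)))
  m1 <- propensity_match(treated, pool)
  m2 <- propensity_match(treated, pool)
  expect_identical(m1$pairs, m2$pairs)
})

test_that("matched t-tests match the closed-form pooled statistic", {
  set.seed(11)
  n <- 200
  treated <- tibble::tibble(id = paste0("t", 1:n), v = rnorm(n, 0.4))
  control <- tibble::tibble(id = paste0("c", 1:n), v = rnorm(n))
  ms <- list(pairs = tibble::tibble(treated_id = treated$id,
                                    control_id = control$id,
                                    distance = 0))
  class(ms) <- "match_set"
  data <- dplyr::bind_rows(treated, control)
  res <- matched_t_test(ms, data, "v")
  xt <- treated$v; xc <- control$v
  sp <- sqrt(((n - 1) * var(xt) + (n - 1) * var(xc)) / (2 * n - 2))
  t_oracle <- (mean(xt) - mean(xc)) / (sp * sqrt(2 / n))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)

  # identical matched groups: no difference
  same <- matched_t_test(ms, dplyr::bind_rows(
    treated, dplyr::mutate(treated, id = paste0("c", 1:n))
  ), "v")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("a planted severity shift is detected in matched groups", {
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 300
    tr <- tibble::tibble(id = paste0("t", 1:n), sev = rnorm(n, 0.5))
    ct <- tibble::tibble(id = paste0("c", 1:n), sev = rnorm(n))
    ms <- structure(list(pairs = tibble::tibble(
      treated_id = tr$id, control_id = ct$id, distance = 0
    )), class = "match_set")
    matched_t_test(ms, dplyr::bind_rows(tr, ct), "sev")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
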