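# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

# Small default-structure study reused by several test files.
fix_study <- function() {
  if (is.null(.fix$study)) {
    .fix$cfg <- sim_config(
      n_participants = 400, seed = 42,
      n_features = c(area = 10, thickness = 10, volume = 6),
      disease_n = c(stroke = 80, dementia = 40, parkinson = 40,
                    multiple_sclerosis = 40)
    )
    .fix$study <- simulate_study(.fix$cfg)
  }
  list(cfg = .fix$cfg, study = .fix$study)
}

# A participant table with hand-set MetS values appended to simulated
# covariates (so design building works).
manual_participants <- function(n = 4, seed = 5) {
  cfg <- sim_config(n_participants = max(n, 2), seed = seed,
                    n_features = c(area = 2, thickness = 2, volume = 2))
  simulate_participants(cfg)[seq_len(n), ]
}

# Independent normal-equations OLS giving beta/se/t/p for one term.
oracle_ols <- function(y, X, term) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * solve(XtX)[term, term])
  t <- beta[term] / se
  list(beta = beta[term], se = se, t = t, p = 2 * pt(-abs(t), df), df = df)
}

# Brute-force two-sample KS statistic: sup over all pooled breakpoints.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}
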