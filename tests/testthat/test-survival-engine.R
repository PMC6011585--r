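test_that("one-covariate fit matches grid + golden-section maximisation", {
  time <- 1:6
  status <- rep(1, 6)
  x <- cbind(z = c(1, 0, 1, 0, 1, 0))
  fit <- fit_cox(time, status, x)
  # coarse grid then golden-section refinement on the explicit likelihood
  grid <- seq(-4, 4, by = 0.01)
  ll <- vapply(grid, function(b) naive_cox_loglik(b, time, status, x),
               numeric(1))
  lo <- grid[which.max(ll)] - 0.02
  hi <- grid[which.max(ll)] + 0.02
  phi <- (sqrt(5) - 1) / 2
  for (i in 1:60) {
    m1 <- hi - phi * (hi - lo)
    m2 <- lo + phi * (hi - lo)
    if (naive_cox_loglik(m1, time, status, x) <
        naive_cox_loglik(m2, time, status, x)) lo <- m1 else hi <- m2
  }
  expect_lt(abs(fit$coefficients[[1]] - (lo + hi) / 2), 1e-4)
  expect_equal(fit$loglik[2],
               naive_cox_loglik(fit$coefficients, time, status, x))
})

test_that("degenerate designs raise informative errors", {
  time <- 1:6; status <- rep(1, 6)
  expect_error(fit_cox(time, status, cbind(const = rep(2, 6))),
               "constant column 'const'")
  expect_error(fit_cox(time, status,
                       cbind(a = c(1, 0, 1, 0, 1, 0),
                             b = c(2, 0, 2, 0, 2, 0))),
               "collinear")
  expect_error(fit_cox(time, rep(0, 6), cbind(a = rnorm(6))),
               "zero events")
  expect_error(fit_cox(c(-1, 1:5), status, cbind(a = rnorm(6))),
               "strictly positive")
})

test_that("permuted covariates give near-zero coefficients", {
  n <- 2000
  z_excess <- 0L
  reps <- 100
  for (k in seq_len(reps)) {
    set.seed(derive_seed(11, k))
    t <- rexp(n, 0.1)
    s <- as.integer(t <= 12)
    t <- pmin(t, 12)
    x <- cbind(perm = sample(rnorm(n)))   # independent of outcome
    fit <- fit_cox(t, s, x)
    z <- fit$summary_table$z[1]
    if (abs(z) >= 4) z_excess <- z_excess + 1L
  }
  expect_lte(z_excess, reps * 0.01)
})

test_that("score vector vanishes at the fitted coefficients", {
  for (k in 1:5) {
    set.seed(derive_seed(3, k))
    n <- 120
    x <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
    t <- rexp(n, 0.08 * exp(0.4 * x[, 1] - 0.3 * x[, 2]))
    s <- as.integer(t <= 15); t <- pmin(t, 15)
    for (tm in c("breslow", "efron")) {
      fit <- fit_cox(t, s, x, tie_method = tm)
      xc <- sweep(x, 2, colMeans(x))
      g <- epimort:::cox_pl(fit$coefficients, t, s, xc, tm)$grad
      expect_lt(max(abs(g)), 1e-6)
    }
  }
})

test_that("Breslow and Efron agree on tie-free data", {
  set.seed(2)
  n <- 150
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  t <- rexp(n, 0.1 * exp(0.5 * x[, 1]))
  s <- as.integer(t <= 10); t <- pmin(t, 10 + runif(n) * 1e-6)
  stopifnot(!anyDuplicated(t[s == 1]))
  fb <- fit_cox(t, s, x, tie_method = "breslow")
  fe <- fit_cox(t, s, x, tie_method = "efron")
  expect_lt(max(abs(fb$coefficients - fe$coefficients)), 1e-10)
  expect_lt(abs(fb$loglik[2] - fe$loglik[2]), 1e-10)
})

test_that("coefficients match the established implementation on random data", {
  skip_if_not_installed("survival")
  for (k in 1:50) {
    set.seed(derive_seed(29, k))
    n <- sample(40:120, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    beta <- runif(p, -0.7, 0.7)
    t <- rexp(n, 0.1 * exp(drop(x %*% beta)))
    if (k %% 2 == 0) t <- ceiling(t * 3)  # induce ties on half the cases
    s <- rbinom(n, 1, 0.8)
    if (sum(s) < 2) s[1:2] <- 1
    tm <- if (k %% 2 == 0) "efron" else "breslow"
    ours <- fit_cox(t, s, x, tie_method = tm)
    ref <- survival::coxph(survival::Surv(t, s) ~ x, ties = tm)
    expect_lt(max(abs(ours$coefficients - unname(coef(ref)))), 1e-6)
    expect_lt(max(abs(ours$var - unname(vcov(ref)))), 1e-6)
  }
})

test_that("Breslow baseline matches hand-evaluated risk sums", {
  # null model: 1 event at t=1 with 2 at risk -> increment 1/2
  b0 <- breslow_baseline(fit_cox(c(1, 2), c(1, 1), matrix(0, 2, 0)),
                         c(1, 2), c(1, 1), matrix(0, 2, 0))
  expect_equal(b0$hazard[1], 0.5)
  expect_equal(b0$cumhaz, c(0.5, 1.5))

  # 4-subject worked example with one binary covariate
  t <- c(1, 2, 3, 4); s <- c(1, 1, 0, 1); x <- cbind(z = c(1, 0, 1, 0))
  fit <- fit_cox(t, s, x)
  b <- breslow_baseline(fit, t, s, x)
  ez <- exp(fit$coefficients[[1]])
  expect_equal(b$hazard,
               c(1 / (2 * ez + 2), 1 / (ez + 2), 1 / 1), tolerance = 1e-12)
  expect_true(all(diff(b$cumhaz) >= 0))

  set.seed(6)
  n <- 80
  x2 <- cbind(a = rnorm(n))
  t2 <- rexp(n, 0.2); s2 <- rbinom(n, 1, 0.7); s2[1] <- 1
  f2 <- fit_cox(t2, s2, x2)
  b2 <- breslow_baseline(f2, t2, s2, x2)
  expect_true(all(diff(b2$cumhaz) >= 0))
  expect_error(breslow_baseline(f2, t2, s2, cbind(x2, x2)), "columns")
})

test_that("Kaplan-Meier follows the hand-applied product-limit formula", {
  km0 <- kaplan_meier(c(2, 4, 6), c(0, 0, 0))
  expect_equal(km0$survival, 1)
  expect_equal(km0$time, 0)

  # times 1+, 2, 3+, 4: drop to 2/3 at t=2, to 0 at t=4
  km <- kaplan_meier(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(km$time, c(0, 2, 4))
  expect_equal(km$survival, c(1, 2 / 3, 0))

  set.seed(10)
  t <- rexp(60, 0.3); s <- rbinom(60, 1, 0.6)
  km2 <- kaplan_meier(pmax(t, 1e-3), s)
  expect_equal(km2$survival[1], 1)
  expect_true(all(diff(km2$survival) <= 0))
  expect_true(all(km2$survival >= 0 & km2$survival <= 1))
})

test_that("log-rank statistic matches the per-event-time hypergeometric oracle", {
  t <- c(1, 2, 3, 4, 5, 6, 7, 8)
  s <- c(1, 1, 1, 0, 1, 1, 0, 1)
  g <- c("a", "b", "a", "b", "a", "b", "a", "b")
  res <- log_rank(t, s, g)
  # oracle: sum O-E and hypergeometric variance over event times
  OmE <- 0; V <- 0
  for (u in sort(unique(t[s == 1]))) {
    risk <- t >= u
    nj <- sum(risk); n1 <- sum(risk & g == "a")
    dj <- sum(t == u & s == 1); d1 <- sum(t == u & s == 1 & g == "a")
    OmE <- OmE + d1 - dj * n1 / nj
    if (nj > 1) V <- V + dj * (nj - dj) / (nj - 1) * n1 / nj * (1 - n1 / nj)
  }
  expect_equal(res$statistic, OmE^2 / V, tolerance = 1e-12)
  expect_equal(res$df, 1L)

  # identical groups -> statistic 0, p 1
  res0 <- log_rank(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                   rep(c("x", "y"), each = 3))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  expect_error(log_rank(1:3, c(1, 1, 1), rep("a", 3)), "two groups")
})

test_that("coefficient sign agrees with log-rank observed-minus-expected", {
  for (k in 1:10) {
    set.seed(derive_seed(41, k))
    n <- 60
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1 * exp(runif(1, -1, 1) * x)) + runif(n) * 1e-9
    s <- as.integer(t <= 12); t <- pmin(t, 12 + runif(n) * 1e-9)
    if (sum(s) < 5 || length(unique(x[s == 1])) < 2) next
    fit <- fit_cox(t, s, cbind(x = x))
    OmE <- 0
    for (u in sort(unique(t[s == 1]))) {
      risk <- t >= u
      OmE <- OmE + sum(t == u & s == 1 & x == 1) -
        sum(t == u & s == 1) * sum(risk & x == 1) / sum(risk)
    }
    expect_equal(sign(fit$coefficients[[1]]), sign(OmE))
  }
})

test_that("direct-adjusted curves reduce to and extend the baseline correctly", {
  set.seed(20)
  n <- 40
  t <- rexp(n, 0.2); s <- rbinom(n, 1, 0.7); s[1:2] <- 1
  # single group, no covariates: exactly exp(-Breslow cumulative hazard)
  cv <- direct_adjusted_curves(t, s, rep("all", n))
  nullfit <- fit_cox(t, s, matrix(0, n, 0))
  H <- breslow_baseline(nullfit, t, s, matrix(0, n, 0))
  expect_equal(cv$survival, c(1, exp(-H$cumhaz)), tolerance = 1e-12)
  expect_equal(cv$survival[cv$time == 0], 1)

  # 6-subject, 2-group, one-covariate hand-expanded averaging oracle
  t6 <- c(1, 2, 3, 4, 5, 6); s6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- c("A", "B", "A", "B", "A", "B")
  z6 <- c(0.2, -0.1, 0.4, 0, -0.3, 0.1)
  cv6 <- direct_adjusted_curves(t6, s6, g6, cbind(z = z6))
  fit <- attr(cv6, "fit")
  bg <- fit$coefficients[["group_B"]]
  bz <- fit$coefficients[["z"]]
  H0 <- breslow_baseline(fit, t6, s6,
                         cbind(group_B = as.numeric(g6 == "B"), z = z6))
  for (gi in c("A", "B")) {
    for (ti in seq_along(H0$time)) {
      manual <- mean(vapply(1:6, function(i)
        exp(-H0$cumhaz[ti] *
              exp(bz * z6[i] + if (gi == "B") bg else 0)), numeric(1)))
      got <- cv6$survival[cv6$group == gi][ti + 1L]
      expect_equal(got, manual, tolerance = 1e-12)
    }
  }
  expect_true(all(cv6$survival >= 0 & cv6$survival <= 1))
  for (gi in c("A", "B"))
    expect_true(all(diff(cv6$survival[cv6$group == gi]) <= 0))
})
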