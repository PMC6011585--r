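# Independent oracles: naive, loop-based reimplementations kept free of
# the package's own computational paths.

# explicit Cox partial log-likelihood (naive risk-set loops)
naive_cox_loglik <- function(beta, time, status, x, ties = "breslow") {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (ut in unique(time[status == 1])) {
    D <- which(time == ut & status == 1)
    R <- which(time >= ut)
    d <- length(D)
    ll <- ll + sum(eta[D])
    if (ties == "breslow") {
      ll <- ll - d * log(sum(exp(eta[R])))
    } else {
      for (l in seq_len(d) - 1)
        ll <- ll - log(sum(exp(eta[R])) - l / d * sum(exp(eta[D])))
    }
  }
  ll
}

# brute-force per-sample aberration flag count
brute_force_ms <- function(betas, cuts, directions) {
  vapply(seq_len(nrow(betas)), function(i) {
    s <- 0L
    for (pr in names(cuts)) {
      v <- betas[i, pr]
      if (is.na(v)) return(NA_integer_)
      hit <- if (directions[[pr]] == "high_tail") v >= cuts[[pr]]
             else v <= cuts[[pr]]
      s <- s + as.integer(hit)
    }
    s
  }, integer(1))
}

# type-7 percentile by explicit sort-and-interpolate
sort_interp_percentile <- function(v, p) {
  v <- sort(v[!is.na(v)])
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# small test cohort with exposures attached
make_test_cohort <- function(n = 400, seed = 42, ...) {
  g <- generate_cohort(generator_config(n_participants = n, seed = seed,
                                        missingness_rates = numeric(0), ...))
  attach_exposures(g$cohort, g$betas)
}

# seeds kept below 2^31 when derived from another integer
derive_seed <- function(seed, k) (seed * 7919L + k * 104729L) %% 2147483647L
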