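#' Kaplan-Meier product-limit survival curve
#'
#' @param time Positive follow-up times.
#' @param status Event indicator (1 = death, 0 = censored).
#' @param group Optional single label attached to the curve.
#' @return Data frame with columns `time` (starting at 0), `survival`
#'   (nonincreasing, 1 at time 0), `n_risk`, `n_event`, and `group`.
#' @export
kaplan_meier <- function(time, status, group = NA_character_) {
  stopifnot(length(time) == length(status), all(time > 0),
            all(status %in% c(0, 1)))
  ord <- order(time)
  t_s <- time[ord]; d_s <- status[ord]
  utimes <- unique(t_s[d_s == 1])
  n <- length(t_s)
  n_risk <- vapply(utimes, function(u) sum(t_s >= u), numeric(1))
  n_event <- vapply(utimes, function(u) sum(t_s == u & d_s == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = c(0, utimes), survival = c(1, surv),
             n_risk = c(n, n_risk), n_event = c(0, n_event),
             group = group, stringsAsFactors = FALSE)
}

#' Log-rank test for equality of survival across groups
#'
#' Standard observed-minus-expected chi-square: at each event time the
#' expected deaths per group follow the hypergeometric law on the risk
#' set; the statistic is the quadratic form of (O - E) over the first
#' k - 1 groups with the summed hypergeometric covariance.
#'
#' @param time,status As in [kaplan_meier()].
#' @param group Group labels (>= 2 non-empty groups).
#' @return List with `statistic`, `df` (= groups - 1) and `p` (upper-tail
#'   chi-square).
#' @export
log_rank <- function(time, status, group) {
  stopifnot(length(time) == length(status), length(group) == length(time))
  g <- factor(group)
  k <- nlevels(g)
  if (k < 2L) stop("log-rank test needs at least two groups")
  utimes <- sort(unique(time[status == 1]))
  OmE <- numeric(k)
  V <- matrix(0, k, k)
  for (u in utimes) {
    at_risk <- time >= u
    nj <- sum(at_risk)
    dying <- time == u & status == 1
    dj <- sum(dying)
    n_g <- tabulate(g[at_risk], k)
    d_g <- tabulate(g[dying], k)
    e_g <- dj * n_g / nj
    OmE <- OmE + d_g - e_g
    if (nj > 1) {
      fac <- dj * (nj - dj) / (nj - 1)
      V <- V + fac * (diag(n_g, k) / nj - outer(n_g, n_g) / nj^2)
    }
  }
  idx <- seq_len(k - 1L)
  Vi <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(
    drop(t(OmE[idx]) %*% solve(Vi, OmE[idx])),
    error = function(e) {
      drop(t(OmE[idx]) %*% MASS_ginv(Vi) %*% OmE[idx])
    })
  list(statistic = stat, df = k - 1L,
       p = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

# Moore-Penrose pseudo-inverse via SVD (degenerate log-rank variance only)
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Direct-adjusted (corrected group prognosis) survival curves
#'
#' Fits one proportional-hazards model on group indicator dummies plus
#' the adjustment covariates, then for each group g averages the
#' model-predicted individual survival `exp(-H0(t) exp(lp_i(g)))` over
#' ALL subjects i with group membership forced to g. With no adjustment
#' covariates and a single group the curve reduces exactly to
#' `exp(-Breslow cumulative hazard)`.
#'
#' @param time,status Survival outcome.
#' @param group Factor (or coercible) of group membership.
#' @param covariates Optional numeric matrix of adjustment covariates.
#' @param tie_method Passed to [fit_cox()].
#' @return Data frame with columns `group`, `time` (0 plus event times)
#'   and `survival`; attribute `"fit"` carries the underlying model.
#' @export
direct_adjusted_curves <- function(time, status, group, covariates = NULL,
                                   tie_method = "breslow") {
  g <- factor(group)
  k <- nlevels(g)
  n <- length(time)
  dummies <- if (k > 1L) {
    m <- matrix(0, n, k - 1L,
                dimnames = list(NULL, paste0("group_", levels(g)[-1L])))
    for (j in 2:k) m[g == levels(g)[j], j - 1L] <- 1
    m
  } else matrix(0, n, 0L)
  covariates <- if (is.null(covariates)) matrix(0, n, 0L)
                else as.matrix(covariates)
  X <- cbind(dummies, covariates)
  fit <- fit_cox(time, status, X, tie_method = tie_method)
  base <- breslow_baseline(fit, time, status, X)
  H0 <- c(0, base$cumhaz)
  tgrid <- c(0, base$time)
  beta <- fit$coefficients
  bg <- beta[seq_len(ncol(dummies))]
  bc <- beta[seq_len(ncol(covariates)) + ncol(dummies)]
  lp_cov <- if (ncol(covariates)) drop(covariates %*% bc) else numeric(n)
  out <- lapply(seq_len(k), function(j) {
    lp <- lp_cov + if (j > 1L) bg[j - 1L] else 0
    surv <- vapply(H0, function(h) mean(exp(-h * exp(lp))), numeric(1))
    data.frame(group = levels(g)[j], time = tgrid, survival = surv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "fit") <- fit
  res
}
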