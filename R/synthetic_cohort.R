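#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter set from which [generate_cohort()] simulates a
#' cohort of older adults with serum 25(OH)D concentrations, the 10-CpG
#' methylation panel, baseline covariates, and proportional-hazards
#' survival under administrative censoring. Defaults emulate the
#' population-based cohort the analyses were designed for: ~15/43/41%
#' vitamin D deficiency/insufficiency/sufficiency, ~41/46/13% low/
#' moderate/high MS levels, ~25% deaths over a ~15.5-year window and
#' median follow-up ~15 years.
#'
#' @param n_participants Cohort size (default 1467, the emulated
#'   analysis sample).
#' @param seed Integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @param vitd_lognormal_params `c(mu, sigma)` of log 25(OH)D (nmol/L).
#' @param season_amplitude Amplitude (nmol/L) of the summer-peaking
#'   cosine added to 25(OH)D by blood-draw month.
#' @param beta_dist_params 10 x 2 matrix (rows = panel probes) of Beta
#'   shape parameters for the marginal beta-value distributions.
#' @param cpg_correlation Pairwise correlation in \[0, 1) of the latent
#'   risk scores behind the 10 beta values.
#' @param true_log_hr_vitd `c(insufficiency, deficiency)` log hazard
#'   ratios vs sufficiency.
#' @param true_log_hr_ms `c(moderate, high)` log hazard ratios vs low
#'   MS level (used when `ms_effect_form = "level"`).
#' @param ms_effect_form `"level"` (categorised risk level enters the
#'   hazard) or `"ordinal"` (per-point effect, for dose-response tests).
#' @param true_log_hr_ms_ordinal Per-score-point log-HR when
#'   `ms_effect_form = "ordinal"`.
#' @param covariate_log_hrs Named log-HRs for covariate signals (see
#'   [cohort_signal()] for recognised names); may be empty.
#' @param baseline_hazard `c(shape, scale)` of the Weibull event-time
#'   baseline (years).
#' @param accrual_years Uniform recruitment window length.
#' @param admin_censor_years Time from study start to the administrative
#'   cut-off.
#' @param missingness_rates Named fractions in \[0, 1) applied by
#'   [inject_missingness()] after generation; defaults mirror the
#'   published per-covariate missing counts. Use an empty vector for a
#'   complete cohort.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 1467L,
                             seed = 1L,
                             vitd_lognormal_params = c(mu = 3.83, sigma = 0.41),
                             season_amplitude = 6,
                             beta_dist_params = default_beta_params(),
                             cpg_correlation = 0.33,
                             true_log_hr_vitd = c(insufficiency = log(1.46),
                                                  deficiency = log(1.99)),
                             true_log_hr_ms = c(moderate = log(1.87),
                                                high = log(3.42)),
                             ms_effect_form = c("level", "ordinal"),
                             true_log_hr_ms_ordinal = log(1.2),
                             covariate_log_hrs = numeric(0),
                             baseline_hazard = c(shape = 1.4, scale = 65),
                             accrual_years = 0.7,
                             admin_censor_years = 15.5,
                             missingness_rates = default_missingness_rates()) {
  ms_effect_form <- match.arg(ms_effect_form)
  cfg <- list(n_participants = as.integer(n_participants), seed = as.integer(seed),
              vitd_lognormal_params = vitd_lognormal_params,
              season_amplitude = season_amplitude,
              beta_dist_params = beta_dist_params,
              cpg_correlation = cpg_correlation,
              true_log_hr_vitd = true_log_hr_vitd,
              true_log_hr_ms = true_log_hr_ms,
              ms_effect_form = ms_effect_form,
              true_log_hr_ms_ordinal = true_log_hr_ms_ordinal,
              covariate_log_hrs = covariate_log_hrs,
              baseline_hazard = baseline_hazard,
              accrual_years = accrual_years,
              admin_censor_years = admin_censor_years,
              missingness_rates = missingness_rates)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

default_beta_params <- function() {
  # hypomethylation-aberrant probes centred high; cg08362785 centred low
  m <- matrix(rep(c(12, 4), each = 10), ncol = 2,
              dimnames = list(unname(ms_panel()), c("a", "b")))
  m["cg08362785", ] <- c(4, 9)
  m
}

default_missingness_rates <- function() {
  c(bmi_class = 3, alcohol_g_day = 106, prevalent_diabetes = 16,
    sbp_mmhg = 27, crp_mg_l = 30, cholesterol_mg_dl = 2,
    vit_supplement = 62, fish_gt1_week = 56) / 1467
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_participants < 0L) stop("configuration error: n_participants < 0")
    if (vitd_lognormal_params[[2]] <= 0)
      stop("configuration error: sigma of log 25(OH)D must be > 0")
    if (any(beta_dist_params <= 0))
      stop("configuration error: Beta shape parameters must be > 0")
    if (!setequal(rownames(beta_dist_params), ms_panel()))
      stop("configuration error: beta_dist_params rows must be the panel probes")
    if (cpg_correlation < 0 || cpg_correlation >= 1)
      stop("configuration error: cpg_correlation must be in [0, 1)")
    if (any(baseline_hazard <= 0))
      stop("configuration error: Weibull shape/scale must be > 0")
    if (accrual_years < 0 || admin_censor_years <= accrual_years)
      stop("configuration error: need admin_censor_years > accrual_years >= 0")
    if (length(missingness_rates) &&
        (any(missingness_rates < 0) || any(missingness_rates >= 1)))
      stop("configuration error: missingness rates must be in [0, 1)")
  })
  invisible(cfg)
}

month_to_season <- function(month) {
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")
  factor(s[month], levels = c("spring", "summer", "autumn", "winter"))
}

alcohol_category <- function(g_day, sex) {
  # sex-specific cut-offs: low (women 0-<20, men 0-<40),
  # intermediate (20-<40 / 40-<60), high (>= 40 / >= 60)
  lo <- ifelse(sex == "male", 40, 20)
  hi <- ifelse(sex == "male", 60, 40)
  out <- rep(NA_character_, length(g_day))
  out[g_day == 0] <- "abstainer"
  out[g_day > 0 & g_day < lo] <- "low"
  out[g_day >= lo & g_day < hi] <- "intermediate"
  out[g_day >= hi] <- "high"
  factor(out, levels = c("abstainer", "low", "intermediate", "high"))
}

yn <- function(x) factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))

leukocyte_types <- function() c("CD4T", "CD8T", "B", "NK", "mono", "gran")

#' Numeric hazard signal for a named covariate
#'
#' Maps a covariate name used in `covariate_log_hrs` to the numeric
#' signal that multiplies its log-HR in the generator's linear
#' predictor. Binary/dummy names give 0/1 indicators; continuous names
#' are centred at their generator means so nonzero effects do not shift
#' the baseline death rate.
#'
#' Recognised names: `age`, `sex_male`, `smoking_current`,
#' `smoking_former`, `bmi_overweight`, `bmi_obese`, `physical_low`,
#' `physical_inactive`, `prevalent_cvd`, `prevalent_diabetes`,
#' `prevalent_cancer`, `vit_supplement`, `fish_gt1_week`,
#' `alcohol_g_day`, `sbp_mmhg`, `crp_mg_l`, `cholesterol_mg_dl`.
#'
#' @param cohort A cohort table.
#' @param name One recognised covariate-signal name.
#' @return Numeric vector, one value per participant.
#' @export
cohort_signal <- function(cohort, name) {
  sig <- switch(name,
    age = cohort$age - 62,
    sex_male = as.numeric(cohort$sex == "male"),
    smoking_current = as.numeric(cohort$smoking == "current"),
    smoking_former = as.numeric(cohort$smoking == "former"),
    bmi_overweight = as.numeric(cohort$bmi_class == "overweight"),
    bmi_obese = as.numeric(cohort$bmi_class == "obese"),
    physical_low = as.numeric(cohort$physical_activity == "low"),
    physical_inactive = as.numeric(cohort$physical_activity == "inactive"),
    prevalent_cvd = as.numeric(cohort$prevalent_cvd == "yes"),
    prevalent_diabetes = as.numeric(cohort$prevalent_diabetes == "yes"),
    prevalent_cancer = as.numeric(cohort$prevalent_cancer == "yes"),
    vit_supplement = as.numeric(cohort$vit_supplement == "yes"),
    fish_gt1_week = as.numeric(cohort$fish_gt1_week == "yes"),
    alcohol_g_day = cohort$alcohol_g_day,
    sbp_mmhg = cohort$sbp_mmhg - 140,
    crp_mg_l = cohort$crp_mg_l - 3.7,
    cholesterol_mg_dl = cohort$cholesterol_mg_dl - 183.5,
    stop("unknown covariate signal '", name, "'"))
  sig
}

#' Generate a synthetic cohort with methylation panel and survival
#'
#' Draws covariates, blood-draw month, leukocyte proportions, seasonal
#' 25(OH)D, and correlated beta values for the 10 MS panel probes (a
#' shared latent risk score per subject plus probe-specific noise,
#' mapped through per-probe Beta quantile transforms, oriented so that
#' aberration of all probes is positively associated). Event times come
#' from a Weibull baseline scaled by `exp(linear predictor)` built from
#' the subject's TRUE vitamin D category, TRUE MS level (scored from the
#' generated betas via [compute_ms()]) and any configured covariate
#' effects; censoring is administrative given uniform accrual.
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (data frame, one row per participant; the
#'   six leukocyte proportions sum to 1) and `betas` (n x 10 matrix).
#'   The attribute `"truth"` on `cohort` records the true linear
#'   predictor and exposure categories before any missingness.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n_participants
  out <- with_preserved_seed(config$seed, {
    id <- sprintf("S%05d", seq_len(n))
    age <- pmin(pmax(stats::rnorm(n, 62.1, 6.5), 50), 75)
    sex <- factor(sample(c("female", "male"), n, TRUE, c(0.548, 0.452)),
                  levels = c("female", "male"))
    smoking <- factor(sample(c("never", "former", "current"), n, TRUE,
                             c(0.483, 0.333, 0.185)),
                      levels = c("never", "former", "current"))
    bmi_class <- factor(sample(c("under_or_normal", "overweight", "obese"),
                               n, TRUE, c(0.271, 0.462, 0.266)),
                        levels = c("under_or_normal", "overweight", "obese"))
    drinks <- stats::runif(n) > 0.318
    alcohol_g_day <- ifelse(drinks,
                            stats::rgamma(n, shape = 1.5,
                                          scale = ifelse(sex == "male", 12, 5)),
                            0)
    physical_activity <- factor(sample(c("medium_or_high", "low", "inactive"),
                                       n, TRUE, c(0.342, 0.459, 0.200)),
                                levels = c("medium_or_high", "low", "inactive"))
    prevalent_cvd <- yn(stats::runif(n) < 0.211)
    prevalent_diabetes <- yn(stats::runif(n) < 0.155)
    prevalent_cancer <- yn(stats::runif(n) < 0.059)
    sbp_mmhg <- stats::rnorm(n, 139.9, 19.8)
    crp_mg_l <- stats::rlnorm(n, meanlog = 0.7, sdlog = 1.05)
    cholesterol_mg_dl <- stats::rnorm(n, 183.5, 60.2)
    vit_supplement <- yn(stats::runif(n) < 0.384)
    fish_gt1_week <- yn(stats::runif(n) < 0.631)
    blood_draw_month <- sample(1:12, n, TRUE)
    season <- month_to_season(blood_draw_month)

    # leukocyte composition: Dirichlet around adult whole-blood means
    lmeans <- c(CD4T = 0.17, CD8T = 0.10, B = 0.06, NK = 0.07,
                mono = 0.08, gran = 0.52)
    lk <- vapply(lmeans * 120, function(sh) stats::rgamma(n, shape = sh),
                 numeric(n))
    if (n == 1L) lk <- matrix(lk, nrow = 1L,
                              dimnames = list(NULL, names(lmeans)))
    lk <- lk / rowSums(lk)
    colnames(lk) <- paste0("leuko_", leukocyte_types())

    vitd <- pmax(stats::rlnorm(n, config$vitd_lognormal_params[[1]],
                               config$vitd_lognormal_params[[2]]) +
                 config$season_amplitude * cospi((blood_draw_month - 7) / 6),
                 0.5)

    # correlated latent risk -> per-probe Beta quantile transform
    rho <- config$cpg_correlation
    shared <- stats::rnorm(n)
    probes <- unname(ms_panel())
    dirs <- ms_panel_directions()
    betas <- matrix(NA_real_, n, 10L, dimnames = list(id, probes))
    for (j in seq_along(probes)) {
      z <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
      u <- if (dirs[[probes[j]]] == "high_tail") stats::pnorm(z)
           else stats::pnorm(-z)
      ab <- config$beta_dist_params[probes[j], ]
      betas[, j] <- stats::qbeta(u, ab[[1]], ab[[2]])
    }

    ms <- if (n >= 4L) compute_ms(betas) else
      data.frame(sample_id = id, score = rep(NA_integer_, n),
                 level = classify_ms(rep(NA_integer_, n), allow_na = TRUE),
                 stringsAsFactors = FALSE)

    vitd_cat <- classify_vitd(vitd)
    lp <- numeric(n)
    lp <- lp + config$true_log_hr_vitd[["insufficiency"]] *
      (vitd_cat == "insufficiency") +
      config$true_log_hr_vitd[["deficiency"]] * (vitd_cat == "deficiency")
    if (config$ms_effect_form == "level") {
      lp <- lp + config$true_log_hr_ms[["moderate"]] * (ms$level == "moderate") +
        config$true_log_hr_ms[["high"]] * (ms$level == "high")
    } else {
      lp <- lp + config$true_log_hr_ms_ordinal * ms$score
    }

    cohort <- data.frame(id = id, age = age, sex = sex, smoking = smoking,
                         bmi_class = bmi_class,
                         alcohol_g_day = alcohol_g_day,
                         alcohol_cat = alcohol_category(alcohol_g_day, sex),
                         physical_activity = physical_activity,
                         prevalent_cvd = prevalent_cvd,
                         prevalent_diabetes = prevalent_diabetes,
                         prevalent_cancer = prevalent_cancer,
                         sbp_mmhg = sbp_mmhg, crp_mg_l = crp_mg_l,
                         cholesterol_mg_dl = cholesterol_mg_dl,
                         vit_supplement = vit_supplement,
                         fish_gt1_week = fish_gt1_week,
                         blood_draw_month = blood_draw_month,
                         season = season, lk,
                         vitd_nmol_l = vitd,
                         stringsAsFactors = FALSE)
    for (nm in names(config$covariate_log_hrs))
      lp <- lp + config$covariate_log_hrs[[nm]] * cohort_signal(cohort, nm)

    shape <- config$baseline_hazard[[1]]
    scl <- config$baseline_hazard[[2]]
    event_time <- scl * (-log(stats::runif(n)) / exp(lp))^(1 / shape)
    entry <- stats::runif(n, 0, config$accrual_years)
    censor_time <- config$admin_censor_years - entry
    cohort$follow_up_years <- pmin(event_time, censor_time)
    cohort$event <- as.integer(event_time <= censor_time)

    if (length(config$missingness_rates))
      cohort <- inject_missingness(cohort, config$missingness_rates)

    attr(cohort, "truth") <- list(lp = lp, vitd_cat = vitd_cat,
                                  ms_score = ms$score, ms_level = ms$level)
    list(cohort = cohort, betas = betas)
  })
  out
}

# run expr under a local seed without clobbering the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mask covariates completely at random
#'
#' Independently sets each named covariate to missing with its rate.
#' Outcome (`follow_up_years`, `event`), identifier and exposure
#' (`vitd_nmol_l`) columns are never maskable. Masking `alcohol_g_day`
#' also masks the derived `alcohol_cat` for the same rows, keeping the
#' two consistent.
#'
#' @param cohort A cohort data frame.
#' @param rates Named fractions in \[0, 1).
#' @return The cohort with missing values injected.
#' @export
inject_missingness <- function(cohort, rates) {
  if (!length(rates)) return(cohort)
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("missingness rates must be named by covariate")
  if (any(rates < 0) || any(rates >= 1))
    stop("missingness rates must be in [0, 1)")
  protected <- c("id", "vitd_nmol_l", "follow_up_years", "event")
  bad <- setdiff(names(rates), setdiff(colnames(cohort), protected))
  if (length(bad))
    stop("cannot mask column(s): ", paste(bad, collapse = ", "))
  for (nm in names(rates)) {
    hit <- stats::runif(nrow(cohort)) < rates[[nm]]
    cohort[[nm]][hit] <- NA
    if (nm == "alcohol_g_day") cohort$alcohol_cat[hit] <- NA
  }
  cohort
}

#' Attach derived exposure columns to a cohort
#'
#' Adds `vitd_cat` (from `vitd_nmol_l`) and, when a beta matrix is
#' given, `ms_score` and `ms_level` (via [compute_ms()], matching on
#' sample/participant id).
#'
#' @param cohort Cohort data frame with `id` and `vitd_nmol_l`.
#' @param betas Optional beta matrix whose row names match `cohort$id`.
#' @param thresholds Optional threshold table for [compute_ms()].
#' @return The cohort with exposure category columns appended.
#' @export
attach_exposures <- function(cohort, betas = NULL, thresholds = NULL) {
  cohort$vitd_cat <- classify_vitd(cohort$vitd_nmol_l, allow_na = TRUE)
  if (!is.null(betas)) {
    ms <- if (is.null(thresholds)) compute_ms(betas)
          else compute_ms(betas, thresholds)
    idx <- match(cohort$id, ms$sample_id)
    if (anyNA(idx))
      stop("beta matrix lacks sample(s): ",
           paste(utils::head(cohort$id[is.na(idx)], 3), collapse = ", "))
    cohort$ms_score <- ms$score[idx]
    cohort$ms_level <- ms$level[idx]
  }
  cohort
}

#' Write / read a cohort table as CSV
#'
#' Missing values are written as empty cells; factor levels (category
#' orderings, reference level first) are restored on read.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `path` invisibly (write); the cohort data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, na = "", qmethod = "double")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", na.strings = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  lev <- list(
    sex = c("female", "male"),
    smoking = c("never", "former", "current"),
    bmi_class = c("under_or_normal", "overweight", "obese"),
    alcohol_cat = c("abstainer", "low", "intermediate", "high"),
    physical_activity = c("medium_or_high", "low", "inactive"),
    prevalent_cvd = c("no", "yes"), prevalent_diabetes = c("no", "yes"),
    prevalent_cancer = c("no", "yes"), vit_supplement = c("no", "yes"),
    fish_gt1_week = c("no", "yes"),
    season = c("spring", "summer", "autumn", "winter"),
    vitd_cat = c("sufficiency", "insufficiency", "deficiency"),
    ms_level = c("low", "moderate", "high"))
  for (nm in intersect(names(lev), colnames(df)))
    df[[nm]] <- factor(df[[nm]], levels = lev[[nm]])
  df
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @export
write_generator_config <- function(config, path) {
  obj <- unclass(config)
  obj$beta_dist_params <- list(probes = rownames(obj$beta_dist_params),
                               a = unname(obj$beta_dist_params[, 1]),
                               b = unname(obj$beta_dist_params[, 2]))
  # named numerics as YAML maps so names survive the round trip
  for (nm in c("vitd_lognormal_params", "true_log_hr_vitd", "true_log_hr_ms",
               "covariate_log_hrs", "baseline_hazard", "missingness_rates"))
    obj[[nm]] <- as.list(obj[[nm]])
  # precision 17 keeps doubles binary-exact through the decimal round trip
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  obj <- yaml::read_yaml(path)
  bp <- obj$beta_dist_params
  obj$beta_dist_params <- matrix(c(bp$a, bp$b), ncol = 2,
                                 dimnames = list(bp$probes, c("a", "b")))
  numify <- function(x) {
    if (is.list(x)) x <- unlist(x)
    if (is.null(x)) x <- numeric(0)
    x
  }
  for (nm in c("vitd_lognormal_params", "true_log_hr_vitd", "true_log_hr_ms",
               "covariate_log_hrs", "baseline_hazard", "missingness_rates"))
    obj[[nm]] <- numify(obj[[nm]])
  do.call(generator_config, obj)
}
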