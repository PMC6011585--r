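exposure_column <- function(exposure = c("vitd", "ms")) {
  exposure <- match.arg(exposure)
  if (exposure == "vitd") "vitd_cat" else "ms_level"
}

exposure_dummies <- function(cohort, exposure, rows) {
  col <- exposure_column(exposure)
  f <- cohort[[col]][rows]
  stopifnot(is.factor(f))
  m <- vapply(levels(f)[-1L], function(lev) as.numeric(f == lev),
              numeric(length(rows)))
  if (length(rows) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- paste(exposure, levels(f)[-1L], sep = "_")
  m
}

#' Category-wise hazard-ratio table for one exposure
#'
#' Fits one proportional-hazards model of the exposure category dummies
#' plus the requested covariate adjustment on complete cases, and lays
#' the result out as the familiar cohort-study table: one row per
#' category with deaths/totals, HR (reference category = 1, flagged,
#' no CI), 95% Wald CI and two-sided p.
#'
#' @param cohort Cohort with exposure columns attached
#'   ([attach_exposures()]).
#' @param exposure `"vitd"` or `"ms"`.
#' @param covariates Adjustment covariate names (cohort columns).
#' @param leukocyte Leukocyte adjustment passed to
#'   [build_model_matrix()].
#' @param subset Optional logical row filter.
#' @param tie_method Passed to [fit_cox()].
#' @return Data frame of class `hr_table` with attributes `fit`,
#'   `n_used`, `n_dropped`.
#' @export
fit_hr_table <- function(cohort, exposure, covariates = character(0),
                         leukocyte = "none", subset = NULL,
                         tie_method = "breslow") {
  col <- exposure_column(exposure)
  stopifnot(col %in% colnames(cohort))
  ok <- !is.na(cohort[[col]])
  if (!is.null(subset)) ok <- ok & subset
  mm <- build_model_matrix(cohort, covariates, leukocyte, subset = ok)
  rows <- mm$rows
  dcount <- tapply(cohort$event[rows], cohort[[col]][rows], sum)
  if (any(dcount == 0, na.rm = TRUE))
    stop("no deaths in exposure category '",
         names(dcount)[which(dcount == 0)[1L]],
         "': hazard ratio non-estimable")
  ed <- exposure_dummies(cohort, exposure, rows)
  x <- cbind(ed, mm$x)
  fit <- fit_cox(cohort$follow_up_years[rows], cohort$event[rows], x,
                 tie_method = tie_method)
  f <- cohort[[col]][rows]
  st <- fit$summary_table
  lev <- levels(f)
  tab <- data.frame(category = lev,
                    n_total = as.integer(table(f)[lev]),
                    n_death = as.integer(tapply(cohort$event[rows], f, sum)[lev]),
                    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_, reference = c(TRUE, rep(FALSE, length(lev) - 1L)),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$hr[1L] <- 1
  idx <- match(paste(exposure, lev[-1L], sep = "_"), st$term)
  tab$hr[-1L] <- st$hr[idx]
  tab$ci_low[-1L] <- st$ci_low[idx]
  tab$ci_high[-1L] <- st$ci_high[idx]
  tab$p[-1L] <- st$p[idx]
  structure(tab, class = c("hr_table", "data.frame"), fit = fit,
            n_used = length(rows), n_dropped = mm$n_dropped)
}

#' Sequential, fully adjusted and mutually adjusted models
#'
#' For each exposure (vitamin D status and MS risk level) fits the
#' three increasingly adjusted models plus the mutual model containing
#' both exposures with the model-3 covariate set. Model 1 adjusts for
#' age, sex and season of blood draw; model 2 additionally for alcohol
#' (g/day), smoking, BMI class, physical activity, vitamin supplement
#' use and fish consumption; model 3 additionally for prevalent CVD,
#' diabetes and cancer, systolic blood pressure, CRP and total
#' cholesterol. The full leukocyte composition is additionally
#' controlled in every model in which the MS is involved.
#'
#' @param cohort Cohort with exposures attached.
#' @param tie_method Passed to [fit_cox()].
#' @return Nested list `result[[exposure]][[model]]` of [fit_hr_table()]
#'   tables; `exposure` in `vitd`, `ms`; `model` in `model1`, `model2`,
#'   `model3`, `mutual`.
#' @export
fit_sequential_models <- function(cohort, tie_method = "breslow") {
  sets <- model_covariate_sets()
  out <- list()
  for (exposure in c("vitd", "ms")) {
    res <- list()
    for (mdl in names(sets)) {
      res[[mdl]] <- fit_hr_table(
        cohort, exposure, sets[[mdl]],
        leukocyte = if (exposure == "ms") "full" else "none",
        tie_method = tie_method)
    }
    res$mutual <- fit_mutual_model(cohort, exposure, sets$model3, tie_method)
    out[[exposure]] <- res
  }
  out
}

# model containing both exposures; rows reported for `exposure`
fit_mutual_model <- function(cohort, exposure, covariates,
                             tie_method = "breslow", subset = NULL) {
  other <- setdiff(c("vitd", "ms"), exposure)
  ok <- !is.na(cohort$vitd_cat) & !is.na(cohort$ms_level)
  if (!is.null(subset)) ok <- ok & subset
  mm <- build_model_matrix(cohort, covariates, leukocyte = "full",
                           subset = ok)
  rows <- mm$rows
  x <- cbind(exposure_dummies(cohort, exposure, rows),
             exposure_dummies(cohort, other, rows), mm$x)
  fit <- fit_cox(cohort$follow_up_years[rows], cohort$event[rows], x,
                 tie_method = tie_method)
  f <- cohort[[exposure_column(exposure)]][rows]
  st <- fit$summary_table
  lev <- levels(f)
  tab <- data.frame(category = lev,
                    n_total = as.integer(table(f)[lev]),
                    n_death = as.integer(tapply(cohort$event[rows], f, sum)[lev]),
                    hr = c(1, st$hr[match(paste(exposure, lev[-1L], sep = "_"),
                                          st$term)]),
                    ci_low = c(NA, st$ci_low[match(paste(exposure, lev[-1L],
                                                         sep = "_"), st$term)]),
                    ci_high = c(NA, st$ci_high[match(paste(exposure, lev[-1L],
                                                           sep = "_"), st$term)]),
                    p = c(NA, st$p[match(paste(exposure, lev[-1L], sep = "_"),
                                         st$term)]),
                    reference = c(TRUE, rep(FALSE, length(lev) - 1L)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(tab, class = c("hr_table", "data.frame"), fit = fit,
            n_used = length(rows), n_dropped = mm$n_dropped)
}

#' Joint 3 x 3 cross-classification analysis
#'
#' Single model with eight dummies for the cross-classification of
#' vitamin D status by MS risk level (reference: sufficiency x low MS),
#' adjusted for the screened covariates and the selected leukocyte
#' subset. Cells with zero deaths (or zero members) are flagged
#' non-estimable (`NA` HR) and excluded from the fit rather than being
#' reported as a zero hazard ratio.
#'
#' @param cohort Cohort with exposures attached.
#' @param screen Result of [screen_covariates()]; computed from the
#'   cohort when `NULL`.
#' @param screen_threshold Threshold when `screen` is `NULL`.
#' @param tie_method Passed to [fit_cox()].
#' @return 9-row `hr_table` data frame with `vitd_cat`, `ms_level`,
#'   deaths/totals, HR, CI, p, `reference` and `estimable` flags.
#' @export
joint_analysis <- function(cohort, screen = NULL, screen_threshold = 0.2,
                           tie_method = "breslow") {
  if (is.null(screen))
    screen <- screen_covariates(cohort, threshold = screen_threshold)
  keep_cov <- screen$covariate[screen$keep]
  ok <- !is.na(cohort$vitd_cat) & !is.na(cohort$ms_level)
  cell <- interaction(cohort$vitd_cat, cohort$ms_level, sep = ":",
                      lex.order = FALSE)
  combos <- expand.grid(vitd_cat = levels(cohort$vitd_cat),
                        ms_level = levels(cohort$ms_level),
                        stringsAsFactors = FALSE)
  combos$label <- paste(combos$vitd_cat, combos$ms_level, sep = ":")
  deaths <- vapply(combos$label, function(l)
    sum(cohort$event[ok & cell == l]), numeric(1))
  totals <- vapply(combos$label, function(l) sum(ok & cell == l), numeric(1))
  estimable <- totals > 0 & deaths > 0
  ref <- combos$label == "sufficiency:low"
  usable <- ok & (cell %in% combos$label[estimable | ref])
  mm <- build_model_matrix(cohort, keep_cov, leukocyte = "selected",
                           subset = usable)
  rows <- mm$rows
  cl <- factor(as.character(cell[rows]),
               levels = c("sufficiency:low",
                          setdiff(combos$label[estimable], "sufficiency:low")))
  dm <- vapply(levels(cl)[-1L], function(lev) as.numeric(cl == lev),
               numeric(length(rows)))
  colnames(dm) <- paste0("cell_", levels(cl)[-1L])
  fit <- fit_cox(cohort$follow_up_years[rows], cohort$event[rows],
                 cbind(dm, mm$x), tie_method = tie_method)
  st <- fit$summary_table
  idx <- match(paste0("cell_", combos$label), st$term)
  tab <- data.frame(vitd_cat = combos$vitd_cat, ms_level = combos$ms_level,
                    n_total = as.integer(totals),
                    n_death = as.integer(deaths),
                    hr = st$hr[idx], ci_low = st$ci_low[idx],
                    ci_high = st$ci_high[idx], p = st$p[idx],
                    reference = ref, estimable = estimable | ref,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$hr[ref] <- 1
  structure(tab, class = c("hr_table", "data.frame"), fit = fit,
            n_used = length(rows), n_dropped = mm$n_dropped,
            screened_covariates = keep_cov)
}

#' Stratified analysis of one indicator within levels of the other
#'
#' Fits the association of one exposure with mortality within each
#' stratum of the other (plus an unstratified "overall" fit), adjusted
#' for the screened covariates and selected leukocyte subset.
#'
#' @param cohort Cohort with exposures attached.
#' @param stratifier `"vitd"` (strata = vitamin D categories, exposure =
#'   MS level) or `"ms"` (vice versa).
#' @param screen,screen_threshold,tie_method As in [joint_analysis()].
#' @return Data frame with a `stratum` column (`"overall"` first)
#'   binding the per-stratum `hr_table` rows; attribute `fits` carries
#'   the underlying models.
#' @export
stratified_analysis <- function(cohort, stratifier = c("vitd", "ms"),
                                screen = NULL, screen_threshold = 0.2,
                                tie_method = "breslow") {
  stratifier <- match.arg(stratifier)
  exposure <- setdiff(c("vitd", "ms"), stratifier)
  if (is.null(screen))
    screen <- screen_covariates(cohort, threshold = screen_threshold)
  keep_cov <- screen$covariate[screen$keep]
  scol <- exposure_column(stratifier)
  strata <- levels(cohort[[scol]])
  strata <- strata[vapply(strata, function(s)
    sum(cohort[[scol]] == s, na.rm = TRUE) > 0, logical(1))]
  fits <- list()
  blocks <- list()
  run <- function(label, subset) {
    t <- tryCatch(
      fit_hr_table(cohort, exposure, keep_cov, leukocyte = "selected",
                   subset = subset, tie_method = tie_method),
      error = function(e) {
        # degenerate stratum (e.g. no deaths in a category): keep the
        # counts, flag the estimates non-estimable
        ecol <- exposure_column(exposure)
        keep <- !is.na(cohort[[ecol]])
        if (!is.null(subset)) keep <- keep & subset
        f <- cohort[[ecol]][keep]
        lev <- levels(f)
        data.frame(category = lev,
                   n_total = as.integer(table(f)[lev]),
                   n_death = as.integer(tapply(cohort$event[keep], f,
                                               function(v) sum(v))[lev]),
                   hr = c(1, rep(NA_real_, length(lev) - 1L)),
                   ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                   reference = c(TRUE, rep(FALSE, length(lev) - 1L)),
                   stringsAsFactors = FALSE)
      })
    fits[[label]] <<- attr(t, "fit")
    cbind(stratum = label, as.data.frame(t))
  }
  blocks$overall <- run("overall", NULL)
  for (s in strata)
    blocks[[s]] <- run(s, !is.na(cohort[[scol]]) & cohort[[scol]] == s)
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  structure(res, fits = fits, screened_covariates = keep_cov)
}

#' Wald heterogeneity test across strata
#'
#' Inverse-variance (Cochran Q) contrast of the stratum-specific log
#' hazard ratios of each non-reference exposure category, against the
#' null of a common effect across strata.
#'
#' @param strat Result of [stratified_analysis()].
#' @return Data frame: `category`, `Q`, `df`, `p`.
#' @export
stratum_heterogeneity <- function(strat) {
  fits <- attr(strat, "fits")
  strata <- setdiff(names(fits), "overall")
  cats <- unique(strat$category[!strat$reference])
  out <- lapply(cats, function(cc) {
    b <- se <- numeric(0)
    for (s in strata) {
      st <- fits[[s]]$summary_table
      i <- grep(paste0("_", cc, "$"), st$term)
      if (length(i) == 1L) { b <- c(b, st$coef[i]); se <- c(se, st$se[i]) }
    }
    if (length(b) < 2L)
      return(data.frame(category = cc, Q = NA_real_, df = NA_integer_,
                        p = NA_real_))
    w <- 1 / se^2
    bbar <- sum(w * b) / sum(w)
    Q <- sum(w * (b - bbar)^2)
    data.frame(category = cc, Q = Q, df = length(b) - 1L,
               p = stats::pchisq(Q, length(b) - 1L, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Render a hazard-ratio table as aligned plain text
#'
#' @param tab An `hr_table` data frame.
#' @param digits Significant digits for HR/CI.
#' @return Character vector of lines, invisibly printed.
#' @export
format_hr_table <- function(tab, digits = 3) {
  fmt <- function(r) {
    if (isTRUE(r$reference)) "Reference"
    else if (!is.na(r$hr))
      sprintf("%.*g (%.*g-%.*g), p=%.2g", digits, r$hr, digits, r$ci_low,
              digits, r$ci_high, r$p)
    else "not estimable"
  }
  lab <- if ("category" %in% colnames(tab)) tab$category
         else paste(tab$vitd_cat, tab$ms_level, sep = " / ")
  lines <- sprintf("%-30s %5d/%5d  %s", lab, tab$n_death, tab$n_total,
                   vapply(seq_len(nrow(tab)), function(i) fmt(tab[i, ]),
                          character(1)))
  lines
}
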