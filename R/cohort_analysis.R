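#' Pearson chi-square test of independence
#'
#' Module surface over [stats::chisq.test()] with no continuity
#' correction, as used for the baseline descriptive tables.
#'
#' @param tab Integer contingency matrix (>= 2 rows and columns, no
#'   all-zero row or column margin).
#' @return List with `statistic`, `df` and upper-tail `p`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab)))
    stop("contingency table must contain nonnegative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Kruskal-Wallis rank test
#'
#' Module surface over [stats::kruskal.test()] (tie-corrected H
#' statistic, chi-square p on groups - 1 df). A degenerate sample in
#' which every observation is identical returns statistic 0, p 1
#' rather than a 0/0 tie correction.
#'
#' @param values Numeric observations (missing values dropped).
#' @param group Group labels.
#' @return List with `statistic`, `df` and `p`.
#' @export
kruskal_wallis <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- factor(group[keep])
  group <- droplevels(group)
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = nlevels(group) - 1L, p = 1))
  res <- stats::kruskal.test(values, group)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

# cohort columns treated as continuous in models and screening
continuous_covariates <- function()
  c("age", "alcohol_g_day", "sbp_mmhg", "crp_mg_l", "cholesterol_mg_dl")

#' Covariate sets of the three sequentially adjusted models
#'
#' Model 1: age, sex, season of blood draw. Model 2: additionally
#' alcohol (g/day), smoking, BMI class, physical activity, vitamin
#' supplement use, fish consumption. Model 3: additionally prevalent
#' CVD/diabetes/cancer, systolic blood pressure, CRP, total
#' cholesterol. The sets are nested by construction.
#'
#' @return Named list of character vectors (`model1` through `model3`).
#' @export
model_covariate_sets <- function() {
  m1 <- c("age", "sex", "season")
  m2 <- c(m1, "alcohol_g_day", "smoking", "bmi_class", "physical_activity",
          "vit_supplement", "fish_gt1_week")
  m3 <- c(m2, "prevalent_cvd", "prevalent_diabetes", "prevalent_cancer",
          "sbp_mmhg", "crp_mg_l", "cholesterol_mg_dl")
  list(model1 = m1, model2 = m2, model3 = m3)
}

leukocyte_columns <- function(adjustment = c("none", "full", "selected")) {
  adjustment <- match.arg(adjustment)
  switch(adjustment,
         none = character(0),
         # full six-part composition: drop granulocytes (parts sum to 1)
         full = paste0("leuko_", c("CD4T", "CD8T", "B", "NK", "mono")),
         # four-type subset: CD4+ T, CD8+ T, B cells, granulocytes
         selected = paste0("leuko_", c("CD4T", "CD8T", "B", "gran")))
}

#' Build a dummy-coded design matrix for survival models
#'
#' Categorical covariates are coded against their reference level (the
#' first factor level: never smoker, under/normal BMI, medium-or-high
#' activity, female, "no", spring, sufficiency, low MS); continuous
#' covariates pass through. Only complete cases over the requested
#' columns are kept, and the dropped count is reported.
#'
#' @param cohort Cohort data frame.
#' @param covariates Character vector of cohort column names.
#' @param leukocyte `"none"`, `"full"` (five of six proportions,
#'   granulocytes dropped against collinearity) or `"selected"` (CD4T,
#'   CD8T, B, granulocytes).
#' @param subset Optional logical vector restricting rows before
#'   complete-case filtering.
#' @return List: `x` (numeric matrix), `rows` (integer indices of
#'   `cohort` used), `n_dropped` (incomplete rows removed), `labels`.
#' @export
build_model_matrix <- function(cohort, covariates,
                               leukocyte = "none", subset = NULL) {
  unknown <- setdiff(covariates, colnames(cohort))
  if (length(unknown))
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  lk <- leukocyte_columns(leukocyte)
  need <- c(covariates, lk)
  rows <- seq_len(nrow(cohort))
  if (!is.null(subset)) rows <- rows[subset]
  cc <- stats::complete.cases(cohort[rows, need, drop = FALSE])
  kept <- rows[cc]
  if (!length(kept)) stop("empty design after complete-case filtering")
  cols <- list()
  for (nm in covariates) {
    v <- cohort[[nm]][kept]
    if (is.numeric(v)) {
      cols[[nm]] <- v
    } else {
      f <- if (is.factor(v)) v else factor(v)
      for (lev in levels(f)[-1L])
        cols[[paste(nm, lev, sep = "_")]] <- as.numeric(f == lev)
    }
  }
  for (nm in lk) cols[[nm]] <- cohort[[nm]][kept]
  x <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, length(kept), 0L)
  list(x = x, rows = kept, n_dropped = length(rows) - length(kept),
       labels = colnames(x))
}

#' Screen candidate covariates against both mortality predictors
#'
#' Bivariable association of each candidate with vitamin D category and
#' with MS risk level: chi-square for categorical candidates,
#' Kruskal-Wallis for continuous. A candidate is kept when either p is
#' strictly below the threshold (guarding against overadjustment in the
#' joint and stratified models).
#'
#' @param cohort Cohort with `vitd_cat` and `ms_level` columns (see
#'   [attach_exposures()]).
#' @param candidates Cohort column names to screen.
#' @param threshold Keep threshold on the smaller p (default 0.2).
#' @return Data frame: `covariate`, `p_vs_vitd`, `p_vs_ms`, `keep`.
#' @export
screen_covariates <- function(cohort, candidates = default_candidates(),
                              threshold = 0.2) {
  stopifnot(all(c("vitd_cat", "ms_level") %in% colnames(cohort)))
  if (!length(candidates))
    return(data.frame(covariate = character(0), p_vs_vitd = numeric(0),
                      p_vs_ms = numeric(0), keep = logical(0)))
  unknown <- setdiff(candidates, colnames(cohort))
  if (length(unknown))
    stop("unknown candidate(s): ", paste(unknown, collapse = ", "))
  one_p <- function(v, g) {
    keep <- !is.na(v) & !is.na(g)
    if (nlevels(droplevels(factor(g[keep]))) < 2L) return(NA_real_)
    if (is.numeric(v)) kruskal_wallis(v, g)$p
    else {
      tab <- table(v, g)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
      chi_square_test(tab)$p
    }
  }
  pv <- vapply(candidates, function(nm)
    one_p(cohort[[nm]], cohort$vitd_cat), numeric(1))
  pm <- vapply(candidates, function(nm)
    one_p(cohort[[nm]], cohort$ms_level), numeric(1))
  keep <- pmin(pv, pm, na.rm = TRUE) < threshold
  keep[is.na(keep)] <- FALSE   # untestable candidate (degenerate table)
  data.frame(covariate = candidates, p_vs_vitd = unname(pv),
             p_vs_ms = unname(pm), keep = unname(keep),
             row.names = NULL, stringsAsFactors = FALSE)
}

default_candidates <- function()
  c("age", "sex", "smoking", "bmi_class", "alcohol_g_day",
    "physical_activity", "prevalent_cvd", "prevalent_diabetes",
    "prevalent_cancer", "sbp_mmhg", "crp_mg_l", "cholesterol_mg_dl",
    "vit_supplement", "fish_gt1_week", "season")

#' Baseline descriptive table by vitamin D status
#'
#' Mean (SD) for continuous characteristics and n (%) for categorical
#' ones, overall and within each vitamin D category, with a
#' Kruskal-Wallis (continuous) or chi-square (categorical) p-value for
#' differences among categories and the number of missing values per
#' characteristic. With fewer than two populated categories the test is
#' flagged "not applicable" (`NA` p).
#'
#' @param cohort Cohort with a `vitd_cat` column.
#' @param characteristics Cohort columns to summarise.
#' @return Data frame, one row per characteristic (continuous) or per
#'   level (categorical): `characteristic`, `level`, `stat`
#'   (`"mean_sd"`/`"n_pct"`), `overall_1`, `overall_2` (mean & SD, or n
#'   & %), one pair of columns per category, `p` and `n_missing` on the
#'   first row of each characteristic.
#' @export
descriptive_table <- function(cohort,
                              characteristics = default_descriptives(cohort)) {
  stopifnot("vitd_cat" %in% colnames(cohort))
  g <- droplevels(factor(cohort$vitd_cat))
  cats <- levels(g)
  testable <- length(cats) >= 2L
  out <- list()
  for (nm in characteristics) {
    v <- cohort[[nm]]
    n_missing <- sum(is.na(v))
    if (is.numeric(v)) {
      p <- if (testable) kruskal_wallis(v, g)$p else NA_real_
      row <- data.frame(characteristic = nm, level = NA_character_,
                        stat = "mean_sd",
                        overall_1 = mean(v, na.rm = TRUE),
                        overall_2 = stats::sd(v, na.rm = TRUE),
                        stringsAsFactors = FALSE)
      for (cc in cats) {
        vv <- v[g == cc & !is.na(g)]
        row[[paste0(cc, "_1")]] <- mean(vv, na.rm = TRUE)
        row[[paste0(cc, "_2")]] <- stats::sd(vv, na.rm = TRUE)
      }
      row$p <- p
      row$n_missing <- n_missing
      out[[nm]] <- row
    } else {
      f <- if (is.factor(v)) v else factor(v)
      tab <- table(f, g)
      p <- if (testable && nrow(tab) >= 2L &&
               all(colSums(tab) > 0) && all(rowSums(tab) > 0))
        chi_square_test(tab)$p else NA_real_
      rows <- lapply(levels(f), function(lev) {
        r <- data.frame(characteristic = nm, level = lev, stat = "n_pct",
                        overall_1 = sum(f == lev, na.rm = TRUE),
                        overall_2 = 100 * sum(f == lev, na.rm = TRUE) /
                          sum(!is.na(f)),
                        stringsAsFactors = FALSE)
        for (cc in cats) {
          num <- sum(f == lev & g == cc, na.rm = TRUE)
          den <- sum(!is.na(f) & g == cc, na.rm = TRUE)
          r[[paste0(cc, "_1")]] <- num
          r[[paste0(cc, "_2")]] <- if (den > 0) 100 * num / den else NA_real_
        }
        r
      })
      block <- do.call(rbind, rows)
      block$p <- c(p, rep(NA_real_, nrow(block) - 1L))
      block$n_missing <- c(n_missing, rep(NA_integer_, nrow(block) - 1L))
      out[[nm]] <- block
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

default_descriptives <- function(cohort) {
  cand <- c("age", "sex", "smoking", "bmi_class", "alcohol_cat",
            "physical_activity", "prevalent_cvd", "prevalent_diabetes",
            "prevalent_cancer", "sbp_mmhg", "crp_mg_l", "cholesterol_mg_dl",
            "vit_supplement", "fish_gt1_week", "ms_level")
  intersect(cand, colnames(cohort))
}
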