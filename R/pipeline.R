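#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (load a
#'   cohort CSV and beta-matrix CSV).
#' @param generator A [generator_config()] (synthetic mode).
#' @param cohort_path,betas_path Input CSVs (files mode).
#' @param out_dir Output directory (created if absent).
#' @param analyses Character subset of `descriptives`, `sequential`,
#'   `joint`, `stratified`, `dose_response`, `curves`; empty vector
#'   runs only generation/loading and scoring.
#' @param screen_threshold Bivariable screening threshold (default 0.2).
#' @param seed Seed for synthetic mode (overrides the generator seed so
#'   all pipeline randomness funnels through one value).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            generator = generator_config(),
                            cohort_path = NULL, betas_path = NULL,
                            out_dir = "epimort_run",
                            analyses = c("descriptives", "sequential",
                                         "joint", "stratified",
                                         "dose_response", "curves"),
                            screen_threshold = 0.2,
                            seed = NULL) {
  mode <- match.arg(mode)
  known <- c("descriptives", "sequential", "joint", "stratified",
             "dose_response", "curves")
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analysis toggle(s): ",
                        paste(bad, collapse = ", "))
  if (screen_threshold <= 0 || screen_threshold >= 1)
    stop("screen_threshold must be in (0, 1)")
  if (mode == "files" && (is.null(cohort_path) || is.null(betas_path)))
    stop("files mode needs cohort_path and betas_path")
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  structure(list(mode = mode, generator = generator,
                 cohort_path = cohort_path, betas_path = betas_path,
                 out_dir = out_dir, analyses = analyses,
                 screen_threshold = screen_threshold),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: generate/load -> score -> descriptives -> sequential
#' models -> joint -> stratified -> dose-response -> adjusted curves.
#' Every enabled stage writes its tables as CSV under `out_dir`, a log
#' line with row counts in/out is appended to `run.log`, and a YAML
#' manifest listing every artifact with its MD5 checksum is written
#' last. Outputs are deterministic given the configuration seed. A
#' stage error halts the run with the stage named; the manifest of the
#' artifacts produced so far is still written, flagged `incomplete`.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list with `artifacts`, `complete`,
#'   `stages`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  artifacts <- character(0)
  stages <- character(0)
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(as.data.frame(df), p, sep = ",", row.names = FALSE,
                       na = "", qmethod = "double")
    artifacts <<- c(artifacts, p)
    p
  }
  finish <- function(complete) {
    manifest <- list(
      complete = complete, stages = stages,
      artifacts = lapply(artifacts, function(p)
        list(path = basename(p), md5 = unname(tools::md5sum(p)),
             bytes = unname(file.size(p)))))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    manifest
  }
  stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e) {
      logline("stage %s: FAILED (%s)", name, conditionMessage(e))
      finish(FALSE)
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dat <- stage("input", {
    if (config$mode == "synthetic") {
      g <- generate_cohort(config$generator)
      emit(g$cohort, "cohort.csv")
      write_beta_matrix(g$betas, file.path(config$out_dir, "betas.csv"))
      artifacts <- c(artifacts, file.path(config$out_dir, "betas.csv"))
      logline("stage input: generated cohort n=%d", nrow(g$cohort))
      g
    } else {
      cohort <- read_cohort(config$cohort_path)
      betas <- read_beta_matrix(config$betas_path)
      logline("stage input: loaded cohort n=%d, betas %dx%d",
              nrow(cohort), nrow(betas), ncol(betas))
      list(cohort = cohort, betas = betas)
    }
  })

  cohort <- stage("score", {
    thresholds <- compute_thresholds(dat$betas)
    emit(thresholds, "thresholds.csv")
    co <- attach_exposures(dat$cohort, dat$betas, thresholds)
    emit(compute_ms(dat$betas, thresholds), "scores.csv")
    logline("stage score: scored %d samples (%d missing scores)",
            nrow(co), sum(is.na(co$ms_score)))
    co
  })

  screen <- NULL
  if (any(c("joint", "stratified") %in% config$analyses)) {
    screen <- stage("screen", {
      s <- screen_covariates(cohort, threshold = config$screen_threshold)
      emit(s, "covariate_screen.csv")
      logline("stage screen: kept %d of %d candidates", sum(s$keep), nrow(s))
      s
    })
  }

  if ("descriptives" %in% config$analyses) stage("descriptives", {
    d <- descriptive_table(cohort)
    emit(d, "descriptives.csv")
    logline("stage descriptives: %d rows", nrow(d))
  })

  if ("sequential" %in% config$analyses) stage("sequential", {
    seqm <- fit_sequential_models(cohort)
    for (exposure in names(seqm)) for (mdl in names(seqm[[exposure]])) {
      t <- seqm[[exposure]][[mdl]]
      emit(t, sprintf("hr_%s_%s.csv", exposure, mdl))
      logline("stage sequential: %s %s n_used=%d dropped=%d", exposure, mdl,
              attr(t, "n_used"), attr(t, "n_dropped"))
    }
  })

  if ("joint" %in% config$analyses) stage("joint", {
    j <- joint_analysis(cohort, screen = screen)
    emit(j, "hr_joint.csv")
    logline("stage joint: n_used=%d dropped=%d", attr(j, "n_used"),
            attr(j, "n_dropped"))
  })

  if ("stratified" %in% config$analyses) stage("stratified", {
    for (s in c("vitd", "ms")) {
      t <- stratified_analysis(cohort, s, screen = screen)
      emit(t, sprintf("hr_stratified_by_%s.csv", s))
      logline("stage stratified: by %s, %d rows", s, nrow(t))
    }
  })

  if ("dose_response" %in% config$analyses) stage("dose_response", {
    for (e in c("vitd", "ms")) {
      dr <- fit_dose_response(cohort, e,
                              covariates = model_covariate_sets()$model3,
                              leukocyte = if (e == "ms") "full" else "none")
      emit(dr, sprintf("dose_response_%s.csv", e))
      logline("stage dose_response: %s, %d grid points", e, nrow(dr))
    }
  })

  if ("curves" %in% config$analyses) stage("curves", {
    ok <- !is.na(cohort$vitd_cat) & !is.na(cohort$ms_level)
    grp <- interaction(cohort$vitd_cat[ok], cohort$ms_level[ok],
                       sep = ":", drop = TRUE)
    cov <- cbind(age = cohort$age[ok],
                 sex_male = as.numeric(cohort$sex[ok] == "male"))
    cv <- direct_adjusted_curves(cohort$follow_up_years[ok],
                                 cohort$event[ok], grp, cov)
    emit(cv, "adjusted_curves.csv")
    lr <- log_rank(cohort$follow_up_years[ok], cohort$event[ok], grp)
    emit(data.frame(statistic = lr$statistic, df = lr$df, p = lr$p),
         "log_rank.csv")
    logline("stage curves: %d groups, log-rank p=%.3g", nlevels(grp), lr$p)
  })

  invisible(finish(TRUE))
}
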