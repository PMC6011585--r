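#' The 10-CpG mortality risk score panel
#'
#' Probe identifiers of the ten blood DNA-methylation CpG sites whose
#' aberrant methylation defines the mortality risk score (MS). Aberration
#' is hypomethylation (first beta-value quartile) for nine probes and
#' hypermethylation (fourth quartile) for cg08362785.
#'
#' @return Named character vector of length 10: values are the probe IDs,
#'   names give the aberrant tail (`"low_tail"` or `"high_tail"`).
#' @examples
#' ms_panel()
#' @export
ms_panel <- function() {
  probes <- c("cg01612140", "cg05575921", "cg06126421", "cg08362785",
              "cg10321156", "cg14975410", "cg19572487", "cg23665802",
              "cg24704287", "cg25983901")
  dir <- ifelse(probes == "cg08362785", "high_tail", "low_tail")
  stats::setNames(probes, dir)
}

ms_panel_directions <- function() {
  p <- ms_panel()
  stats::setNames(names(p), p)
}

#' Read a beta-value matrix from CSV/TSV
#'
#' The file must have a header row of probe IDs, with sample IDs in the
#' first column. Beta values are methylation fractions in \[0, 1\]; empty
#' cells are treated as missing.
#'
#' @param path Path to a CSV (or TSV, detected by extension) file.
#' @return Numeric matrix (samples x probes) with sample IDs as row names
#'   and probe IDs as column names.
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  if (ncol(raw) < 2L)
    stop("beta matrix file must have a sample-id column plus >=1 probe column")
  ids <- raw[[1L]]
  probes <- colnames(raw)[-1L]
  if (anyDuplicated(probes))
    stop("duplicate probe id(s): ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(raw), length(probes),
              dimnames = list(ids, probes))
  for (j in seq_along(probes)) {
    cell <- raw[[j + 1L]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric beta value '%s' at row '%s', probe '%s'",
                   cell[bad[1L]], ids[bad[1L]], probes[j]))
    out <- which(!is.na(val) & (val < 0 | val > 1))
    if (length(out))
      stop(sprintf("beta value %g outside [0,1] at row '%s', probe '%s'",
                   val[out[1L]], ids[out[1L]], probes[j]))
    m[, j] <- val
  }
  m
}

#' Write a beta-value matrix to CSV
#'
#' Inverse of [read_beta_matrix()]: first column `sample_id`, remaining
#' columns the probes. Missing values are written as empty cells.
#'
#' @param betas Numeric matrix with sample row names and probe column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path) {
  stopifnot(is.matrix(betas))
  df <- data.frame(sample_id = rownames(betas), betas,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", na = "")
  invisible(path)
}

check_panel <- function(betas) {
  stopifnot(is.matrix(betas), is.numeric(betas) || nrow(betas) == 0L)
  missing <- setdiff(ms_panel(), colnames(betas))
  if (length(missing))
    stop("beta matrix lacks panel probe(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Quartile aberration thresholds for the MS panel
#'
#' Derives, per panel probe, the beta-value cut defining aberrant
#' methylation: the 75th empirical percentile for cg08362785 (aberration =
#' hypermethylation) and the 25th percentile for the other nine probes
#' (aberration = hypomethylation). Percentiles use linear interpolation
#' between order statistics (type-7 rule); missing betas are excluded
#' per probe.
#'
#' @param betas Beta matrix containing all 10 panel probes with at least
#'   4 non-missing values each.
#' @return Data frame with columns `probe`, `cut_value`, `direction`
#'   (`low_tail`/`high_tail`) and `source` (`"cohort_derived"`).
#' @export
compute_thresholds <- function(betas) {
  check_panel(betas)
  dirs <- ms_panel_directions()
  cut <- vapply(names(dirs), function(pr) {
    v <- betas[, pr]
    v <- v[!is.na(v)]
    if (length(v) < 4L)
      stop("probe ", pr, " has fewer than 4 non-missing values")
    p <- if (dirs[[pr]] == "high_tail") 0.75 else 0.25
    unname(stats::quantile(v, p, type = 7))
  }, numeric(1))
  data.frame(probe = names(dirs), cut_value = unname(cut),
             direction = unname(dirs), source = "cohort_derived",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' User-supplied aberration thresholds
#'
#' Wraps externally derived quartile cuts (e.g. carried over from a
#' discovery cohort) in the threshold table format used by [compute_ms()].
#'
#' @param cuts Named numeric vector of beta-value cuts, one per panel probe.
#' @return Threshold data frame with `source = "user_supplied"`.
#' @export
supplied_thresholds <- function(cuts) {
  dirs <- ms_panel_directions()
  missing <- setdiff(names(dirs), names(cuts))
  if (length(missing))
    stop("cuts missing for panel probe(s): ", paste(missing, collapse = ", "))
  data.frame(probe = names(dirs), cut_value = unname(cuts[names(dirs)]),
             direction = unname(dirs), source = "user_supplied",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute the mortality risk score
#'
#' Per sample, the MS is the number of panel CpGs with aberrant
#' methylation (0-10): beta at or below the cut for low-tail probes,
#' at or above the cut for cg08362785 (a value exactly at the cut counts
#' as aberrant). Samples missing any panel beta receive a missing score,
#' not zero.
#'
#' @param betas Beta matrix containing the 10 panel probes.
#' @param thresholds Threshold table from [compute_thresholds()] or
#'   [supplied_thresholds()]; by default derived from `betas` itself.
#' @return Data frame with columns `sample_id`, `score` (integer 0-10 or
#'   `NA`) and `level` (`low`/`moderate`/`high` factor, `NA` when the
#'   score is missing).
#' @export
compute_ms <- function(betas, thresholds = compute_thresholds(betas)) {
  check_panel(betas)
  need <- setdiff(ms_panel(), thresholds$probe)
  if (length(need))
    stop("thresholds lack panel probe(s): ", paste(need, collapse = ", "))
  n <- nrow(betas)
  score <- integer(n)
  any_na <- logical(n)
  if (n > 0L) {
    flags <- matrix(FALSE, n, 10L)
    for (j in seq_len(10L)) {
      row <- thresholds[thresholds$probe == ms_panel()[j], ]
      v <- betas[, row$probe]
      flags[, j] <- if (row$direction == "high_tail") v >= row$cut_value
                    else v <= row$cut_value
      any_na <- any_na | is.na(v)
    }
    flags[is.na(flags)] <- FALSE
    score <- as.integer(rowSums(flags))
    score[any_na] <- NA_integer_
  }
  data.frame(sample_id = if (is.null(rownames(betas))) as.character(seq_len(n))
                         else rownames(betas),
             score = score,
             level = classify_ms(score, allow_na = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' MS risk levels
#'
#' Maps scores to risk levels: low (0-1), moderate (2-5), high (> 5).
#'
#' @param score Integer vector of scores in 0-10.
#' @param allow_na Tolerate missing scores (returned as `NA` level)?
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
classify_ms <- function(score, allow_na = FALSE) {
  if (!allow_na && anyNA(score)) stop("missing score")
  ok <- is.na(score) | (score >= 0 & score <= 10 & score == floor(score))
  if (!all(ok))
    stop("score out of range 0-10: ", paste(score[!ok], collapse = ", "))
  cut(score, breaks = c(-0.5, 1.5, 5.5, 10.5),
      labels = c("low", "moderate", "high"))
}

#' Vitamin D status categories
#'
#' Classifies serum 25-hydroxyvitamin D concentration (nmol/L):
#' deficiency < 30, insufficiency 30 to < 50, sufficiency >= 50.
#'
#' @param conc Non-negative concentration(s) in nmol/L.
#' @param allow_na Tolerate missing concentrations?
#' @return Factor with levels `sufficiency`, `insufficiency`, `deficiency`
#'   (reference level first).
#' @export
classify_vitd <- function(conc, allow_na = FALSE) {
  if (!allow_na && anyNA(conc)) stop("missing concentration")
  if (any(conc < 0, na.rm = TRUE))
    stop("negative 25(OH)D concentration")
  f <- cut(conc, breaks = c(-Inf, 30, 50, Inf), right = FALSE,
           labels = c("deficiency", "insufficiency", "sufficiency"))
  factor(f, levels = c("sufficiency", "insufficiency", "deficiency"))
}
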