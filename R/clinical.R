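PANSS_ITEMS <- c("p1", "p2", "p3", "n1", "n4", "n6", "g5", "g9")

#' Load and validate a PANSS-8 clinical table
#'
#' Reads a delimited table with one row per subject carrying the eight PANSS-8
#' item scores (P1 delusions, P2 conceptual disorganization, P3 hallucinations,
#' N1 blunted affect, N4 social withdrawal, N6 lack of spontaneity, G5
#' mannerisms, G9 unusual thoughts), a binary medication-exposure flag and the
#' duration of untreated psychosis (DUP, months; may be missing). Every item
#' score must lie in 1..7 and subject ids must be unique; violations raise an
#' error naming the subject and item. Missing DUP entries are reported with a
#' message, never dropped.
#'
#' @param path path to a CSV/TSV file with columns
#'   `subject_id,p1,p2,p3,n1,n4,n6,g5,g9,medication,dup_months` (extra columns
#'   are carried through untouched).
#' @param sep field separator; `""` (default) auto-detects comma vs tab from
#'   the header line.
#' @return a `data.frame` of class `panss_cohort`, one validated row per
#'   subject.
#' @seealso [panss_fixture_path()] for the packaged 19-subject table.
#' @export
load_panss <- function(path, sep = "") {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  if (identical(sep, "")) {
    header <- readLines(path, n = 1L)
    if (length(header) == 0L) stop("clinical table is empty: ", path)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE)
  if (nrow(tab) == 0L) stop("clinical table has a header but no subjects: ", path)
  needed <- c("subject_id", PANSS_ITEMS, "medication", "dup_months")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L)
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  validate_panss(tab)
}

#' @rdname load_panss
#' @param records a data frame with the columns listed under [load_panss()].
#' @export
validate_panss <- function(records) {
  records <- as.data.frame(records)
  if (anyDuplicated(records$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(records$subject_id[duplicated(records$subject_id)]),
               collapse = ", "))
  for (item in PANSS_ITEMS) {
    v <- records[[item]]
    bad <- which(is.na(v) | v != round(v) | v < 1 | v > 7)
    if (length(bad) > 0L)
      stop(sprintf("item %s out of range [1, 7] for subject %s (value %s)",
                   toupper(item), records$subject_id[bad[1]], v[bad[1]]))
  }
  if (!all(records$medication %in% c(0L, 1L)))
    stop("medication must be binary 0/1 (any antipsychotic exposure)")
  dup <- records$dup_months
  if (any(!is.na(dup) & dup < 0)) stop("dup_months must be non-negative")
  if (anyNA(dup))
    message("DUP missing for subject(s) ",
            paste(records$subject_id[is.na(dup)], collapse = ", "),
            "; will be mean-imputed in design matrices")
  class(records) <- c("panss_cohort", "data.frame")
  records
}

#' Path to the packaged 19-subject PANSS-8 fixture
#'
#' The published clinical table of the 19 first-episode-psychosis subjects:
#' PANSS-8 items, medication flags and DUP, together with the printed
#' negative/positive/total composite columns (`printed_*`) for cross-checks.
#'
#' @param file fixture file name; other packaged tables are
#'   `"model_diagnostics.csv"` (per-subject explained variance),
#'   `"subject_estimates.csv"` (per-subject `exp(posterior mean)` connectivity,
#'   columns ordered `dlpfc_self, str_to_dlpfc, dlpfc_to_str, str_self`) and
#'   `"group_model_evidence.csv"` (published group free energies per symptom
#'   model).
#' @return absolute path to the installed file.
#' @export
panss_fixture_path <- function(file = "panss8_cohort.csv") {
  path <- system.file("extdata", file, package = "fsdcm", mustWork = FALSE)
  if (!nzchar(path)) stop("fixture not installed: ", file)
  path
}

#' PANSS-8 composite scores
#'
#' Total positive = P1 + P2 + P3, total negative = N1 + N4 + N6, and the
#' PANSS-8 total over all eight items. G5 and G9 contribute only to the total.
#'
#' @param records a `panss_cohort` (or any data frame with the item columns).
#' @return a data frame with `subject_id`, `total_positive`, `total_negative`
#'   and `panss8_total`, one row per subject.
#' @export
composite_scores <- function(records) {
  records <- as.data.frame(records)
  data.frame(
    subject_id     = records$subject_id,
    total_positive = records$p1 + records$p2 + records$p3,
    total_negative = records$n1 + records$n4 + records$n6,
    panss8_total   = rowSums(records[PANSS_ITEMS])
  )
}

#' Paired difference t test
#'
#' Classical paired t statistics for two equal-length score vectors: mean and
#' SD of the differences, `t = mean / (sd / sqrt(n))` on `n - 1` degrees of
#' freedom, and the two-sided 95% confidence interval from the t quantile.
#' Zero-variance differences make t undefined; this is reported as an explicit
#' error state (`ok = FALSE`), never as an infinite statistic.
#'
#' @param a,b numeric vectors of equal length `n >= 2`; differences are
#'   `a - b`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return an object of class `paired_test`: list with `mean_diff`, `sd_diff`,
#'   `t_stat`, `df`, `ci_low`, `ci_high`, `p_value`, `n`, `ok`.
#' @examples
#' coh <- load_panss(panss_fixture_path())
#' cs <- composite_scores(coh)
#' paired_difference_test(cs$total_positive, cs$total_negative)
#' @export
paired_difference_test <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- as.numeric(a) - as.numeric(b)
  m <- mean(d)
  s <- stats::sd(d)
  out <- list(mean_diff = m, sd_diff = s, n = n, df = n - 1L)
  if (s <= 0) {
    out$ok <- FALSE
    out$t_stat <- NA_real_
    out$ci_low <- out$ci_high <- out$p_value <- NA_real_
    warning("zero-variance differences: t statistic undefined")
  } else {
    se <- s / sqrt(n)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    out$ok <- TRUE
    out$t_stat <- m / se
    out$ci_low <- m - tq * se
    out$ci_high <- m + tq * se
    out$p_value <- 2 * stats::pt(-abs(out$t_stat), df = n - 1)
  }
  structure(out, class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t test: mean diff %.2f (SD %.2f), n = %d\n",
              x$mean_diff, x$sd_diff, x$n))
  if (isTRUE(x$ok)) {
    cat(sprintf("t(%d) = %.2f, 95%% CI [%.2f, %.2f], p = %.2g\n",
                x$df, x$t_stat, x$ci_low, x$ci_high, x$p_value))
  } else {
    cat("t undefined (zero-variance differences)\n")
  }
  invisible(x)
}

#' The nine symptom models of the group analysis
#'
#' Eight symptom covariates — the single items P1/P2/P3/N1/N4/N6, the positive
#' and negative composites — plus a null model with no covariate.
#'
#' @return character vector of the nine model labels.
#' @export
model_space <- function() {
  c("delusions", "disorganization", "hallucinations", "total positive",
    "blunted affect", "social withdrawal", "lack of spontaneity",
    "total negative", "null")
}

model_covariate <- function(records, model_name) {
  cs <- composite_scores(records)
  switch(model_name,
    "delusions"           = records$p1,
    "disorganization"     = records$p2,
    "hallucinations"      = records$p3,
    "total positive"      = cs$total_positive,
    "blunted affect"      = records$n1,
    "social withdrawal"   = records$n4,
    "lack of spontaneity" = records$n6,
    "total negative"      = cs$total_negative,
    stop("unknown model name '", model_name, "'; valid labels: ",
         paste(model_space(), collapse = ", "))
  )
}

#' Build a second-level (PEB) design matrix
#'
#' For the null model: a single column of ones. For every other model: a
#' constant column followed by the symptom covariate of interest and two
#' covariates of no interest — the binary medication flag and DUP. All
#' covariates are mean-centered, so the constant column encodes the
#' group-mean connectivity. Missing DUP values are imputed with the
#' within-sample mean before centering (so they carry exactly zero weight in
#' the nuisance column).
#'
#' @param records a validated `panss_cohort`.
#' @param model_name one of [model_space()].
#' @return a numeric matrix of class `peb_design` (rows = subjects, named
#'   columns), with attributes `model` and `subject_id`.
#' @export
build_design_matrix <- function(records, model_name) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (identical(model_name, "null")) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "constant"))
  } else {
    covariate <- as.numeric(model_covariate(records, model_name))
    dup <- records$dup_months
    if (anyNA(dup)) {
      message("imputing mean DUP for subject(s) ",
              paste(records$subject_id[is.na(dup)], collapse = ", "))
      dup[is.na(dup)] <- mean(dup, na.rm = TRUE)
    }
    X <- cbind(constant   = 1,
               covariate  = covariate - mean(covariate),
               medication = records$medication - mean(records$medication),
               dup        = dup - mean(dup))
    if (qr(X)$rank < ncol(X))
      stop("design matrix for model '", model_name, "' is rank deficient")
  }
  structure(X, model = model_name, subject_id = records$subject_id,
            class = c("peb_design", class(X)))
}
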