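# Closed category sets of the survey schema. Provinces are the 13 Canadian
# provinces and territories, two-letter postal codes.
PROVINCE_CODES <- c("ON", "QC", "BC", "AB", "MB", "SK", "NS", "NB", "NL",
                    "PE", "YT", "NT", "NU")

SURVEY_LEVELS <- list(
  province = PROVINCE_CODES,
  age_group = c("le40", "gt40"),
  role = c("staff", "resident", "retired"),
  setting = c("academic", "community", "other"),
  subspecialty = c("pediatric", "general", "other"),
  annual_volume_group = c("le50", "gt50"),
  technique = c("extracapsular_monopolar", "cold_steel",
                "intracapsular_microdebrider", "intracapsular_coblator",
                "other"),
  opioid_sparing = c("0", "1"),
  min_age_kind = c("no_limit", "never", "weight_based", "numeric")
)

OPIOID_TOKENS <- c("morphine", "codeine", "oxycodone", "hydromorphone",
                   "fentanyl", "tramadol", "other")

SURVEY_COLUMNS <- c("respondent_id", "province", "age_group", "role",
                    "setting", "subspecialty", "annual_volume_group",
                    "technique", "opioid_sparing", "min_age_kind",
                    "min_age_years", "preferred_opioid",
                    "least_preferred_opioid")

# Fields that enter the modelling phase; respondents missing any of these
# are excluded from every model (the survey's complete-case rule). Practice
# setting is deliberately not in this set: its "other" level is handled by
# the setting dichotomy, not by global exclusion.
MODELING_FIELDS <- c("province", "opioid_sparing", "age_group",
                     "subspecialty", "annual_volume_group", "technique")

#' Construct a survey dataset
#'
#' Validates a respondent-level data frame against the survey schema and
#' attaches a province index (a mapping from the province codes present to
#' contiguous integers) used by the hierarchical model.
#'
#' Missing answers are encoded as `NA` (empty fields in CSV). The opioid
#' preference columns may hold several `;`-separated choices, since
#' respondents could select multiple answers.
#'
#' @param respondents Data frame with columns
#'   `respondent_id, province, age_group, role, setting, subspecialty,
#'   annual_volume_group, technique, opioid_sparing, min_age_kind,
#'   min_age_years, preferred_opioid, least_preferred_opioid`.
#' @return A list of class `survey_dataset` with elements `respondents` and
#'   `province_index`.
#' @export
survey_dataset <- function(respondents) {
  df <- as.data.frame(respondents, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SURVEY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing survey columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[SURVEY_COLUMNS]
  df$respondent_id <- as.character(df$respondent_id)
  if (anyDuplicated(df$respondent_id)) {
    stop("respondent_id values must be unique", call. = FALSE)
  }
  for (col in names(SURVEY_LEVELS)) {
    vals <- as.character(df[[col]])
    vals[!is.na(vals) & vals == ""] <- NA
    bad <- !is.na(vals) & !(vals %in% SURVEY_LEVELS[[col]])
    if (any(bad)) {
      stop(sprintf("unknown %s token(s) at row(s) %s: %s", col,
                   paste(which(bad), collapse = ", "),
                   paste(unique(vals[bad]), collapse = ", ")),
           call. = FALSE)
    }
    df[[col]] <- vals
  }
  df$opioid_sparing <- as.integer(df$opioid_sparing)
  df$min_age_years <- suppressWarnings(as.numeric(df$min_age_years))
  bad_age <- !is.na(df$min_age_years) &
    (df$min_age_years < 0 | df$min_age_years > 18)
  if (any(bad_age)) {
    stop("min_age_years outside [0, 18] at row(s) ",
         paste(which(bad_age), collapse = ", "), call. = FALSE)
  }
  need_years <- !is.na(df$min_age_kind) & df$min_age_kind == "numeric"
  if (any(need_years & is.na(df$min_age_years))) {
    stop("min_age_kind 'numeric' requires min_age_years at row(s) ",
         paste(which(need_years & is.na(df$min_age_years)), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("preferred_opioid", "least_preferred_opioid")) {
    vals <- as.character(df[[col]])
    vals[!is.na(vals) & vals == ""] <- NA
    toks <- strsplit(vals[!is.na(vals)], ";", fixed = TRUE)
    bad <- vapply(toks, function(t) any(!(t %in% OPIOID_TOKENS)), logical(1))
    if (length(bad) && any(bad)) {
      stop("unknown opioid token(s) in ", col, ": ",
           paste(unique(unlist(toks)[!(unlist(toks) %in% OPIOID_TOKENS)]),
                 collapse = ", "), call. = FALSE)
    }
    df[[col]] <- vals
  }
  present <- unique(df$province[!is.na(df$province)])
  present <- PROVINCE_CODES[PROVINCE_CODES %in% present]
  province_index <- stats::setNames(seq_along(present), present)
  structure(list(respondents = df, province_index = province_index),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("Survey dataset: %d respondents across %d provinces\n",
              nrow(x$respondents), length(x$province_index)))
  invisible(x)
}

#' Number of respondents in a survey dataset
#' @param x A `survey_dataset`.
#' @return Integer respondent count.
#' @export
n_respondents <- function(x) {
  stopifnot(inherits(x, "survey_dataset"))
  nrow(x$respondents)
}

#' Read and write the survey CSV
#'
#' The on-disk format is a plain UTF-8 comma-separated file with the exact
#' header of the survey schema; missing answers are empty fields. A
#' write/read round trip preserves every field and row order, and re-writing
#' a freshly read file reproduces it byte for byte.
#'
#' @param path File path.
#' @param dataset A `survey_dataset`.
#' @return `read_survey_csv()` returns a `survey_dataset`;
#'   `write_survey_csv()` invisibly returns `path`.
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(header, paste(SURVEY_COLUMNS, collapse = ","))) {
    stop("malformed survey CSV header (line 1) in ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  if (ncol(df) != length(SURVEY_COLUMNS)) {
    stop("malformed survey CSV: wrong column count", call. = FALSE)
  }
  survey_dataset(df)
}

#' @rdname read_survey_csv
#' @export
write_survey_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  df <- dataset$respondents
  df$min_age_years <- ifelse(is.na(df$min_age_years), NA,
                             format(df$min_age_years, trim = TRUE,
                                    scientific = FALSE))
  utils::write.table(df, path, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Complete-case filter
#'
#' Retains exactly the respondents with no missing value among
#' `required_fields`, mirroring the survey analysis in which incomplete
#' questionnaires are excluded from the modelling phase.
#'
#' @param dataset A `survey_dataset`.
#' @param required_fields Character vector of schema columns that must be
#'   non-missing. Defaults to the modelled fields
#'   (province, outcome and the four always-reported covariates).
#' @return A filtered `survey_dataset` (province index rebuilt). A message
#'   reports how many respondents were removed; an empty result warns.
#' @export
complete_case_filter <- function(dataset,
                                 required_fields = MODELING_FIELDS) {
  stopifnot(inherits(dataset, "survey_dataset"))
  unknown <- setdiff(required_fields, SURVEY_COLUMNS)
  if (length(unknown)) {
    stop("unknown field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  df <- dataset$respondents
  keep <- !Reduce(`|`, lapply(df[required_fields], is.na))
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf("complete-case filter removed %d of %d respondents",
                    removed, nrow(df)))
  }
  if (!any(keep)) warning("complete-case filter removed every respondent")
  survey_dataset(df[keep, , drop = FALSE])
}

#' Dichotomize a survey covariate
#'
#' Deterministic 0/1 coding of the five modelled clinician characteristics:
#' \describe{
#'   \item{age}{`gt40` -> 1, `le40` -> 0.}
#'   \item{subspecialty}{`pediatric` -> 1; `general` and `other` pooled -> 0.}
#'   \item{setting}{`academic` -> 1, `community` -> 0; `other` is treated as
#'     missing by default (the contrast names only two arms) or pooled into
#'     community via `setting_other = "community"`.}
#'   \item{volume}{`gt50` -> 1, `le50` -> 0 (exactly 50 procedures per year
#'     falls in the `le50` arm).}
#'   \item{technique}{`intracapsular_coblator` -> 1, everything else -> 0.
#'     Intracapsular microdebrider is coded 0 by default; set
#'     `microdebrider = "one"` to group it with coblation.}
#' }
#'
#' @param dataset A `survey_dataset`.
#' @param covariate One of `"age"`, `"subspecialty"`, `"setting"`,
#'   `"volume"`, `"technique"`.
#' @param setting_other `"missing"` (default) or `"community"`.
#' @param microdebrider `"zero"` (default) or `"one"`.
#' @return Integer vector of 0/1 (NA where the answer is missing or mapped
#'   to missing), one entry per respondent.
#' @export
dichotomize <- function(dataset, covariate,
                        setting_other = c("missing", "community"),
                        microdebrider = c("zero", "one")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  setting_other <- match.arg(setting_other)
  microdebrider <- match.arg(microdebrider)
  df <- dataset$respondents
  out <- switch(covariate,
    age = ifelse(df$age_group == "gt40", 1L, 0L),
    subspecialty = ifelse(df$subspecialty == "pediatric", 1L, 0L),
    setting = {
      x <- ifelse(df$setting == "academic", 1L,
                  ifelse(df$setting == "community", 0L, NA_integer_))
      if (setting_other == "community") {
        x[!is.na(df$setting) & df$setting == "other"] <- 0L
      }
      x
    },
    volume = ifelse(df$annual_volume_group == "gt50", 1L, 0L),
    technique = {
      one <- df$technique == "intracapsular_coblator"
      if (microdebrider == "one") {
        one <- one | df$technique == "intracapsular_microdebrider"
      }
      ifelse(one, 1L, 0L)
    },
    stop("unknown covariate: ", covariate, call. = FALSE)
  )
  as.integer(out)
}

#' Summarize minimum-age responses
#'
#' Respondents report either no minimum age, never prescribing, a
#' weight-based rule, or a numeric minimum age in years. For the numeric
#' responses this computes mean, SD and a two-sided t confidence interval
#' for the mean (n - 1 degrees of freedom).
#'
#' @param dataset A `survey_dataset`.
#' @param ci_level Confidence level, default 0.95.
#' @return A list of class `min_age_summary` with counts per response kind
#'   (`n_no_limit`, `n_never`, `n_weight_based`, `n_numeric`), `mean_years`,
#'   `sd_years`, `ci_level`, `ci_bounds` and `ci_defined` (FALSE with fewer
#'   than 2 numeric responses).
#' @export
summarize_min_age <- function(dataset, ci_level = 0.95) {
  stopifnot(inherits(dataset, "survey_dataset"))
  df <- dataset$respondents
  kind <- df$min_age_kind
  counts <- vapply(c("no_limit", "never", "weight_based", "numeric"),
                   function(k) sum(!is.na(kind) & kind == k), integer(1))
  years <- df$min_age_years[!is.na(kind) & kind == "numeric"]
  n <- length(years)
  if (n >= 2) {
    m <- mean(years)
    s <- stats::sd(years)
    half <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1) * s / sqrt(n)
    ci <- c(m - half, m + half)
    defined <- TRUE
  } else {
    m <- if (n == 1) years else NA_real_
    s <- NA_real_
    ci <- c(NA_real_, NA_real_)
    defined <- FALSE
  }
  structure(
    list(n_no_limit = counts[["no_limit"]], n_never = counts[["never"]],
         n_weight_based = counts[["weight_based"]],
         n_numeric = n, mean_years = m, sd_years = s,
         ci_level = ci_level, ci_bounds = ci, ci_defined = defined),
    class = "min_age_summary"
  )
}

#' @export
print.min_age_summary <- function(x, ...) {
  cat(sprintf(
    "Minimum-age responses: %d no limit, %d never prescribe, %d weight-based, %d numeric\n",
    x$n_no_limit, x$n_never, x$n_weight_based, x$n_numeric))
  if (x$ci_defined) {
    cat(sprintf("  numeric ages: mean %.1f y (SD %.1f), %d%% CI [%.1f, %.1f]\n",
                x$mean_years, x$sd_years, round(100 * x$ci_level),
                x$ci_bounds[1], x$ci_bounds[2]))
  } else {
    cat("  too few numeric responses for a confidence interval\n")
  }
  invisible(x)
}

#' Tally a categorical survey question
#'
#' Counts and percentages per category over non-missing responses. The
#' opioid-preference questions allow multiple selections (`;`-separated);
#' each selected category counts once per respondent, so multi-select
#' percentages are per-respondent and may total more than 100.
#'
#' @param dataset A `survey_dataset`.
#' @param field A categorical schema column, e.g. `"preferred_opioid"`,
#'   `"least_preferred_opioid"`, `"opioid_sparing"`, `"technique"`.
#' @return Data frame with columns `category`, `count`, `percent` (percent
#'   of non-missing respondents), sorted by decreasing count.
#' @export
tally_preferences <- function(dataset, field) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!field %in% SURVEY_COLUMNS || field %in% c("respondent_id",
                                                 "min_age_years")) {
    stop("`field` must be a categorical survey column", call. = FALSE)
  }
  vals <- as.character(dataset$respondents[[field]])
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  toks <- unlist(strsplit(vals, ";", fixed = TRUE))
  tab <- sort(table(toks), decreasing = TRUE)
  data.frame(
    category = names(tab),
    count = as.integer(tab),
    percent = if (n > 0) 100 * as.integer(tab) / n else numeric(0),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
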