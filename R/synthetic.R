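# Fixed allocation of the remaining provinces in the reconstructed survey:
# only ON/QC/BC proportions are reported, so the rest of the sample is
# spread over 7 further provinces by this documented constant (sums to 32).
PAPER_PROVINCE_COUNTS <- c(ON = 33, QC = 22, BC = 13, AB = 10, MB = 5,
                           SK = 4, NS = 4, NB = 3, NL = 3, PE = 3)

#' Configuration for the synthetic survey generator
#'
#' Defaults emulate the survey the analysis is designed for: about 100
#' respondents clustered in 10 provinces with the reconstructed province
#' mix, covariate prevalences at the reported demographic marginals, an
#' overall opioid-sparing rate near 73% (`true_alpha = logit(0.73)` with no
#' covariate effects), moderate between-province variability
#' (`true_sigma = 0.5`), and a per-field missingness rate chosen so that
#' roughly 4 of 100 respondents have an incomplete questionnaire.
#'
#' @param n_respondents Number of respondents.
#' @param province_weights Named probability vector over province codes
#'   (must sum to 1).
#' @param covariate_prevalences Named fractions for the five binary
#'   covariates (`age`, `subspecialty`, `setting`, `volume`, `technique`),
#'   giving the prevalence of the coded-1 group.
#' @param true_alpha Intercept on the logit scale.
#' @param true_betas Named vector of true covariate effects (logit scale);
#'   names must be covariate names; missing names mean 0.
#' @param true_sigma Between-province SD (>= 0).
#' @param missing_rate Per-modelled-field probability of a missing answer
#'   (missing completely at random).
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_respondents = 100,
                             province_weights = PAPER_PROVINCE_COUNTS /
                               sum(PAPER_PROVINCE_COUNTS),
                             covariate_prevalences = c(age = 0.60,
                                                       subspecialty = 0.24,
                                                       setting = 0.40,
                                                       volume = 0.50,
                                                       technique = 0.16),
                             true_alpha = logit(0.73),
                             true_betas = numeric(0),
                             true_sigma = 0.5,
                             missing_rate = 0.007,
                             seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_respondents < 1) stop("`n_respondents` must be positive", call. = FALSE)
  if (is.null(names(province_weights)) ||
      !all(names(province_weights) %in% PROVINCE_CODES)) {
    stop("`province_weights` must be named with province codes", call. = FALSE)
  }
  if (abs(sum(province_weights) - 1) > 1e-8 || any(province_weights < 0)) {
    stop("`province_weights` must be nonnegative and sum to 1", call. = FALSE)
  }
  if (!all(names(covariate_prevalences) %in% names(COVARIATE_GROUPS)) ||
      any(covariate_prevalences < 0 | covariate_prevalences > 1)) {
    stop("`covariate_prevalences` must be fractions named by covariate",
         call. = FALSE)
  }
  if (length(true_betas) &&
      !all(names(true_betas) %in% names(covariate_prevalences))) {
    stop("`true_betas` names must match covariates", call. = FALSE)
  }
  if (true_sigma < 0) stop("`true_sigma` must be nonnegative", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1) {
    stop("`missing_rate` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_respondents = as.integer(n_respondents),
         province_weights = province_weights,
         covariate_prevalences = covariate_prevalences,
         true_alpha = true_alpha, true_betas = true_betas,
         true_sigma = true_sigma, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# binary covariate value -> survey category token
covariate_token <- function(covariate, value) {
  map <- list(
    age = c("le40", "gt40"),
    subspecialty = c("general", "pediatric"),
    setting = c("community", "academic"),
    volume = c("le50", "gt50"),
    technique = c("extracapsular_monopolar", "intracapsular_coblator")
  )
  map[[covariate]][value + 1L]
}

covariate_source_field <- c(age = "age_group", subspecialty = "subspecialty",
                            setting = "setting",
                            volume = "annual_volume_group",
                            technique = "technique")

#' Generate a synthetic survey dataset
#'
#' Simulates respondent records with the statistical structure the
#' hierarchical model assumes: provinces multinomial, binary covariates
#' independent Bernoulli, province intercepts \eqn{b_j \sim N(0, \sigma)},
#' and outcomes Bernoulli on the logit scale
#' \eqn{\alpha + x^T\beta + b_{j}}. Missing answers are injected completely
#' at random, per modelled field. Deterministic under the config seed.
#'
#' @param config A `synthetic_config`.
#' @return A list: `dataset` (a `survey_dataset`) and `truth` (the hidden
#'   generating parameters: `alpha`, `betas`, `sigma`, per-province `b`),
#'   for parameter-recovery testing.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- config$n_respondents
  provs <- names(config$province_weights)
  province <- sample(provs, n, replace = TRUE,
                     prob = config$province_weights)
  b <- stats::rnorm(length(provs), 0, config$true_sigma)
  names(b) <- provs
  covs <- names(config$covariate_prevalences)
  xmat <- sapply(covs, function(cv) {
    stats::rbinom(n, 1, config$covariate_prevalences[[cv]])
  })
  eta <- rep(config$true_alpha, n) + b[province]
  for (cv in names(config$true_betas)) {
    eta <- eta + config$true_betas[[cv]] * xmat[, cv]
  }
  y <- stats::rbinom(n, 1, invlogit(eta))

  df <- data.frame(
    respondent_id = sprintf("R%03d", seq_len(n)),
    province = province,
    age_group = covariate_token("age", xmat[, "age"]),
    role = "staff",
    setting = covariate_token("setting", xmat[, "setting"]),
    subspecialty = covariate_token("subspecialty", xmat[, "subspecialty"]),
    annual_volume_group = covariate_token("volume", xmat[, "volume"]),
    technique = covariate_token("technique", xmat[, "technique"]),
    opioid_sparing = as.character(y),
    min_age_kind = "no_limit",
    min_age_years = NA_character_,
    preferred_opioid = "morphine",
    least_preferred_opioid = "codeine",
    stringsAsFactors = FALSE
  )
  if (config$missing_rate > 0) {
    for (field in MODELING_FIELDS) {
      drop <- stats::runif(n) < config$missing_rate
      df[[field]][drop] <- NA
    }
  }
  list(dataset = survey_dataset(df),
       truth = list(alpha = config$true_alpha,
                    betas = config$true_betas,
                    sigma = config$true_sigma, b = b))
}

#' Reconstructed survey with the reported marginal frequencies
#'
#' Builds a deterministic-marginal dataset of exactly 100 respondents whose
#' one-way frequencies match the reported demographics: age 40/60
#' (<=40 / >40), role 90/8/2, setting 40 academic / 58 community / 2 other
#' (the published setting counts total 101, so one "other" is dropped),
#' subspecialty 68 general / 24 pediatric / 8 other, technique
#' 68/10/2/16/4, provinces ON 33 / QC 22 / BC 13 with the remaining 32
#' spread by a fixed split, and 73 opioid-sparing outcomes. Exactly 4
#' respondents carry a missing annual-volume answer (the one modelled field
#' without a published marginal), all in the non-sparing arm, so the
#' complete-case set holds 96 respondents with 73 sparing — the modelling
#' sample. Minimum-age responses are 45 no-limit / 2 never / 1 weight-based
#' / 49 numeric (a fixed bimodal set of ages, mean ~8.6 y, SD ~5.7) with 3
#' missing; 82 respondents prefer morphine and 79 least-prefer codeine.
#'
#' The joint distribution across columns is unknown, so each column is
#' independently shuffled under the seed; the fixture supports
#' marginal-level checks, never subgroup-level reproduction.
#'
#' @param seed Integer seed for the joint assignment.
#' @return A `survey_dataset` of 100 respondents.
#' @export
paper_margins_dataset <- function(seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- 100L
  shuffle <- function(x) sample(x, length(x))
  province <- shuffle(rep(names(PAPER_PROVINCE_COUNTS),
                          PAPER_PROVINCE_COUNTS))
  age <- shuffle(rep(c("le40", "gt40"), c(40, 60)))
  role <- shuffle(rep(c("staff", "resident", "retired"), c(90, 8, 2)))
  setting <- shuffle(rep(c("academic", "community", "other"), c(40, 58, 2)))
  subspec <- shuffle(rep(c("general", "pediatric", "other"), c(68, 24, 8)))
  technique <- shuffle(rep(c("extracapsular_monopolar", "cold_steel",
                             "intracapsular_microdebrider",
                             "intracapsular_coblator", "other"),
                           c(68, 10, 2, 16, 4)))
  outcome <- shuffle(rep(c(1L, 0L), c(73, 27)))
  # volume is unreported: even split among the 96 complete cases; the 4
  # incomplete questionnaires (missing volume) come from the non-sparing arm
  volume <- shuffle(rep(c("le50", "gt50"), c(48, 48)))
  incomplete <- sample(which(outcome == 0L), 4)
  vol_full <- character(n)
  vol_full[-incomplete] <- volume
  vol_full[incomplete] <- NA_character_

  min_age_kind <- shuffle(rep(c("no_limit", "never", "weight_based",
                                "numeric", NA),
                              c(45, 2, 1, 49, 3)))
  ages <- shuffle(c(rep(2, 6), rep(3, 7), rep(4, 7), rep(5, 7),
                    rep(13, 3), rep(14, 5), rep(15, 8), rep(16, 6)))
  min_age_years <- rep(NA_real_, n)
  min_age_years[!is.na(min_age_kind) & min_age_kind == "numeric"] <- ages
  preferred <- shuffle(rep(c("morphine", "other"), c(82, 18)))
  least <- shuffle(rep(c("codeine", "other"), c(79, 21)))

  survey_dataset(data.frame(
    respondent_id = sprintf("R%03d", seq_len(n)),
    province = province, age_group = age, role = role, setting = setting,
    subspecialty = subspec, annual_volume_group = vol_full,
    technique = technique, opioid_sparing = as.character(outcome),
    min_age_kind = min_age_kind, min_age_years = min_age_years,
    preferred_opioid = preferred, least_preferred_opioid = least,
    stringsAsFactors = FALSE
  ))
}
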