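#' Logit and inverse-logit transforms
#'
#' `logit()` maps a probability in the open interval (0, 1) to the log-odds
#' scale; `invlogit()` is its inverse. These are used throughout: the
#' intercept prior of the hierarchical model lives on the logit scale, and
#' posterior draws are mapped back to probabilities with `invlogit()`.
#'
#' @param p Numeric vector of probabilities, all strictly inside (0, 1).
#' @param x Numeric vector on the log-odds scale.
#' @return Numeric vector of the same length.
#' @examples
#' logit(0.61)      # ~0.447, the default intercept prior centre
#' invlogit(0)      # 0.5
#' @export
logit <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must be strictly inside (0, 1)", call. = FALSE)
  }
  log(p) - log1p(-p)
}

#' @rdname logit
#' @export
invlogit <- function(x) {
  stats::plogis(x)
}

#' Construct a table of historical studies for prior elicitation
#'
#' Each study contributes a reported proportion of opioid-sparing practice
#' together with its sample size and publication year. Recency is measured
#' from a reference year (by default 2013, the year of the FDA black-box
#' warning against codeine after pediatric adenotonsillectomy, taken as the
#' point after which practice plausibly started shifting).
#'
#' @param study_id Character vector of short labels.
#' @param publication_year Integer vector of calendar years; every year must
#'   be strictly after `reference_year` (see [compute_study_weights()]).
#' @param sample_size Positive integer vector of respondent counts.
#' @param sparing_proportion Numeric vector of opioid-sparing proportions,
#'   strictly inside (0, 1).
#' @return A data frame of class `historical_studies`.
#' @export
historical_studies <- function(study_id, publication_year, sample_size,
                               sparing_proportion) {
  n <- length(study_id)
  if (n < 1) stop("at least one study is required", call. = FALSE)
  lens <- c(length(publication_year), length(sample_size),
            length(sparing_proportion))
  if (any(lens != n)) stop("all fields must have equal length", call. = FALSE)
  if (any(sample_size < 1 | sample_size != round(sample_size))) {
    stop("`sample_size` must be positive integers", call. = FALSE)
  }
  if (any(sparing_proportion <= 0 | sparing_proportion >= 1)) {
    stop("`sparing_proportion` must lie strictly inside (0, 1)", call. = FALSE)
  }
  out <- data.frame(
    study_id = as.character(study_id),
    publication_year = as.integer(publication_year),
    sample_size = as.integer(sample_size),
    sparing_proportion = as.numeric(sparing_proportion),
    stringsAsFactors = FALSE
  )
  class(out) <- c("historical_studies", "data.frame")
  out
}

#' Read historical studies from CSV
#'
#' Expects the header `study_id,publication_year,sample_size,sparing_proportion`.
#'
#' @param path Path to a UTF-8, comma-separated file.
#' @return A `historical_studies` data frame.
#' @export
read_historical_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("study_id", "publication_year", "sample_size",
              "sparing_proportion")
  if (!identical(names(df), needed)) {
    stop("historical-study CSV header must be exactly: ",
         paste(needed, collapse = ","), call. = FALSE)
  }
  historical_studies(df$study_id, df$publication_year, df$sample_size,
                     df$sparing_proportion)
}

#' Recency- and size-weighted study weights
#'
#' Assigns each historical study a weight proportional to
#' \eqn{t_i \, n_i \, p_i (1 - p_i)}, where \eqn{t_i} is the number of years
#' between publication and the reference year, \eqn{n_i} the sample size and
#' \eqn{p_i} the reported opioid-sparing proportion, then normalizes the
#' weights to sum to one. Larger and more recent studies therefore carry
#' more weight, as do studies whose proportion is estimated with more
#' Bernoulli information per respondent.
#'
#' An alternative scheme, `"inverse_variance"`, weights by
#' \eqn{t_i \, n_i / (p_i (1 - p_i))} — recency times the inverse of the
#' binomial variance of the reported proportion, the form standard
#' meta-analysis would use — and is provided for sensitivity analysis.
#'
#' @param studies A `historical_studies` data frame.
#' @param reference_year Integer year from which recency is counted
#'   (default 2013). Every study must postdate it; studies published in or
#'   before the reference year are rejected rather than silently given zero
#'   weight.
#' @param scheme `"recency_size"` (default) or `"inverse_variance"`.
#' @return Numeric weight vector summing to 1, named by `study_id`.
#' @examples
#' st <- historical_studies(c("A", "B"), c(2014, 2019), c(100, 200), c(0.2, 0.6))
#' compute_study_weights(st)  # ~ c(0.053, 0.947)
#' @export
compute_study_weights <- function(studies, reference_year = 2013,
                                  scheme = c("recency_size",
                                             "inverse_variance")) {
  scheme <- match.arg(scheme)
  if (!inherits(studies, "historical_studies")) {
    studies <- historical_studies(studies$study_id, studies$publication_year,
                                  studies$sample_size,
                                  studies$sparing_proportion)
  }
  bad <- studies$publication_year <= reference_year
  if (any(bad)) {
    stop("study published in or before the reference year ", reference_year,
         ": ", paste(studies$study_id[bad], collapse = ", "), call. = FALSE)
  }
  t_i <- studies$publication_year - reference_year
  n_i <- studies$sample_size
  p_i <- studies$sparing_proportion
  raw <- switch(scheme,
    recency_size = t_i * n_i * p_i * (1 - p_i),
    inverse_variance = t_i * n_i / (p_i * (1 - p_i))
  )
  w <- raw / sum(raw)
  names(w) <- studies$study_id
  w
}

#' Weighted pooled prior proportion
#'
#' The elicited prior probability of opioid-sparing practice: the weighted
#' mean \eqn{\sum_i w_i p_i} of the historical proportions.
#'
#' @param studies A `historical_studies` data frame.
#' @param weights Weight vector as returned by [compute_study_weights()].
#' @return A single probability in (0, 1).
#' @export
pooled_prior_proportion <- function(studies, weights) {
  if (length(weights) != nrow(studies)) {
    stop("`weights` must have one entry per study", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("`weights` must be nonnegative and sum to 1", call. = FALSE)
  }
  sum(weights * studies$sparing_proportion)
}

#' Prior hyperparameters of the hierarchical model
#'
#' Bundles every prior hyperparameter: a Normal prior on the intercept
#' (logit scale), Normal(0, `coef_sd`) priors on covariate coefficients, and
#' an Exponential(`re_sd_rate`) prior on the between-province SD of the
#' random intercepts.
#'
#' Defaults follow the elicited analysis: intercept centred at
#' `logit(pooled)` with SD 1.18 (a Normal chosen to approximate a logistic
#' distribution on the probability scale), coefficient SD 0.5 (no prior
#' expectation of association, similar implied group-level probability
#' spread), and unit-rate Exponential on the random-intercept SD (weakly
#' informative in the absence of prior knowledge of inter-provincial
#' variability).
#'
#' @param pooled Prior pooled probability of opioid-sparing practice in (0, 1).
#' @param intercept_sd Positive SD of the intercept prior (logit scale).
#' @param coef_sd Positive SD of the coefficient priors.
#' @param re_sd_rate Positive rate of the Exponential prior on the
#'   random-intercept SD.
#' @param reference_year Reference year used in elicitation (stored for the
#'   run manifest).
#' @return A list of class `prior_config` with fields `reference_year`,
#'   `intercept_mean`, `intercept_sd`, `coef_sd`, `re_sd_rate`.
#' @examples
#' build_prior_config(0.61)  # intercept_mean ~0.447
#' @export
build_prior_config <- function(pooled, intercept_sd = 1.18, coef_sd = 0.5,
                               re_sd_rate = 1.0, reference_year = 2013) {
  if (length(pooled) != 1 || pooled <= 0 || pooled >= 1) {
    stop("`pooled` must be a single probability in (0, 1)", call. = FALSE)
  }
  if (intercept_sd <= 0 || coef_sd <= 0 || re_sd_rate <= 0) {
    stop("`intercept_sd`, `coef_sd` and `re_sd_rate` must be strictly positive",
         call. = FALSE)
  }
  structure(
    list(
      reference_year = as.integer(reference_year),
      intercept_mean = logit(pooled),
      intercept_sd = as.numeric(intercept_sd),
      coef_sd = as.numeric(coef_sd),
      re_sd_rate = as.numeric(re_sd_rate)
    ),
    class = "prior_config"
  )
}

#' @export
print.prior_config <- function(x, ...) {
  cat("Prior configuration\n")
  cat(sprintf("  intercept  ~ Normal(%.4f, %.3f)  [logit scale; centre = %.1f%% probability]\n",
              x$intercept_mean, x$intercept_sd, 100 * invlogit(x$intercept_mean)))
  cat(sprintf("  coefficients ~ Normal(0, %.3f)\n", x$coef_sd))
  cat(sprintf("  province SD  ~ Exponential(rate = %.3f)\n", x$re_sd_rate))
  invisible(x)
}

#' Write / read a prior configuration as YAML
#'
#' @param config A `prior_config` object.
#' @param path Output path.
#' @return `read_prior_yaml()` returns a `prior_config`.
#' @export
write_prior_yaml <- function(config, path) {
  stopifnot(inherits(config, "prior_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_prior_yaml
#' @export
read_prior_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- build_prior_config(invlogit(x$intercept_mean),
                            intercept_sd = x$intercept_sd,
                            coef_sd = x$coef_sd,
                            re_sd_rate = x$re_sd_rate,
                            reference_year = x$reference_year)
  # round-trip exactly: invlogit/logit can lose the last ulp
  cfg$intercept_mean <- x$intercept_mean
  cfg
}

#' Monte-Carlo prior predictive interval for the sparing probability
#'
#' Characterizes the prior implied for the probability of opioid-sparing
#' prescribing in a new province by simulation: draws
#' \eqn{\mu \sim N(\mathrm{intercept\_mean}, \mathrm{intercept\_sd})},
#' \eqn{\sigma \sim \mathrm{Exp}(\mathrm{re\_sd\_rate})},
#' \eqn{b \mid \sigma \sim N(0, \sigma)} and reports the equal-tailed
#' interval of \eqn{\mathrm{invlogit}(\mu + b)}. The random-intercept layer
#' widens the interval relative to the plain Normal logit prior.
#'
#' @param config A `prior_config`.
#' @param level Interval level in (0, 1), default 0.90.
#' @param n_draws Number of Monte-Carlo draws (at least 1000; default 2e5).
#' @param seed Integer seed (mandatory: the interval is a Monte-Carlo
#'   estimate and must be reproducible).
#' @return A list of class `prior_estimate` with `pooled_proportion`,
#'   `logit_mean`, `interval_level` and `prior_interval` (lower, upper).
#' @export
prior_predictive_interval <- function(config, level = 0.90, n_draws = 2e5,
                                      seed) {
  stopifnot(inherits(config, "prior_config"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be a single value in (0, 1)", call. = FALSE)
  }
  if (n_draws < 1000) stop("`n_draws` must be at least 1000", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  mu <- stats::rnorm(n_draws, config$intercept_mean, config$intercept_sd)
  sigma <- stats::rexp(n_draws, config$re_sd_rate)
  b <- stats::rnorm(n_draws, 0, sigma)
  p <- invlogit(mu + b)
  alpha <- (1 - level) / 2
  ci <- stats::quantile(p, c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(
      pooled_proportion = invlogit(config$intercept_mean),
      logit_mean = config$intercept_mean,
      interval_level = level,
      prior_interval = ci
    ),
    class = "prior_estimate"
  )
}

#' @export
print.prior_estimate <- function(x, ...) {
  cat(sprintf(
    "Elicited prior: %.1f%% sparing (logit mean %.3f), %d%% prior interval [%.1f%%, %.1f%%]\n",
    100 * x$pooled_proportion, x$logit_mean, round(100 * x$interval_level),
    100 * x$prior_interval[1], 100 * x$prior_interval[2]))
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
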