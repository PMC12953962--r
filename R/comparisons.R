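# Reference / index group labels for each dichotomized covariate, in the
# direction the dichotomy codes them (index = coded 1).
COVARIATE_GROUPS <- list(
  age = c(reference = "age <=40 y", index = "age >40 y"),
  subspecialty = c(reference = "general/other", index = "pediatric ORL"),
  setting = c(reference = "community", index = "academic"),
  volume = c(reference = "<=50 cases/y", index = ">50 cases/y"),
  technique = c(reference = "other technique", index = "intracapsular coblation")
)

#' Posterior probability of superiority
#'
#' Fraction of posterior draws in which one group's sparing probability
#' exceeds the other's. With `paired = TRUE` (the default, for draw vectors
#' from the same fit) the comparison is made draw by draw; ties count 0.5.
#' Unpaired vectors are compared across all pairs (rank-based, computed
#' without forming the pair grid). The statistic depends only on ranks, so
#' it is invariant under any strictly monotone transform applied to both
#' vectors.
#'
#' @param draws_a,draws_b Numeric draw vectors (probabilities or any
#'   monotone transform of them); equal length required when paired.
#' @param paired Compare draw-by-draw (default) or across all pairs.
#' @return Fraction in [0, 1]: the posterior probability that `a` exceeds
#'   `b`.
#' @export
superiority_probability <- function(draws_a, draws_b, paired = TRUE) {
  if (!length(draws_a) || !length(draws_b)) {
    stop("draw vectors must be non-empty", call. = FALSE)
  }
  if (paired) {
    if (length(draws_a) != length(draws_b)) {
      stop("paired comparison requires equal-length draw vectors",
           call. = FALSE)
    }
    return(mean((draws_a > draws_b) + 0.5 * (draws_a == draws_b)))
  }
  sb <- sort(draws_b)
  n_b <- length(sb)
  # for each a: #(b < a) + 0.5 * #(b == a)
  lo <- findInterval(draws_a, sb, left.open = TRUE)   # strictly less
  hi <- findInterval(draws_a, sb)                      # less or equal
  mean((lo + 0.5 * (hi - lo)) / n_b)
}

#' Fit a univariate comparison model
#'
#' Fits the hierarchical Bernoulli-logit model with a single dichotomized
#' clinician characteristic and province random intercepts, and summarizes
#' the two groups' sparing probabilities at the median province
#' (\eqn{b = 0}): reference group \eqn{\mathrm{invlogit}(\alpha)}, index
#' group \eqn{\mathrm{invlogit}(\alpha + \beta)}. The posterior probability
#' that the index group is more opioid-sparing is the fraction of draws
#' with \eqn{\beta > 0} (ties at exactly 0 count 0.5).
#'
#' Respondents are first restricted to the modelling complete-case set,
#' then to those with a defined value of the dichotomized covariate (the
#' practice-setting contrast excludes the "other" setting by default).
#'
#' @param dataset A `survey_dataset`.
#' @param covariate One of `"age"`, `"subspecialty"`, `"setting"`,
#'   `"volume"`, `"technique"`.
#' @param prior A `prior_config`.
#' @param level Credible level for the group summaries (default 0.90).
#' @param seed Integer seed.
#' @param ... Passed to [sample_posterior()] (chains, iterations, ...).
#' @return A list of class `comparison_result`: `covariate`, `groups`,
#'   `draws_reference`, `draws_index` (probability draws), `summary` (per
#'   group), `superiority_probability`, `n`, and `fit` (the
#'   `posterior_draws`).
#' @export
fit_univariate <- function(dataset, covariate, prior, level = 0.90, seed,
                           ...) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!covariate %in% names(COVARIATE_GROUPS)) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  cc <- suppressMessages(complete_case_filter(dataset))
  x <- dichotomize(cc, covariate)
  keep <- !is.na(x)
  df <- cc$respondents[keep, , drop = FALSE]
  x <- x[keep]
  groups <- COVARIATE_GROUPS[[covariate]]
  for (arm in c(0, 1)) {
    if (!any(x == arm)) {
      stop(sprintf("empty arm for covariate '%s': no respondents in group '%s'",
                   covariate, groups[[arm + 1]]), call. = FALSE)
    }
  }
  X <- matrix(x, ncol = 1, dimnames = list(NULL, covariate))
  spec <- model_spec(df$opioid_sparing, X, df$province, prior)
  fit <- sample_posterior(spec, seed = seed, ...)
  comparison_from_fit(fit, covariate, level)
}

# Build a comparison_result from a fitted single-covariate model.
comparison_from_fit <- function(fit, covariate, level = 0.90) {
  m <- as_draws_matrix(fit)
  beta <- m[, paste0("beta_", covariate)]
  p_ref <- invlogit(m[, "alpha"])
  p_idx <- invlogit(m[, "alpha"] + beta)
  smry <- summarize_posterior(
    cbind(reference = p_ref, index = p_idx), level = level)
  structure(
    list(covariate = covariate,
         groups = COVARIATE_GROUPS[[covariate]],
         draws_reference = p_ref, draws_index = p_idx,
         summary = smry,
         superiority_probability = mean((beta > 0) + 0.5 * (beta == 0)),
         n = length(fit$spec$y),
         fit = fit),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  s <- x$summary
  lev <- round(100 * attr(s, "level"))
  cat(sprintf("Comparison: %s (n = %d complete)\n", x$covariate, x$n))
  for (i in 1:2) {
    cat(sprintf("  %-24s %.0f%% %d%% CrI [%.0f%%, %.0f%%]\n",
                x$groups[[i]], 100 * s$mean[i], lev,
                100 * s$lower[i], 100 * s$upper[i]))
  }
  cat(sprintf("  P(%s more sparing) = %.0f%%\n", x$groups[["index"]],
              100 * x$superiority_probability))
  invisible(x)
}

#' Fit a multivariable comparison model
#'
#' Same model family with several dichotomized covariates at once; complete
#' cases across all of them. Duplicate (collinear) columns are tolerated
#' with a warning — the Normal(0, coef_sd) priors regularize the fit.
#'
#' @inheritParams fit_univariate
#' @param covariates Character vector of two or more covariate names.
#' @return A list of class `multivariable_fit`: `fit` (the
#'   `posterior_draws`), `covariates`, per-covariate `summary` (posterior
#'   mean and CrI of each beta plus its superiority probability), and `n`.
#' @export
fit_multivariable <- function(dataset, covariates, prior, level = 0.90,
                              seed, ...) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (length(covariates) < 2) {
    stop("`covariates` must name at least two covariates", call. = FALSE)
  }
  unknown <- setdiff(unique(covariates), names(COVARIATE_GROUPS))
  if (length(unknown)) stop("unknown covariate(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cc <- suppressMessages(complete_case_filter(dataset))
  cols <- lapply(covariates, function(cv) dichotomize(cc, cv))
  keep <- !Reduce(`|`, lapply(cols, is.na))
  df <- cc$respondents[keep, , drop = FALSE]
  X <- do.call(cbind, lapply(cols, function(v) v[keep]))
  cn <- make.unique(covariates, sep = "_dup")
  colnames(X) <- cn
  dup <- duplicated(t(X))
  if (any(dup)) {
    warning("collinear duplicate covariate column(s): ",
            paste(cn[dup], collapse = ", "), call. = FALSE)
  }
  spec <- model_spec(df$opioid_sparing, X, df$province, prior)
  fit <- sample_posterior(spec, seed = seed, ...)
  m <- as_draws_matrix(fit)
  betas <- m[, paste0("beta_", cn), drop = FALSE]
  smry <- summarize_posterior(betas, level = level)
  smry$superiority_probability <-
    apply(betas, 2, function(b) mean((b > 0) + 0.5 * (b == 0)))
  structure(
    list(fit = fit, covariates = cn, summary = smry, n = length(spec$y)),
    class = "multivariable_fit"
  )
}

#' @export
print.multivariable_fit <- function(x, ...) {
  cat(sprintf("Multivariable model: %s (n = %d complete)\n",
              paste(x$covariates, collapse = " + "), x$n))
  print(x$summary, digits = 3)
  invisible(x)
}
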