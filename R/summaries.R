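#' Posterior means and equal-tailed credible intervals
#'
#' Summarizes posterior draws as means with equal-tailed credible intervals
#' (quantiles at (1-level)/2 and 1-(1-level)/2, linear interpolation).
#' Results are reported at 90% by default: in a survey of this size the
#' extreme quantiles needed for wider intervals are estimated poorly.
#'
#' @param x A `posterior_draws`, a numeric vector of draws, or a matrix with
#'   one column per quantity.
#' @param level Credible level in (0, 1), default 0.90.
#' @param functionals Optional named list of functions, each mapping the
#'   merged draws matrix to a vector of per-draw values; summaries of these
#'   are appended (e.g. a probability-of-sparing functional).
#' @return Data frame of class `posterior_summary` with columns `quantity`,
#'   `mean`, `lower`, `upper`, plus `level` attribute.
#' @export
summarize_posterior <- function(x, level = 0.90, functionals = NULL) {
  if (length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be a single value in (0, 1)", call. = FALSE)
  }
  if (inherits(x, "posterior_draws")) {
    m <- as_draws_matrix(x)
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(colnames(m))) colnames(m) <- paste0("q", seq_len(ncol(m)))
  } else {
    m <- matrix(as.numeric(x), ncol = 1,
                dimnames = list(NULL, deparse(substitute(x))))
  }
  if (nrow(m) == 0) stop("draws are empty", call. = FALSE)
  cols <- lapply(seq_len(ncol(m)), function(j) m[, j])
  names(cols) <- colnames(m)
  if (!is.null(functionals)) {
    extra <- lapply(functionals, function(f) f(m))
    cols <- c(cols, extra)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- data.frame(
    quantity = names(cols),
    mean = vapply(cols, mean, numeric(1)),
    lower = vapply(cols, function(v) stats::quantile(v, probs[1], names = FALSE),
                   numeric(1)),
    upper = vapply(cols, function(v) stats::quantile(v, probs[2], names = FALSE),
                   numeric(1)),
    row.names = NULL
  )
  attr(out, "level") <- level
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Per-draw probability of opioid-sparing prescribing
#'
#' Maps posterior draws to the probability scale. Two functionals are
#' available:
#' \describe{
#'   \item{`new_province`}{the marginal probability for a respondent from a
#'     fresh province: \eqn{\mathrm{invlogit}(\alpha + b^*)} with
#'     \eqn{b^* \sim N(0, \sigma)} drawn fresh per posterior draw (seeded).
#'     This propagates between-province variability and is the default
#'     headline functional.}
#'   \item{`median_province`}{the probability at the median province
#'     (\eqn{b = 0}): \eqn{\mathrm{invlogit}(\alpha)}. Used for subgroup
#'     comparison curves.}
#' }
#'
#' @param draws A `posterior_draws` from an intercept-only or covariate
#'   model (the covariates are held at 0, i.e. the reference group).
#' @param mode `"new_province"` (default) or `"median_province"`.
#' @param seed Integer seed for the fresh province intercepts (required for
#'   `new_province`).
#' @return Numeric vector of probabilities, one per merged draw.
#' @export
probability_of_sparing <- function(draws,
                                   mode = c("new_province",
                                            "median_province"),
                                   seed = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  mode <- match.arg(mode)
  m <- as_draws_matrix(draws)
  alpha <- m[, "alpha"]
  if (mode == "median_province" || !draws$spec$include_re) {
    return(invlogit(alpha))
  }
  if (is.null(seed)) {
    stop("`seed` is required for new_province mode", call. = FALSE)
  }
  sigma <- m[, "sigma"]
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  bstar <- stats::rnorm(length(alpha), 0, sigma)
  invlogit(alpha + bstar)
}
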