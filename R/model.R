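#' Specify a hierarchical Bernoulli-logit model
#'
#' The model for respondent \eqn{i} in province \eqn{j(i)} is
#' \deqn{y_i \sim \mathrm{Bernoulli}(\mathrm{invlogit}(\alpha + x_i^T\beta + b_{j(i)})),
#'       \quad b_j \sim N(0, \sigma),}
#' with priors taken from a [build_prior_config()] object: Normal on the
#' intercept \eqn{\alpha}, Normal(0, coef_sd) on each coefficient, and
#' Exponential on the between-province SD \eqn{\sigma}. Only complete cases
#' are admitted: no element of `y`, `X` or `province` may be missing.
#'
#' @param y Binary outcome vector (1 = opioid-sparing).
#' @param X Numeric matrix of binary covariate columns (may have 0 columns);
#'   column names label the coefficients.
#' @param province Factor, character or integer vector of province labels,
#'   one per observation; levels are indexed contiguously.
#' @param prior A `prior_config`.
#' @param include_re Include province random intercepts (default TRUE). With
#'   `FALSE` the model is a plain logistic regression (\eqn{\sigma} fixed at
#'   0, no \eqn{b}).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(y, X = NULL, province = NULL, prior,
                       include_re = TRUE) {
  stopifnot(inherits(prior, "prior_config"))
  y <- as.numeric(y)
  n <- length(y)
  if (any(is.na(y)) || !all(y %in% c(0, 1))) {
    stop("`y` must be 0/1 with no missing values (complete cases only)",
         call. = FALSE)
  }
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("`X` must have one row per observation", call. = FALSE)
  if (anyNA(X)) stop("`X` must not contain missing values", call. = FALSE)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (include_re) {
    if (is.null(province)) stop("`province` is required when include_re = TRUE",
                                call. = FALSE)
    if (length(province) != n || anyNA(province)) {
      stop("`province` must be complete, one entry per observation",
           call. = FALSE)
    }
    f <- factor(province)
    province_levels <- levels(f)
    province_id <- as.integer(f)
  } else {
    province_levels <- character(0)
    province_id <- rep(1L, n)
  }
  structure(
    list(y = y, X = X, province_id = province_id,
         province_levels = province_levels, prior = prior,
         include_re = include_re),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "Bernoulli-logit model: %d observations, %d covariate(s), %s\n",
    length(x$y), ncol(x$X),
    if (x$include_re) sprintf("%d province random intercepts",
                              length(x$province_levels))
    else "no random intercepts"))
  invisible(x)
}

# Ordered parameter names of a spec: intercept, coefficients, then (if the
# random-intercept layer is on) the between-province SD and one intercept
# per province.
param_names <- function(spec) {
  nm <- "alpha"
  if (ncol(spec$X) > 0) nm <- c(nm, paste0("beta_", colnames(spec$X)))
  if (spec$include_re) {
    nm <- c(nm, "sigma",
            if (length(spec$province_levels))
              paste0("b_", spec$province_levels))
  }
  nm
}

#' Model log likelihood
#'
#' Sum of Bernoulli-logit log densities
#' \eqn{\sum_i y_i \log p_i + (1-y_i)\log(1-p_i)} with
#' \eqn{p_i = \mathrm{invlogit}(\alpha + x_i^T\beta + b_{j(i)})}, computed in
#' a form stable for linear predictors up to |eta| ~ 700.
#'
#' @param params List with elements `alpha` (scalar), `beta` (one per
#'   covariate), `sigma` (positive scalar; ignored when the spec has no
#'   random intercepts) and `b` (one per province).
#' @param spec A `model_spec`.
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(params, spec) {
  stopifnot(inherits(spec, "model_spec"))
  eta <- linear_predictor(params, spec)
  sum(spec$y * eta - softplus(eta))
}

# eta_i = alpha + x_i' beta + b_{province(i)}
linear_predictor <- function(params, spec) {
  K <- ncol(spec$X)
  beta <- if (is.null(params$beta)) numeric(0) else params$beta
  if (length(beta) != K) {
    stop("`beta` must have one entry per covariate", call. = FALSE)
  }
  eta <- rep(params$alpha, length(spec$y))
  if (K > 0) eta <- eta + drop(spec$X %*% beta)
  if (spec$include_re) {
    b <- params$b
    if (length(b) != length(spec$province_levels)) {
      stop("`b` must have one entry per province", call. = FALSE)
    }
    eta <- eta + b[spec$province_id]
  }
  eta
}

softplus <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

#' Model log prior
#'
#' Joint log prior density of the parameters under a `prior_config`, up to
#' an additive constant that does not depend on the parameters: Normal on
#' the intercept, Normal(0, coef_sd) on each coefficient, Exponential on the
#' random-intercept SD and Normal(0, sigma) on each province intercept.
#' A non-positive `sigma` returns `-Inf` (rejection), not an error.
#'
#' @inheritParams log_likelihood
#' @param prior A `prior_config`.
#' @return Scalar log prior density; `-Inf` outside the support.
#' @export
log_prior <- function(params, prior) {
  stopifnot(inherits(prior, "prior_config"))
  lp <- stats::dnorm(params$alpha, prior$intercept_mean, prior$intercept_sd,
                     log = TRUE)
  if (length(params$beta)) {
    lp <- lp + sum(stats::dnorm(params$beta, 0, prior$coef_sd, log = TRUE))
  }
  if (!is.null(params$sigma) || length(params$b)) {
    sigma <- params$sigma
    if (is.null(sigma) || sigma <= 0) return(-Inf)
    lp <- lp + stats::dexp(sigma, prior$re_sd_rate, log = TRUE)
    if (length(params$b)) {
      lp <- lp + sum(stats::dnorm(params$b, 0, sigma, log = TRUE))
    }
  }
  lp
}
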