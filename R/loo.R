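log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Pointwise log likelihood matrix
#'
#' Bernoulli-logit log density of every observation under every posterior
#' draw; the input to leave-one-out computations. Row sums reproduce the
#' per-draw model log likelihood.
#'
#' @param draws A `posterior_draws`.
#' @param spec The `model_spec` the draws were fitted to (defaults to the
#'   spec stored in `draws`).
#' @return Matrix (merged draws) x observations.
#' @export
pointwise_loglik <- function(draws, spec = draws$spec) {
  stopifnot(inherits(draws, "posterior_draws"), inherits(spec, "model_spec"))
  m <- as_draws_matrix(draws)
  n <- length(spec$y)
  K <- ncol(spec$X)
  if (K > 0) {
    bnames <- paste0("beta_", colnames(spec$X))
    if (!all(bnames %in% colnames(m))) {
      stop("draws do not contain coefficients for this spec", call. = FALSE)
    }
  }
  eta <- matrix(m[, "alpha"], nrow = nrow(m), ncol = n)
  if (K > 0) {
    eta <- eta + m[, paste0("beta_", colnames(spec$X)), drop = FALSE] %*%
      t(spec$X)
  }
  if (spec$include_re) {
    bcols <- paste0("b_", spec$province_levels)
    if (!all(bcols %in% colnames(m))) {
      stop("draws do not contain province intercepts for this spec",
           call. = FALSE)
    }
    eta <- eta + m[, bcols, drop = FALSE][, spec$province_id, drop = FALSE]
  }
  ll <- sweep(eta, 2, spec$y, function(e, y) y * e) - softplus_mat(eta)
  dimnames(ll) <- NULL
  ll
}

softplus_mat <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# Zhang-Stephens (2009) generalized Pareto fit to exceedances x > 0 via a
# quantile grid over theta = -xi/sigma with profile-likelihood weights.
# Returns the shape xi ("Pareto k") and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) stop("need at least 5 exceedances", call. = FALSE)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of <- function(th) -mean(log1p(-th * x))
  prof <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m),
                  function(j) sum(exp(prof - prof[j])), numeric(1))
  theta_hat <- sum(theta * w)
  xi <- mean(log1p(-theta_hat * x))
  sigma <- -xi / theta_hat
  list(xi = xi, sigma = sigma)
}

qgpd <- function(p, xi, sigma) {
  if (abs(xi) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-xi * log1p(-p)) / xi
}

#' PSIS leave-one-out expected log predictive density
#'
#' Estimates the leave-one-out ELPD from a pointwise log-likelihood matrix
#' by Pareto-smoothed importance sampling. For each observation the raw
#' importance ratios are the reciprocals of the likelihood; the largest
#' \eqn{M = \min(\lceil 0.2 S \rceil, \lceil 3\sqrt{S} \rceil)} ratios are
#' fitted to a generalized Pareto distribution, replaced by the
#' corresponding expected order statistics, and truncated at the raw
#' maximum. The fitted shape (`pareto_k`) diagnoses reliability; values
#' above 0.7 are flagged with a warning.
#'
#' @param loglik Matrix of pointwise log likelihoods, draws x observations.
#' @return A list of class `elpd_result`: `pointwise_elpd`, `total_elpd`,
#'   `se` (\eqn{\sqrt{n \,\mathrm{var}}} of the pointwise values),
#'   `pareto_k` per observation, `method = "psis"`.
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (anyNA(loglik) || any(!is.finite(loglik))) {
    stop("`loglik` must be finite", call. = FALSE)
  }
  S <- nrow(loglik)
  n <- ncol(loglik)
  if (S < 400) warning("fewer than 400 draws; PSIS-LOO may be unreliable",
                       call. = FALSE)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    lw <- -loglik[, i]
    lw <- lw - max(lw)
    ord <- order(lw)
    tail_idx <- ord[(S - M + 1):S]
    cutpoint <- lw[ord[S - M]]
    exceed <- exp(lw[tail_idx]) - exp(cutpoint)
    if (M >= 5 && stats::sd(exceed) > 0) {
      fit <- gpd_fit(exceed)
      pareto_k[i] <- fit$xi
      p_grid <- (rank(lw[tail_idx], ties.method = "first") - 0.5) / M
      smoothed <- exp(cutpoint) + qgpd(p_grid, fit$xi, fit$sigma)
      lw[tail_idx] <- pmin(log(smoothed), 0)  # truncate at raw max (= 0)
    } else {
      pareto_k[i] <- 0  # degenerate tail: nothing to smooth
    }
    pointwise[i] <- log_sum_exp(lw + loglik[, i]) - log_sum_exp(lw)
  }
  if (any(pareto_k > 0.7)) {
    warning(sprintf("%d observation(s) with Pareto k > 0.7; PSIS estimate unreliable there",
                    sum(pareto_k > 0.7)), call. = FALSE)
  }
  new_elpd_result(pointwise, pareto_k, "psis")
}

new_elpd_result <- function(pointwise, pareto_k, method,
                            all_converged = TRUE) {
  n <- length(pointwise)
  structure(
    list(pointwise_elpd = pointwise,
         total_elpd = sum(pointwise),
         se = sqrt(n * stats::var(pointwise)),
         pareto_k = pareto_k,
         method = method,
         all_converged = all_converged),
    class = "elpd_result"
  )
}

#' @export
print.elpd_result <- function(x, ...) {
  cat(sprintf("ELPD (%s): %.1f (SE %.1f), n = %d\n", x$method,
              x$total_elpd, x$se, length(x$pointwise_elpd)))
  if (x$method == "psis") {
    cat(sprintf("  max Pareto k: %.2f\n", max(x$pareto_k)))
  }
  if (!x$all_converged) cat("  warning: some refits failed convergence\n")
  invisible(x)
}

#' Exact leave-one-out ELPD by refitting
#'
#' Refits the model once per observation with that observation held out,
#' and scores it by the log posterior-predictive density
#' \eqn{\log \frac{1}{S}\sum_k p(y_i \mid \theta^{(k)})}. If the held-out
#' observation's province has no other respondents, its intercept is drawn
#' fresh from \eqn{N(0, \sigma^{(k)})}. Intended as the gold standard for
#' validating [psis_loo()] at small n (guarded at n <= 200).
#'
#' @param spec A `model_spec`.
#' @param n_chains,n_warmup,n_iter Sampler settings per refit (smaller
#'   defaults than a headline fit; n refits are run).
#' @param seed Integer seed; refits and fresh province intercepts derive
#'   their streams from it.
#' @param ess_floor,rhat_threshold Convergence thresholds per refit; any
#'   refit failing them flags the result (never a silent success).
#' @return An `elpd_result` with `method = "exact_refit"` and
#'   `all_converged`.
#' @export
exact_refit_loo <- function(spec, n_chains = 2, n_warmup = 750, n_iter = 750,
                            seed, rhat_threshold = 1.05, ess_floor = 100) {
  stopifnot(inherits(spec, "model_spec"))
  n <- length(spec$y)
  if (n > 200) stop("exact refit LOO guarded at n <= 200", call. = FALSE)
  pointwise <- numeric(n)
  converged <- logical(n)
  prov_labels <- if (spec$include_re) {
    spec$province_levels[spec$province_id]
  } else rep(NA_character_, n)
  for (i in seq_len(n)) {
    sub <- model_spec(
      spec$y[-i], spec$X[-i, , drop = FALSE],
      if (spec$include_re) prov_labels[-i] else NULL,
      spec$prior, include_re = spec$include_re)
    fit <- withCallingHandlers(
      sample_posterior(sub, n_chains = n_chains, n_warmup = n_warmup,
                       n_iter = n_iter, seed = chain_seed(seed, i),
                       rhat_threshold = rhat_threshold,
                       ess_floor = ess_floor),
      warning = function(w) invokeRestart("muffleWarning"))
    converged[i] <- fit$convergence$pass
    m <- as_draws_matrix(fit)
    eta <- m[, "alpha"]
    if (ncol(spec$X) > 0) {
      eta <- eta + drop(m[, paste0("beta_", colnames(spec$X)), drop = FALSE] %*%
                          spec$X[i, ])
    }
    if (spec$include_re) {
      bcol <- paste0("b_", prov_labels[i])
      if (bcol %in% colnames(m)) {
        eta <- eta + m[, bcol]
      } else {
        old <- .save_rng()
        set.seed(chain_seed(seed + 1L, i))
        eta <- eta + stats::rnorm(nrow(m), 0, m[, "sigma"])
        .restore_rng(old)
      }
    }
    ll_i <- spec$y[i] * eta - softplus(eta)
    pointwise[i] <- log_sum_exp(ll_i) - log(length(ll_i))
  }
  if (!all(converged)) {
    warning(sprintf("%d of %d leave-one-out refits failed convergence thresholds",
                    sum(!converged), n), call. = FALSE)
  }
  new_elpd_result(pointwise, rep(NA_real_, n), "exact_refit",
                  all_converged = all(converged))
}

#' Rank models by leave-one-out ELPD
#'
#' Sorts models by total ELPD (best first) and reports each model's
#' difference to the best together with the standard error of the pointwise
#' differences, \eqn{\sqrt{n \,\mathrm{var}(\Delta_i)}}. All results must
#' come from the same observations in the same order.
#'
#' @param results List of `elpd_result` objects.
#' @param labels Character labels, one per result.
#' @return Data frame: `label`, `elpd`, `se`, `delta_elpd`, `delta_se`,
#'   `max_pareto_k`, `method`, sorted by decreasing `elpd`.
#' @export
compare_models <- function(results, labels) {
  if (length(results) != length(labels)) {
    stop("`labels` must have one entry per result", call. = FALSE)
  }
  ns <- vapply(results, function(r) length(r$pointwise_elpd), integer(1))
  if (length(unique(ns)) != 1) {
    stop("all results must be computed on the same observations",
         call. = FALSE)
  }
  n <- ns[1]
  elpds <- vapply(results, function(r) r$total_elpd, numeric(1))
  best <- which.max(elpds)
  delta <- elpds - elpds[best]
  delta_se <- vapply(seq_along(results), function(j) {
    d <- results[[j]]$pointwise_elpd - results[[best]]$pointwise_elpd
    sqrt(n * stats::var(d))
  }, numeric(1))
  out <- data.frame(
    label = labels,
    elpd = elpds,
    se = vapply(results, function(r) r$se, numeric(1)),
    delta_elpd = delta,
    delta_se = delta_se,
    max_pareto_k = vapply(results, function(r) {
      if (all(is.na(r$pareto_k))) NA_real_ else max(r$pareto_k)
    }, numeric(1)),
    method = vapply(results, function(r) r$method, character(1)),
    row.names = NULL
  )
  out[order(-out$elpd), , drop = FALSE]
}
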