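#' Split-chain Gelman-Rubin statistic
#'
#' Potential scale reduction factor computed on split chains: each chain is
#' halved, giving 2C sequences of length n; with within-sequence variance W
#' and between-sequence variance B the statistic is
#' \eqn{\sqrt{((n-1)/n \cdot W + B/n) / W}}. Values near 1 indicate that the
#' chains have mixed.
#'
#' If every sequence has zero within variance (degenerate, e.g. identical
#' constant chains) the statistic is reported as 1 with a warning.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 4) {
    stop("need at least 2 chains and 4 draws per chain", call. = FALSE)
  }
  half <- split_chains(x)
  n <- nrow(half)
  W <- mean(apply(half, 2, stats::var))
  B <- n * stats::var(colMeans(half))
  if (W == 0) {
    warning("degenerate chains: zero within-chain variance", call. = FALSE)
    return(1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

# halve each chain column -> 2C columns of equal length
split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

#' Effective sample size
#'
#' Multi-chain ESS via the standard autocorrelation summation: combined
#' lag-t correlations are estimated from the within-chain autocovariances on
#' split chains, and the sum is truncated at the first lag pair whose sum is
#' negative (Geyer's initial positive sequence). Degenerate (zero-variance)
#' chains return the total draw count.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar effective sample size.
#' @export
ess_mean <- function(x) {
  x <- as.matrix(x)
  half <- split_chains(x)
  n <- nrow(half)
  C <- ncol(half)
  vars <- apply(half, 2, stats::var)
  W <- mean(vars)
  if (W == 0) return(n * C)
  B <- n * stats::var(colMeans(half))
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- n - 1
  # per-chain autocovariances (biased, denominator n), averaged over chains
  acov <- sapply(seq_len(C), function(c) {
    a <- stats::acf(half[, c], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)  # index 1 = lag 0
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # sum lag pairs (1,2), (3,4), ... while positive
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- n * C / (1 + 2 * s)
  min(ess, n * C)
}

#' Convergence report for posterior draws
#'
#' Computes split-chain R-hat and ESS for every parameter; the fit passes if
#' the largest R-hat is below `rhat_threshold` and the smallest ESS is at
#' least `ess_floor`.
#'
#' @param draws A `posterior_draws`.
#' @param rhat_threshold Maximum acceptable split R-hat (default 1.01).
#' @param ess_floor Minimum acceptable ESS (default 400).
#' @return A list of class `convergence_report`: `table` (parameter, rhat,
#'   ess), `pass`, and the thresholds.
#' @export
convergence_report <- function(draws, rhat_threshold = 1.01,
                               ess_floor = 400) {
  stopifnot(inherits(draws, "posterior_draws"))
  nm <- dimnames(draws$draws)[[3]]
  tab <- data.frame(
    parameter = nm,
    rhat = vapply(nm, function(p) split_rhat(draws$draws[, , p]), numeric(1)),
    ess = vapply(nm, function(p) ess_mean(draws$draws[, , p]), numeric(1)),
    row.names = NULL
  )
  structure(
    list(table = tab,
         pass = max(tab$rhat) < rhat_threshold & min(tab$ess) >= ess_floor,
         rhat_threshold = rhat_threshold, ess_floor = ess_floor),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: %s (R-hat < %.3f, ESS >= %.0f)\n",
              if (x$pass) "PASS" else "FAIL", x$rhat_threshold, x$ess_floor))
  print(x$table, digits = 4)
  invisible(x)
}
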