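# Shared fixtures, all built in code.

default_prior <- function() build_prior_config(0.61)

# Minimal valid respondent rows; override any column by name.
make_survey_df <- function(n = 4, ...) {
  df <- data.frame(
    respondent_id = sprintf("R%03d", seq_len(n)),
    province = rep(c("ON", "QC"), length.out = n),
    age_group = rep(c("le40", "gt40"), length.out = n),
    role = "staff",
    setting = rep(c("academic", "community"), length.out = n),
    subspecialty = rep(c("pediatric", "general"), length.out = n),
    annual_volume_group = rep(c("le50", "gt50"), length.out = n),
    technique = rep(c("extracapsular_monopolar", "intracapsular_coblator"),
                    length.out = n),
    opioid_sparing = rep(c("1", "0"), length.out = n),
    min_age_kind = "no_limit",
    min_age_years = NA_character_,
    preferred_opioid = "morphine",
    least_preferred_opioid = "codeine",
    stringsAsFactors = FALSE
  )
  override <- list(...)
  for (nm in names(override)) df[[nm]] <- override[[nm]]
  df
}

# Hand-built posterior_draws object over given per-draw alpha/sigma vectors,
# for functional-level tests that need exact control of the draws.
fake_posterior_draws <- function(alpha, sigma = NULL, beta = NULL,
                                 beta_name = "x1") {
  n_draws <- length(alpha)
  half <- ceiling(n_draws / 2)
  include_re <- !is.null(sigma)
  y <- c(1, 0)
  prov <- c("ON", "ON")
  X <- if (!is.null(beta)) {
    matrix(c(0, 1), ncol = 1, dimnames = list(NULL, beta_name))
  } else NULL
  spec <- model_spec(y, X, if (include_re) prov else NULL,
                     default_prior(), include_re = include_re)
  nm <- param_names(spec)
  cols <- list(alpha = alpha)
  if (!is.null(beta)) cols[[paste0("beta_", beta_name)]] <- beta
  if (include_re) {
    cols$sigma <- sigma
    cols$b_ON <- rep(0, n_draws)
  }
  stopifnot(identical(names(cols), nm))
  # two pseudo-chains of equal length
  arr <- array(NA_real_, dim = c(half, 2, length(nm)),
               dimnames = list(NULL, NULL, nm))
  for (k in seq_along(nm)) {
    v <- c(cols[[k]], rep(cols[[k]][n_draws], 2 * half - n_draws))
    arr[, , k] <- matrix(v, ncol = 2)
  }
  structure(
    list(draws = arr, accept_rate = NULL, seed = 1L, n_warmup = 0L,
         spec = spec, convergence = list(pass = TRUE)),
    class = "posterior_draws"
  )
}

# Quick sampler settings for tests that need many fits.
quick_fit <- function(spec, seed, n_chains = 2, n_warmup = 400,
                      n_iter = 400, thin = 1) {
  suppressWarnings(
    sample_posterior(spec, n_chains = n_chains, n_warmup = n_warmup,
                     n_iter = n_iter, thin = thin, seed = seed)
  )
}
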