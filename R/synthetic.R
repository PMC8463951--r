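# Synthetic tract data ----------------------------------------------------
#
# The study's raw EHR/ACS inputs are not publicly deposited, so validation
# runs on synthetic tract lattices with known ground truth: spatially
# autocorrelated covariates (SAR filter), and outcomes generated under each
# spatial model family either as a Gaussian rate surface or as
# binomially-drawn cancellation counts on a logit linear predictor.

SPREG_FAMILIES <- c("iid", "sar", "sdm", "sem", "sdem", "sma", "sac")
PROB_CLIP <- 1e-6  # keeps binomial probabilities away from 0/1

family_needs <- function(family) {
  list(rho    = family %in% c("sar", "sdm", "sac"),
       lambda = family %in% c("sem", "sdem", "sma", "sac"),
       theta  = family %in% c("sdm", "sdem"))
}

check_dgp_params <- function(family, params, n_covariates) {
  family <- match.arg(family, SPREG_FAMILIES)
  need <- family_needs(family)
  if (is.null(params$beta) || length(params$beta) != n_covariates + 1) {
    abort_arg("params$beta must have length n_covariates + 1 (intercept first)")
  }
  for (p in c("rho", "lambda")) {
    if (need[[p]] && is.null(params[[p]])) {
      abort_arg("family '", family, "' requires params$", p)
    }
    if (!need[[p]] && !is.null(params[[p]]) && params[[p]] != 0) {
      abort_arg("family '", family, "' does not use params$", p)
    }
    if (!is.null(params[[p]]) && abs(params[[p]]) >= 1) {
      abort_arg("params$", p, " must lie in (-1, 1)")
    }
  }
  if (need$theta) {
    if (is.null(params$theta) || length(params$theta) != n_covariates) {
      abort_arg("family '", family, "' requires params$theta of length ",
                n_covariates)
    }
  }
  family
}

#' Simulate spatially autocorrelated covariates
#'
#' Each covariate column is a SAR-filtered Gaussian field
#' `x = (I - phi W)^-1 e`, `e ~ N(0, I)`: the simplest mechanism that
#' reproduces the spatial clustering of community covariates seen in real
#' tract data. `phi = 0` gives iid columns.
#'
#' @param w A `tract_weights` object (row-standardised).
#' @param n_covariates Number of columns.
#' @param phi Spatial autocorrelation of the filter, in (-1, 1).
#' @param seed Integer seed; fully determines the output.
#' @return Numeric matrix (tracts x covariates) with columns `x1, x2, ...`.
#' @export
simulate_covariates <- function(w, n_covariates, phi = 0, seed = 1) {
  stopifnot(inherits(w, "tract_weights"), n_covariates >= 1)
  if (!is.numeric(phi) || abs(phi) >= 1) {
    abort_arg("phi must lie in (-1, 1)")
  }
  n <- w$n
  E <- with_seed(seed, matrix(rnorm(n * n_covariates), n, n_covariates))
  X <- if (phi == 0) E else {
    A <- Matrix::Diagonal(n) - phi * w$W
    as.matrix(Matrix::solve(A, E))
  }
  colnames(X) <- paste0("x", seq_len(n_covariates))
  X
}

# Reduced-form surface shared by the rate and count generators: given the
# innovation vector eps, return y for the requested family.
reduced_form <- function(X, w, family, params, eps) {
  n <- nrow(X)
  Xb <- cbind(1, X) %*% params$beta
  W <- w$W
  add_durbin <- function(v) {
    if (!is.null(params$theta) && length(params$theta)) {
      v + as.matrix(W %*% X) %*% params$theta
    } else v
  }
  solve_A <- function(par, v) {
    as.numeric(Matrix::solve(Matrix::Diagonal(n) - par * W, v))
  }
  y <- switch(family,
    iid  = Xb + eps,
    sar  = solve_A(params$rho, Xb + eps),
    sdm  = solve_A(params$rho, add_durbin(Xb) + eps),
    sem  = Xb + solve_A(params$lambda, eps),
    sdem = add_durbin(Xb) + solve_A(params$lambda, eps),
    sma  = Xb + as.numeric((Matrix::Diagonal(n) + params$lambda * W) %*% eps),
    sac  = solve_A(params$rho, Xb + solve_A(params$lambda, eps))
  )
  as.numeric(y)
}

#' Simulate a rate surface under a spatial data-generating process
#'
#' Draws `y` from the reduced form of the chosen family:
#' iid `y = Xb + e`; spatial lag (sar) `y = (I-rho W)^-1 (Xb + e)`;
#' spatial Durbin (sdm) adds `WX theta` inside the filter; spatial error
#' (sem) `y = Xb + (I-lambda W)^-1 e`; Durbin error (sdem) adds `WX theta`
#' outside; moving average (sma) `y = Xb + (I+lambda W) e`; SARAR (sac)
#' `y = (I-rho W)^-1 (Xb + (I-lambda W)^-1 e)`; `e ~ N(0, sigma^2 I)`.
#'
#' @param X Covariate matrix (no intercept column).
#' @param w A `tract_weights` object.
#' @param family One of `iid, sar, sdm, sem, sdem, sma, sac`.
#' @param params List with `beta` (intercept first, length ncol(X)+1) and,
#'   as the family requires, `rho`, `lambda`, `theta`.
#' @param sigma Innovation standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Numeric outcome vector.
#' @export
simulate_rate_surface <- function(X, w, family, params, sigma, seed = 1) {
  stopifnot(inherits(w, "tract_weights"), is.matrix(X) || is.data.frame(X))
  X <- as.matrix(X)
  family <- check_dgp_params(family, params, ncol(X))
  if (sigma < 0) abort_arg("sigma must be nonnegative")
  eps <- with_seed(seed, rnorm(nrow(X), sd = sigma))
  reduced_form(X, w, family, params, eps)
}

#' Simulate per-tract case and cancellation counts
#'
#' Tract surgical volumes are drawn lognormally,
#' `n_i = max(1, round(exp(N(count_log_mean, count_log_sd))))`; the linear
#' predictor `eta` follows the family's reduced form (as in
#' [simulate_rate_surface()]); cancellation probabilities are
#' `p_i = plogis(eta_i)` clipped to `(1e-6, 1 - 1e-6)`; counts are
#' `k_i ~ Binomial(n_i, p_i)`.
#'
#' @inheritParams simulate_rate_surface
#' @param count_log_mean,count_log_sd Log-scale mean and sd of tract
#'   surgical volume.
#' @param seed Integer seed, expanded into independent substreams for the
#'   noise, the volumes and the binomial draws.
#' @return List with integer vectors `n_cases` and `n_cancel`.
#' @export
simulate_counts <- function(X, w, family, params, sigma,
                            count_log_mean = log(150), count_log_sd = 0.6,
                            seed = 1) {
  X <- as.matrix(X)
  family <- check_dgp_params(family, params, ncol(X))
  seeds <- derive_seeds(seed, 3)
  eps <- with_seed(seeds[1], rnorm(nrow(X), sd = sigma))
  eta <- reduced_form(X, w, family, params, eps)
  p <- pmin(pmax(plogis(eta), PROB_CLIP), 1 - PROB_CLIP)
  n_cases <- with_seed(seeds[2], {
    pmax(1L, as.integer(round(exp(rnorm(nrow(X), count_log_mean,
                                        count_log_sd)))))
  })
  n_cancel <- with_seed(seeds[3], rbinom(nrow(X), n_cases, p))
  list(n_cases = n_cases, n_cancel = n_cancel)
}

#' Configuration for a synthetic tract data set
#'
#' Validates and freezes all knobs of the generator. The defaults emulate a
#' mid-sized hospital service area: a 20 x 20 lattice (400 tracts), six
#' clustered covariates, a spatial-lag outcome with moderate dependence and
#' tract volumes around 150 cases.
#'
#' @param rows,cols Lattice dimensions (`rows*cols >= 9`).
#' @param cell_size Cell side length.
#' @param n_covariates Number of covariates.
#' @param covariate_autocorr SAR-filter autocorrelation phi in (-1, 1).
#' @param dgp_family Outcome family, one of
#'   `iid, sar, sdm, sem, sdem, sma, sac`.
#' @param true_beta Coefficients, intercept first (length n_covariates + 1).
#' @param true_theta Durbin coefficients (sdm/sdem) or NULL.
#' @param true_rho,true_lambda Spatial parameters in (-1, 1), present iff
#'   the family uses them.
#' @param noise_sd Innovation sd.
#' @param count_log_mean,count_log_sd Lognormal tract-volume parameters.
#' @param min_cases Exclusion threshold carried to preprocessing.
#' @param outcome_mode `"binomial_count"` (counts, logit link) or
#'   `"gaussian_rate"` (continuous surface).
#' @param seed Integer master seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(rows = 20, cols = 20, cell_size = 1,
                         n_covariates = 6, covariate_autocorr = 0.6,
                         dgp_family = "sar",
                         true_rho = if (dgp_family %in% c("sar", "sdm", "sac"))
                           0.5 else NULL,
                         true_beta = c(qlogis(0.05) * (1 - (true_rho %||% 0)),
                                       rep_len(c(0.3, -0.2, 0.15, 0.1, -0.1,
                                                 0.05), n_covariates)),
                         true_theta = NULL,
                         true_lambda = if (dgp_family %in%
                                           c("sem", "sdem", "sma", "sac"))
                           0.5 else NULL,
                         noise_sd = 0.2,
                         count_log_mean = log(150), count_log_sd = 0.6,
                         min_cases = 20,
                         outcome_mode = "binomial_count", seed = 1) {
  if (rows * cols < 9) abort_arg("rows*cols must be at least 9")
  dgp_family <- match.arg(dgp_family, SPREG_FAMILIES)
  outcome_mode <- match.arg(outcome_mode, c("binomial_count", "gaussian_rate"))
  if (abs(covariate_autocorr) >= 1) {
    abort_arg("covariate_autocorr must lie in (-1, 1)")
  }
  if (noise_sd < 0) abort_arg("noise_sd must be nonnegative")
  params <- list(beta = true_beta, theta = true_theta, rho = true_rho,
                 lambda = true_lambda)
  check_dgp_params(dgp_family, params, n_covariates)
  cfg <- list(rows = rows, cols = cols, cell_size = cell_size,
              n_covariates = n_covariates,
              covariate_autocorr = covariate_autocorr,
              dgp_family = dgp_family, params = params,
              noise_sd = noise_sd, count_log_mean = count_log_mean,
              count_log_sd = count_log_sd, min_cases = min_cases,
              outcome_mode = outcome_mode, seed = seed)
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a full synthetic tract data set
#'
#' Lattice, weights, covariates and outcome in one call, with the master
#' seed expanded into independent substreams (covariates / noise / counts)
#' so that changing one stage's dimensions does not perturb the others.
#'
#' @param config A [synth_config()] object.
#' @return List with `tracts` (a `tract_frame` with counts, crude rates and
#'   covariate columns), `weights` (`tract_weights`), `X`, `truth` (the
#'   noiseless/linear-predictor surface and the generator parameters).
#' @export
simulate_tract_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  seeds <- derive_seeds(config$seed, 3)
  tracts <- make_tract_lattice(config$rows, config$cols, config$cell_size)
  w <- tract_weights(tracts)
  X <- simulate_covariates(w, config$n_covariates,
                           config$covariate_autocorr, seed = seeds[1])
  if (config$outcome_mode == "binomial_count") {
    cnt <- simulate_counts(X, w, config$dgp_family, config$params,
                           config$noise_sd, config$count_log_mean,
                           config$count_log_sd, seed = seeds[2])
    tracts$n_cases <- cnt$n_cases
    tracts$n_cancel <- cnt$n_cancel
    tracts$crude_rate <- ifelse(cnt$n_cases > 0,
                                cnt$n_cancel / cnt$n_cases, NA_real_)
  } else {
    tracts$rate <- simulate_rate_surface(X, w, config$dgp_family,
                                         config$params, config$noise_sd,
                                         seed = seeds[2])
  }
  for (j in seq_len(ncol(X))) tracts[[colnames(X)[j]]] <- X[, j]
  eta0 <- reduced_form(X, w, config$dgp_family, config$params,
                       rep(0, nrow(X)))
  list(tracts = tracts, weights = w, X = X,
       truth = list(surface = eta0, params = config$params,
                    family = config$dgp_family, config = config))
}
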