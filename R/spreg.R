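# Spatial regression by maximum likelihood --------------------------------
#
# One fitting function covers the model zoo used for tract-rate modelling:
#
#   glm        y = Xb + e                        (OLS)
#   ridge_glm  OLS with an L2 penalty on the slopes
#   sar        y = rho W y + Xb + e              (spatial lag)
#   sdm        sar + WX theta                    (spatial Durbin)
#   sem        y = Xb + u,  u = lambda W u + e   (spatial error)
#   sdem       sem + WX theta                    (Durbin error)
#   sma        y = Xb + (I + lambda W) e         (moving average)
#   sac        y = rho W y + Xb + u, u = lambda W u + e  (SARAR)
#   ridge_sar  sar with an L2 penalty inside the beta step
#
# Spatial parameters are estimated by concentrated (profile) likelihood:
# at each candidate rho/lambda, beta and sigma^2 have closed forms, and the
# log-determinant term is evaluated from the cached eigenvalues of W,
# ln|I - rho W| = sum(ln(1 - rho w_i)). Scalar searches use Brent's method
# on the admissible interval (1/w_min + 1e-6, 1 - 1e-6).

RIDGE_FAMILIES <- c("ridge_glm", "ridge_sar")
ALL_FAMILIES <- c("glm", "ridge_glm", "sar", "sdm", "sem", "sdem",
                  "sma", "sac", "ridge_sar")

#' Optimiser control for [spreg()]
#'
#' @param tol Parameter tolerance of the bounded scalar searches.
#' @param bound_eps Margin keeping rho/lambda strictly inside the
#'   admissible interval.
#' @param grid_starts Multistart grid (each axis) for the SARAR profile
#'   search.
#' @return A list of control settings.
#' @export
spreg_control <- function(tol = 1e-8, bound_eps = 1e-6,
                          grid_starts = c(-0.5, 0, 0.5)) {
  list(tol = tol, bound_eps = bound_eps, grid_starts = grid_starts)
}

# ordinary least squares; errors on singular designs naming the columns
beta_ols <- function(y, A) {
  qr_ <- qr(A)
  if (qr_$rank < ncol(A)) {
    bad <- colnames(A)[qr_$pivot[(qr_$rank + 1):ncol(A)]]
    abort_arg("singular design: dependent column(s) ",
              paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_, y)
  fitted <- as.numeric(A %*% beta)
  list(beta = beta, fitted = fitted, residuals = y - fitted)
}

# ridge with slopes standardised on the data at hand, intercept unpenalised
# and recovered from the means; coefficients returned on the original scale.
# Assumes column 1 of A is the constant intercept.
beta_ridge_std <- function(y, A, penalty) {
  p <- ncol(A)
  if (p == 1) {  # intercept only
    beta <- setNames(mean(y), colnames(A))
    fitted <- rep(mean(y), length(y))
    return(list(beta = beta, fitted = fitted, residuals = y - fitted))
  }
  Xs <- A[, -1, drop = FALSE]
  mu <- colMeans(Xs)
  s <- apply(Xs, 2, sd)
  keep <- s > 0
  b <- numeric(p - 1)
  if (any(keep)) {
    Z <- sweep(sweep(Xs[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
    yc <- y - mean(y)
    M <- crossprod(Z) + diag(penalty, sum(keep))
    b_s <- solve(M, crossprod(Z, yc))
    b[keep] <- as.numeric(b_s) / s[keep]
  }
  b0 <- mean(y) - sum(b * mu)
  beta <- setNames(c(b0, b), colnames(A))
  fitted <- as.numeric(A %*% beta)
  list(beta = beta, fitted = fitted, residuals = y - fitted)
}

# ridge on a spatially filtered design (no standardisation; column 1, the
# filtered intercept, stays unpenalised)
beta_ridge_raw <- function(y, A, penalty) {
  p <- ncol(A)
  J <- diag(c(0, rep(1, p - 1)), p)
  M <- crossprod(A) + penalty * J
  beta <- setNames(as.numeric(solve(M, crossprod(A, y))), colnames(A))
  fitted <- as.numeric(A %*% beta)
  list(beta = beta, fitted = fitted, residuals = y - fitted)
}

gauss_ll <- function(n, sigma2) {
  -(n / 2) * log(2 * pi) - (n / 2) * log(sigma2) - n / 2
}

# admissible interval for a spatial parameter given the eigenvalues of W
spatial_interval <- function(ev, eps) {
  lo <- if (min(ev) < -1e-12) 1 / min(ev) + eps else -1 + eps
  hi <- if (max(ev) > 1e-12) 1 / max(ev) - eps else 1 - eps
  c(lo, hi)
}

#' Fit a spatial regression model to tract rates
#'
#' Maximum-likelihood estimation of the spatial model zoo (see the family
#' table in the package vignette) on a tract table, with optional L2
#' penalty on the slope coefficients for the `ridge_glm` / `ridge_sar`
#' variants. Spatial parameters can be fixed via `rho` / `lambda` (e.g. for
#' profile-likelihood inspection or nested-model comparisons).
#'
#' @param formula Model formula; the response is the tract rate.
#' @param data Tract table (a `tract_frame` or data.frame).
#' @param weights A `tract_weights` object over the rows of `data`
#'   (required for spatial families).
#' @param family One of `glm`, `ridge_glm`, `sar`, `sdm`, `sem`, `sdem`,
#'   `sma`, `sac`, `ridge_sar`.
#' @param penalty Nonnegative L2 penalty (ridge families only).
#' @param rho,lambda Optional fixed values for the spatial parameters.
#' @param control A [spreg_control()] list.
#' @return An object of class `spreg`.
#' @examples
#' sim <- simulate_tract_data(synth_config(rows = 8, cols = 8, seed = 7))
#' d <- add_eb_rate(sim$tracts)
#' fit <- spreg(eb_rate ~ x1 + x2, d, sim$weights, family = "sar")
#' coef(fit)
#' @export
spreg <- function(formula, data, weights = NULL,
                  family = c("glm", "ridge_glm", "sar", "sdm", "sem",
                             "sdem", "sma", "sac", "ridge_sar"),
                  penalty = 0, rho = NULL, lambda = NULL,
                  control = spreg_control()) {
  family <- match.arg(family)
  if (penalty < 0) abort_arg("penalty must be nonnegative")
  if (penalty > 0 && !family %in% RIDGE_FAMILIES) {
    abort_arg("penalty is only available for families ",
              paste(RIDGE_FAMILIES, collapse = ", "))
  }
  base <- switch(family, ridge_glm = "glm", ridge_sar = "sar", family)
  is_ridge <- family %in% RIDGE_FAMILIES

  mf <- model.frame(formula, as.data.frame(data))
  y <- as.numeric(model.response(mf))
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  needs_w <- base %in% c("sar", "sdm", "sem", "sdem", "sma", "sac")
  if (needs_w) {
    if (!inherits(weights, "tract_weights") || weights$n != n) {
      abort_arg("a tract_weights object over the ", n,
                " data rows is required for family '", family, "'")
    }
  }
  has_int <- colnames(X)[1] == "(Intercept)"
  if (!has_int) abort_arg("the model must include an intercept")

  # Durbin families augment the design with WX (intercept not lagged)
  theta_cols <- character(0)
  A <- X
  if (base %in% c("sdm", "sdem") && ncol(X) > 1) {
    WX <- as.matrix(weights$W %*% X[, -1, drop = FALSE])
    colnames(WX) <- paste0("lag.", colnames(X)[-1])
    theta_cols <- colnames(WX)
    A <- cbind(X, WX)
  }
  p <- ncol(A)
  if (n <= p) abort_arg("need more tracts than coefficients (n > p)")

  bstep <- if (!is_ridge) {
    function(yy, AA) beta_ols(yy, AA)
  } else if (base == "glm" || base == "sar") {
    function(yy, AA) beta_ridge_std(yy, AA, penalty)
  } else {
    function(yy, AA) beta_ridge_raw(yy, AA, penalty)
  }
  # for spatially filtered designs (sem/sdem/sac) a raw-scale penalty is used
  bstep_filtered <- if (!is_ridge) {
    function(yy, AA) beta_ols(yy, AA)
  } else {
    function(yy, AA) beta_ridge_raw(yy, AA, penalty)
  }

  eps <- control$bound_eps
  fit <- switch(base,
    glm = {
      bs <- bstep(y, A)
      s2 <- sum(bs$residuals^2) / n
      ll <- if (s2 > 0) gauss_ll(n, s2) else Inf
      list(beta = bs$beta, rho = NULL, lambda = NULL, sigma2 = s2,
           loglik = ll, converged = TRUE)
    },
    sar = {
      ev <- weights_eigenvalues(weights)
      Wy <- as.numeric(weights$W %*% y)
      conc <- function(r) {
        bs <- bstep(y - r * Wy, A)
        s2 <- sum(bs$residuals^2) / n
        gauss_ll(n, s2) + sum(log(1 - r * ev))
      }
      r_hat <- estimate_scalar(conc, ev, rho, eps, control$tol,
                               degenerate_zero = max(abs(ev)) < 1e-12)
      bs <- bstep(y - r_hat * Wy, A)
      s2 <- sum(bs$residuals^2) / n
      list(beta = bs$beta, rho = r_hat, lambda = NULL, sigma2 = s2,
           loglik = gauss_ll(n, s2) + sum(log(1 - r_hat * ev)),
           converged = TRUE)
    },
    sdm = {
      ev <- weights_eigenvalues(weights)
      Wy <- as.numeric(weights$W %*% y)
      conc <- function(r) {
        bs <- bstep(y - r * Wy, A)
        s2 <- sum(bs$residuals^2) / n
        gauss_ll(n, s2) + sum(log(1 - r * ev))
      }
      r_hat <- estimate_scalar(conc, ev, rho, eps, control$tol,
                               degenerate_zero = max(abs(ev)) < 1e-12)
      bs <- bstep(y - r_hat * Wy, A)
      s2 <- sum(bs$residuals^2) / n
      list(beta = bs$beta, rho = r_hat, lambda = NULL, sigma2 = s2,
           loglik = gauss_ll(n, s2) + sum(log(1 - r_hat * ev)),
           converged = TRUE)
    },
    sem = ,
    sdem = {
      ev <- weights_eigenvalues(weights)
      W <- weights$W
      Wy <- as.numeric(W %*% y)
      WA <- as.matrix(W %*% A)
      conc <- function(l) {
        bs <- bstep_filtered(y - l * Wy, A - l * WA)
        s2 <- sum(bs$residuals^2) / n
        gauss_ll(n, s2) + sum(log(1 - l * ev))
      }
      l_hat <- estimate_scalar(conc, ev, lambda, eps, control$tol,
                               degenerate_zero = max(abs(ev)) < 1e-12)
      bs <- bstep_filtered(y - l_hat * Wy, A - l_hat * WA)
      s2 <- sum(bs$residuals^2) / n
      list(beta = bs$beta, rho = NULL, lambda = l_hat, sigma2 = s2,
           loglik = gauss_ll(n, s2) + sum(log(1 - l_hat * ev)),
           converged = TRUE)
    },
    sma = {
      ev <- weights_eigenvalues(weights)
      Wd <- as.matrix(weights$W)
      conc <- function(l) {
        M <- diag(n) + l * Wd
        Z <- solve(M, cbind(y, A))
        bs <- beta_ols(Z[, 1], Z[, -1, drop = FALSE])
        s2 <- sum(bs$residuals^2) / n
        gauss_ll(n, s2) - sum(log(1 + l * ev))
      }
      interval <- c(-1 + eps, 1 - eps)
      l_hat <- if (!is.null(lambda)) lambda
        else if (max(abs(ev)) < 1e-12) 0
        else optimize(conc, interval, maximum = TRUE, tol = control$tol)$maximum
      M <- diag(n) + l_hat * Wd
      Z <- solve(M, cbind(y, A))
      bs <- beta_ols(Z[, 1], Z[, -1, drop = FALSE])
      names(bs$beta) <- colnames(A)
      s2 <- sum(bs$residuals^2) / n
      list(beta = bs$beta, rho = NULL, lambda = l_hat, sigma2 = s2,
           loglik = gauss_ll(n, s2) - sum(log(1 + l_hat * ev)),
           converged = TRUE)
    },
    sac = {
      fit_sac(y, A, weights, rho, lambda, bstep_filtered, control)
    }
  )

  beta_all <- fit$beta
  theta <- if (length(theta_cols)) beta_all[theta_cols] else NULL
  beta <- beta_all[setdiff(names(beta_all), theta_cols)]

  # in-sample signal ("trend") prediction per the reduced forms
  trend <- as.numeric(A %*% beta_all)
  if (base %in% c("sar", "sdm", "sac") &&
      !is.null(fit$rho) && fit$rho != 0) {
    trend <- as.numeric(Matrix::solve(
      Matrix::Diagonal(n) - fit$rho * weights$W, trend))
  }

  df <- length(beta_all) + 1 +
    (!is.null(fit$rho)) + (!is.null(fit$lambda))
  out <- list(
    family = family, base_family = base,
    coefficients = beta_all, beta = beta, theta = theta,
    rho = fit$rho, lambda = fit$lambda, sigma2 = fit$sigma2,
    loglik = fit$loglik, df = df, penalty = penalty,
    converged = fit$converged, flat_warning = fit$flat_warning %||% FALSE,
    n = n, terms = attr(mf, "terms"), call = match.call(),
    design = A, y = y, fitted = trend, residuals = y - trend,
    ids = if (!is.null(data$tract_id)) as.character(data$tract_id) else NULL
  )
  class(out) <- "spreg"
  out
}

# scalar spatial-parameter search (or fixed value passthrough)
estimate_scalar <- function(conc, ev, fixed, eps, tol, degenerate_zero) {
  if (!is.null(fixed)) return(fixed)
  if (degenerate_zero) return(0)
  interval <- spatial_interval(ev, eps)
  optimize(conc, interval, maximum = TRUE, tol = tol)$maximum
}

# SARAR profile search: nested bounded scalar optimisation (outer rho,
# inner lambda) plus a multistart grid scan polished with L-BFGS-B.
fit_sac <- function(y, A, weights, rho, lambda, bstep, control) {
  n <- length(y)
  ev <- weights_eigenvalues(weights)
  W <- weights$W
  Wy <- as.numeric(W %*% y)
  WA <- as.matrix(W %*% A)
  eps <- control$bound_eps
  prof <- function(r, l) {
    Ay <- y - r * Wy
    WAy <- as.numeric(W %*% Ay)
    bs <- bstep(Ay - l * WAy, A - l * WA)
    s2 <- sum(bs$residuals^2) / n
    gauss_ll(n, s2) + sum(log(1 - r * ev)) + sum(log(1 - l * ev))
  }
  if (max(abs(ev)) < 1e-12) {  # no spatial structure at all
    r_hat <- rho %||% 0; l_hat <- lambda %||% 0
  } else if (!is.null(rho) && !is.null(lambda)) {
    r_hat <- rho; l_hat <- lambda
  } else {
    interval <- spatial_interval(ev, eps)
    inner_max <- function(r) {
      if (!is.null(lambda)) return(prof(r, lambda))
      optimize(function(l) prof(r, l), interval, maximum = TRUE,
               tol = control$tol)$objective
    }
    inner_arg <- function(r) {
      if (!is.null(lambda)) return(lambda)
      optimize(function(l) prof(r, l), interval, maximum = TRUE,
               tol = control$tol)$maximum
    }
    cands <- list()
    if (is.null(rho)) {
      r0 <- optimize(inner_max, interval, maximum = TRUE,
                     tol = control$tol)$maximum
      cands[[1]] <- c(r0, inner_arg(r0))
    } else {
      cands[[1]] <- c(rho, inner_arg(rho))
    }
    # multistart polish over the grid
    starts <- expand.grid(r = control$grid_starts, l = control$grid_starts)
    starts$r <- pmin(pmax(starts$r, interval[1]), interval[2])
    starts$l <- pmin(pmax(starts$l, interval[1]), interval[2])
    if (is.null(rho) && is.null(lambda)) {
      for (s in seq_len(nrow(starts))) {
        opt <- tryCatch(
          optim(c(starts$r[s], starts$l[s]),
                function(par) prof(par[1], par[2]),
                method = "L-BFGS-B",
                lower = rep(interval[1], 2), upper = rep(interval[2], 2),
                control = list(fnscale = -1, factr = 1e3)),
          error = function(e) NULL)
        if (!is.null(opt)) cands[[length(cands) + 1]] <- opt$par
      }
    }
    lls <- vapply(cands, function(p_) prof(p_[1], p_[2]), numeric(1))
    best <- cands[[which.max(lls)]]
    r_hat <- if (is.null(rho)) best[1] else rho
    l_hat <- if (is.null(lambda)) best[2] else lambda
    flat <- FALSE
    if (length(lls) > 1) {
      spread <- max(lls) - min(lls)
      locs <- do.call(rbind, cands)
      disp <- max(dist(locs))
      if (spread < 1e-6 && disp > 0.05) {
        warning("SARAR profile likelihood is nearly flat across multistarts")
        flat <- TRUE
      }
    }
  }
  Ay <- y - r_hat * Wy
  WAy <- as.numeric(W %*% Ay)
  bs <- bstep(Ay - l_hat * WAy, A - l_hat * WA)
  s2 <- sum(bs$residuals^2) / n
  list(beta = setNames(bs$beta, colnames(A)), rho = r_hat, lambda = l_hat,
       sigma2 = s2,
       loglik = gauss_ll(n, s2) + sum(log(1 - r_hat * ev)) +
         sum(log(1 - l_hat * ev)),
       converged = TRUE,
       flat_warning = exists("flat", inherits = FALSE) && isTRUE(flat))
}
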