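# S3 methods for spreg fits ----------------------------------------------

#' @export
print.spreg <- function(x, ...) {
  cat(sprintf("Spatial regression fit: family '%s' (n = %d)\n",
              x$family, x$n))
  cat("Coefficients:\n")
  print(round(x$coefficients, 6))
  if (!is.null(x$rho)) cat(sprintf("rho (spatial lag):    %.6f\n", x$rho))
  if (!is.null(x$lambda)) cat(sprintf("lambda (spatial err): %.6f\n",
                                      x$lambda))
  cat(sprintf("sigma^2 = %.6g, log-likelihood = %.4f", x$sigma2, x$loglik))
  if (x$penalty > 0) cat(sprintf(", L2 penalty = %g", x$penalty))
  cat("\n")
  invisible(x)
}

#' @export
summary.spreg <- function(object, ...) {
  structure(list(fit = object), class = "summary.spreg")
}

#' @export
print.summary.spreg <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$theta)) {
    cat("Durbin (WX) coefficients:\n")
    print(round(f$theta, 6))
  }
  cat(sprintf("Residual summary:\n"))
  print(summary(f$residuals))
  invisible(x)
}

#' @export
coef.spreg <- function(object, ...) object$coefficients

#' @export
logLik.spreg <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
residuals.spreg <- function(object, ...) object$residuals

#' @export
fitted.spreg <- function(object, ...) object$fitted

#' Signal predictions for (held-out) tracts
#'
#' Predictions come from the fitted reduced form using the full weight
#' structure and never any observed outcome ("trend" prediction):
#' `glm/ridge_glm/sem/sdem`: `X b (+ WX theta)`;
#' `sar/sdm/ridge_sar/sac`: `(I - rho W)^-1 (X b + WX theta)`;
#' `sma`: `X b`. This keeps held-out evaluation honest: perturbing a test
#' tract's outcome cannot change its prediction.
#'
#' @param object A `spreg` fit.
#' @param newdata Tract table covering all tracts (train + test).
#' @param weights A `tract_weights` object over the rows of `newdata`.
#' @param ids Optional tract IDs (or integer indices) to return; default
#'   all rows.
#' @param ... Unused.
#' @return Named numeric vector of predicted rates.
#' @export
predict.spreg <- function(object, newdata, weights = NULL, ids = NULL, ...) {
  tt <- delete.response(object$terms)
  mf <- model.frame(tt, as.data.frame(newdata))
  X <- model.matrix(tt, mf)
  n <- nrow(X)
  needs_w <- object$base_family %in% c("sar", "sdm", "sem", "sdem",
                                       "sma", "sac")
  if (needs_w && (!inherits(weights, "tract_weights") || weights$n != n)) {
    abort_arg("a tract_weights object over the newdata rows is required")
  }
  A <- X
  if (object$base_family %in% c("sdm", "sdem") && ncol(X) > 1) {
    WX <- as.matrix(weights$W %*% X[, -1, drop = FALSE])
    colnames(WX) <- paste0("lag.", colnames(X)[-1])
    A <- cbind(X, WX)
  }
  stopifnot(identical(colnames(A), names(object$coefficients)))
  pred <- as.numeric(A %*% object$coefficients)
  if (object$base_family %in% c("sar", "sdm", "sac") && object$rho != 0) {
    M <- Matrix::Diagonal(n) - object$rho * weights$W
    pred <- tryCatch(as.numeric(Matrix::solve(M, pred)),
                     error = function(e) abort_arg(
                       "(I - rho W) is singular at rho = ", object$rho))
  }
  nm <- if (!is.null(newdata$tract_id)) as.character(newdata$tract_id)
    else as.character(seq_len(n))
  names(pred) <- nm
  if (!is.null(ids)) {
    if (is.numeric(ids)) return(pred[ids])
    return(pred[match(as.character(ids), nm)])
  }
  pred
}

#' Simulate outcomes from a fitted spatial model
#'
#' Draws new outcome vectors from the fitted family's reduced form on the
#' training design, with innovations `N(0, sigma2_hat)`.
#'
#' @param object A `spreg` fit.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param weights The `tract_weights` used at fit time (needed for spatial
#'   families).
#' @param ... Unused.
#' @return A data.frame with `nsim` columns.
#' @export
simulate.spreg <- function(object, nsim = 1, seed = NULL, weights = NULL,
                           ...) {
  n <- object$n
  base <- object$base_family
  needs_w <- base %in% c("sar", "sdm", "sem", "sdem", "sma", "sac")
  if (needs_w && !inherits(weights, "tract_weights")) {
    abort_arg("supply the tract_weights used at fit time")
  }
  mu <- as.numeric(object$design %*% object$coefficients)
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(b) {
      e <- rnorm(n, sd = sqrt(object$sigma2))
      u <- switch(base,
        glm = e,
        sar = , sdm = e,
        sem = , sdem = as.numeric(Matrix::solve(
          Matrix::Diagonal(n) - object$lambda * weights$W, e)),
        sma = as.numeric((Matrix::Diagonal(n) +
                            object$lambda * weights$W) %*% e),
        sac = as.numeric(Matrix::solve(
          Matrix::Diagonal(n) - object$lambda * weights$W, e)))
      yb <- mu + u
      if (base %in% c("sar", "sdm", "sac") && object$rho != 0) {
        yb <- as.numeric(Matrix::solve(
          Matrix::Diagonal(n) - object$rho * weights$W, yb))
      }
      yb
    }, numeric(n))
  })
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}
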