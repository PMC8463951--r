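# Spatial diagnostics -----------------------------------------------------
#
# Global Moran's I with Monte-Carlo permutation inference, covariate
# screening (spatial clustering + VIF collinearity), and geographically
# weighted local Pearson correlation of observed vs predicted rates.

#' Global Moran's I with permutation inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`
#' and `S0` the total weight. Inference is by random permutation of the
#' values over tracts (W fixed): the two-sided p-value is
#' `(1 + #{|I_perm - E[I]| >= |I_obs - E[I]|}) / (1 + n_perm)` with
#' `E[I] = -1/(n-1)`. A permutation 95% interval (`I +/- 1.96 sd(I_perm)`)
#' is also reported for CI-style plots.
#'
#' @param x Numeric variable over tracts (positive variance required).
#' @param w A `tract_weights` object (row-standardised).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @param alpha Significance level for the `significant` flag.
#' @return A `moran_result`: `I`, `expectation`, `p_value`, `perm_sd`,
#'   `ci_low`, `ci_high`, `n_perm`, `seed`, `alpha`, `significant`.
#' @export
global_moran <- function(x, w, n_perm = 999, seed = 1, alpha = 0.05) {
  stopifnot(inherits(w, "tract_weights"), length(x) == w$n)
  if (anyNA(x)) abort_arg("missing values in x")
  if (var(x) == 0) abort_arg("constant variable: Moran's I undefined")
  n <- w$n
  W <- w$W
  s0 <- sum(W)
  moran_stat <- function(z) {
    (n / s0) * as.numeric(z %*% (W %*% z)) / sum(z^2)
  }
  z <- x - mean(x)
  I_obs <- moran_stat(z)
  e_I <- -1 / (n - 1)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      zb <- z[sample.int(n)]
      moran_stat(zb)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm - e_I) >= abs(I_obs - e_I))) / (1 + n_perm)
  res <- list(I = I_obs, expectation = e_I, p_value = p,
              perm_sd = sd(perm),
              ci_low = I_obs - 1.96 * sd(perm),
              ci_high = I_obs + 1.96 * sd(perm),
              n_perm = n_perm, seed = seed, alpha = alpha,
              significant = p < alpha)
  class(res) <- "moran_result"
  res
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf(
    "Global Moran's I = %.4f (E[I] = %.4f), permutation p = %.4g [%d perms]%s\n",
    x$I, x$expectation, x$p_value, x$n_perm,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Screen covariates for spatial clustering
#'
#' Variables whose global Moran's I permutation p-value is at or above
#' `alpha` show no evidence of spatial clustering and are marked
#' not-retained.
#'
#' @param tracts Tract table.
#' @param variables Column names to screen.
#' @param w A `tract_weights` object.
#' @inheritParams global_moran
#' @return Data frame: `variable`, `moran_I`, `moran_p`, `retained`,
#'   `reason`.
#' @export
screen_by_moran <- function(tracts, variables, w, alpha = 0.05,
                            n_perm = 999, seed = 1) {
  stopifnot(all(variables %in% names(tracts)))
  seeds <- derive_seeds(seed, length(variables))
  rows <- lapply(seq_along(variables), function(i) {
    m <- global_moran(tracts[[variables[i]]], w, n_perm = n_perm,
                      seed = seeds[i], alpha = alpha)
    data.frame(variable = variables[i], moran_I = m$I, moran_p = m$p_value,
               retained = m$p_value < alpha,
               reason = if (m$p_value < alpha) NA_character_ else
                 "no spatial clustering")
  })
  do.call(rbind, rows)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing column `j`
#' on all other columns plus an intercept. Exactly collinear columns get
#' `Inf`.
#'
#' @param X Numeric matrix or data frame of covariates (no intercept).
#' @return Named vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(p >= 2, nrow(X) > p)
  out <- setNames(numeric(p), colnames(X) %||% paste0("V", seq_len(p)))
  for (j in seq_len(p)) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    sse <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- if (sst == 0) 1 else 1 - sse / sst
    out[j] <- if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Combined clustering + collinearity screen
#'
#' The diagnostics table behind model construction: a covariate is retained
#' iff its Moran permutation p-value is below `alpha` and its VIF is below
#' `vif_threshold`.
#'
#' @inheritParams screen_by_moran
#' @param vif_threshold Collinearity limit (default 10).
#' @return Data frame with `moran_I`, `moran_p`, `vif`, `retained`,
#'   `reason`; thresholds in attributes.
#' @export
screen_covariates <- function(tracts, variables, w, alpha = 0.05,
                              vif_threshold = 10, n_perm = 999, seed = 1) {
  mor <- screen_by_moran(tracts, variables, w, alpha = alpha,
                         n_perm = n_perm, seed = seed)
  v <- vif(as.data.frame(tracts)[, variables, drop = FALSE])
  mor$vif <- unname(v[mor$variable])
  collinear <- mor$vif >= vif_threshold
  mor$reason[collinear & mor$retained] <- "collinear (VIF at/above threshold)"
  mor$retained <- mor$retained & !collinear
  attr(mor, "alpha") <- alpha
  attr(mor, "vif_threshold") <- vif_threshold
  mor
}

#' Geographically weighted Pearson correlation
#'
#' Around each tract, a bisquare kernel over centroid distances with
#' adaptive bandwidth (distance to the `adaptive_k`-th nearest tract)
#' defines local weights; the locally weighted Pearson correlation between
#' observed and predicted values is computed per tract. Significance is
#' assessed by globally permuting the predicted vector and recomputing all
#' local correlations (two-sided on |r|, no multiplicity correction; the
#' flag count and alpha are recorded so users can post-correct).
#'
#' @param observed,predicted Aligned numeric vectors over tracts.
#' @param tracts A `tract_frame` (or matrix of centroids).
#' @param adaptive_k Number of nearest tracts setting the local bandwidth.
#' @param n_perm Number of global permutations.
#' @param seed Integer seed.
#' @param alpha Per-tract significance level.
#' @return Data frame `tract_id`, `local_r`, `p_value`, `significant`;
#'   kernel metadata in attributes.
#' @export
gw_pearson <- function(observed, predicted, tracts, adaptive_k = 50,
                       n_perm = 999, seed = 1, alpha = 0.05) {
  cen <- if (is.matrix(tracts)) tracts else tract_centroids(tracts)
  n <- length(observed)
  stopifnot(length(predicted) == n, nrow(cen) == n, adaptive_k < n)
  D <- as.matrix(stats::dist(cen))
  # adaptive bisquare: bandwidth = distance to the k-th nearest other tract
  h <- apply(D, 1, function(d) sort(d[-which.min(d)])[adaptive_k])
  K <- (1 - (D / h)^2)^2 * (D < h)  # rows i: kernel around tract i
  rs <- rowSums(K)
  Kn <- K / rs
  local_r <- function(o, p) {
    mo <- Kn %*% o; mp <- Kn %*% p
    cov_ <- Kn %*% (o * p) - mo * mp
    vo <- Kn %*% (o^2) - mo^2
    vp <- Kn %*% (p^2) - mp^2
    den <- sqrt(pmax(vo, 0) * pmax(vp, 0))
    r <- as.numeric(cov_ / den)
    r[den < 1e-14] <- NA_real_
    pmin(pmax(r, -1), 1)
  }
  r_obs <- local_r(observed, predicted)
  exceed <- integer(n)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      rp <- local_r(observed, predicted[sample.int(n)])
      exceed <- exceed + (!is.na(rp) & !is.na(r_obs) &
                            abs(rp) >= abs(r_obs))
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  p[is.na(r_obs)] <- NA_real_
  out <- data.frame(
    tract_id = if (!is.matrix(tracts)) tracts$tract_id else
      sprintf("T%04d", seq_len(n)),
    local_r = r_obs, p_value = p,
    significant = !is.na(p) & p < alpha)
  attr(out, "kernel") <- "bisquare"
  attr(out, "adaptive_k") <- adaptive_k
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "n_significant") <- sum(out$significant)
  out
}
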