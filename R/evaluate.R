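# Evaluation --------------------------------------------------------------
#
# Nested k-fold cross-validation with inner grid search for the penalised
# families, RMSE on the percentage-rate scale with a normal-approximation
# 95% CI over outer folds, residual Moran diagnostics, permutation feature
# importance, and the individual-prediction-aggregation (IPA) baseline
# that averages case-level predicted probabilities within tracts.

#' Random k-fold assignment
#'
#' Fold sizes differ by at most one; deterministic given the seed.
#'
#' @param n Number of units.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold labels of length `n`.
#' @export
kfold_split <- function(n, k = 10, seed = 1) {
  if (n < k) abort_arg("n must be at least k")
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  with_seed(seed, sample(rep.int(seq_len(k), sizes)))
}

#' Root mean square error
#'
#' `sqrt(mean((observed - predicted)^2))`, in whatever units the inputs
#' carry (the cross-validation drivers report rates on the percentage
#' scale).
#'
#' @param observed,predicted Aligned numeric vectors.
#' @return Numeric RMSE.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort_arg("observed and predicted lengths differ")
  }
  if (length(observed) == 0) abort_arg("empty vectors")
  sqrt(mean((observed - predicted)^2))
}

#' Default hyperparameter grid
#'
#' Integer powers of ten from 1e-6 to 1e6 (13 values), the screening range
#' used for the L2 penalties.
#'
#' @return Numeric vector of 13 candidate penalties.
#' @export
default_penalty_grid <- function() 10^seq(-6, 6)

new_cv_result <- function(family, fold_rmse, selected, seed, unit,
                          dropped = 0L) {
  m <- mean(fold_rmse)
  se <- sd(fold_rmse) / sqrt(length(fold_rmse))
  out <- list(family = family, fold_rmse = fold_rmse,
              mean_rmse = m, ci_low = m - 1.96 * se, ci_high = m + 1.96 * se,
              selected = selected, seed = seed, unit = unit,
              dropped_tracts = dropped)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validated %s: RMSE %.4f%s (95%% CI %.4f-%.4f), %d folds\n",
              x$family, x$mean_rmse, if (x$unit == "percent") "%" else "",
              x$ci_low, x$ci_high, length(x$fold_rmse)))
  if (length(unique(unlist(x$selected))) > 1 || !is.null(x$selected[[1]])) {
    sel <- unlist(x$selected)
    if (!is.null(sel)) cat("Selected penalties per outer fold:",
                           paste(signif(sel, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Nested cross-validated evaluation of a tract-rate model
#'
#' Outer k-fold over tracts; for tunable (ridge) families an inner k-fold
#' grid search on the training tracts picks the penalty minimising mean
#' inner-validation RMSE (ties go to the smallest penalty), the winner is
#' refit on the full training set, and held-out tracts are predicted by the
#' signal reduced form over the full weight structure (never using held-out
#' outcomes). The weight matrix is re-row-standardised on each training
#' subset. Reported RMSE is `mean +/- 1.96 SE` over the outer folds, on the
#' percentage-rate scale by default.
#'
#' @param data Tract table (retained tracts).
#' @param formula Model formula (response = rate column).
#' @param weights `tract_weights` over the rows of `data`.
#' @param family Model family (see [spreg()]).
#' @param grid Penalty grid for ridge families (default
#'   [default_penalty_grid()]); ignored otherwise.
#' @param outer_k,inner_k Fold counts.
#' @param seed Integer seed driving the fold assignments.
#' @param unit `"percent"` (default; proportions scaled by 100) or
#'   `"response"` (RMSE on the outcome's own scale).
#' @return A `cv_result`.
#' @export
nested_cv <- function(data, formula, weights, family = "glm", grid = NULL,
                      outer_k = 10, inner_k = 10, seed = 1,
                      unit = c("percent", "response")) {
  unit <- match.arg(unit)
  data <- as.data.frame(data)
  n <- nrow(data)
  stopifnot(inherits(weights, "tract_weights"), weights$n == n)
  tunable <- family %in% RIDGE_FAMILIES
  if (tunable && is.null(grid)) grid <- default_penalty_grid()
  folds <- kfold_split(n, outer_k, seed)
  inner_seeds <- derive_seeds(seed, outer_k)
  yname <- all.vars(formula)[1]
  scale_f <- if (unit == "percent") 100 else 1
  fold_rmse <- numeric(outer_k)
  selected <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    best_pen <- NULL
    w_tr <- subset_weights(weights, tr)
    if (tunable) {
      inner_folds <- kfold_split(length(tr), inner_k, seed = inner_seeds[f])
      err <- matrix(NA_real_, inner_k, length(grid))
      for (g in seq_len(inner_k)) {
        itr <- tr[inner_folds != g]
        iva <- tr[inner_folds == g]
        w_itr <- subset_weights(weights, itr)
        for (ci in seq_along(grid)) {
          fit <- spreg(formula, data[itr, , drop = FALSE], w_itr,
                       family = family, penalty = grid[ci])
          # inner predictions over the outer-training universe only
          pred <- predict(fit, data[tr, , drop = FALSE], w_tr,
                          ids = match(iva, tr))
          err[g, ci] <- rmse(data[[yname]][iva], pred)
        }
      }
      grid_rmse <- colMeans(err)
      best_pen <- grid[which.min(grid_rmse)]  # which.min: smallest on ties
      selected[[f]] <- best_pen
    }
    fit <- spreg(formula, data[tr, , drop = FALSE], w_tr, family = family,
                 penalty = best_pen %||% 0)
    pred <- predict(fit, data, weights, ids = te)
    fold_rmse[f] <- rmse(data[[yname]][te] * scale_f, pred * scale_f)
  }
  new_cv_result(family, fold_rmse, selected, seed, unit)
}

#' Moran test of model residuals
#'
#' Spatially autocorrelated residuals indicate a misspecified model. Uses
#' the in-sample residuals (outcome minus signal prediction).
#'
#' @param fit A `spreg` fit.
#' @param weights The `tract_weights` used at fit time.
#' @inheritParams global_moran
#' @return A `moran_result`.
#' @export
residual_moran <- function(fit, weights, n_perm = 999, seed = 1,
                           alpha = 0.05) {
  stopifnot(inherits(fit, "spreg"))
  global_moran(residuals(fit), weights, n_perm = n_perm, seed = seed,
               alpha = alpha)
}

#' Permutation feature importance
#'
#' The importance of a variable is the increase in RMSE when that single
#' column is shuffled within the data set, the model's predictions being
#' recomputed (not refit). Shuffling happens on the modelling (already
#' preprocessed) columns; `n_repeats` independent shuffles are averaged.
#'
#' @param fit A `spreg` fit.
#' @param data The modelling table the fit was trained on.
#' @param weights `tract_weights` over `data` (spatial families).
#' @param n_repeats Shuffles per variable.
#' @param seed Integer seed.
#' @param unit As in [nested_cv()].
#' @return An `importance_table` data.frame: `variable`, `delta_rmse`,
#'   `rank`, plus `sd_delta`; metadata in attributes.
#' @export
permutation_importance <- function(fit, data, weights = NULL,
                                   n_repeats = 20, seed = 1,
                                   unit = c("percent", "response")) {
  unit <- match.arg(unit)
  stopifnot(inherits(fit, "spreg"))
  data <- as.data.frame(data)
  scale_f <- if (unit == "percent") 100 else 1
  yname <- all.vars(fit$terms)[1]
  y <- data[[yname]] * scale_f
  base_pred <- predict(fit, data, weights) * scale_f
  baseline <- rmse(y, base_pred)
  vars <- setdiff(all.vars(delete.response(fit$terms)), yname)
  seeds <- derive_seeds(seed, length(vars))
  rows <- lapply(seq_along(vars), function(i) {
    v <- vars[i]
    deltas <- with_seed(seeds[i], {
      vapply(seq_len(n_repeats), function(b) {
        shuffled <- data
        shuffled[[v]] <- sample(shuffled[[v]])
        pred <- predict(fit, shuffled, weights) * scale_f
        rmse(y, pred) - baseline
      }, numeric(1))
    })
    data.frame(variable = v, delta_rmse = mean(deltas),
               sd_delta = if (n_repeats > 1) sd(deltas) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-out$delta_rmse, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "baseline_rmse") <- baseline
  attr(out, "n_repeats") <- n_repeats
  attr(out, "seed") <- seed
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("Permutation importance (baseline RMSE %.4f, %d repeats)\n",
              attr(x, "baseline_rmse"), attr(x, "n_repeats")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Individual-prediction-aggregation baseline
#'
#' Cross-validates a case-level logistic regression (a plain stand-in for
#' a richer case-level learner) with tracts as the grouping unit: no case
#' of a held-out tract ever enters training. Per held-out tract the
#' predicted rate is the mean predicted probability over its cases; the
#' tract-level RMSE is computed against `outcome_column` exactly as for the
#' tract-level models.
#'
#' @param cases Case table: `tract_id`, `outcome` (0/1), numeric feature
#'   columns.
#' @param tracts Tract table with `outcome_column` (observed rates).
#' @param features Case feature columns (default: all numeric except
#'   `outcome`).
#' @param outcome_column Tract column holding observed rates
#'   (default `"eb_rate"`).
#' @param k Number of folds (tract-level).
#' @param seed Integer seed (same fold stream as [nested_cv()] for a given
#'   seed).
#' @param unit As in [nested_cv()].
#' @return A `cv_result` (family `"ipa"`); tracts dropped for having no
#'   cases in a fold are counted in `dropped_tracts`.
#' @export
ipa_baseline <- function(cases, tracts, features = NULL,
                         outcome_column = "eb_rate", k = 10, seed = 1,
                         unit = c("percent", "response")) {
  unit <- match.arg(unit)
  tracts <- as.data.frame(tracts)
  stopifnot(outcome_column %in% names(tracts),
            all(c("tract_id", "outcome") %in% names(cases)))
  if (is.null(features)) {
    features <- setdiff(names(cases)[vapply(cases, is.numeric, logical(1))],
                        "outcome")
  }
  scale_f <- if (unit == "percent") 100 else 1
  n <- nrow(tracts)
  folds <- kfold_split(n, k, seed)
  fml <- stats::as.formula(paste("outcome ~",
                                 paste(features, collapse = " + ")))
  fold_rmse <- numeric(k)
  dropped <- 0L
  for (f in seq_len(k)) {
    tr_ids <- tracts$tract_id[folds != f]
    te_ids <- tracts$tract_id[folds == f]
    tr_cases <- cases[cases$tract_id %in% tr_ids, , drop = FALSE]
    te_cases <- cases[cases$tract_id %in% te_ids, , drop = FALSE]
    m <- stats::glm(fml, data = tr_cases, family = stats::binomial())
    pr <- predict(m, newdata = te_cases, type = "response")
    agg <- tapply(pr, factor(te_cases$tract_id, levels = te_ids), mean)
    ok <- !is.na(agg)
    dropped <- dropped + sum(!ok)
    obs <- tracts[[outcome_column]][match(te_ids[ok], tracts$tract_id)]
    fold_rmse[f] <- rmse(obs * scale_f, as.numeric(agg[ok]) * scale_f)
  }
  if (dropped > 0) {
    message(sprintf("ipa_baseline: %d tract-fold cells had no cases", dropped))
  }
  new_cv_result("ipa", fold_rmse, vector("list", k), seed, unit, dropped)
}
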