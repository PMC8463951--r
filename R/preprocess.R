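# Tract preprocessing -----------------------------------------------------
#
# Turns case-level records and raw tract covariates into the modelling
# table: aggregation, a-priori tract exclusion, empirical Bayes shrinkage
# of crude rates toward a beta prior, driving-time categorisation, grand
# mean / mode imputation, monetary categorisation and IQR rescaling. Every
# stage returns a new table and logs its filter/imputation counts.

log_note <- function(x, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  attr(x, "provenance") <- c(attr(x, "provenance"), msg)
  x
}

#' Provenance log of a preprocessing pipeline
#' @param x A table produced by the preprocessing stages.
#' @return Character vector of logged filter/imputation messages.
#' @export
provenance <- function(x) attr(x, "provenance") %||% character(0)

#' Aggregate case-level records to tract level
#'
#' Tallies `n_cases`, `n_cancel` and the crude cancellation rate per tract
#' from the case outcomes, and appends one tract column per case feature
#' (mean over the tract's cases by default). Tracts with no matched cases
#' get missing feature values (imputed later), not zeros.
#'
#' @param cases Data frame with `case_id`, `tract_id`, `outcome` (0/1
#'   cancelled) and numeric feature columns.
#' @param tracts A `tract_frame`; rows are the universe of tracts.
#' @param features Character vector of case columns to aggregate (default:
#'   all numeric columns other than `outcome`).
#' @param how Aggregation: `"mean"`, `"sum"` or `"rate"` (mean of a 0/1
#'   column).
#' @return A new `tract_frame` with counts, `crude_rate` and the aggregated
#'   feature columns.
#' @export
aggregate_cases <- function(cases, tracts, features = NULL, how = "mean") {
  how <- match.arg(how, c("mean", "sum", "rate"))
  if (is.null(cases) || nrow(cases) == 0) abort_arg("no cases")
  stopifnot(all(c("tract_id", "outcome") %in% names(cases)),
            is_tract_frame(tracts))
  unmatched <- setdiff(unique(cases$tract_id), tracts$tract_id)
  out <- as_tract_frame(tracts)
  if (length(unmatched)) {
    out <- log_note(out, "aggregate_cases: %d case tract ID(s) unmatched (%s)",
                    length(unmatched),
                    paste(utils::head(unmatched, 3), collapse = ", "))
    cases <- cases[cases$tract_id %in% tracts$tract_id, , drop = FALSE]
    if (nrow(cases) == 0) abort_arg("no cases match the tract table")
  }
  if (is.null(features)) {
    features <- names(cases)[vapply(cases, is.numeric, logical(1))]
    features <- setdiff(features, c("outcome"))
  }
  grp <- factor(cases$tract_id, levels = tracts$tract_id)
  out$n_cases <- as.integer(tabulate(grp, nbins = nrow(tracts)))
  canc <- vapply(split(as.numeric(cases$outcome), grp), sum, numeric(1))
  out$n_cancel <- as.integer(canc[match(tracts$tract_id, names(canc))])
  agg_fun <- switch(how, mean = mean, rate = mean, sum = sum)
  out$crude_rate <- ifelse(out$n_cases > 0, out$n_cancel / out$n_cases,
                           NA_real_)
  for (f in features) {
    out[[f]] <- vapply(tracts$tract_id, function(id) {
      v <- cases[[f]][cases$tract_id == id]
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else agg_fun(v)
    }, numeric(1))
  }
  out <- log_note(out, "aggregate_cases: %d cases over %d tracts (%d empty)",
                  nrow(cases), nrow(tracts), sum(out$n_cases == 0))
  out
}

#' Flag tracts excluded a priori
#'
#' Tracts with no inhabitants (when a population column is supplied) or
#' with fewer than `min_cases` surgical cases are flagged excluded, with a
#' reason code; nothing is dropped, so tract sets stay stable across
#' stages. The retained count is logged.
#'
#' @param tracts A `tract_frame` with `n_cases`.
#' @param min_cases Exclusion threshold (default 20 cases).
#' @param population_column Optional name of a population column; zero
#'   population excludes the tract (reason `"no inhabitants"`, which takes
#'   precedence over the case-count rule).
#' @return New `tract_frame` with `excluded_flag` and `excluded_reason`.
#' @export
filter_tracts <- function(tracts, min_cases = 20, population_column = NULL) {
  stopifnot(is_tract_frame(tracts), !is.null(tracts$n_cases))
  out <- tracts
  out$excluded_flag <- FALSE
  out$excluded_reason <- NA_character_
  few <- out$n_cases < min_cases
  out$excluded_flag[few] <- TRUE
  out$excluded_reason[few] <- "fewer than min_cases surgical cases"
  if (!is.null(population_column)) {
    pop0 <- !is.na(out[[population_column]]) & out[[population_column]] == 0
    out$excluded_flag[pop0] <- TRUE
    out$excluded_reason[pop0] <- "no inhabitants"
  }
  n_exc <- sum(out$excluded_flag)
  out <- log_note(out,
    "filter_tracts: %d of %d tracts excluded (%.1f%%), %d retained",
    n_exc, nrow(out), format_pct(n_exc, nrow(out)), nrow(out) - n_exc)
  out
}

#' Method-of-moments beta prior for tract rates
#'
#' Fits a beta prior to the crude tract rates: prior mean `m` is the pooled
#' rate `sum(k)/sum(n)`; the between-tract variance is the case-weighted
#' variance of crude rates around `m`, `s2 = sum(n_i (r_i - m)^2) / sum(n)`;
#' then `a + b = m(1-m)/s2 - 1` and `a = m (a+b)`. If the implied `a+b` is
#' nonpositive (between-tract variance at or beyond the binomial limit) or
#' `s2 = 0`, the prior is degenerate and shrinkage is bypassed.
#'
#' @param k Cancellation counts (retained tracts only).
#' @param n Case counts.
#' @return An `eb_prior` object: `a`, `b`, `m`, `degenerate`.
#' @export
estimate_beta_prior <- function(k, n) {
  stopifnot(length(k) == length(n), length(k) >= 2, all(n >= 0),
            all(k <= n))
  if (sum(n) == 0) abort_arg("no cases: sum(n) = 0")
  m <- sum(k) / sum(n)
  r <- ifelse(n > 0, k / n, m)
  s2 <- sum(n * (r - m)^2) / sum(n)
  prior <- list(a = NA_real_, b = NA_real_, m = m, s2 = s2,
                degenerate = TRUE)
  if (s2 > 0 && m > 0 && m < 1) {
    ab <- m * (1 - m) / s2 - 1
    if (ab > 0) {
      prior$a <- m * ab
      prior$b <- (1 - m) * ab
      prior$degenerate <- FALSE
    }
  }
  class(prior) <- "eb_prior"
  prior
}

#' @export
print.eb_prior <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Degenerate beta prior: mean %.4f (shrinkage bypassed)\n",
                x$m))
  } else {
    cat(sprintf("Beta prior: a = %.3f, b = %.3f (mean %.4f, strength %.1f)\n",
                x$a, x$b, x$m, x$a + x$b))
  }
  invisible(x)
}

#' Empirical Bayes shrinkage of crude rates
#'
#' Posterior-mean rates under the beta prior:
#' `eb = (k + a) / (n + a + b)`. Each shrunk rate lies weakly between the
#' crude rate and the prior mean, and the pull toward the prior vanishes as
#' `n` grows. With a degenerate prior the crude rates are returned
#' unchanged; tracts with `n = 0` receive the prior mean.
#'
#' @param k,n Counts as in [estimate_beta_prior()].
#' @param prior An `eb_prior` object.
#' @return Numeric vector of shrunk rates.
#' @export
eb_shrink <- function(k, n, prior) {
  stopifnot(inherits(prior, "eb_prior"), length(k) == length(n))
  if (prior$degenerate) {
    return(ifelse(n > 0, k / n, prior$m))
  }
  (k + prior$a) / (n + prior$a + prior$b)
}

#' Categorise driving time into 6-minute bins
#'
#' Bins `[0,6) ... [54,60]` map to categories 1..10 and anything beyond 60
#' minutes (strictly) to the overflow category 11; exactly 60 minutes is
#' not "farther than 1 hour away" and stays in bin 10. Missing stays
#' missing.
#'
#' @param minutes Nonnegative driving times (NA allowed).
#' @return Integer categories 1..11.
#' @export
categorize_driving_time <- function(minutes) {
  if (any(minutes < 0, na.rm = TRUE)) abort_arg("negative driving time")
  idx <- floor(minutes / 6) + 1
  idx[!is.na(minutes) & minutes == 60] <- 10
  idx[!is.na(minutes) & minutes > 60] <- 11
  as.integer(idx)
}

#' Per-tract EB-smoothed driving-time profile
#'
#' For each of the 11 driving-time categories, the per-tract proportion of
#' cases in that category is shrunk with its own empirical Bayes beta prior
#' (each category versus the rest as a binomial). The globally most common
#' category is dropped as the base (ties broken toward the lower index) to
#' avoid the induced linear dependence; the remaining 10 columns are
#' returned as tract covariates.
#'
#' @param cases Case table with `tract_id` and `drive_minutes`.
#' @param tracts A `tract_frame` defining the tract universe.
#' @return Data frame with `tract_id` and `drive_cat_<c>` columns; the
#'   dropped base category is recorded in attribute `base_category`.
#' @export
drive_time_tract_profile <- function(cases, tracts) {
  stopifnot("drive_minutes" %in% names(cases), is_tract_frame(tracts))
  obs <- cases[!is.na(cases$drive_minutes), , drop = FALSE]
  if (nrow(obs) == 0) {
    warning("all driving times missing; drive-time stage skipped")
    return(NULL)
  }
  cat_ <- categorize_driving_time(obs$drive_minutes)
  grp <- factor(obs$tract_id, levels = tracts$tract_id)
  n <- as.integer(tabulate(grp, nbins = nrow(tracts)))
  totals <- tabulate(cat_, nbins = 11L)
  base <- which.max(totals)  # which.max takes the first (lowest) on ties
  out <- data.frame(tract_id = tracts$tract_id)
  for (cc in setdiff(seq_len(11L), base)) {
    k <- as.integer(tabulate(as.integer(grp)[cat_ == cc],
                             nbins = nrow(tracts)))
    pr <- estimate_beta_prior(k, n)
    out[[sprintf("drive_cat_%02d", cc)]] <- eb_shrink(k, n, pr)
  }
  attr(out, "base_category") <- base
  out
}

#' Grand-mean / mode imputation
#'
#' Continuous columns get the grand mean of the observed values;
#' categorical columns get the modal observed value (ties toward the first
#' encountered level). The number of imputed cells is recorded in the
#' attribute `n_imputed` and logged.
#'
#' @param column Vector with missing values.
#' @param kind `"continuous"` or `"categorical"`.
#' @return Imputed column.
#' @export
impute_missing <- function(column, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  miss <- is.na(column)
  if (all(miss)) abort_arg("all values missing; cannot impute")
  n_imp <- sum(miss)
  if (n_imp > 0) {
    fill <- if (kind == "continuous") {
      mean(column[!miss])
    } else {
      tab <- table(column[!miss])
      names(tab)[which.max(tab)]
    }
    if (kind == "categorical" && is.factor(column)) {
      column[miss] <- factor(fill, levels = levels(column))
    } else if (kind == "categorical") {
      column[miss] <- fill
    } else {
      column[miss] <- fill
    }
  }
  attr(column, "n_imputed") <- n_imp
  if (n_imp > 0) message(sprintf("impute_missing: %d cell(s) imputed", n_imp))
  column
}

#' Categorise a monetary column on fixed breakpoints
#'
#' Half-open bins: values below the first breakpoint get category 1, values
#' in `[b_i, b_{i+1})` get `i + 1`, values at or above the last breakpoint
#' get the top category (a value equal to a breakpoint falls in the upper
#' bin). Default breakpoints are the sample quartiles of the observed
#' values.
#'
#' @param values Numeric column (NA allowed, carried through).
#' @param breakpoints Strictly increasing breakpoints; default the 25/50/75
#'   percent quantiles.
#' @return Integer category column with attribute `breakpoints`.
#' @export
categorize_monetary <- function(values, breakpoints = NULL) {
  if (is.null(breakpoints)) {
    breakpoints <- unname(quantile(values, c(0.25, 0.5, 0.75), na.rm = TRUE))
    breakpoints <- unique(breakpoints)
  }
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    abort_arg("breakpoints must be strictly increasing")
  }
  out <- findInterval(values, breakpoints) + 1L
  attr(out, "breakpoints") <- breakpoints
  out
}

#' Rescale a column by its interquartile range
#'
#' Divides by the IQR of the observed values (linear-interpolation
#' quantiles, the default type 7), so a one-unit change in the rescaled
#' variable is one IQR of the original. A zero-IQR column is returned
#' unchanged with a warning.
#'
#' @param column Numeric column.
#' @param observed Optional logical mask of genuinely observed (non-imputed)
#'   cells used to compute the IQR; default all non-missing.
#' @return Rescaled column with attribute `iqr`.
#' @export
rescale_iqr <- function(column, observed = NULL) {
  stopifnot(is.numeric(column))
  use <- if (is.null(observed)) !is.na(column) else observed & !is.na(column)
  iqr <- unname(diff(quantile(column[use], c(0.25, 0.75), type = 7)))
  if (iqr == 0) {
    warning("IQR is zero; column left unscaled")
    attr(column, "iqr") <- 0
    return(column)
  }
  out <- column / iqr
  attr(out, "iqr") <- iqr
  out
}

#' Empirical Bayes rate column for a tract table
#'
#' Convenience stage: estimates the beta prior on the retained tracts and
#' appends `eb_rate` (excluded tracts keep their crude rate shrunk under
#' the same prior, but they do not inform it).
#'
#' @param tracts A `tract_frame` with `n_cases`, `n_cancel` and (after
#'   [filter_tracts()]) `excluded_flag`.
#' @return The table with an `eb_rate` column; the prior in attribute
#'   `eb_prior`.
#' @export
add_eb_rate <- function(tracts) {
  stopifnot(is_tract_frame(tracts), !is.null(tracts$n_cases),
            !is.null(tracts$n_cancel))
  keep <- if (is.null(tracts$excluded_flag)) rep(TRUE, nrow(tracts)) else
    !tracts$excluded_flag
  prior <- estimate_beta_prior(tracts$n_cancel[keep], tracts$n_cases[keep])
  tracts$eb_rate <- eb_shrink(tracts$n_cancel, tracts$n_cases, prior)
  attr(tracts, "eb_prior") <- prior
  tracts
}
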