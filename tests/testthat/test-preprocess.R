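# Tract preprocessing: aggregation, exclusion, EB shrinkage, categorisation

test_that("case aggregation tallies counts, rates and feature means", {
  tr <- as_tract_frame(data.frame(tract_id = c("A", "B", "C")))
  cases <- data.frame(
    case_id = sprintf("c%d", 1:7),
    tract_id = c("A", "A", "A", "B", "B", "B", "B"),
    outcome = c(0, 0, 0, 1, 0, 0, 0),
    prior_no_show = c(0, 1, 2, 0, 0, 1, 3))
  out <- suppressMessages(aggregate_cases(cases, tr))
  expect_equal(out$n_cases, c(3L, 4L, 0L))
  expect_equal(out$n_cancel, c(0L, 1L, 0L))
  expect_equal(out$crude_rate, c(0, 0.25, NA_real_))
  expect_equal(out$prior_no_show, c(1.0, 1.0, NA_real_))
  expect_error(aggregate_cases(cases[0, ], tr), "no cases")
})

test_that("a-priori tract exclusion mirrors the filtering arithmetic", {
  set.seed(4)
  n_cases <- c(rep(25L, 463), sample(0:19, 9, replace = TRUE))
  tr <- as_tract_frame(data.frame(tract_id = sprintf("t%03d", 1:472),
                                  n_cases = n_cases,
                                  population = 100L))
  out <- suppressMessages(filter_tracts(tr, min_cases = 20,
                                        population_column = "population"))
  expect_equal(sum(!out$excluded_flag), 463)
  expect_equal(sum(out$excluded_flag), 9)
  expect_match(provenance(out)[1], "9 of 472.*1.9%.*463 retained")

  # vacuous filter
  out0 <- suppressMessages(filter_tracts(tr, min_cases = 0,
                                         population_column = "population"))
  expect_false(any(out0$excluded_flag))

  # zero population dominates even with plenty of cases
  tr$population[1] <- 0L
  out2 <- suppressMessages(filter_tracts(tr, min_cases = 20,
                                         population_column = "population"))
  expect_true(out2$excluded_flag[1])
  expect_equal(out2$excluded_reason[1], "no inhabitants")
})

test_that("beta prior matches the method-of-moments arithmetic", {
  k <- c(1, 5, 10); n <- c(50, 50, 50)
  pr <- estimate_beta_prior(k, n)
  # independent hand evaluation
  m <- sum(k) / sum(n)
  s2 <- sum(n * (k / n - m)^2) / sum(n)
  ab <- m * (1 - m) / s2 - 1
  expect_equal(pr$m, m)
  expect_false(pr$degenerate)
  expect_equal(pr$a, m * ab, tolerance = 1e-12)
  expect_equal(pr$b, (1 - m) * ab, tolerance = 1e-12)

  # prior mean always the pooled rate
  set.seed(8)
  k2 <- rbinom(20, 100, 0.07); n2 <- rep(100, 20)
  expect_equal(estimate_beta_prior(k2, n2)$m, sum(k2) / sum(n2))

  # identical crude rates: zero between-tract variance, degenerate prior
  pr0 <- estimate_beta_prior(c(5, 5, 5), c(100, 100, 100))
  expect_true(pr0$degenerate)
  expect_equal(eb_shrink(c(5, 5, 5), c(100, 100, 100), pr0),
               rep(0.05, 3))
  expect_error(estimate_beta_prior(c(0, 0), c(0, 0)), "sum\\(n\\) = 0")
})

test_that("EB shrinkage contracts toward the prior mean", {
  pr <- structure(list(a = 2, b = 38, m = 0.05, degenerate = FALSE),
                  class = "eb_prior")
  expect_equal(eb_shrink(0, 10, pr), 2 / 50)
  # shrinkage vanishes with n
  r <- vapply(c(10, 100, 1e4, 1e7), function(n) {
    eb_shrink(round(0.08 * n), n, pr)
  }, numeric(1))
  expect_lt(abs(r[4] - 0.08), 1e-4)
  expect_true(all(diff(abs(r - 0.08)) <= 0))

  # worked three-tract set: between-ness and oracle agreement
  k <- c(1, 5, 10); n <- c(50, 50, 50)
  prm <- estimate_beta_prior(k, n)
  eb <- eb_shrink(k, n, prm)
  expect_equal(eb, (k + prm$a) / (n + prm$a + prm$b))
  crude <- k / n
  expect_true(all(pmin(crude, prm$m) - 1e-12 <= eb &
                    eb <= pmax(crude, prm$m) + 1e-12))
  expect_lte(var(eb), var(crude))
  # n = 0 with a proper prior returns the prior mean
  expect_equal(eb_shrink(0, 0, prm), prm$a / (prm$a + prm$b))
})

test_that("variance contraction holds across simulated fixtures", {
  for (s in 1:5) {
    sim <- simulate_tract_data(synth_config(rows = 6, cols = 6, seed = s))
    tr <- sim$tracts
    pr <- estimate_beta_prior(tr$n_cancel, tr$n_cases)
    eb <- eb_shrink(tr$n_cancel, tr$n_cases, pr)
    expect_lte(var(eb), var(tr$crude_rate))
  }
})

test_that("driving times bin into 6-minute categories with a 60-minute edge", {
  expect_equal(categorize_driving_time(7), 2L)
  expect_equal(categorize_driving_time(60), 10L)
  expect_equal(categorize_driving_time(60.01), 11L)
  expect_equal(categorize_driving_time(0), 1L)
  expect_equal(categorize_driving_time(c(5.99, 6, 54, 59.9, 120)),
               c(1L, 2L, 10L, 10L, 11L))
  expect_true(is.na(categorize_driving_time(NA_real_)))
  expect_error(categorize_driving_time(-1), "negative")
})

test_that("drive-time profiles drop the modal base and stay near-additive", {
  # two categories with equal global frequency: tie broken to lower index
  tr <- as_tract_frame(data.frame(tract_id = c("A", "B")))
  cases <- data.frame(tract_id = rep(c("A", "B"), each = 4),
                      drive_minutes = c(2, 2, 10, 10, 2, 2, 10, 10))
  prof <- drive_time_tract_profile(cases, tr)
  expect_equal(attr(prof, "base_category"), 1L)
  expect_false("drive_cat_01" %in% names(prof))
  expect_true("drive_cat_02" %in% names(prof))

  # near-additivity of the 11 per-category shrunk proportions
  set.seed(12)
  tr2 <- as_tract_frame(data.frame(tract_id = sprintf("t%03d", 1:100)))
  cases2 <- data.frame(
    tract_id = rep(tr2$tract_id, each = 30),
    drive_minutes = pmin(rexp(3000, 1 / 25), 80))
  cat2 <- categorize_driving_time(cases2$drive_minutes)
  grp <- factor(cases2$tract_id, levels = tr2$tract_id)
  n <- as.integer(table(grp))
  total <- rep(0, 100)
  for (cc in 1:11) {
    k <- as.integer(tabulate(as.integer(grp)[cat2 == cc], nbins = 100))
    total <- total + eb_shrink(k, n, estimate_beta_prior(k, n))
  }
  expect_true(all(abs(total - 1) < 0.02))

  cases_na <- data.frame(tract_id = "A", drive_minutes = NA_real_)
  expect_warning(out <- drive_time_tract_profile(cases_na, tr), "skipped")
  expect_null(out)
})

test_that("imputation uses grand means and modes and counts its cells", {
  expect_equal(suppressMessages(impute_missing(c(1, NA, 3))), c(1, 2, 3),
               ignore_attr = TRUE)
  imp <- suppressMessages(impute_missing(c("A", "A", "B", NA),
                                         kind = "categorical"))
  expect_equal(unclass(imp)[4], "A", ignore_attr = TRUE)
  expect_equal(attr(imp, "n_imputed"), 1L)
  # 31 of 463 incomes missing -> 31 cells imputed
  set.seed(3)
  inc <- rnorm(463, 5e4, 1e4)
  inc[sample(463, 31)] <- NA
  out <- suppressMessages(impute_missing(inc))
  expect_equal(attr(out, "n_imputed"), 31L)
  expect_false(anyNA(out))
  expect_error(impute_missing(c(NA, NA)), "all values missing")
})

test_that("monetary categorisation uses half-open bins on the breakpoints", {
  expect_equal(categorize_monetary(c(10, 20, 30), breakpoints = 20),
               c(1L, 2L, 2L), ignore_attr = TRUE)  # on the breakpoint: upper
  expect_error(categorize_monetary(1:3, breakpoints = c(2, 2)),
               "strictly increasing")
  set.seed(5)
  v <- rnorm(100)
  cats <- categorize_monetary(v)
  expect_equal(sort(unique(cats)), 1:4)
  expect_true(all(abs(table(cats) - 25) <= 1))  # quartiles up to ties
})

test_that("IQR rescaling divides by the interquartile range", {
  out <- rescale_iqr(c(0, 25, 50, 75, 100))
  expect_equal(unclass(out), c(0, 0.5, 1, 1.5, 2), ignore_attr = TRUE)
  expect_equal(attr(out, "iqr"), 50)
  expect_warning(same <- rescale_iqr(rep(3, 5)), "zero")
  expect_equal(unclass(same), rep(3, 5), ignore_attr = TRUE)
  set.seed(6)
  v <- rexp(200)
  expect_equal(unname(diff(quantile(rescale_iqr(v), c(0.25, 0.75)))), 1,
               tolerance = 1e-12)
})

test_that("preprocessing stages do not mutate their inputs", {
  sim <- simulate_tract_data(synth_config(rows = 4, cols = 4, seed = 2))
  before <- sim$tracts
  snapshot <- as.data.frame(before)
  invisible(suppressMessages(filter_tracts(before, min_cases = 10)))
  invisible(add_eb_rate(before))
  expect_identical(as.data.frame(before), snapshot)
})
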