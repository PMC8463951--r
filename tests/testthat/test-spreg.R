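# Maximum-likelihood spatial regression

make_xy <- function(fx, ncov = 2, family = "iid", pars = NULL, sigma = 0.3,
                    seed = 61) {
  X <- simulate_covariates(fx$w, ncov, phi = 0.4, seed = seed)
  pars <- pars %||% list(beta = c(0.5, seq_len(ncov) / 2))
  y <- simulate_rate_surface(X, fx$w, family, pars, sigma, seed = seed + 1)
  d <- as.data.frame(fx$tracts)
  for (j in seq_len(ncov)) d[[paste0("x", j)]] <- X[, j]
  d$y <- y
  d
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("OLS fits match closed forms", {
  fx <- lattice_fixture(6, 5)
  d <- make_xy(fx, 2, sigma = 0)
  f0 <- spreg(y ~ x1 + x2, d, fx$w, family = "glm")
  expect_equal(unname(coef(f0)), c(0.5, 0.5, 1.0), tolerance = 1e-10)
  expect_equal(f0$sigma2, 0, tolerance = 1e-20)

  fint <- spreg(y ~ 1, d, fx$w, family = "glm")
  expect_equal(unname(coef(fint)), mean(d$y), tolerance = 1e-12)

  set.seed(62)
  Xr <- matrix(rnorm(90), 30, 3)
  dr <- data.frame(y = rnorm(30), a = Xr[, 1], b = Xr[, 2], c = Xr[, 3])
  fr <- spreg(y ~ a + b + c, dr, family = "glm")
  A <- cbind(1, Xr)
  beta_ne <- solve(t(A) %*% A, t(A) %*% dr$y)
  expect_equal(unname(coef(fr)), as.numeric(beta_ne), tolerance = 1e-10)

  dr$dup <- dr$a
  expect_error(spreg(y ~ a + dup, dr, family = "glm"), "dup")
})

test_that("ridge regression hits its closed form and limits", {
  set.seed(63)
  d <- data.frame(y = rnorm(10), u = rnorm(10), v = rnorm(10))
  f0 <- spreg(y ~ u + v, d, family = "glm")
  fr0 <- spreg(y ~ u + v, d, family = "ridge_glm", penalty = 0)
  expect_equal(coef(fr0), coef(f0), tolerance = 1e-10)

  # worked penalised normal equations (standardised slopes, c = 2.5)
  cc <- 2.5
  X <- as.matrix(d[, c("u", "v")])
  mu <- colMeans(X); s <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, mu), 2, s, "/")
  bs <- solve(t(Z) %*% Z + diag(cc, 2), t(Z) %*% (d$y - mean(d$y)))
  slopes <- as.numeric(bs) / s
  b0 <- mean(d$y) - sum(slopes * mu)
  fr <- spreg(y ~ u + v, d, family = "ridge_glm", penalty = cc)
  expect_equal(unname(coef(fr)), unname(c(b0, slopes)), tolerance = 1e-10)

  # infinite-penalty limit: slopes -> 0, intercept -> mean(y)
  fbig <- spreg(y ~ u + v, d, family = "ridge_glm", penalty = 1e12)
  expect_lt(max(abs(coef(fbig)[-1])), 1e-9)
  expect_equal(unname(coef(fbig)[1]), mean(d$y), tolerance = 1e-6)

  # penalty rejected outside the ridge families
  expect_error(spreg(y ~ u, d, family = "glm", penalty = 1), "ridge")
})

test_that("ridge slope norms are non-increasing in the penalty", {
  fx <- lattice_fixture(7, 7)
  d <- make_xy(fx, 3, family = "sar", pars = list(beta = c(0, 1, -1, 0.5),
                                                  rho = 0.5))
  norms_glm <- vapply(10^seq(-3, 3), function(cc) {
    sqrt(sum(coef(spreg(y ~ x1 + x2 + x3, d, family = "ridge_glm",
                        penalty = cc))[-1]^2))
  }, numeric(1))
  expect_true(all(diff(norms_glm) <= 1e-12))
  norms_sar <- vapply(10^seq(-3, 3), function(cc) {
    sqrt(sum(coef(spreg(y ~ x1 + x2 + x3, d, fx$w, family = "ridge_sar",
                        penalty = cc, rho = 0.4))[-1]^2))
  }, numeric(1))
  expect_true(all(diff(norms_sar) <= 1e-12))
})

test_that("spatial-lag likelihood matches a dense normal density", {
  fx <- lattice_fixture(5, 5)
  d <- make_xy(fx, 2, family = "sar",
               pars = list(beta = c(0.2, 1, -0.5), rho = 0.5))
  Wd <- as.matrix(weights_matrix(fx$w))
  X <- cbind(1, d$x1, d$x2)
  for (r in seq(-0.9, 0.9, length.out = 21)) {
    fit <- spreg(y ~ x1 + x2, d, fx$w, family = "sar", rho = r)
    A <- diag(25) - r * Wd
    mu <- solve(A, X %*% coef(fit))
    Sigma <- fit$sigma2 * solve(A) %*% t(solve(A))
    expect_equal(fit$loglik, dense_mvn_ll(d$y, as.numeric(mu), Sigma),
                 tolerance = 1e-8)
  }
})

test_that("spatial-error and SARAR likelihoods match dense densities", {
  fx <- lattice_fixture(5, 5)
  Wd <- as.matrix(weights_matrix(fx$w))
  d <- make_xy(fx, 2, family = "sem",
               pars = list(beta = c(0.2, 1, -0.5), lambda = 0.6))
  X <- cbind(1, d$x1, d$x2)
  for (l in seq(-0.9, 0.9, length.out = 21)) {
    fit <- spreg(y ~ x1 + x2, d, fx$w, family = "sem", lambda = l)
    B <- diag(25) - l * Wd
    Sigma <- fit$sigma2 * solve(B) %*% t(solve(B))
    expect_equal(fit$loglik,
                 dense_mvn_ll(d$y, as.numeric(X %*% coef(fit)), Sigma),
                 tolerance = 1e-8)
  }
  # SARAR profile at a grid of (rho, lambda) pairs
  d2 <- make_xy(fx, 2, family = "sac",
                pars = list(beta = c(0.2, 1, -0.5), rho = 0.4,
                            lambda = 0.3))
  for (r in c(-0.5, 0, 0.4)) {
    for (l in c(-0.3, 0, 0.5)) {
      fit <- spreg(y ~ x1 + x2, d2, fx$w, family = "sac", rho = r,
                   lambda = l)
      A <- diag(25) - r * Wd; B <- diag(25) - l * Wd
      mu <- solve(A, X %*% coef(fit))
      AB <- solve(B %*% A)
      Sigma <- fit$sigma2 * AB %*% t(AB)
      expect_equal(fit$loglik, dense_mvn_ll(d2$y, as.numeric(mu), Sigma),
                   tolerance = 1e-8)
    }
  }
})

test_that("moving-average likelihood matches a dense density", {
  fx <- lattice_fixture(5, 5)
  Wd <- as.matrix(weights_matrix(fx$w))
  d <- make_xy(fx, 2, family = "sma",
               pars = list(beta = c(0.2, 1, -0.5), lambda = 0.5))
  X <- cbind(1, d$x1, d$x2)
  for (l in seq(-0.9, 0.9, length.out = 21)) {
    fit <- spreg(y ~ x1 + x2, d, fx$w, family = "sma", lambda = l)
    M <- diag(25) + l * Wd
    Sigma <- fit$sigma2 * M %*% t(M)
    expect_equal(fit$loglik,
                 dense_mvn_ll(d$y, as.numeric(X %*% coef(fit)), Sigma),
                 tolerance = 1e-8)
  }
})

test_that("constrained spatial fits reduce to OLS", {
  fx <- lattice_fixture(6, 6)
  d <- make_xy(fx, 2, family = "sar", pars = list(beta = c(0, 1, 1),
                                                  rho = 0.4))
  f_glm <- spreg(y ~ x1 + x2, d, fx$w, family = "glm")
  for (fam in c("sar", "sem", "sma")) {
    args <- list(y ~ x1 + x2, d, fx$w, family = fam)
    if (fam == "sar") args$rho <- 0 else args$lambda <- 0
    f <- do.call(spreg, args)
    expect_equal(coef(f), coef(f_glm), tolerance = 1e-8)
    expect_equal(f$sigma2, f_glm$sigma2, tolerance = 1e-10)
  }
  f_sac <- spreg(y ~ x1 + x2, d, fx$w, family = "sac", rho = 0, lambda = 0)
  expect_equal(coef(f_sac), coef(f_glm), tolerance = 1e-8)

  # SARAR profile at (rho, 0) equals the spatial-lag concentrated likelihood
  for (r in c(-0.4, 0.2, 0.6)) {
    f1 <- spreg(y ~ x1 + x2, d, fx$w, family = "sac", rho = r, lambda = 0)
    f2 <- spreg(y ~ x1 + x2, d, fx$w, family = "sar", rho = r)
    expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  }
})

test_that("likelihoods nest across families and optima dominate rho = 0", {
  fx <- lattice_fixture(8, 8)
  d <- make_xy(fx, 2, family = "sac",
               pars = list(beta = c(0.2, 1, -0.7), rho = 0.4, lambda = 0.3),
               sigma = 0.4)
  fml <- y ~ x1 + x2
  ll <- function(fam, ...) spreg(fml, d, fx$w, family = fam, ...)$loglik
  expect_gte(ll("sar") + 1e-8, ll("glm"))
  expect_gte(ll("sdm") + 1e-8, ll("sar"))
  expect_gte(ll("sem") + 1e-8, ll("glm"))
  expect_gte(ll("sdem") + 1e-8, ll("sem"))
  expect_gte(ll("sac") + 1e-8, ll("sar"))
  expect_gte(ll("sac") + 1e-8, ll("sem"))
  f_sem <- spreg(fml, d, fx$w, family = "sem")
  f_sem0 <- spreg(fml, d, fx$w, family = "sem", lambda = 0)
  expect_gte(f_sem$loglik + 1e-10, f_sem0$loglik)
})

test_that("Durbin designs carry the lagged covariates", {
  fx <- lattice_fixture(6, 6)
  d <- make_xy(fx, 3, family = "sdm",
               pars = list(beta = c(0, 1, -1, 0.5), rho = 0.4,
                           theta = c(0.5, 0, -0.3)))
  f <- spreg(y ~ x1 + x2 + x3, d, fx$w, family = "sdm")
  expect_length(coef(f), 7)  # 1 + 3 + 3 lagged
  expect_named(f$theta, c("lag.x1", "lag.x2", "lag.x3"))
  f2 <- spreg(y ~ x1 + x2 + x3, d, fx$w, family = "sdem")
  expect_length(f2$theta, 3)
})

test_that("estimates are equivariant under tract reordering", {
  fx <- lattice_fixture(6, 6)
  d <- make_xy(fx, 2, family = "sar", pars = list(beta = c(0.1, 1, -0.5),
                                                  rho = 0.5))
  f1 <- spreg(y ~ x1 + x2, d, fx$w, family = "sar")
  perm <- spatialdosc:::with_seed(71, sample(36))
  d2 <- d[perm, ]
  w2 <- subset_weights(fx$w, perm)
  f2 <- spreg(y ~ x1 + x2, as_tract_frame(d2), w2, family = "sar")
  expect_equal(f2$rho, f1$rho, tolerance = 1e-6)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-6)
})

test_that("signal predictions follow the reduced forms", {
  fx <- lattice_fixture(6, 6)
  d <- make_xy(fx, 2, family = "sar", pars = list(beta = c(0.1, 1, -0.5),
                                                  rho = 0.5))
  f_glm <- spreg(y ~ x1 + x2, d, fx$w, family = "glm")
  p <- predict(f_glm, d)
  expect_equal(unname(p),
               as.numeric(cbind(1, d$x1, d$x2) %*% coef(f_glm)),
               tolerance = 1e-12)

  f_sar0 <- spreg(y ~ x1 + x2, d, fx$w, family = "sar", rho = 0)
  expect_equal(predict(f_sar0, d, fx$w), predict(f_glm, d),
               tolerance = 1e-10)

  f_sar <- spreg(y ~ x1 + x2, d, fx$w, family = "sar")
  pred <- predict(f_sar, d, fx$w)
  Wd <- as.matrix(weights_matrix(fx$w))
  oracle <- solve(diag(36) - f_sar$rho * Wd,
                  cbind(1, d$x1, d$x2) %*% coef(f_sar))
  expect_equal(unname(pred), as.numeric(oracle), tolerance = 1e-10)

  # subsetting by tract id
  ids <- d$tract_id[c(3, 9)]
  expect_equal(predict(f_sar, d, fx$w, ids = ids), pred[ids])
})

test_that("model simulation reproduces the fitted moments roughly", {
  fx <- lattice_fixture(7, 7)
  d <- make_xy(fx, 2, family = "sem", pars = list(beta = c(0.3, 1, -0.5),
                                                  lambda = 0.5))
  f <- spreg(y ~ x1 + x2, d, fx$w, family = "sem")
  sims <- simulate(f, nsim = 200, seed = 81, weights = fx$w)
  expect_equal(dim(sims), c(49, 200))
  mu <- rowMeans(as.matrix(sims))
  expect_equal(mu, unname(fitted(f)), tolerance = 0.2)
})
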