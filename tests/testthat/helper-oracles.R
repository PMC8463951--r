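# Independent oracles and fixture builders shared across tests. These are
# deliberately naive (dense double loops, textbook formulas) so they cannot
# share code paths with the package implementation.

# Moran's I as a literal double sum over the dense weight matrix.
moran_double_sum <- function(x, Wmat) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- sum(Wmat)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + Wmat[i, j] * z[i] * z[j]
    }
  }
  (n / s0) * num / sum(z^2)
}

# Dense multivariate normal log density via base solve()/determinant().
dense_mvn_ll <- function(y, mu, Sigma) {
  n <- length(y)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  quad <- as.numeric(t(y - mu) %*% solve(Sigma, y - mu))
  -0.5 * (n * log(2 * pi) + ld + quad)
}

# Random connected-ish symmetric weighted graph as a tract_weights object.
random_graph_weights <- function(n, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  # random spanning chain guarantees no empty graph; extra random edges
  ord <- sample(n)
  for (k in seq_len(n - 1)) A[ord[k], ord[k + 1]] <- runif(1, 0.2, 2)
  extra <- which(upper.tri(A) & matrix(runif(n * n) < 0.25, n, n))
  A[extra] <- runif(length(extra), 0.2, 2)
  A <- A + t(A)
  diag(A) <- 0
  nb <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  raw <- lapply(seq_len(n), function(i) A[i, nb[[i]]])
  tr <- as_tract_frame(data.frame(tract_id = sprintf("g%02d", seq_len(n))))
  row_standardize(tr, nb, raw)
}

# Small lattice + weights reused by many tests.
lattice_fixture <- function(rows, cols, cell = 1) {
  tr <- make_tract_lattice(rows, cols, cell)
  list(tracts = tr, w = tract_weights(tr))
}

# Case table for the IPA baseline: per tract n_i cases with exactly k_i
# cancellations and pure-noise case features.
make_case_table <- function(tracts, n_features = 3, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(tracts)), function(i) {
    n <- tracts$n_cases[i]
    k <- tracts$n_cancel[i]
    out <- data.frame(
      case_id = sprintf("%s-c%04d", tracts$tract_id[i], seq_len(n)),
      tract_id = tracts$tract_id[i],
      outcome = sample(c(rep(1L, k), rep(0L, n - k))))
    for (f in seq_len(n_features)) {
      out[[paste0("f", f)]] <- rnorm(n)
    }
    out
  })
  do.call(rbind, rows)
}
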