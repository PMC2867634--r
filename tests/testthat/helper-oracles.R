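# Independent oracles: deliberately naive linear-space implementations used
# only on tiny instances where underflow cannot occur, plus small fixture
# generators.

# linear-space penalized marginal log-likelihood (no logsumexp)
lin_marginal <- function(data, params) {
  tot <- 0
  for (g in seq_along(data$y)) {
    dens <- 0
    for (k in seq_len(params$K)) {
      dens <- dens + params$p[k] *
        prod(dnorm(data$y[[g]], params$mu[k], sqrt(params$sigma2[k])))
    }
    tot <- tot + log(dens)
  }
  tot + sum(log(params$p))
}

# linear-space responsibilities
lin_estep <- function(data, params) {
  t(vapply(data$y, function(y) {
    w <- vapply(seq_len(params$K), function(k) {
      params$p[k] * prod(dnorm(y, params$mu[k], sqrt(params$sigma2[k])))
    }, numeric(1))
    w / sum(w)
  }, numeric(params$K)))
}

# small random dataset: G cells, n_g in [nmin, nmax], one normal population
rand_cell_data <- function(G, nmin = 2, nmax = 8, mean = 0, sd = 1) {
  cell_dataset(
    paste0("c", seq_len(G)),
    lapply(seq_len(G), function(i) rnorm(sample(nmin:nmax, 1), mean, sd))
  )
}

# two clearly separated cell groups (separation in units of sd)
split_cell_data <- function(G1 = 3, G2 = 3, n_per = 25, delta = 10, sd = 1) {
  cell_dataset(
    paste0("c", seq_len(G1 + G2)),
    c(lapply(seq_len(G1), function(i) rnorm(n_per, 0, sd)),
      lapply(seq_len(G2), function(i) rnorm(n_per, delta, sd)))
  )
}
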