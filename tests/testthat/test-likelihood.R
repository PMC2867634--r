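# model_core: cell likelihood, penalized complete and marginal objectives

test_that("cell_loglik equals the sum of normal log-densities", {
  expect_equal(cell_loglik(0, 0, 1), -0.5 * log(2 * pi))
  expect_equal(cell_loglik(c(1, 1), 1, 1), -log(2 * pi))
  y <- c(0.3, -1.2, 2.1)
  oracle <- sum(vapply(y, function(yi)
    log(1 / sqrt(2 * pi * 2.0) * exp(-(yi - 0.5)^2 / (2 * 2.0))), numeric(1)))
  expect_equal(cell_loglik(y, 0.5, 2.0), oracle, tolerance = 1e-12)
})

test_that("cell_loglik rejects invalid inputs", {
  expect_error(cell_loglik(numeric(0), 0, 1), "at least one")
  expect_error(cell_loglik(1, 0, 0), "positive")
  expect_error(cell_loglik(1, 0, -1), "positive")
  expect_error(cell_loglik(c(1, NA), 0, 1), "finite")
})

test_that("penalized complete-data log-likelihood matches hand expansion", {
  d <- cell_dataset(c("g1", "g2"), list(c(0.1, -0.2), c(2.0, 1.8, 2.2)))
  pp <- mixture_params(c(0, 2), c(1, 0.5), c(0.3, 0.7))
  s <- rbind(c(1, 0), c(0, 1))
  hand <- log(0.3) + cell_loglik(c(0.1, -0.2), 0, 1) +
    log(0.7) + cell_loglik(c(2.0, 1.8, 2.2), 2, 0.5) +
    log(0.3) + log(0.7)
  expect_equal(penalized_complete_loglik(d, pp, s), hand, tolerance = 1e-12)
})

test_that("K = 1 collapses both objectives to the plain log-likelihood", {
  set.seed(42)
  d <- rand_cell_data(4)
  pp <- mixture_params(0.3, 1.2, 1)
  plain <- sum(vapply(d$y, cell_loglik, numeric(1), mu = 0.3, sigma2 = 1.2))
  expect_equal(penalized_complete_loglik(d, pp, matrix(1, 4, 1)), plain)
  expect_equal(marginal_penalized_loglik(d, pp), plain)
})

test_that("imbalanced mixing proportions lower the penalized value on symmetric data", {
  d <- cell_dataset(c("lo", "hi"), list(c(-1, -1.2), c(1, 1.2)))
  s <- rbind(c(1, 0), c(0, 1))
  bal <- penalized_complete_loglik(d, mixture_params(c(-1.1, 1.1), c(1, 1), c(.5, .5)), s)
  imb <- penalized_complete_loglik(d, mixture_params(c(-1.1, 1.1), c(1, 1), c(.25, .75)), s)
  expect_lt(imb, bal)
})

test_that("a zero mixing proportion evaluates to -Inf, not an error", {
  d <- cell_dataset(c("a", "b"), list(0, 1))
  pp <- mixture_params(c(0, 1), c(1, 1), c(0, 1))
  expect_identical(penalized_complete_loglik(d, pp, rbind(c(0, 1), c(0, 1))),
                   -Inf)
  expect_identical(marginal_penalized_loglik(d, pp), -Inf)
})

test_that("marginal penalized log-likelihood matches a linear-space oracle", {
  set.seed(7)
  for (rep in 1:5) {
    d <- rand_cell_data(3, nmin = 1, nmax = 4)
    pp <- mixture_params(rnorm(2), runif(2, 0.5, 2), c(0.4, 0.6))
    expect_equal(marginal_penalized_loglik(d, pp), lin_marginal(d, pp),
                 tolerance = 1e-10)
  }
})

test_that("identical components collapse to the one-component value plus K log(1/K)", {
  set.seed(11)
  d <- rand_cell_data(5)
  one <- mixture_params(0.2, 1.1, 1)
  for (K in 2:4) {
    many <- mixture_params(rep(0.2, K), rep(1.1, K), rep(1 / K, K))
    expect_equal(marginal_penalized_loglik(d, many),
                 marginal_penalized_loglik(d, one) + K * log(1 / K),
                 tolerance = 1e-10)
  }
})

test_that("marginalization dominates any hard assignment at the same parameters", {
  set.seed(13)
  for (rep in 1:10) {
    d <- rand_cell_data(4)
    pp <- mixture_params(rnorm(3), runif(3, 0.3, 2), c(0.2, 0.3, 0.5))
    s <- diag(3)[sample(1:3, 4, replace = TRUE), ]
    expect_gte(marginal_penalized_loglik(d, pp),
               penalized_complete_loglik(d, pp, s))
  }
})

test_that("the marginal objective is invariant under component relabeling", {
  set.seed(17)
  d <- rand_cell_data(4)
  mu <- c(-1, 0.5, 2); s2 <- c(1, 2, 0.5); p <- c(0.2, 0.5, 0.3)
  ref <- marginal_penalized_loglik(d, mixture_params(mu, s2, p))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_identical(
      marginal_penalized_loglik(d, mixture_params(mu[perm], s2[perm], p[perm])),
      ref)
  }
})

test_that("mixture_params enforces its invariants and canonical order", {
  pp <- mixture_params(c(2, 0), c(1, 4), c(0.3, 0.7))
  expect_equal(pp$mu, c(0, 2))
  expect_equal(pp$p, c(0.7, 0.3))
  tie <- mixture_params(c(1, 1), c(5, 2), c(0.5, 0.5))
  expect_equal(tie$sigma2, c(2, 5))
  expect_error(mixture_params(0, 0, 1), "positive")
  expect_error(mixture_params(c(0, 1), c(1, 1), c(0.6, 0.6)), "sum to 1")
  expect_error(mixture_params(c(0, 1), c(1, 1), c(-0.1, 1.1)), "negative")
})

test_that("cell_dataset validates its invariants", {
  expect_error(cell_dataset(c("a", "a"), list(1, 2)), "unique")
  expect_error(cell_dataset("a", list(numeric(0))), "at least one phenotype")
  expect_error(cell_dataset("a", list(c(1, Inf))), "finite")
  d <- cell_dataset(c("a", "b"), list(c(1, 2), 3))
  expect_equal(d$total_n, 3L)
  expect_equal(d$n, c(2L, 1L))
})
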