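# em_fitter: E-step, M-step, hard assignment, multi-start fitting

test_that("e_step reduces to symmetry and closed forms in degenerate cases", {
  set.seed(1)
  d <- rand_cell_data(4)
  ident <- mixture_params(c(0, 0), c(1, 1), c(0.5, 0.5))
  expect_true(all(abs(e_step(d, ident) - 0.5) < 1e-12))
  one <- mixture_params(0, 1, 1)
  expect_true(all(e_step(d, one) == 1))
  # proportional to p when components coincide
  skew <- mixture_params(c(0, 0), c(1, 1), c(0.25, 0.75))
  expect_true(all(abs(e_step(d, skew)[, 1] - 0.25) < 1e-12))
})

test_that("e_step matches a linear-space hand computation", {
  d <- cell_dataset(c("g1", "g2"), list(0.2, 1.5))
  pp <- mixture_params(c(0, 2), c(1, 1), c(0.4, 0.6))
  s <- e_step(d, pp)
  expect_equal(unname(s), lin_estep(d, pp), tolerance = 1e-12)
  expect_equal(rowSums(s), c(g1 = 1, g2 = 1), tolerance = 1e-12)
})

test_that("hard_assign takes the row argmax with ties to the lower index", {
  s <- rbind(a = c(0.9, 0.1), b = c(0.5, 0.5), c = c(0.2, 0.8))
  expect_identical(hard_assign(s), c(a = 1L, b = 1L, c = 2L))
  s3 <- rbind(g1 = c(0.2, 0.8), g2 = c(0.6, 0.4), g3 = c(0.5, 0.5))
  expect_identical(unname(hard_assign(s3)), c(2L, 1L, 1L))
})

test_that("m_step reproduces closed-form updates", {
  d <- cell_dataset(c("lo", "hi"), list(c(1, 3), c(10, 14)))
  onehot <- rbind(c(1, 0), c(0, 1))
  pp <- m_step(d, onehot)
  expect_equal(pp$mu, c(2, 12))
  expect_equal(pp$sigma2, c(1, 4))        # within-cell biased (ML) variances
  expect_equal(pp$p, c(0.5, 0.5))         # (1 + 1)/(2 + 2)
  # all-equal responsibilities put every mean at the grand mean
  eq <- matrix(0.5, 2, 2)
  pe <- m_step(d, eq)
  expect_equal(pe$mu, rep(7, 2))
  expect_equal(pe$p, c(0.5, 0.5))
})

test_that("m_step matches an explicit weighted-sum oracle with fractional weights", {
  d <- cell_dataset(c("a", "b", "c"), list(c(0, 1), c(2, 3, 4), 6))
  s <- rbind(c(0.8, 0.2), c(0.5, 0.5), c(0.1, 0.9))
  st <- cell_stats(d)
  mu_o <- s2_o <- numeric(2)
  for (k in 1:2) {
    num <- den <- 0
    for (g in 1:3) {
      num <- num + s[g, k] * sum(d$y[[g]])
      den <- den + s[g, k] * length(d$y[[g]])
    }
    mu_o[k] <- num / den
    v <- 0
    for (g in 1:3) v <- v + s[g, k] * sum((d$y[[g]] - mu_o[k])^2)
    s2_o[k] <- v / den
  }
  p_o <- (1 + colSums(s)) / (2 + 3)
  pp <- m_step(d, s)
  ord <- order(mu_o)
  expect_equal(pp$mu, mu_o[ord], tolerance = 1e-12)
  expect_equal(pp$sigma2, s2_o[ord], tolerance = 1e-12)
  expect_equal(pp$p, p_o[ord], tolerance = 1e-12)
})

test_that("an empty component keeps its previous parameters but earns penalty weight", {
  d <- cell_dataset(c("a", "b"), list(c(0, 1), c(0.5, 1.5)))
  s <- rbind(c(1, 0), c(1, 0))
  prev <- mixture_params(c(0, 5), c(1, 2), c(0.5, 0.5))
  pp <- m_step(d, s, prev = prev)
  expect_equal(pp$mu[2], 5)
  expect_equal(pp$sigma2[2], 2)
  expect_equal(pp$p[2], 1 / (2 + 2))   # (1 + 0)/(K + G)
  expect_error(m_step(d, s), "no previous parameters")
})

test_that("fit_mixture with K = 1 reproduces the closed form in one pass", {
  set.seed(5)
  d <- rand_cell_data(6, nmin = 3, nmax = 9, mean = 2, sd = 1.5)
  f <- fit_mixture(d, 1)
  y <- unlist(d$y)
  expect_equal(f$params$mu, mean(y), tolerance = 1e-10)
  expect_equal(f$params$sigma2, mean((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(f$params$p, 1)
  expect_equal(f$objective, marginal_penalized_loglik(d, f$params),
               tolerance = 1e-10)
})

test_that("fit_mixture recovers two well-separated cell groups", {
  set.seed(9)
  d <- split_cell_data(G1 = 3, G2 = 4, n_per = 25, delta = 10)
  f <- fit_mixture(d, 2, seed = 1)
  expect_identical(unname(f$assignment), c(rep(1L, 3), rep(2L, 4)))
  expect_lt(abs(f$params$mu[1] - 0), 3 / sqrt(75))   # 3 standard errors
  expect_lt(abs(f$params$mu[2] - 10), 3 / sqrt(100))
  expect_true(f$converged)
})

test_that("fit_mixture validates K", {
  d <- cell_dataset(c("a", "b"), list(1:3 / 2, 4:6 / 2))
  expect_error(fit_mixture(d, 0), "positive integer")
  expect_error(fit_mixture(d, 3), "cannot exceed")
})

test_that("the EM objective never decreases across iterations", {
  set.seed(21)
  for (rep in 1:100) {
    d <- rand_cell_data(sample(3:7, 1), nmin = 1, nmax = 6)
    K <- sample(1:3, 1)
    K <- min(K, length(d$labels))
    f <- fit_mixture(d, K, em_control(n_starts = 3, max_iter = 200))
    expect_lte(f$worst_drop, 1e-8)
  }
})

test_that("mixing proportions sum to one after every M-step", {
  set.seed(23)
  for (rep in 1:20) {
    d <- rand_cell_data(5)
    s <- matrix(runif(10), 5, 2)
    s <- s / rowSums(s)
    expect_equal(sum(m_step(d, s)$p), 1, tolerance = 1e-12)
    f <- fit_mixture(d, 2, em_control(n_starts = 2))
    expect_equal(sum(f$params$p), 1, tolerance = 1e-10)
  }
})

test_that("responsibilities returned by fit_mixture agree with one E-step at the fit", {
  set.seed(25)
  d <- split_cell_data(2, 3, n_per = 10, delta = 4)
  f <- fit_mixture(d, 2, seed = 3)
  expect_equal(f$responsibilities, e_step(d, f$params), tolerance = 1e-9)
  expect_equal(f$objective, marginal_penalized_loglik(d, f$params),
               tolerance = 1e-9)
})

test_that("fitting is deterministic for a fixed seed", {
  set.seed(31)
  d <- rand_cell_data(6)
  f1 <- fit_mixture(d, 3, seed = 11)
  f2 <- fit_mixture(d, 3, seed = 11)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective, f2$objective)
})

test_that("the penalty drives the K = 2 proportions to one half on flat data", {
  # every cell identical => the likelihood is flat in p and the penalty's
  # fixed point p = 1/K is reached exactly
  d <- cell_dataset(paste0("c", 1:9), rep(list(c(-1, 0, 0.5, 1, 2)), 9))
  f <- fit_mixture(d, 2, seed = 1)
  # the proportion fixed point is approached geometrically; the objective
  # stopping rule leaves a sub-1e-3 gap
  expect_equal(f$params$p, c(0.5, 0.5), tolerance = 0.01)
})
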