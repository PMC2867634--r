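#' Parameters of a K-component normal mixture
#'
#' Container for the component means, variances and mixing proportions of a
#' K-component phenotype mixture. Components are stored in canonical order
#' (ascending mean, ties broken by ascending variance) so that fits are
#' comparable across runs and against a generating truth.
#'
#' @param mu numeric vector of component means.
#' @param sigma2 numeric vector of component variances (all positive).
#' @param p numeric vector of mixing proportions; must sum to 1 (tolerance
#'   1e-10). Zeros are tolerated for likelihood evaluation, although any
#'   penalized fit has every p strictly positive.
#' @return an object of class `mixture_params` with elements `K`, `mu`,
#'   `sigma2`, `p`.
#' @examples
#' mixture_params(mu = c(0, 2), sigma2 = c(1, 1), p = c(0.4, 0.6))
#' @export
mixture_params <- function(mu, sigma2, p) {
  mu <- as.numeric(mu); sigma2 <- as.numeric(sigma2); p <- as.numeric(p)
  K <- length(mu)
  if (K < 1L) stop("a mixture needs at least one component")
  if (length(sigma2) != K || length(p) != K)
    stop("'mu', 'sigma2' and 'p' must have the same length")
  if (!all(is.finite(mu)) || !all(is.finite(sigma2)) || !all(is.finite(p)))
    stop("mixture parameters must be finite")
  if (any(sigma2 <= 0)) stop("all component variances must be positive")
  if (any(p < 0)) stop("mixing proportions cannot be negative")
  if (abs(sum(p) - 1) > 1e-10)
    stop("mixing proportions must sum to 1 (tolerance 1e-10)")
  ord <- order(mu, sigma2)
  structure(list(K = K, mu = mu[ord], sigma2 = sigma2[ord], p = p[ord]),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("mixture_params with", x$K, "component(s):\n")
  for (k in seq_len(x$K))
    cat(sprintf("  %d: N(%.4g, %.4g; p = %.4g)\n", k, x$mu[k], x$sigma2[k],
                x$p[k]))
  invisible(x)
}

#' Normal log-likelihood of one genotype cell
#'
#' Sum of normal log-densities of the phenotype values in one cell under a
#' single mixture component.
#'
#' @param y numeric vector of phenotype values (nonempty, finite).
#' @param mu component mean.
#' @param sigma2 component variance (positive).
#' @return the log-likelihood, a finite scalar for finite inputs.
#' @examples
#' cell_loglik(c(0), 0, 1)  # -log(2*pi)/2
#' @export
cell_loglik <- function(y, mu, sigma2) {
  if (length(y) < 1L) stop("'y' must contain at least one observation")
  if (!all(is.finite(y))) stop("'y' must be finite")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("'sigma2' must be positive")
  sum(dnorm(y, mean = mu, sd = sqrt(sigma2), log = TRUE))
}

# G x K matrix of per-cell component log-likelihoods from sufficient stats
loglik_matrix <- function(st, params) {
  G <- length(st$n)
  K <- params$K
  L <- matrix(0, G, K)
  for (k in seq_len(K)) {
    L[, k] <- -0.5 * st$n * log(2 * pi * params$sigma2[k]) -
      (st$ss + st$n * (st$mean - params$mu[k])^2) / (2 * params$sigma2[k])
  }
  rownames(L) <- st$labels
  L
}

row_logsumexp <- function(A) {
  m <- apply(A, 1L, max)
  m + log(rowSums(exp(A - m)))
}

#' Penalized complete-data log-likelihood
#'
#' Evaluates the penalized complete-data objective
#' \deqn{\sum_g \sum_k s_{gk} [\log p_k + \log \Pr(y_g \mid \mu_k, \sigma^2_k)]
#'   + \sum_k \log p_k}
#' at a given cell-to-component assignment. With a one-hot `s` this is the
#' classified (hard-assignment) penalized log-likelihood; fractional weights
#' are accepted. A zero mixing proportion yields `-Inf`, not an error (the
#' penalty makes p = 0 impossible at any maximum).
#'
#' @param data a [cell_dataset].
#' @param params a [mixture_params]; columns of `s` must follow its component
#'   order.
#' @param s G x K matrix of assignment weights with rows summing to 1.
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
penalized_complete_loglik <- function(data, params, s) {
  st <- cell_stats(data)
  s <- as.matrix(s)
  if (nrow(s) != length(st$n) || ncol(s) != params$K)
    stop("'s' must be a G x K matrix matching data and params")
  if (any(abs(rowSums(s) - 1) > 1e-10))
    stop("rows of 's' must sum to 1")
  L <- loglik_matrix(st, params)
  A <- sweep(L, 2L, log(params$p), "+")
  terms <- ifelse(s > 0, s * A, 0)       # 0 * -Inf counts as 0
  sum(terms) + sum(log(params$p))
}

#' Penalized marginal log-likelihood
#'
#' The model-selection objective of the penalized mixture:
#' \deqn{pl_M(K) = \sum_g \log \sum_k p_k \Pr(y_g \mid \mu_k, \sigma^2_k)
#'   + \sum_k \log p_k,}
#' computed entirely in log space (a cell's joint density over its n_g
#' observations underflows in linear space already for a few dozen samples).
#'
#' @inheritParams penalized_complete_loglik
#' @return scalar log-likelihood (possibly `-Inf` when some p is 0).
#' @export
marginal_penalized_loglik <- function(data, params) {
  st <- cell_stats(data)
  L <- loglik_matrix(st, params)
  A <- sweep(L, 2L, log(params$p), "+")
  sum(row_logsumexp(A)) + sum(log(params$p))
}
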