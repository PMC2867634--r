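#' EM fitting controls
#'
#' Settings for the multi-start EM fitter. The defaults are tuned to the
#' scale of this problem: the number of genotype cells G is small (a few
#' dozen at most), so EM restarts are cheap and generous iteration limits
#' cost nothing.
#'
#' @param n_starts number of initializations. The first start cuts the
#'   cell-mean ranking at equal-frequency quantiles; the remaining starts cut
#'   it at uniformly random positions (every start yields nonempty
#'   components).
#' @param max_iter maximum EM iterations per start.
#' @param rel_tol relative change of the penalized marginal log-likelihood at
#'   which a start is declared converged.
#' @return list of class `em_control`.
#' @export
em_control <- function(n_starts = 10L, max_iter = 500L, rel_tol = 1e-8) {
  stopifnot(n_starts >= 1L, max_iter >= 1L, rel_tol > 0)
  structure(list(n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol),
            class = "em_control")
}

#' E-step: posterior cell-to-component responsibilities
#'
#' Computes the G x K matrix of responsibilities
#' \eqn{s_{gk} \propto p_k \Pr(y_g \mid \mu_k, \sigma^2_k)}, row-normalized,
#' via log-sum-exp.
#'
#' @param data a [cell_dataset].
#' @param params a [mixture_params].
#' @return G x K numeric matrix with rows summing to 1, rownames = cell
#'   labels.
#' @export
e_step <- function(data, params) {
  st <- cell_stats(data)
  L <- loglik_matrix(st, params)
  A <- sweep(L, 2L, log(params$p), "+")
  s <- exp(A - row_logsumexp(A))
  rownames(s) <- st$labels
  s
}

#' Hard assignment of cells to components
#'
#' Maps every genotype cell to the component with the largest responsibility;
#' ties break toward the lower (canonical) component index so output is
#' deterministic.
#'
#' @param s G x K responsibility matrix (rows sum to 1).
#' @return named integer vector of component indices, one per cell.
#' @export
hard_assign <- function(s) {
  s <- as.matrix(s)
  setNames(max.col(s, ties.method = "first"), rownames(s))
}

#' M-step: penalized parameter updates
#'
#' Given responsibilities, updates the component means and variances by
#' weighted cell-level sums and the mixing proportions by the penalized rule
#' \eqn{\hat p_k = (1 + \sum_g s_{gk}) / (K + G)}, which sums to one exactly
#' and keeps every component's weight strictly positive. Variances are
#' floored at `sigma2_floor` so singleton cells cannot produce degenerate
#' spikes. A component receiving essentially no weight retains the mean and
#' variance given in `prev`.
#'
#' @param data a [cell_dataset].
#' @param s G x K responsibility matrix.
#' @param prev optional [mixture_params] supplying fallback values for empty
#'   components (column order must match `s`).
#' @param sigma2_floor variance floor; defaults to 1e-8 times the overall
#'   phenotype variance.
#' @return a [mixture_params] (canonically sorted).
#' @export
m_step <- function(data, s, prev = NULL, sigma2_floor = NULL) {
  st <- cell_stats(data)
  s <- as.matrix(s)
  G <- length(st$n)
  K <- ncol(s)
  if (nrow(s) != G) stop("'s' must have one row per genotype cell")
  if (is.null(sigma2_floor)) sigma2_floor <- default_sigma2_floor(st)
  W <- colSums(s)
  D <- colSums(s * st$n)
  p <- (1 + W) / (K + G)
  mu <- numeric(K)
  s2 <- numeric(K)
  for (k in seq_len(K)) {
    if (D[k] > 1e-12) {
      mu[k] <- sum(s[, k] * st$n * st$mean) / D[k]
      s2[k] <- max(
        sum(s[, k] * (st$ss + st$n * (st$mean - mu[k])^2)) / D[k],
        sigma2_floor
      )
    } else {
      if (is.null(prev))
        stop("component ", k,
             " received no weight and no previous parameters were supplied")
      mu[k] <- prev$mu[k]
      s2[k] <- prev$sigma2[k]
    }
  }
  mixture_params(mu, s2, p)
}

#' Fit a K-component penalized mixture to genotype cells
#'
#' Multi-start EM maximization of the penalized marginal log-likelihood. Each
#' start begins from a hard rank-based split of the cells by mean, runs E- and
#' M-steps until the objective stabilizes, and the best start is returned with
#' components in canonical (ascending-mean) order.
#'
#' @param data a [cell_dataset].
#' @param K number of components, between 1 and the number of cells G (more
#'   components than cells is unidentifiable at the cell level).
#' @param control an [em_control].
#' @param seed optional integer seed (set before drawing random starts).
#' @return object of class `mixture_fit`: `params`, `responsibilities`,
#'   `objective` (penalized marginal log-likelihood), `assignment` (hard
#'   cell-to-cluster map), `n_iter`, `converged`, and diagnostics.
#' @examples
#' d <- cell_dataset(c("a", "b", "c", "d"),
#'                   list(rnorm(20), rnorm(20), rnorm(20, 5), rnorm(20, 5)))
#' fit_mixture(d, K = 2, seed = 1)
#' @export
fit_mixture <- function(data, K, control = em_control(), seed = NULL) {
  stopifnot(inherits(data, "cell_dataset"), inherits(control, "em_control"))
  G <- length(data$labels)
  if (!is.numeric(K) || length(K) != 1L || K != round(K) || K < 1)
    stop("'K' must be a single positive integer")
  K <- as.integer(K)
  if (K > G)
    stop("K (", K, ") cannot exceed the number of genotype cells (", G, ")")
  if (!is.null(seed)) set.seed(seed)
  st <- cell_stats(data)
  floor_ <- default_sigma2_floor(st)
  res <- cpp_fit_mixture(st$n, st$mean, st$ss, K, control$n_starts,
                         control$max_iter, control$rel_tol, floor_)
  s <- res$s
  dimnames(s) <- list(data$labels, NULL)
  if (res$worst_drop > 1e-8)
    warning("EM objective decreased by more than 1e-8 relative during fitting")
  structure(
    list(params = mixture_params(res$mu, res$sigma2, res$p),
         responsibilities = s, objective = res$objective,
         assignment = hard_assign(s), K = K, n_iter = res$n_iter,
         converged = res$converged, worst_drop = res$worst_drop,
         sigma2_floor = floor_, control = control),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "penalized mixture fit: K = %d, penalized marginal loglik = %.4f (%s, %d iter)\n",
    x$K, x$objective, if (x$converged) "converged" else "not converged",
    x$n_iter))
  print(x$params)
  cat("hard assignment:\n")
  for (k in seq_len(x$K)) {
    members <- names(x$assignment)[x$assignment == k]
    cat(sprintf("  cluster %d: %s\n", k,
                if (length(members)) paste(members, collapse = ", ")
                else "(empty)"))
  }
  invisible(x)
}
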