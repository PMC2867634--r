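#' Likelihood-ratio statistic for the number of mixture components
#'
#' \eqn{\lambda = -2 [pl_M(K_1) - pl_M(K_2)]}, computed from the best
#' multi-start penalized fits at K1 and K2. Because the penalty
#' \eqn{\sum_k \log p_k} grows more negative with K, \eqn{\lambda} can be
#' negative when the extra component buys nothing; the bootstrap comparison
#' clamps at zero on both sides.
#'
#' @param data a [cell_dataset].
#' @param K1,K2 component counts with 1 <= K1 < K2 <= G.
#' @param control an [em_control].
#' @param seed optional integer seed.
#' @return the statistic (numeric scalar).
#' @export
lrt_statistic <- function(data, K1, K2, control = em_control(), seed = NULL) {
  G <- length(data$labels)
  if (!(K1 >= 1 && K1 < K2)) stop("need 1 <= K1 < K2")
  if (K2 > G) stop("K2 (", K2, ") cannot exceed the number of cells (", G, ")")
  if (!is.null(seed)) set.seed(seed)
  f1 <- fit_mixture(data, K1, control)
  f2 <- fit_mixture(data, K2, control)
  -2 * (f1$objective - f2$objective)
}

boot_p_value <- function(lambda_obs, lambda_star) {
  (1 + sum(pmax(lambda_star, 0) >= max(lambda_obs, 0))) /
    (1 + length(lambda_star))
}

#' Parametric-bootstrap p-value for one LRT step
#'
#' Fits the K1 (null) and K2 (alternative) penalized mixtures, then simulates
#' `n_boot` datasets from the fitted null on the observed cell structure
#' (same G and per-cell sample sizes; cells are drawn into components by the
#' fitted proportions and observations from the assigned component), refits
#' both models on each replicate, and returns the empirical p-value
#' \eqn{(1 + \#\{\lambda^* \ge \lambda\}) / (1 + n_{boot})}.
#'
#' @inheritParams lrt_statistic
#' @param n_boot number of bootstrap replicates (the reference analysis used
#'   5000).
#' @return list of class `lrt_step` with `K1`, `K2`, `lambda`, `n_boot`,
#'   `p_value`.
#' @export
bootstrap_lrt <- function(data, K1, K2 = K1 + 1, n_boot = 5000,
                          control = em_control(), seed = NULL) {
  G <- length(data$labels)
  if (!(K1 >= 1 && K1 < K2)) stop("need 1 <= K1 < K2")
  if (K2 > G) stop("K2 (", K2, ") cannot exceed the number of cells (", G, ")")
  if (n_boot < 1) stop("'n_boot' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  f1 <- fit_mixture(data, K1, control)
  f2 <- fit_mixture(data, K2, control)
  lambda <- -2 * (f1$objective - f2$objective)
  st <- cell_stats(data)
  lambda_star <- cpp_boot_lambda(st$n, f1$params$mu, f1$params$sigma2,
                                 f1$params$p, as.integer(K2),
                                 as.integer(n_boot), control$n_starts,
                                 control$max_iter, control$rel_tol, 1e-8)
  structure(list(K1 = K1, K2 = K2, lambda = lambda, n_boot = n_boot,
                 p_value = boot_p_value(lambda, lambda_star),
                 null_fit = f1, alt_fit = f2),
            class = "lrt_step")
}

#' Sequential model-size selection from step p-values
#'
#' The selection arithmetic of the sequential LRT, separated from the
#' bootstrap machinery: steps (1 vs 2), (2 vs 3), ... are accepted while the
#' running sum of the rejecting steps' p-values stays within the family-wise
#' threshold `alpha`; the procedure stops at the first step that fails. The
#' cumulative p-value — the family-wise type I error of the selection — is
#' the sum of the accepted steps' p-values.
#'
#' @param p_values numeric vector of per-step bootstrap p-values for
#'   (1,2), (2,3), ... in order.
#' @param alpha family-wise threshold in (0,1).
#' @return list with `selected_K`, `cumulative_p` and logical `rejected` per
#'   step.
#' @examples
#' sequential_selection(c(0.008, 0.032, 0.143))  # K = 3, cumulative 0.040
#' @export
sequential_selection <- function(p_values, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, all(p_values >= 0), all(p_values <= 1))
  cum <- 0
  selected <- 1L
  rejected <- logical(length(p_values))
  for (i in seq_along(p_values)) {
    if (cum + p_values[i] <= alpha) {
      cum <- cum + p_values[i]
      selected <- i + 1L
      rejected[i] <- TRUE
    } else break
  }
  list(selected_K = selected, cumulative_p = cum, rejected = rejected)
}

#' Sequential likelihood-ratio test with bootstrap p-values
#'
#' Runs the full sequential procedure on a dataset: tests (1 vs 2), (2 vs 3),
#' ... with parametric-bootstrap p-values, advancing while each step rejects
#' and the cumulative p-value stays within `alpha`, and stopping at the first
#' non-rejecting step (or at `k_max`). The selected model's hard partition of
#' the genotype cells is returned along with the test trail.
#'
#' @param data a [cell_dataset].
#' @param alpha family-wise threshold (default 5\%).
#' @param n_boot bootstrap replicates per step.
#' @param k_max largest number of components to consider (defaults to the
#'   number of cells G).
#' @param control an [em_control].
#' @param seed optional integer seed governing starts and bootstrap draws.
#' @param continue_after_fail if `TRUE`, later steps are still computed after
#'   the first non-rejection, for diagnostics only; the selection is frozen at
#'   the first failure either way.
#' @return object of class `sequential_lrt`: `steps` (data frame with one row
#'   per step: K1, K2, lambda, p_value, decision), `selected_K`,
#'   `cumulative_p`, `alpha`, `params`, `assignment`, `responsibilities`,
#'   `empty_clusters`, and the selected `fit`.
#' @export
sequential_lrt <- function(data, alpha = 0.05, n_boot = 5000, k_max = NULL,
                           control = em_control(), seed = NULL,
                           continue_after_fail = FALSE) {
  stopifnot(inherits(data, "cell_dataset"))
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must lie in (0, 1)")
  if (n_boot < 1) stop("'n_boot' must be a positive integer")
  G <- length(data$labels)
  k_max <- if (is.null(k_max)) G else min(as.integer(k_max), G)
  if (!is.null(seed)) set.seed(seed)
  st <- cell_stats(data)

  fits <- vector("list", max(k_max, 1L))
  get_fit <- function(K) {
    if (is.null(fits[[K]])) fits[[K]] <<- fit_mixture(data, K, control)
    fits[[K]]
  }

  steps <- list()
  cum <- 0
  selected <- 1L
  selecting <- TRUE
  K1 <- 1L
  while (K1 + 1L <= k_max) {
    f1 <- get_fit(K1)
    f2 <- get_fit(K1 + 1L)
    lambda <- -2 * (f1$objective - f2$objective)
    lambda_star <- cpp_boot_lambda(st$n, f1$params$mu, f1$params$sigma2,
                                   f1$params$p, K1 + 1L, as.integer(n_boot),
                                   control$n_starts, control$max_iter,
                                   control$rel_tol, 1e-8)
    p <- boot_p_value(lambda, lambda_star)
    reject <- selecting && (cum + p <= alpha)
    steps[[length(steps) + 1L]] <- data.frame(
      K1 = K1, K2 = K1 + 1L, lambda = lambda, n_boot = n_boot, p_value = p,
      decision = if (reject) "reject" else "accept",
      stringsAsFactors = FALSE
    )
    if (reject) {
      cum <- cum + p
      selected <- K1 + 1L
    } else {
      if (!continue_after_fail) break
      selecting <- FALSE
    }
    K1 <- K1 + 1L
  }

  fit_sel <- get_fit(selected)
  assignment <- fit_sel$assignment
  structure(
    list(steps = if (length(steps)) do.call(rbind, steps) else
           data.frame(K1 = integer(), K2 = integer(), lambda = numeric(),
                      n_boot = integer(), p_value = numeric(),
                      decision = character()),
         selected_K = selected, cumulative_p = cum, alpha = alpha,
         params = fit_sel$params, assignment = assignment,
         responsibilities = fit_sel$responsibilities,
         empty_clusters = setdiff(seq_len(selected), unique(assignment)),
         n_boot = n_boot, seed = seed, fit = fit_sel),
    class = "sequential_lrt"
  )
}

#' @export
print.sequential_lrt <- function(x, ...) {
  cat("sequential penalized-mixture LRT\n")
  if (nrow(x$steps)) {
    print(x$steps, row.names = FALSE)
  } else {
    cat("  (no steps: a single genotype cell admits only one component)\n")
  }
  cat(sprintf("selected K = %d, cumulative p-value = %.4g (alpha = %g)\n",
              x$selected_K, x$cumulative_p, x$alpha))
  print(x$params)
  for (k in seq_len(x$selected_K)) {
    members <- names(x$assignment)[x$assignment == k]
    cat(sprintf("  cluster %d: %s\n", k,
                if (length(members)) paste(members, collapse = ", ")
                else "(empty)"))
  }
  invisible(x)
}

#' Write sequential-test reports
#'
#' Writes `<prefix>_steps.tsv` (one row per LRT step plus a summary row),
#' `<prefix>_partition.tsv` (cluster membership and component parameters per
#' cell) and `<prefix>.json` (the full machine-readable result).
#'
#' @param x a `sequential_lrt` object.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_lrt_report <- function(x, prefix) {
  stopifnot(inherits(x, "sequential_lrt"))
  steps_path <- paste0(prefix, "_steps.tsv")
  part_path <- paste0(prefix, "_partition.tsv")
  json_path <- paste0(prefix, ".json")

  steps <- x$steps
  summary_row <- data.frame(
    K1 = NA_integer_, K2 = x$selected_K, lambda = NA_real_,
    n_boot = x$n_boot, p_value = x$cumulative_p, decision = "selected",
    stringsAsFactors = FALSE
  )
  write.table(rbind(steps, summary_row), steps_path, sep = "\t",
              quote = FALSE, row.names = FALSE)

  k <- x$assignment
  part <- data.frame(
    genotype_cell = names(k), cluster = as.integer(k),
    mu = x$params$mu[k], sigma2 = x$params$sigma2[k], p = x$params$p[k],
    stringsAsFactors = FALSE
  )
  write.table(part, part_path, sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(
    list(selected_K = x$selected_K, cumulative_p = x$cumulative_p,
         alpha = x$alpha, n_boot = x$n_boot, seed = x$seed, steps = x$steps,
         params = list(mu = x$params$mu, sigma2 = x$params$sigma2,
                       p = x$params$p),
         assignment = as.list(x$assignment),
         empty_clusters = x$empty_clusters),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(steps_path, part_path, json_path))
}
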