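#' Canonical block list of a partition
#'
#' Turns an assignment vector (cell label -> block id) into a canonical list
#' of blocks: each block's labels sorted, blocks ordered by their first
#' label. Two assignments describe the same set partition exactly when their
#' canonical block lists are identical.
#'
#' @param assignment named vector mapping cell labels to block ids.
#' @return unnamed list of sorted character vectors.
#' @export
partition_blocks <- function(assignment) {
  blocks <- lapply(split(names(assignment), assignment), sort)
  unname(blocks[order(vapply(blocks, `[`, "", 1L))])
}

#' Exact recovery of the generating partition
#'
#' `TRUE` iff the estimated assignment equals the truth as a set partition of
#' the cells (block labels are ignored; a refinement or coarsening is not
#' recovery). Both assignments must cover the same cell set.
#'
#' @param estimated,truth named vectors mapping cell labels to block ids.
#' @return logical scalar.
#' @examples
#' recovered(c(a = 1, b = 1, c = 2), c(c = 9, a = 3, b = 3))  # TRUE
#' @export
recovered <- function(estimated, truth) {
  if (is.null(names(estimated)) || is.null(names(truth)))
    stop("both partitions must be named by cell label")
  if (!setequal(names(estimated), names(truth)))
    stop("estimated and true partitions cover different cell sets")
  identical(partition_blocks(estimated), partition_blocks(truth))
}

#' Monte Carlo power and recovery of the mixture and RPM methods
#'
#' Replicates an epistasis scenario `n_datasets` times and applies the
#' penalized-mixture sequential LRT and/or the RPM comparator to each
#' dataset, estimating power (proportion of datasets rejecting the
#' one-component/one-group null) and recovery probability (proportion whose
#' final partition of the observed cells exactly equals the generating
#' partition). With `method = "both"` the two methods are applied to the
#' same simulated datasets. Each dataset uses seed `master_seed + i`, so a
#' run is fully reproducible and individual datasets can be replayed.
#'
#' @param model,situation,mu,n,maf scenario, see [simulate_epistasis()].
#' @param n_datasets number of replicate datasets.
#' @param alpha test level applied to both methods (family-wise for the
#'   sequential LRT, merge + permutation level for RPM).
#' @param n_boot bootstrap replicates per LRT step.
#' @param n_perm permutations for the RPM R-squared test.
#' @param method `"mixture"`, `"rpm"` or `"both"`.
#' @param control an [em_control].
#' @param master_seed integer master seed.
#' @return object of class `epistasis_eval`: `power`, `recovery`, `se_power`,
#'   `se_recovery` (named per method), the per-dataset `results` data frame
#'   and the `config`.
#' @export
run_experiment <- function(model, situation, mu, n = 500, n_datasets = 200,
                           alpha = 0.05, n_boot = 499, n_perm = 499,
                           method = c("mixture", "rpm", "both"), maf = 0.5,
                           control = em_control(), master_seed = 1) {
  method <- match.arg(method)
  do_mix <- method %in% c("mixture", "both")
  do_rpm <- method %in% c("rpm", "both")
  rows <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    ds_seed <- master_seed + i
    set.seed(ds_seed)
    sim <- simulate_epistasis(model, mu, situation, n, maf)
    truth <- sim$truth[sim$data$labels]
    row <- data.frame(dataset = i, seed = ds_seed)
    if (do_mix) {
      sq <- sequential_lrt(sim$data, alpha = alpha, n_boot = n_boot,
                           control = control)
      row$mixture_K <- sq$selected_K
      row$mixture_reject <- sq$selected_K > 1L
      row$mixture_recover <- recovered(sq$assignment, truth)
    }
    if (do_rpm) {
      part <- rpm_partition(sim$data, hsd_alpha = alpha)
      tst <- rpm_test(sim$data, part, n_perm = n_perm, hsd_alpha = alpha)
      row$rpm_groups <- part$n_groups
      row$rpm_reject <- tst$p_value <= alpha
      row$rpm_recover <- recovered(part$assignment, truth)
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  rate <- function(col) mean(results[[col]])
  mc_se <- function(p) sqrt(p * (1 - p) / n_datasets)
  methods <- c(if (do_mix) "mixture", if (do_rpm) "rpm")
  power <- setNames(vapply(paste0(methods, "_reject"), rate, numeric(1)),
                    methods)
  recovery <- setNames(vapply(paste0(methods, "_recover"), rate, numeric(1)),
                       methods)
  structure(
    list(power = power, recovery = recovery,
         se_power = vapply(power, mc_se, numeric(1)),
         se_recovery = vapply(recovery, mc_se, numeric(1)),
         n_datasets = n_datasets, results = results,
         config = list(model = model, situation = situation, mu = mu, n = n,
                       n_datasets = n_datasets, alpha = alpha,
                       n_boot = n_boot, n_perm = n_perm, method = method,
                       maf = maf, master_seed = master_seed)),
    class = "epistasis_eval"
  )
}

#' @export
print.epistasis_eval <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "epistasis evaluation: %s model, %s variance, mu = %g, n = %d, %d datasets, alpha = %g\n",
    cfg$model, cfg$situation, cfg$mu, cfg$n, cfg$n_datasets, cfg$alpha))
  for (m in names(x$power)) {
    cat(sprintf("  %-8s power = %5.1f%% (MC SE %.1f), recovery = %5.1f%% (MC SE %.1f)\n",
                m, 100 * x$power[[m]], 100 * x$se_power[[m]],
                100 * x$recovery[[m]], 100 * x$se_recovery[[m]]))
  }
  invisible(x)
}

#' Write an evaluation result as TSV and JSON
#'
#' @param x an `epistasis_eval`.
#' @param prefix output path prefix; writes `<prefix>.tsv` (per-dataset rows)
#'   and `<prefix>.json` (summary + config).
#' @return character vector of files written, invisibly.
#' @export
write_eval_report <- function(x, prefix) {
  stopifnot(inherits(x, "epistasis_eval"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  write.table(x$results, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(power = as.list(x$power), recovery = as.list(x$recovery),
         se_power = as.list(x$se_power), se_recovery = as.list(x$se_recovery),
         config = x$config),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
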