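#' Restricted Partition Method: merge genotype cells by Tukey's HSD
#'
#' Comparator method: genotype cells are ranked by phenotype mean and
#' adjacent groups are merged while they are not significantly different by a
#' Tukey HSD test, using the studentized-range critical value with pooled
#' within-group variance and the Tukey-Kramer adaptation for unbalanced group
#' sizes. At each iteration the adjacent pair with the smallest standardized
#' mean difference is examined; if it fails to reach `hsd_alpha` it is merged
#' and the procedure repeats, otherwise merging stops (all wider pairs are at
#' least as significant).
#'
#' @param data a [cell_dataset] with more samples than cells (within-group
#'   variance must be estimable).
#' @param hsd_alpha significance level of the HSD merge test.
#' @return object of class `rpm_partition`: `groups` (list of cell-label
#'   vectors in ascending mean order), `assignment` (named group index per
#'   cell), `trail` (merge history), `n_groups`, `hsd_alpha`.
#' @export
rpm_partition <- function(data, hsd_alpha = 0.05) {
  stopifnot(inherits(data, "cell_dataset"))
  if (!(hsd_alpha > 0 && hsd_alpha < 1)) stop("'hsd_alpha' must lie in (0,1)")
  st <- cell_stats(data)
  G <- length(st$n)
  if (data$total_n <= G)
    stop("RPM needs more samples than genotype cells to estimate variance")
  ord <- order(st$mean)
  res <- rpm_partition_stats(st$n[ord], st$mean[ord], st$ss[ord], hsd_alpha)
  grp <- res$grp
  labels_ord <- st$labels[ord]
  groups <- unname(split(labels_ord, grp))
  assignment <- setNames(integer(G), labels_ord)
  assignment[labels_ord] <- grp
  structure(
    list(groups = groups, assignment = assignment[st$labels],
         trail = res$trail, n_groups = max(grp), hsd_alpha = hsd_alpha),
    class = "rpm_partition"
  )
}

# core merge loop on mean-ordered per-cell statistics; returns the group id
# of each (ordered) cell plus the merge trail
rpm_partition_stats <- function(n, m, ss, hsd_alpha) {
  G <- length(n)
  N <- sum(n)
  grp <- seq_len(G)
  trail <- list()
  repeat {
    J <- grp[G]
    if (J == 1L) break
    gn <- as.vector(rowsum(n, grp))
    gsum <- as.vector(rowsum(n * m, grp))
    gmean <- gsum / gn
    gss <- as.vector(rowsum(ss + n * (m - gmean[grp])^2, grp))
    df <- N - J
    mse <- sum(gss) / df
    delta <- diff(gmean)
    if (mse > 0) {
      q <- delta / sqrt(mse / 2 * (1 / gn[-J] + 1 / gn[-1]))
    } else {
      q <- ifelse(delta > 0, Inf, 0)
    }
    jm <- which.min(q)
    p <- if (is.infinite(q[jm])) 0
         else if (q[jm] <= 0) 1
         else ptukey(q[jm], nmeans = J, df = df, lower.tail = FALSE)
    if (p > hsd_alpha) {
      trail[[length(trail) + 1L]] <- data.frame(
        n_groups_before = J, merged_pair = jm, q = q[jm], p_value = p)
      grp[grp > jm] <- grp[grp > jm] - 1L
    } else break
  }
  list(grp = grp,
       trail = if (length(trail)) do.call(rbind, trail) else
         data.frame(n_groups_before = integer(), merged_pair = integer(),
                    q = numeric(), p_value = numeric()))
}

#' @export
print.rpm_partition <- function(x, ...) {
  cat("RPM partition:", x$n_groups, "group(s) at HSD alpha =", x$hsd_alpha,
      "\n")
  for (j in seq_along(x$groups))
    cat(sprintf("  group %d: %s\n", j, paste(x$groups[[j]], collapse = ", ")))
  invisible(x)
}

#' Permutation R-squared test of an RPM grouping
#'
#' Tests the final RPM grouping with the coefficient of determination of the
#' phenotype on the grouping (between-group over total sum of squares). The
#' null distribution is built by permuting phenotype values across all
#' samples and re-running the entire RPM merge pipeline on each permutation,
#' so the test accounts for the grouping having been chosen from the data.
#' A single-group partition has r2 = 0 and p = 1 by construction (every
#' permuted r2 is at least 0), so no permutations are drawn in that case.
#'
#' @param data a [cell_dataset].
#' @param partition an `rpm_partition` of `data`; computed from `data` when
#'   omitted.
#' @param n_perm number of permutations.
#' @param hsd_alpha merge level used when re-running the pipeline on each
#'   permutation (and for `partition` when it is computed here).
#' @param seed optional integer seed.
#' @return object of class `rpm_result`: `partition`, `r2`, `p_value`,
#'   `n_perm`.
#' @export
rpm_test <- function(data, partition = NULL, n_perm = 1000, hsd_alpha = 0.05,
                     seed = NULL) {
  stopifnot(inherits(data, "cell_dataset"))
  if (n_perm < 1) stop("'n_perm' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(partition)) partition <- rpm_partition(data, hsd_alpha)
  st <- cell_stats(data)
  N <- data$total_n
  gm <- sum(st$n * st$mean) / N
  sst <- sum(st$ss) + sum(st$n * (st$mean - gm)^2)

  grp_of_cell <- partition$assignment[st$labels]
  gn <- as.vector(rowsum(st$n, grp_of_cell))
  gsum <- as.vector(rowsum(st$n * st$mean, grp_of_cell))
  r2 <- if (sst > 0) sum(gn * (gsum / gn - gm)^2) / sst else 0

  if (r2 <= 0) {
    p <- 1
  } else {
    y_all <- unlist(data$y, use.names = FALSE)
    cell_idx <- rep(seq_along(st$n), st$n)
    r2_star <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample(cell_idx)
      sums <- as.vector(rowsum(y_all, idx))
      sqs <- as.vector(rowsum(y_all^2, idx))
      mb <- sums / st$n
      ssb <- pmax(sqs - st$n * mb^2, 0)
      o <- order(mb)
      res <- rpm_partition_stats(st$n[o], mb[o], ssb[o], hsd_alpha)
      pn <- as.vector(rowsum(st$n[o], res$grp))
      psum <- as.vector(rowsum(st$n[o] * mb[o], res$grp))
      r2_star[b] <- sum(pn * (psum / pn - gm)^2) / sst
    }
    p <- (1 + sum(r2_star >= r2)) / (1 + n_perm)
  }
  structure(list(partition = partition, r2 = r2, p_value = p, n_perm = n_perm,
                 hsd_alpha = hsd_alpha),
            class = "rpm_result")
}

#' @export
print.rpm_result <- function(x, ...) {
  cat(sprintf("RPM test: %d group(s), R^2 = %.4f, permutation p = %.4g (%d permutations)\n",
              x$partition$n_groups, x$r2, x$p_value, x$n_perm))
  invisible(x)
}

#' Write RPM reports
#'
#' Same report shape as [write_lrt_report()] for side-by-side comparison:
#' `<prefix>_groups.tsv` (group membership per cell plus a summary row) and
#' `<prefix>.json`.
#'
#' @param x an `rpm_result`.
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_rpm_report <- function(x, prefix) {
  stopifnot(inherits(x, "rpm_result"))
  groups_path <- paste0(prefix, "_groups.tsv")
  json_path <- paste0(prefix, ".json")
  a <- x$partition$assignment
  df <- data.frame(genotype_cell = names(a), group = as.integer(a),
                   stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(genotype_cell = sprintf(
    "summary: %d groups, r2 = %.6g, p = %.6g", x$partition$n_groups, x$r2,
    x$p_value), group = NA_integer_))
  write.table(df, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_groups = x$partition$n_groups, r2 = x$r2, p_value = x$p_value,
         n_perm = x$n_perm, hsd_alpha = x$hsd_alpha,
         groups = x$partition$groups,
         assignment = as.list(x$partition$assignment)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(groups_path, json_path))
}
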