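two_locus_labels <- function() {
  a <- c("AA", "Aa", "aa")
  b <- c("BB", "Bb", "bb")
  as.vector(outer(a, b, paste0))  # AABB, AaBB, aaBB, AABb, ...
}

#' Generating partition of the nine two-locus genotype cells
#'
#' The block structure of the two purely epistatic architectures. In the
#' checkerboard model the four cells heterozygous at exactly one locus form
#' the baseline block and the remaining five cells the elevated block. In the
#' diagonal model the six off-diagonal cells are baseline, the double
#' heterozygote forms its own block (its mean offset is half the diagonal
#' offset), and the two diagonal homozygote cells the third block.
#'
#' @param model `"checkerboard"` or `"diagonal"`.
#' @return named integer vector over the nine cell labels (`"AABB"` style);
#'   block ids are 1 = baseline, then ascending mean.
#' @export
true_partition <- function(model = c("checkerboard", "diagonal")) {
  model <- match.arg(model)
  labels <- two_locus_labels()
  het_a <- grepl("Aa", labels)
  het_b <- grepl("Bb", labels)
  if (model == "checkerboard") {
    block <- ifelse(xor(het_a, het_b), 1L, 2L)
  } else {
    diag_hom <- labels %in% c("AABB", "aabb")
    double_het <- labels == "AaBb"
    block <- ifelse(diag_hom, 3L, ifelse(double_het, 2L, 1L))
  }
  setNames(block, labels)
}

#' Moment-matched gamma parameters
#'
#' Shape and scale of the gamma distribution with a given mean and variance:
#' shape = mean^2 / variance, scale = variance / mean.
#'
#' @param mean,variance positive reals.
#' @return list with `shape` and `scale`.
#' @examples
#' gamma_params(1, 1)  # exponential: shape 1, scale 1
#' @export
gamma_params <- function(mean, variance) {
  if (!is.finite(mean) || mean <= 0) stop("'mean' must be positive")
  if (!is.finite(variance) || variance <= 0) stop("'variance' must be positive")
  list(shape = mean^2 / variance, scale = variance / mean)
}

#' Simulate a two-locus epistatic dataset
#'
#' Draws `n` unrelated individuals: two-locus genotypes from Hardy-Weinberg
#' cell probabilities at the given minor allele frequency (independent loci),
#' then a phenotype from the cell's block distribution. Blocks and means:
#' checkerboard — baseline cells at mean 1, elevated cells at `1 + mu`;
#' diagonal — off-diagonal cells at 1, double heterozygote at `1 + mu/2`,
#' diagonal homozygotes at `1 + mu`. Variance situations: `"equal"` all
#' variances 1; `"unequal"` baseline variance 1, non-baseline variance 4
#' (SD 2); `"gamma"` gamma-distributed phenotypes with the same means and all
#' variances 1. Cells with no sampled individuals are dropped from the
#' dataset (they carry no likelihood); the returned truth always covers all
#' nine cells and recovery scoring restricts it to the observed ones.
#'
#' @param model `"checkerboard"` or `"diagonal"`.
#' @param mu effect size (mean offset of the elevated block), `mu >= 0`.
#' @param situation `"equal"`, `"unequal"` or `"gamma"`.
#' @param n sample size per dataset (the reference simulations used 500).
#' @param maf minor allele frequency at each locus, in (0, 0.5].
#' @param seed optional integer seed.
#' @return list of class `epistasis_sim` with `data` (a [cell_dataset] of the
#'   observed cells), `truth` (named block id per cell, all nine cells) and
#'   `scenario`.
#' @examples
#' sim <- simulate_epistasis("checkerboard", mu = 1, situation = "equal",
#'                           n = 200, seed = 1)
#' sim$data
#' @export
simulate_epistasis <- function(model = c("checkerboard", "diagonal"), mu,
                               situation = c("equal", "unequal", "gamma"),
                               n = 500, maf = 0.5, seed = NULL) {
  model <- match.arg(model)
  situation <- match.arg(situation)
  if (!is.finite(mu) || mu < 0) stop("'mu' must be a nonnegative real")
  if (!(maf > 0 && maf <= 0.5)) stop("'maf' must lie in (0, 0.5]")
  if (n < 1) stop("'n' must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  labels <- two_locus_labels()
  geno_p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)  # AA, Aa, aa
  cell_p <- as.vector(outer(geno_p, geno_p))
  truth <- true_partition(model)

  block_mu <- if (model == "checkerboard") c(1, 1 + mu)
              else c(1, 1 + mu / 2, 1 + mu)
  n_blocks <- length(block_mu)
  block_var <- switch(situation,
    equal = rep(1, n_blocks),
    unequal = c(1, rep(4, n_blocks - 1)),
    gamma = rep(1, n_blocks)
  )

  counts <- as.vector(rmultinom(1, n, cell_p))
  keep <- counts > 0
  y <- vector("list", sum(keep))
  kept_labels <- labels[keep]
  for (i in seq_along(kept_labels)) {
    blk <- truth[[kept_labels[i]]]
    m <- block_mu[blk]
    v <- block_var[blk]
    ni <- counts[keep][i]
    y[[i]] <- if (situation == "gamma") {
      gp <- gamma_params(m, v)
      rgamma(ni, shape = gp$shape, scale = gp$scale)
    } else {
      rnorm(ni, mean = m, sd = sqrt(v))
    }
  }
  structure(
    list(data = cell_dataset(kept_labels, y), truth = truth,
         scenario = list(model = model, mu = mu, situation = situation,
                         n = n, maf = maf, seed = seed)),
    class = "epistasis_sim"
  )
}
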