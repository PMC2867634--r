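#' Phenotype observations grouped into genotype cells
#'
#' A `cell_dataset` is the unit of analysis for genotype-cell clustering: a
#' set of `G` genotype cells (diplotypes, multi-locus genotypes, or any other
#' opaque group label), each carrying the numeric phenotype values of the
#' samples that share that genotype. All clustering and testing in this
#' package happens at the cell level, never at the sample level.
#'
#' @param labels character vector of unique genotype-cell labels.
#' @param phenotypes list of numeric vectors, one per cell, each with at least
#'   one finite phenotype value.
#' @return An object of class `cell_dataset`: a list with elements `labels`,
#'   `y` (list of phenotype vectors), `n` (per-cell sample counts) and
#'   `total_n`.
#' @examples
#' d <- cell_dataset(c("*1/*1", "*1/*4"), list(c(1.2, 0.8), c(3.1, 2.9, 3.3)))
#' d$total_n
#' @export
cell_dataset <- function(labels, phenotypes) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("a cell_dataset needs at least one genotype cell")
  if (anyDuplicated(labels)) stop("genotype cell labels must be unique")
  if (!is.list(phenotypes) || length(phenotypes) != length(labels))
    stop("'phenotypes' must be a list with one numeric vector per label")
  phenotypes <- lapply(phenotypes, as.numeric)
  n <- vapply(phenotypes, length, integer(1))
  if (any(n < 1L)) stop("every genotype cell needs at least one phenotype value")
  if (!all(vapply(phenotypes, function(y) all(is.finite(y)), logical(1))))
    stop("all phenotype values must be finite")
  structure(
    list(labels = labels, y = phenotypes, n = n, total_n = sum(n)),
    class = "cell_dataset"
  )
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat("cell_dataset:", length(x$labels), "genotype cells,", x$total_n,
      "samples\n")
  st <- cell_stats(x)
  df <- data.frame(cell = x$labels, n = st$n, mean = signif(st$mean, 4),
                   sd = signif(sqrt(st$ss / pmax(st$n - 1, 1)), 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cell_dataset <- function(x, ...) {
  data.frame(
    sample_id = paste0("s", seq_len(x$total_n)),
    genotype_cell = rep(x$labels, x$n),
    phenotype = unlist(x$y, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Per-cell sufficient statistics
#'
#' Count, mean and within-cell sum of squares for every genotype cell. The
#' normal cell likelihood depends on the data only through these.
#'
#' @param data a [cell_dataset].
#' @return list with vectors `n`, `mean`, `ss` (within-cell sum of squares
#'   about the cell mean) and `labels`.
#' @export
cell_stats <- function(data) {
  stopifnot(inherits(data, "cell_dataset"))
  m <- vapply(data$y, mean, numeric(1))
  ss <- mapply(function(y, mu) sum((y - mu)^2), data$y, m)
  list(n = as.numeric(data$n), mean = m, ss = as.numeric(ss),
       labels = data$labels)
}

# variance floor for the M-step: a small fraction of the overall (biased)
# phenotype variance, so singleton cells cannot collapse a component
default_sigma2_floor <- function(st, frac = 1e-8) {
  N <- sum(st$n)
  gm <- sum(st$n * st$mean) / N
  v <- (sum(st$ss) + sum(st$n * (st$mean - gm)^2)) / N
  if (v > 0) frac * v else 1e-12
}

#' Read a long-format genotype-cell phenotype table
#'
#' Reads a TSV/CSV file with header columns `sample_id`, `genotype_cell` and
#' `phenotype` and groups samples into a [cell_dataset], preserving the order
#' in which cells first appear. Field separator is inferred from the file
#' extension (`.csv` uses a comma, anything else a tab).
#'
#' @param path path to the input file.
#' @param transform `"none"` or `"log"`; with `"log"` the natural logarithm is
#'   applied to each phenotype at load time (useful for ratio phenotypes such
#'   as metabolite ratios).
#' @return a [cell_dataset].
#' @export
read_cell_dataset <- function(path, transform = c("none", "log")) {
  transform <- match.arg(transform)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   check.names = FALSE, comment.char = "", quote = "\"")
  for (col in c("sample_id", "genotype_cell", "phenotype")) {
    if (!col %in% names(df))
      stop("input file is missing required column '", col, "'")
  }
  ph <- suppressWarnings(as.numeric(df$phenotype))
  bad <- which(!is.finite(ph))
  if (length(bad))
    stop("non-numeric or non-finite phenotype in data row(s): ",
         paste(bad, collapse = ", "))
  if (transform == "log") {
    bad <- which(ph <= 0)
    if (length(bad))
      stop("log transform requires positive phenotypes; offending data row(s): ",
           paste(bad, collapse = ", "))
    ph <- log(ph)
  }
  cells <- unique(df$genotype_cell)
  cell_dataset(cells, lapply(cells, function(cl) ph[df$genotype_cell == cl]))
}

#' Write a cell dataset as a long-format TSV
#'
#' Writes the standard three-column table (`sample_id`, `genotype_cell`,
#' `phenotype`) consumed by [read_cell_dataset()].
#'
#' @param data a [cell_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_dataset <- function(data, path) {
  stopifnot(inherits(data, "cell_dataset"))
  write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
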