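#' Per-site nucleotide diversity from an allele count
#'
#' The unbiased per-site estimator
#' \deqn{\pi = \frac{n}{n-1} \, 2 \hat p (1 - \hat p)
#'       = \frac{2 a (n - a)}{n (n - 1)}}
#' with `n` called chromosomes and `a` alternate chromosomes. This equals
#' the mean pairwise difference over all `C(n, 2)` chromosome pairs, which
#' is what the test suite checks it against.
#'
#' @param alt_count Alternate-allele chromosome count, or an
#'   `allele_count` object (then `total_count` is taken from it).
#' @param total_count Called chromosomes (>= 2).
#' @return Per-site diversity in [0, 1].
#' @examples
#' site_pi(2, 4)   # 4 differing pairs of 6 -> 2/3
#' site_pi(5, 10)  # (10/9) * 0.5
#' @export
site_pi <- function(alt_count, total_count = NULL) {
  if (inherits(alt_count, "allele_count")) {
    total_count <- alt_count$total_count
    alt_count <- alt_count$alt_count
  }
  if (any(total_count < 2)) {
    stop("site_pi is undefined for fewer than 2 called chromosomes")
  }
  if (any(alt_count < 0 | alt_count > total_count)) {
    stop("alt_count must lie in [0, total_count]")
  }
  2 * alt_count * (total_count - alt_count) / (total_count * (total_count - 1))
}

#' Genome-wide nucleotide diversity of one population
#'
#' Sums [site_pi()] over every variant site within the population's samples
#' and divides by the total ungapped genome length, so monomorphic
#' (unrepresented) positions contribute zero implicitly. Sites with any
#' missing genotype in the population are removed from the sum, and no
#' Hardy-Weinberg filtering is applied.
#'
#' @param genotypes Dosage matrix.
#' @param panel Population panel.
#' @param population Population label to summarize.
#' @param ungapped_lengths Named numeric vector or two-column data.frame
#'   (`chrom`, `length`) of ungapped chromosome lengths in bp.
#' @return Object of class `pi_summary`: list with `population`,
#'   `sum_site_pi`, `n_variable_sites`, `ungapped_length`, `genome_pi`.
#' @export
genome_pi <- function(genotypes, panel, population, ungapped_lengths) {
  if (!population %in% panel$population) {
    stop("population not in panel: ", population)
  }
  if (is.data.frame(ungapped_lengths)) {
    ungapped_lengths <- stats::setNames(ungapped_lengths$length,
                                        ungapped_lengths$chrom)
  }
  total_len <- sum(as.numeric(ungapped_lengths))
  if (!isTRUE(total_len > 0)) stop("ungapped length must be positive")
  samples <- panel$sample[panel$population == population]
  g <- genotypes[samples, , drop = FALSE]
  g <- g[, colSums(is.na(g)) == 0L, drop = FALSE]  # drop sites with missing data
  n <- 2L * nrow(g)
  a <- colSums(g)
  variable <- a > 0L & a < n
  s <- if (any(variable)) sum(site_pi(a[variable], n)) else 0
  out <- list(population = population, sum_site_pi = s,
              n_variable_sites = sum(variable), ungapped_length = total_len,
              genome_pi = s / total_len)
  class(out) <- "pi_summary"
  out
}

#' @export
print.pi_summary <- function(x, ...) {
  cat(sprintf("%s: genome-wide pi = %.4g (sum %.4g over %d variable sites / %.4g bp)\n",
              x$population, x$genome_pi, x$sum_site_pi, x$n_variable_sites,
              x$ungapped_length))
  invisible(x)
}

#' Read/write ungapped chromosome length tables
#'
#' Two-column TSV `chrom  length`.
#' @param path File path.
#' @export
read_lengths <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length") %in% names(x)))
  x
}

#' @rdname read_lengths
#' @param lengths data.frame `chrom`, `length`.
#' @export
write_lengths <- function(lengths, path) {
  utils::write.table(lengths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
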