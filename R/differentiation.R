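#' Per-population and pooled-group allele frequencies for a SNP list
#'
#' Tallies alternate-allele counts per population and, for each requested
#' group of populations, pools the counts (group frequency = sum of member
#' alternate counts / sum of member called chromosomes). Pooling by counts
#' rather than averaging population frequencies makes the result identical
#' to tallying a merged callset, and invariant to how a population is split
#' across panels.
#'
#' @param genotypes Dosage matrix.
#' @param panel Population panel.
#' @param snp_keys Variant keys to tabulate (default: all columns).
#'   Unresolvable keys are dropped with a warning and listed in the
#'   `unresolved` attribute.
#' @param groups Named list of population-label vectors to pool (e.g.
#'   `list(EUR = c("REF01", "REF02"))`).
#' @return A long-format data.frame of class `frequency_table` with columns
#'   `key`, `unit` (population or group name), `level`
#'   (`"population"`/`"group"`), `alt_count`, `total_count`, `frequency`.
#' @export
population_frequencies <- function(genotypes, panel, snp_keys = NULL,
                                   groups = NULL) {
  if (is.null(snp_keys)) snp_keys <- colnames(genotypes)
  unresolved <- setdiff(snp_keys, colnames(genotypes))
  if (length(unresolved) > 0L) {
    warning(length(unresolved), " SNP key(s) not in the genotype matrix; dropped")
    snp_keys <- setdiff(snp_keys, unresolved)
  }
  pops <- unique(panel$population)
  per_pop <- lapply(pops, function(p) {
    ac <- allele_counts(genotypes[, snp_keys, drop = FALSE],
                        samples = panel$sample[panel$population == p])
    data.frame(key = ac$key, unit = p, level = "population",
               alt_count = ac$alt_count, total_count = ac$total_count,
               frequency = ac$frequency, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_pop)
  if (!is.null(groups)) {
    if (is.null(names(groups)) || any(names(groups) == "")) {
      stop("groups must be a named list of population vectors")
    }
    per_group <- lapply(names(groups), function(gname) {
      members <- groups[[gname]]
      if (length(members) == 0L) stop("empty group: ", gname)
      if (!all(members %in% pops)) {
        stop("group '", gname, "' names unknown population(s): ",
             paste(setdiff(members, pops), collapse = ", "))
      }
      sub <- tab[tab$unit %in% members, ]
      agg <- stats::aggregate(cbind(alt_count, total_count) ~ key, sub, sum)
      data.frame(key = agg$key, unit = gname, level = "group",
                 alt_count = agg$alt_count, total_count = agg$total_count,
                 frequency = agg$alt_count / agg$total_count,
                 stringsAsFactors = FALSE)
    })
    tab <- rbind(tab, do.call(rbind, per_group))
  }
  rownames(tab) <- NULL
  attr(tab, "unresolved") <- unresolved
  class(tab) <- c("frequency_table", "data.frame")
  tab
}

#' Absolute allele-frequency difference between two units
#'
#' @param freq_table Output of [population_frequencies()].
#' @param focal,comparison Unit names (population labels or group names)
#'   present in the table.
#' @return Named numeric vector of `|f_focal - f_comparison|` per variant.
#'   Variants with zero called chromosomes in either unit are excluded and
#'   listed in the `excluded` attribute.
#' @export
abs_freq_diff <- function(freq_table, focal, comparison) {
  for (u in c(focal, comparison)) {
    if (!u %in% freq_table$unit) stop("unit not in frequency table: ", u)
  }
  f1 <- freq_table[freq_table$unit == focal, ]
  f2 <- freq_table[freq_table$unit == comparison, ]
  keys <- intersect(f1$key, f2$key)
  a <- stats::setNames(f1$frequency, f1$key)[keys]
  ta <- stats::setNames(f1$total_count, f1$key)[keys]
  b <- stats::setNames(f2$frequency, f2$key)[keys]
  tb <- stats::setNames(f2$total_count, f2$key)[keys]
  ok <- ta > 0 & tb > 0
  d <- abs(a - b)[ok]
  attr(d, "excluded") <- keys[!ok]
  d
}

#' Top-tail percentile outlier scan of frequency differences
#'
#' The threshold is the `(100 - top_percentile)`-th percentile of the
#' differences (linear-interpolation quantile); outliers are the variants
#' strictly above it. With `top_percentile = 0.1` this flags the 0.1st
#' percentile top tail.
#'
#' @param diffs Named vector of absolute frequency differences.
#' @param top_percentile Tail size in percent (default 0.1).
#' @return Object of class `diff_scan`: list with `threshold`,
#'   `outliers` (variant keys), `n`, `top_percentile`, and the input
#'   `diffs`.
#' @export
outlier_scan <- function(diffs, top_percentile = 0.1) {
  if (length(diffs) == 0L) stop("empty difference vector")
  stopifnot(top_percentile > 0, top_percentile < 100)
  if (length(diffs) < 1000L) {
    warning("fewer than 1000 values: a ", top_percentile,
            "% tail threshold is poorly determined")
  }
  thr <- unname(stats::quantile(diffs, 1 - top_percentile / 100, type = 7))
  out <- list(threshold = thr,
              outliers = names(diffs)[diffs > thr],
              n = length(diffs), top_percentile = top_percentile,
              diffs = diffs)
  class(out) <- "diff_scan"
  out
}

#' @export
print.diff_scan <- function(x, ...) {
  cat(sprintf(
    "outlier scan: %d of %d variants above the %.4g%% tail threshold (>%.4g)\n",
    length(x$outliers), x$n, x$top_percentile, x$threshold))
  invisible(x)
}

#' Binned histogram of allele frequencies (plain-table density summary)
#'
#' @param freqs Numeric vector of frequencies in [0, 1].
#' @param n_bins Number of equal-width bins (default 50).
#' @return data.frame `bin_mid`, `count`, `density`.
#' @export
frequency_histogram <- function(freqs, n_bins = 50) {
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- graphics::hist(freqs, breaks = breaks, plot = FALSE)
  data.frame(bin_mid = h$mids, count = h$counts, density = h$density)
}
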