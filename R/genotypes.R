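#' Count alternate alleles for one variant over a sample subset
#'
#' Missing genotypes are excluded: they contribute neither to the alternate
#' count nor to the total, so the total counts called chromosomes only.
#' A variant with no called genotype in the subset yields the degenerate
#' count (0, 0) with frequency `NaN` and `degenerate = TRUE`.
#'
#' @param genotypes Dosage matrix (samples x variants).
#' @param variant Variant key (column name) or column index.
#' @param samples Sample ids (row names) or indices; default all samples.
#' @return An object of class `allele_count`: list with `alt_count`,
#'   `total_count`, `frequency`, `degenerate`.
#' @examples
#' m <- matrix(c(0L, 1L, 2L), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), "chr1:100:A:G"))
#' allele_count(m, "chr1:100:A:G")  # 3 of 6 chromosomes, frequency 0.5
#' @export
allele_count <- function(genotypes, variant, samples = NULL) {
  if (is.character(variant) && !variant %in% colnames(genotypes)) {
    stop("variant not in matrix: ", variant)
  }
  if (is.null(samples)) samples <- seq_len(nrow(genotypes))
  if (length(samples) == 0L) stop("sample subset is empty")
  if (is.character(samples)) {
    missing <- setdiff(samples, rownames(genotypes))
    if (length(missing) > 0L) {
      stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
    }
  }
  d <- genotypes[samples, variant]
  called <- !is.na(d)
  ac <- list(alt_count = sum(d[called]),
             total_count = 2L * sum(called),
             frequency = if (any(called)) sum(d[called]) / (2 * sum(called)) else NaN,
             degenerate = !any(called))
  class(ac) <- "allele_count"
  ac
}

#' @export
print.allele_count <- function(x, ...) {
  cat(sprintf("allele count: %d / %d chromosomes (frequency %.4g)%s\n",
              x$alt_count, x$total_count, x$frequency,
              if (x$degenerate) " [degenerate: all genotypes missing]" else ""))
  invisible(x)
}

#' Vectorized allele counts for every variant over a sample subset
#'
#' @inheritParams allele_count
#' @return data.frame with columns `key`, `alt_count`, `total_count`,
#'   `frequency` (`NaN` where no genotype is called).
#' @export
allele_counts <- function(genotypes, samples = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(genotypes))
  if (length(samples) == 0L) stop("sample subset is empty")
  g <- genotypes[samples, , drop = FALSE]
  called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  data.frame(key = colnames(g), alt_count = alt, total_count = 2L * called,
             frequency = alt / (2 * called),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Recode dosages to the 1/2/3 genotype coding
#'
#' The structure pipeline codes genotypes as 1 for homozygous reference,
#' 2 for heterozygous and 3 for homozygous alternate. The coding has no
#' missing state, so the input must be complete: filter variants with any
#' missingness first (see [drop_missing_variants()]).
#'
#' @param genotypes Dosage matrix with no missing entries.
#' @return The matrix with every dosage incremented by one.
#' @export
code_genotypes <- function(genotypes) {
  if (anyNA(genotypes)) {
    stop("missing dosages present; the 1/2/3 coding has no missing state - ",
         "drop incompletely genotyped variants first (drop_missing_variants)")
  }
  genotypes + 1L
}

#' Drop variants with any missing genotype
#'
#' @param genotypes Dosage matrix.
#' @param variants Optional paired variant table, filtered alongside.
#' @return The filtered matrix, or a list `(genotypes, variants)` when a
#'   variant table is supplied.
#' @export
drop_missing_variants <- function(genotypes, variants = NULL) {
  keep <- colSums(is.na(genotypes)) == 0L
  g <- genotypes[, keep, drop = FALSE]
  if (is.null(variants)) return(g)
  list(genotypes = g, variants = variants[keep, , drop = FALSE])
}

#' Restrict a genotype matrix / variant table pair to biallelic autosomes
#'
#' All records handled by this package are biallelic by construction (see
#' [read_vcf()]); this filter additionally restricts to a chromosome
#' whitelist, by default the 22 human autosomes. Chromosome names are
#' compared after dialect normalization unless `normalize = FALSE`, in
#' which case a whitelist that matches no variant while its normalized form
#' would is reported as a dialect mismatch rather than silently returning
#' an empty set.
#'
#' @param genotypes Dosage matrix.
#' @param variants Paired variant table.
#' @param chrom_whitelist Chromosomes to keep; default the 22 autosomes.
#' @param normalize Normalize naming dialects before comparing (default TRUE).
#' @return list `(genotypes, variants)` restricted to the whitelist.
#' @export
filter_biallelic_autosomal <- function(genotypes, variants,
                                       chrom_whitelist = autosome_whitelist(),
                                       normalize = TRUE) {
  stopifnot(ncol(genotypes) == nrow(variants))
  if (normalize) {
    keep <- normalize_chrom(variants$chrom) %in% normalize_chrom(chrom_whitelist)
  } else {
    keep <- variants$chrom %in% chrom_whitelist
    if (!any(keep) &&
        any(normalize_chrom(variants$chrom) %in% normalize_chrom(chrom_whitelist))) {
      stop("chromosome naming dialect mismatch between variants and ",
           "whitelist (e.g. '1' vs 'chr1'); set normalize = TRUE or ",
           "normalize names with normalize_chrom()")
    }
  }
  if (!any(keep)) warning("no variants on whitelisted chromosomes; empty result")
  list(genotypes = genotypes[, keep, drop = FALSE],
       variants = variants[keep, , drop = FALSE])
}
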