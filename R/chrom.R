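#' Normalize chromosome names across naming dialects
#'
#' GRCh37-era resources mix the Ensembl-style (`"1"`, `"X"`, `"MT"`) and
#' UCSC-style (`"chr1"`, `"chrX"`, `"chrM"`) chromosome naming dialects.
#' All comparisons inside this package are performed on normalized names so
#' that callsets from either dialect can be intersected safely.
#'
#' @param chrom Character vector of chromosome names.
#' @param dialect Target dialect: `"chr"` (UCSC-style, default) or `"plain"`
#'   (Ensembl-style).
#' @return Character vector of the same length in the requested dialect.
#' @examples
#' normalize_chrom(c("1", "chr2", "MT", "chrX"))
#' normalize_chrom(c("chr1", "chrM"), dialect = "plain")
#' @export
normalize_chrom <- function(chrom, dialect = c("chr", "plain")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(chrom) | is.factor(chrom))
  x <- as.character(chrom)
  bare <- sub("^chr", "", x)
  # mitochondrial naming differs between the dialects beyond the prefix
  bare[bare %in% c("M", "MT")] <- if (dialect == "chr") "M" else "MT"
  if (dialect == "chr") paste0("chr", bare) else bare
}

#' Default autosome whitelist
#'
#' @param dialect Naming dialect, see [normalize_chrom()].
#' @return Character vector of the 22 human autosome names.
#' @export
autosome_whitelist <- function(dialect = c("chr", "plain")) {
  normalize_chrom(as.character(1:22), dialect = match.arg(dialect))
}

# canonical variant key used to pair genotype columns with variant rows
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
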