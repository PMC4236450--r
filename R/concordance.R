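#' Genotype concordance of a callset against a gold-standard truth set
#'
#' Treats an independent genotyping platform (e.g. a SNP array) as the gold
#' standard and measures the callset against it, in the sense used when WGS
#' SNP calls are benchmarked against arrays:
#'
#' * FDR: among calls made at sites the truth set assayed, the fraction
#'   whose unphased genotype contradicts the truth genotype.
#' * FNR: among truth variants (assayed sites with a non-reference truth
#'   genotype), the fraction not matched by a call with the same genotype.
#'
#' Matching is at genotype level: a call is correct only if site and
#' unphased genotype both agree. Truth rows with genotype 0 represent
#' assayed homozygous-reference sites; they define the assayed universe and
#' can convict a spurious call but are not themselves truth variants.
#' Calls at sites the truth set never assayed are ignored (the platform
#' cannot adjudicate them).
#'
#' @param calls data.frame of genotype calls with columns `sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `genotype` (alt-allele dosage 0/1/2; rows with
#'   genotype 0 are non-calls and are dropped).
#' @param truth data.frame of the same shape; genotype 0 rows mark assayed
#'   reference-homozygous sites.
#' @return Object of class `concordance_report`: list with `n_calls`
#'   (calls at assayed sites), `n_truth` (truth variants), `n_matching`,
#'   `fdr`, `fnr` (`NA` with `degenerate = TRUE` when undefined).
#' @export
concordance <- function(calls, truth) {
  req <- c("sample", "chrom", "pos", "ref", "alt", "genotype")
  stopifnot(all(req %in% names(calls)), all(req %in% names(truth)))
  site_key <- function(x) {
    paste(x$sample, normalize_chrom(as.character(x$chrom)), x$pos, x$ref,
          x$alt, sep = ":")
  }
  calls <- calls[calls$genotype > 0, , drop = FALSE]
  ck <- site_key(calls)
  tk <- site_key(truth)
  if (anyDuplicated(tk)) stop("duplicate (sample, site) rows in truth set")
  truth_gt <- stats::setNames(truth$genotype, tk)

  assayed <- ck %in% tk
  n_calls <- sum(assayed)
  match_ok <- assayed & calls$genotype == truth_gt[ck]
  n_matching <- sum(match_ok)

  is_truth_variant <- truth$genotype > 0
  n_truth <- sum(is_truth_variant)
  matched_truth <- tk[is_truth_variant] %in% ck[match_ok]
  n_missed <- sum(!matched_truth)

  rep <- list(
    n_calls = n_calls, n_truth = n_truth, n_matching = n_matching,
    fdr = if (n_calls > 0) (n_calls - n_matching) / n_calls else NA_real_,
    fnr = if (n_truth > 0) n_missed / n_truth else NA_real_,
    degenerate = n_calls == 0 || n_truth == 0
  )
  class(rep) <- "concordance_report"
  rep
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance: %d assayed calls, %d truth variants, %d matching\n  FDR %s  FNR %s%s\n",
    x$n_calls, x$n_truth, x$n_matching,
    ifelse(is.na(x$fdr), "undefined", sprintf("%.4g%%", 100 * x$fdr)),
    ifelse(is.na(x$fnr), "undefined", sprintf("%.4g%%", 100 * x$fnr)),
    if (x$degenerate) "  [degenerate: no assayed overlap]" else ""))
  invisible(x)
}

#' Read/write genotype tables for concordance checks
#'
#' TSV with header `sample  chrom  pos  ref  alt  genotype`.
#' @param path File path.
#' @export
read_genotype_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(pos = "integer", genotype = "integer"))
}

#' @rdname read_genotype_table
#' @param table Genotype table.
#' @export
write_genotype_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
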