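# small in-code fixtures

write_vcf_text <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN_CLASS,Number=1,Type=String,Description=\"x\">",
    "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

toy_matrix <- function(dosages, samples = NULL, keys = NULL) {
  m <- matrix(as.integer(dosages), nrow = length(dosages) %/%
                ifelse(is.null(keys), 1L, length(keys)))
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(m)))
  if (is.null(keys)) keys <- paste0("chr1:", 100 * seq_len(ncol(m)), ":A:G")
  dimnames(m) <- list(samples, keys)
  m
}

small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_populations = 3, samples_per_population = 16,
                    n_snps = 600, n_gwas_snps = 100, n_planted_outliers = 2,
                    n_rare = 15, n_low_count_private = 5, n_private = 3,
                    n_deletion_loci = 40, seed = seed, ...)
  list(config = cfg, sim = simulate_genotypes(cfg))
}
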