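# Shared configuration for the numbered analysis scripts.
#
# The study design: one focal population of 16 deeply sequenced diploid
# genomes against 14 reference populations of 16 samples each. Every
# script sources this file, builds (or reuses) the same run directory, and
# writes its stage tables under results/run/<stage>/.

library(wgspopgen)

ANALYSIS_SEED <- 1
RUN_DIR <- "results/run"

analysis_config <- function() {
  run_config(
    RUN_DIR, seed = ANALYSIS_SEED,
    sim = sim_config(n_snps = 8000, n_gwas_snps = 2000,
                     n_planted_outliers = 2, n_rare = 60,
                     n_low_count_private = 12, n_private = 6,
                     n_deletion_loci = 200, false_deletion_frac = 0.1,
                     seed = ANALYSIS_SEED),
    n_perm = 999)
}

show_table <- function(stage, file, n = 6) {
  x <- utils::read.delim(file.path(RUN_DIR, stage, file))
  print(utils::head(x, n))
  invisible(x)
}
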