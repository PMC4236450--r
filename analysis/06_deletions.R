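#!/usr/bin/env Rscript
# Stage 6: deletion callset algebra.
#
# Size-filters the per-sample calls to (50 bp, 100 kbp), drops calls that
# failed the external genotyper stand-in, merges the rest into
# non-redundant sites at >= 80% reciprocal overlap, flags novelty against
# the reference catalogue (> 50% reciprocal), counts carrier heterozygous
# SNPs inside each novel site (a real deletion cannot contain any), and
# reports deleted-allele frequencies. With 10% planted false calls the
# zero-het fraction should sit near 90%.

source("analysis/00_setup.R")

run_stage("deletions", analysis_config())
s <- show_table("deletions", "summary.tsv")
cat(sprintf(paste0(
  "\n%d calls merged into %d sites (%d novel).\n",
  "%.1f%% of novel sites contain no carrier het SNP; %.1f%% exactly one.\n",
  "%d singleton sites (frequency %.3f%%); %d sites on multiple chromosomes.\n"),
  s$n_calls, s$n_sites, s$n_novel,
  100 * s$frac_novel_zero_het, 100 * s$frac_novel_one_het,
  s$n_singleton, 100 * deletion_frequency(1, 16), s$n_multi_chromosome))
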