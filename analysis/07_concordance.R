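#!/usr/bin/env Rscript
# Stage 7: genotype concordance against the simulated gold standard.
#
# Benchmarks the degraded callset against the truth genotype table the
# way WGS SNP calls are benchmarked against genotyping arrays: FDR is the
# fraction of assayed calls contradicting the gold-standard genotype, FNR
# the fraction of gold-standard variants not recovered with the right
# genotype. The planted per-site error and drop-out rates are 0.2% each,
# so both rates should come back at a few tenths of a percent.

source("analysis/00_setup.R")

run_stage("concordance", analysis_config())
conc <- show_table("concordance", "concordance.tsv")
cat(sprintf("\nFDR %.3f%%, FNR %.3f%% over %d assayed calls\n",
            conc$fdr_percent, conc$fnr_percent, conc$n_calls))
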