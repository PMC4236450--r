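#!/usr/bin/env Rscript
# Stage 2: per-population nucleotide diversity.
#
# Sums the unbiased per-site pi over every variable site within each
# population and normalizes by the total ungapped genome length. On the
# Balding-Nichols fixture all populations share an ancestral frequency
# law, so the per-population values should be similar; differences trace
# to the divergence parameter and sampling noise.

source("analysis/00_setup.R")

run_stage("diversity", analysis_config())
pi_tab <- show_table("diversity", "pi.tsv", n = 15)
cat(sprintf("\ngenome-wide pi spans %.3g - %.3g per bp across populations\n",
            min(pi_tab$genome_pi), max(pi_tab$genome_pi)))
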