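#!/usr/bin/env Rscript
# Per-specimen intra-tooth summaries for the Hazor case study: descriptive
# statistics per isotope, full-seasonal-cycle flags, and the crown positions
# of the d18O extremes that anchor the strontium pairs.

suppressPackageStartupMessages(library(isoherd))
dir.create("results", showWarnings = FALSE)

seqs <- hazor_sequences()  # synthetic reconstruction of the sampled teeth
summaries <- suppressWarnings(summarize_sequences(seqs))

report <- summary_table(summaries, digits = 1)
utils::write.csv(as.data.frame(report), "results/summaries.csv",
                 row.names = FALSE)

cat(sprintf("%d specimens, %d increments\n",
            nrow(summaries), sum(summaries$n)))
cat(sprintf("full seasonal cycle recorded in %d of %d d18O sequences\n",
            sum(summaries$full_cycle), nrow(summaries)))
caprine <- summaries[summaries$taxon %in% c("sheep", "goat", "sheep/goat"), ]
cat(sprintf("caprine intra-tooth d18O range: %.1f to %.1f permil\n",
            round_half_up(min(caprine$d18O_delta), 1),
            round_half_up(max(caprine$d18O_delta), 1)))
cat("wrote results/summaries.csv\n")
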