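#!/usr/bin/env Rscript
# Assemblage statistics: relative taxon frequencies per period, chi-square
# association of taxa with period (with standardized residuals), and
# age-at-death cohorts from the mandibular wear records.

suppressPackageStartupMessages(library(isoherd))
dir.create("results", showWarnings = FALSE)

counts <- hazor_nisp()
cat(sprintf("total NISP identified to genus: %d\n", sum(counts)))

freq <- taxon_frequencies(counts, hazor_grouping())
utils::write.csv(as.data.frame(freq), "results/freq.csv", row.names = FALSE)
cap <- function(p) freq$display[freq$group == "caprine" & freq$period == p]
cat(sprintf("caprine share: early IRIIA %s%%, late IRIIA %s%%, IRIIB %s%%\n",
            cap("early_IRIIA"), cap("late_IRIIA"), cap("IRIIB")))
ce <- function(p) freq$display[freq$group == "cattle_equid" & freq$period == p]
cat(sprintf("cattle+equid share: early IRIIA %s%%, IRIIB %s%%\n",
            ce("early_IRIIA"), ce("IRIIB")))

chs <- chi_square(counts)
cat(sprintf("taxon-by-period chi-square: %.2f on %d df (p = %.2g)\n",
            chs$statistic, chs$df, chs$p_value))
big <- which(abs(chs$residuals) > 2, arr.ind = TRUE)
for (i in seq_len(nrow(big))) {
  cat(sprintf("  |residual| > 2: %s x %s (%+.1f)\n",
              rownames(counts)[big[i, 1]], colnames(counts)[big[i, 2]],
              chs$residuals[big[i, 1], big[i, 2]]))
}
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(list(statistic = chs$statistic, df = chs$df,
                            p_value = chs$p_value,
                            residuals = as.data.frame(chs$residuals)),
                       "results/chisq.json", auto_unbox = TRUE, digits = NA)
}

dist <- suppressWarnings(age_cohorts(hazor_wear(), wear_mapping("hazor_table1")))
utils::write.csv(as.data.frame.matrix(dist), "results/cohorts_age.csv")
cat("age cohorts (rows periods, cols cohorts 1-5 + unassigned):\n")
print(dist)
cat("wrote results/freq.csv, results/chisq.json, results/cohorts_age.csv\n")
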