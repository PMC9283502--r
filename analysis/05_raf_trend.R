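#!/usr/bin/env Rscript
# Stage 5: pre/post field-application resistant-allele-frequency trends --
# per-location allele odds ratios and the equal-weight pooled contrasts from
# the interaction logit model.

library(kdrmonitor)

counts <- read_count_table(kdr_fixture("field"))
out <- run_trend_experiment(counts)

write.table(out$by_location, "results/raf_by_location.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(out$pooled, "results/raf_pooled.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(out$by_location)
cat("pooled (equal-weight over locations) post-vs-pre odds ratios:\n")
print(out$pooled[, c("year", "locus", "odds_ratio", "or_lo", "or_hi", "p_value")])
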