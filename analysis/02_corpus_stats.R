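#!/usr/bin/env Rscript
# Stage 2 — frequency, dosage and attribute statistics per cirrhosis stage.
#
# Reproduces the layout of the clinical frequency tables: per-herb use
# frequency, rate (% of prescriptions), proportion (% of all occurrences),
# dose range and mean, plus occurrence-weighted property/flavor/meridian
# percents for the high-frequency herbs.

library(herbmicrobeMR)

prescriptions <- read_prescriptions("results/inputs/prescriptions.csv")
dir.create("results/corpus", showWarnings = FALSE, recursive = TRUE)

for (st in unique(prescriptions$stage)) {
  sub <- prescriptions[prescriptions$stage == st, ]
  ft <- frequency_table(sub)
  write.table(ft, sprintf("results/corpus/frequency_%s.tsv", st),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- ft[1, ]
  cat(sprintf("%s: %d herbs; most frequent %s (%d uses, rate %.2f%%, proportion %.2f%%)\n",
              st, nrow(ft), top$herb, top$frequency, top$rate, top$proportion))
}

# synthetic attribute dictionary: assign properties/flavors/meridians to the
# herb universe so the occurrence-weighted attribute statistics can run
set.seed(11)
herbs <- sort(unique(prescriptions$herb))
attrs <- data.frame(
  herb = herbs,
  properties = sample(c("cold", "cool", "mild", "warm"), length(herbs), TRUE),
  flavors = vapply(herbs, function(h)
    paste(sample(c("bitter", "sweet", "pungent", "sour", "salty", "bland"),
                 sample(1:3, 1)), collapse = ";"), character(1)),
  meridians = vapply(herbs, function(h)
    paste(sample(c("liver", "spleen", "lung", "kidney", "heart", "stomach"),
                 sample(1:4, 1)), collapse = ";"), character(1)),
  dose_lo_g = 3, dose_hi_g = 15)
write.csv(attrs, "results/inputs/herb_attributes.csv", row.names = FALSE)
attrs <- read_herb_attributes("results/inputs/herb_attributes.csv")

for (st in unique(prescriptions$stage)) {
  sub <- prescriptions[prescriptions$stage == st, ]
  ft <- frequency_table(sub)
  high <- ft$herb[ft$frequency > stats::quantile(ft$frequency, 0.5)]
  af <- attribute_frequencies(sub, attrs, high)
  write.table(af, sprintf("results/corpus/attributes_%s.tsv", st),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lead <- af[!duplicated(af$axis), ]
  cat(sprintf("%s attribute leaders: %s\n", st,
              paste(sprintf("%s %s (%.2f%%)", lead$axis, lead$level,
                            lead$percent), collapse = ", ")))
}
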