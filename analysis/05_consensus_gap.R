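#!/usr/bin/env Rscript
# 50% consensus across the six delimitations, barcoding-gap statistics at
# the species and the OTU level, and the species-by-OTU report table.
# Reads the artifacts written by 04_delimit.R.

library(barcodelim)

seed <- 2026L
lib <- read_library("results/benchmark/benchmark.fasta",
                    "results/benchmark/benchmark_metadata.tsv")
truth <- read.delim("results/benchmark/benchmark_truth.tsv")

res <- run_pipeline(library = lib, seed = seed)

cat("Consensus:", res$consensus$n_otus, "OTUs over",
    length(res$consensus$input_methods), "methods (truth:",
    length(unique(truth$otu_label)), "species);",
    res$consensus$n_transitive_pairs, "transitive pair(s)\n")

print(res$gap_species)
print(res$gap_otu)

write.table(res$gap_otu$histogram, "results/gap_histogram_otu.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$species_otu_table, "results/species_otu_table.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

summary <- res$summary
jsonlite::write_json(summary, "results/summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("Wrote results/summary.json, results/species_otu_table.tsv and",
    "results/gap_histogram_otu.tsv\n")
if (nrow(res$species_otu_table) == 0) {
  cat("No morphological species was split into multiple OTUs on this run.\n")
} else {
  print(res$species_otu_table)
}
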