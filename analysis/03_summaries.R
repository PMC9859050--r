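#!/usr/bin/env Rscript
# Summary statistics of the called variants: substitution spectrum (Ts/Tv
# pair classes), per-region variability under both metrics (share-of-total
# and per-bp), within-population polymorphism counts, and overall
# changes-per-bp densities. Writes the Circos-ready tables under results/.

suppressMessages(library(organvar))

seed <- 20221225L
cp_ref <- build_reference("plastome", seed = seed)
features <- cp_ref$features
variants <- read_variant_table("results/plastome_variants.tsv")
popmap <- read_population_map("results/data/population_map.tsv")

spectrum <- tstv_breakdown(variants)
write.table(spectrum, "results/spectrum.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("spectrum over %d SNPs: %.1f%% transversions, %.1f%% transitions\n",
            attr(spectrum, "n_snps"),
            100 * attr(spectrum, "transversions") / attr(spectrum, "n_snps"),
            100 * attr(spectrum, "transitions") / attr(spectrum, "n_snps")))

ir <- features[features$type == "IR", ]
trimmed_len <- cp_ref$length - (ir$end[2] - ir$start[2] + 1L)
inv <- build_region_inventory(features, trimmed_len)
regions <- per_region_summary(variants, inv)
write.table(regions, "results/regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("most variable regions (share of all mutations):\n")
print(head(regions[, c("region", "class", "snps", "indels", "share_of_total")], 5))

vs <- variants[setdiff(names(variants), "REF")]
pops <- per_population_counts(vs, popmap)
write.table(pops, "results/populations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("within-population polymorphism (SNPs / InDels):\n")
print(pops)

mt_var <- read_variant_table("results/mitogenome_variants.tsv")
mt_len <- ncol(read_alignment("results/data/mitogenome_true_alignment.fasta"))
density <- data.frame(
  molecule = c("plastome", "mitogenome"),
  mutations = c(nrow(variants), nrow(mt_var)),
  length = c(cp_ref$length, mt_len),
  changes_per_bp = c(changes_per_bp(nrow(variants), cp_ref$length),
                     changes_per_bp(nrow(mt_var), mt_len)))
write.table(density, "results/density.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("changes per bp: plastome %.3g, mitogenome %.3g (ratio %.1f)\n",
            density$changes_per_bp[1], density$changes_per_bp[2],
            density$changes_per_bp[1] / density$changes_per_bp[2]))
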