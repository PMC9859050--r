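#!/usr/bin/env Rscript
# Generate the synthetic study system: a plastome-like reference with
# LSC/IR/SSC architecture and a 14-region, 3-chromosome mitogenome-like set,
# then simulate the 16-individual / 5-population sample (plus the single
# southern outgroup individual) with planted SNPs and InDels under
# region-dependent rates. Writes the true alignments, truth tables and
# population map under results/data/.

suppressMessages(library(organvar))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20221225L

cp_ref <- build_reference("plastome", seed = seed)
mt_ref <- build_reference("mitogenome", seed = seed)
cp <- simulate_population(cp_ref, simulation_config("plastome", seed = seed + 1L))
mt <- simulate_regions(mt_ref, simulation_config("mitogenome", seed = seed + 2L))

write_alignment(cp$alignment, file.path(out, "plastome_true_alignment.fasta"))
write_alignment(mt$alignment, file.path(out, "mitogenome_true_alignment.fasta"))
write_features(cp_ref$features, file.path(out, "plastome.gff3"), seqid = "plastome")
for (s in names(cp$sequences))
  write_alignment(setNames(cp$sequences[s], s),
                  file.path(out, paste0("plastome_", s, ".fasta")))
write.table(data.frame(sample = names(cp$popmap), population = unname(cp$popmap)),
            file.path(out, "population_map.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cp$truth$variants, file.path(out, "plastome_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mt$truth$variants, file.path(out, "mitogenome_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("plastome: %d bp reference, %d-column true alignment, %d planted events (%d SNP / %d InDel)\n",
            cp_ref$length, ncol(cp$alignment), nrow(cp$truth$variants),
            sum(cp$truth$variants$type == "SNP"),
            sum(cp$truth$variants$type == "InDel")))
cat(sprintf("mitogenome: 14 regions / %d bp, %d planted events (%d SNP / %d InDel)\n",
            ncol(mt$alignment), nrow(mt$truth$variants),
            sum(mt$truth$variants$type == "SNP"),
            sum(mt$truth$variants$type == "InDel")))
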