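#!/usr/bin/env Rscript
# Collapse individuals into haplotypes over all variant characters (SNP
# alleles + InDel block presence/absence) and build randomized
# minimum-spanning-tree networks on indel-block distances; edges present in
# some but not all randomized iterations are the alternative pathways.

suppressMessages(library(organvar))

seed <- 20221225L
popmap <- read_population_map("results/data/population_map.tsv")

for (mol in c("plastome", "mitogenome")) {
  variants <- read_variant_table(sprintf("results/%s_variants.tsv", mol))
  aln <- read_alignment(sprintf("results/data/%s_true_alignment.fasta", mol))
  hm <- haplotype_matrix(variants)
  hm <- hm[setdiff(rownames(hm), "REF"), , drop = FALSE]
  hap <- collapse_haplotypes(hm)
  reps <- vapply(attr(hap, "classes"), `[`, character(1), 1L)
  dmat <- indelblock_dist_matrix(aln[reps, , drop = FALSE])
  net <- rmst_network(dmat, iterations = 2000, seed = seed,
                      haplotypes = hap, popmap = popmap)
  write.table(net$nodes, sprintf("results/%s_network_nodes.tsv", mol),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(net$edges, sprintf("results/%s_network_edges.tsv", mol),
              sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(network_igraph(net),
                      sprintf("results/%s_network.graphml", mol), "graphml")
  cat(sprintf("%s: %d haplotypes in %d individuals; network %d edges (%d alternative), MST weight %g\n",
              mol, nrow(net$nodes), nrow(hm), nrow(net$edges),
              sum(net$edges$alternative), net$mst_weight))
}
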