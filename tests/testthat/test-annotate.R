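test_that("region inventory tiles the reference with named spacers and introns", {
  inv <- build_region_inventory(two_gene_features(), 140L)
  expect_equal(sum(inv$length), 140L)
  expect_true(all(inv$start[-1] == inv$end[-nrow(inv)] + 1L))
  expect_equal(inv$name[inv$class == "intergenic"],
               c("ter--g1", "g1--g2", "g2--ter"))
  expect_equal(sum(inv$class == "intron"), 1L)   # the two-exon gene
  expect_equal(inv$start[inv$class == "intron"], 91L)

  overlapping <- rbind(feat("a", "gene", 10, 50), feat("b", "gene", 40, 80))
  expect_error(build_region_inventory(overlapping, 100L), "ambiguous annotation")
})

test_that("locate_variant assigns positions to their containing region", {
  inv <- build_region_inventory(two_gene_features(), 140L)
  expect_equal(locate_variant(20L, inv)$region_type, "exon")
  expect_equal(locate_variant(50L, inv)$region_name, "g1--g2")
  expect_equal(locate_variant(95L, inv)$region_type, "intron")
  expect_error(locate_variant(141L, inv), "out of range")
})

test_that("snp_effect matches the translation oracle", {
  # CDS "ATGGCT" at 11..16 on the plus strand
  fts <- rbind(feat("g", "gene", 11, 16), feat("g", "CDS", 11, 16))
  refseq <- c(strsplit("AAAAAAAAAA", "")[[1]], strsplit("ATGGCT", "")[[1]],
              rep("A", 10))
  # codon 2 position 3: GCT -> GCA, Ala -> Ala
  expect_equal(snp_effect(16L, "T", "A", fts, refseq), "synonymous")
  # codon 2 position 2: GCT -> GAT, Ala -> Asp
  expect_equal(snp_effect(15L, "C", "A", fts, refseq), "nonsynonymous")
  # outside any CDS
  expect_equal(snp_effect(5L, "A", "C", fts, refseq), "noncoding")
  # stop-codon involvement is flagged: TGG -> TGA (Trp -> stop, code 11)
  fts2 <- rbind(feat("w", "gene", 1, 3), feat("w", "CDS", 1, 3))
  eff <- snp_effect(3L, "G", "A", fts2, c("T", "G", "G"))
  expect_equal(as.character(eff), "nonsynonymous")
  expect_true(isTRUE(attr(eff, "stop_involved")))
  # frame error
  fts3 <- rbind(feat("f", "gene", 1, 4), feat("f", "CDS", 1, 4))
  expect_error(snp_effect(2L, "C", "A", fts3, c("A", "C", "G", "T")),
               "frame error")
})

test_that("minus-strand effects equal plus-strand effects after revcomp", {
  set.seed(13)
  for (rep in 1:10) {
    L <- 60L
    refseq <- sample(c("A", "C", "G", "T"), L, TRUE)
    fts <- rbind(feat("g", "gene", 13, 33), feat("g", "CDS", 13, 33))
    pos <- sample(13:33, 1)
    ref_b <- refseq[pos]
    alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
    plus <- snp_effect(pos, ref_b, alt_b, fts, refseq)
    # mirror the genome
    rc <- organvar:::revcomp(refseq)
    fts_rc <- fts; fts_rc$start <- L - fts$end + 1L; fts_rc$end <- L - fts$start + 1L
    fts_rc$strand <- "-"
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    minus <- snp_effect(L - pos + 1L, unname(comp[ref_b]), unname(comp[alt_b]),
                        fts_rc, rc)
    expect_equal(as.character(minus), as.character(plus))
  }
})

test_that("annotation of called variants is exact on planted CDS SNPs", {
  ref <- build_reference("plastome", seed = 4)
  cfg <- simulation_config("plastome", seed = 17,
                           snp_rate = c(exon = 0.01, intron = 0, spacer = 0),
                           indel_rate = c(exon = 0, intron = 0, spacer = 0),
                           population_divergence = 0, outgroup_mutations = 0)
  sim <- simulate_population(ref, cfg)
  aln <- trim_second_ir(sim$alignment, ref$features, "REF")
  v <- call_variants(aln, "REF")
  ir <- ref$features[ref$features$type == "IR", ]
  trimmed_len <- ref$length - (ir$end[2] - ir$start[2] + 1L)
  va <- annotate_variants(v, ref$features, ref$sequence[seq_len(trimmed_len)],
                          code = "plastid")
  expect_gt(nrow(va), 10L)
  expect_true(all(va$region_type == "exon"))
  expect_true(all(va$effect %in% c("synonymous", "nonsynonymous", "noncoding")))
  # oracle: translate every planted codon change independently via Biostrings
  gc11 <- Biostrings::getGeneticCode("11")
  for (i in seq_len(nrow(va))) {
    if (va$effect[i] == "noncoding") next   # tRNA/rRNA exons
    cds <- organvar:::spliced_cds(
      unique(ref$features$name[ref$features$type == "CDS" &
                                 ref$features$start <= va$ref_position[i] &
                                 ref$features$end >= va$ref_position[i]])[1],
      ref$features, ref$sequence)
    j <- match(va$ref_position[i], cds$positions)
    codon <- (j - 1) %/% 3
    ref_cdn <- paste(cds$bases[(codon * 3 + 1):(codon * 3 + 3)], collapse = "")
    alt_b <- strsplit(va$alt_alleles[i], ",")[[1]][1]
    if (cds$strand == "-") alt_b <- c(A="T",C="G",G="C",T="A")[[alt_b]]
    alt_cdn_v <- strsplit(ref_cdn, "")[[1]]
    alt_cdn_v[j - codon * 3] <- alt_b
    expected <- if (gc11[[ref_cdn]] == gc11[[paste(alt_cdn_v, collapse = "")]])
      "synonymous" else "nonsynonymous"
    expect_equal(va$effect[i], expected)
  }
})
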