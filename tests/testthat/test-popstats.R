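mini_snp_table <- function(pairs) {
  # pairs: list of c(ref, alt or "alt1,alt2")
  core <- data.frame(ref_position = seq_along(pairs),
                     col_start = seq_along(pairs), col_end = seq_along(pairs),
                     type = "SNP",
                     ref_allele = vapply(pairs, `[`, "", 1),
                     alt_alleles = vapply(pairs, `[`, "", 2),
                     alt_count = 1L, stringsAsFactors = FALSE)
  gt <- matrix("A", nrow(core), 2, dimnames = list(NULL, c("x", "y")))
  variant_table(core, gt)
}

test_that("spectrum classifies transitions and transversions correctly", {
  sp <- tstv_breakdown(mini_snp_table(list(c("A", "G"))))
  expect_equal(attr(sp, "transitions"), 1)
  expect_equal(attr(sp, "transversions"), 0)
  sp2 <- tstv_breakdown(mini_snp_table(list(
    c("A", "G"), c("C", "T"), c("A", "C"), c("A", "T"), c("G", "C"), c("T", "G"))))
  expect_equal(sp2$count, rep(1, 6))
  expect_equal(sum(sp2$percent), 100)
  # multiallelic: one unit split equally across alt classes
  sp3 <- tstv_breakdown(mini_snp_table(list(c("A", "G,C"))))
  expect_equal(sp3$count[sp3$class == "A<->G"], 0.5)
  expect_equal(sp3$count[sp3$class == "A<->C"], 0.5)
  expect_error(tstv_breakdown(mini_snp_table(list(c("A", "N")))),
               "unclassifiable")
})

test_that("spectrum conservation: ts + tv equals total SNPs on simulated data", {
  ref <- build_reference("plastome", seed = 3)
  for (s in 1:5) {
    sim <- simulate_population(ref, simulation_config("plastome", seed = 50 + s))
    v <- call_variants(trim_second_ir(sim$alignment, ref$features, "REF"), "REF")
    sp <- tstv_breakdown(v)
    expect_equal(attr(sp, "transitions") + attr(sp, "transversions"),
                 sum(v$type == "SNP"))
  }
})

test_that("printed percentage spectrum reconstructs integer counts summing to 64", {
  pub <- read.delim(system.file("extdata", "published_plastome_spectrum.tsv",
                                package = "organvar"))
  counts <- reconstruct_class_counts(pub$percent, 64)
  expect_equal(counts, c(6L, 24L, 2L, 12L, 9L, 11L))
  expect_equal(sum(counts), 64L)
  expect_equal(sum(counts[pub$kind == "transversion"]), 44L)
})

test_that("per-region summary computes both variability metrics", {
  inv <- build_region_inventory(two_gene_features(), 140L)
  core <- data.frame(ref_position = c(20L, 50L, 51L), col_start = c(20L, 50L, 51L),
                     col_end = c(20L, 50L, 53L), type = c("SNP", "SNP", "InDel"),
                     ref_allele = c("A", "C", "ACG"), alt_alleles = c("G", "T", "-"),
                     alt_count = 1L, region_name = c("g1", "g1--g2", "g1--g2"),
                     region_type = c("exon", "intergenic", "intergenic"),
                     effect = "noncoding", stringsAsFactors = FALSE)
  vt <- variant_table(core, matrix("A", 3, 1, dimnames = list(NULL, "s")))
  rs <- per_region_summary(vt, inv)
  g12 <- rs[rs$region == "g1--g2", ]
  expect_equal(g12$snps, 1L)
  expect_equal(g12$indels, 1L)
  expect_equal(g12$share_of_total, 2 / 3)
  expect_equal(g12$per_bp_density, 2 / 20)
  expect_equal(sum(rs$share_of_total), 1)
  empty_regions <- rs[rs$snps + rs$indels == 0, ]
  expect_true(all(empty_regions$share_of_total == 0))
  expect_true(all(empty_regions$per_bp_density == 0))
})

test_that("published hotspot shares reproduce the printed percentages", {
  hs <- read.delim(system.file("extdata", "published_plastome_hotspots.tsv",
                               package = "organvar"))
  shares <- 100 * (hs$snps + hs$indels) / 160
  expect_equal(round(shares, 2), c(20.62, 7.50, 6.88), tolerance = 0.011)
  # and the 0.44% figure for the rps16 intron is per-bp, not share-of-total:
  # 5 variants over ~1.1 kb, an order of magnitude below 5/160
  expect_false(isTRUE(all.equal(round(100 * 5 / 160, 2), 0.44)))
})

test_that("within-population polymorphism follows the >=2-alleles rule", {
  gt <- pulsatilla_mito_snps()
  core <- data.frame(ref_position = seq_len(ncol(gt)),
                     col_start = seq_len(ncol(gt)), col_end = seq_len(ncol(gt)),
                     type = "SNP", ref_allele = gt[1, ], alt_alleles = "N",
                     alt_count = 1L, stringsAsFactors = FALSE)
  vt <- variant_table(core, t(gt))
  roster <- pulsatilla_samples()
  popmap <- setNames(roster$population, roster$sample)
  pc <- per_population_counts(vt, popmap)
  expect_equal(pc$snps[pc$population == "P4"], 2L)
  expect_equal(pc$snps[pc$population == "P8"], 4L)
  expect_equal(pc$snps[pc$population == "P9"], 5L)
  expect_equal(pc$snps[pc$population == "P13"], 0L)

  # invariant to sample order and to allele relabeling
  vt2 <- variant_table(core, t(gt)[, sample(rownames(gt))])
  pc2 <- per_population_counts(vt2, popmap)
  expect_equal(pc2[order(pc2$population), ], pc[order(pc$population), ],
               ignore_attr = TRUE)
  relab <- t(gt); relab[relab == "A"] <- "Z"; relab[relab == "C"] <- "A"
  relab[relab == "Z"] <- "C"
  pc3 <- per_population_counts(variant_table(core, relab), popmap)
  expect_equal(pc3$snps, pc$snps)

  single <- per_population_counts(vt, setNames(c(rep("P", 15), "Q"),
                                               rownames(gt)))
  expect_true(single$flagged[single$population == "Q"])
  expect_equal(single$snps[single$population == "Q"], 0L)
})

test_that("changes_per_bp is a guarded ratio", {
  expect_equal(changes_per_bp(0, 1000), 0)
  expect_equal(changes_per_bp(160, 162272), 160 / 162272)
  expect_equal(round(changes_per_bp(160, 162272), 7), 9.86e-4)
  expect_equal(round(changes_per_bp(24, 331950), 8), 7.23e-5)
  expect_error(changes_per_bp(5, 0), "positive")
})
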