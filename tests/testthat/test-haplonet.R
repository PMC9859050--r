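test_that("haplotype collapsing deduplicates exact character strings", {
  m <- char_aln(a = "ACGT", b = "ACGT", c = "ACGA")
  h <- collapse_haplotypes(m)
  expect_equal(h$haplotype, c("a", "a", "c"))

  gt <- pulsatilla_mito_snps()
  h2 <- collapse_haplotypes(gt)
  expect_length(attr(h2, "classes"), 7L)   # SNP-only haplotype classes
  p13 <- unique(h2$haplotype[h2$sample %in% c("P13-1", "P13-2", "P13-3")])
  expect_length(p13, 1L)                   # the P13 trio shares one haplotype
  # independent oracle: plain string deduplication
  expect_equal(length(unique(apply(gt, 1, paste, collapse = ""))), 7L)
})

test_that("indelblock distance counts substitutions plus gap blocks once", {
  expect_equal(indelblock_distance("ACGT", "ACGT"), 0L)
  expect_equal(indelblock_distance("AC--GT", "ACTTGT"), 1L)
  expect_equal(indelblock_distance("AC--GT", "AC--GT"), 0L)
  # same span shared, plus a private block elsewhere
  expect_equal(indelblock_distance("AC--G-", "AC--GT"), 1L)
  # overlapping but non-identical blocks are distinct events on both sides
  expect_equal(indelblock_distance("A---GT", "A--CGT"), 2L)
  # substitutions at sites where both have bases
  expect_equal(indelblock_distance("ACGT", "TCGA"), 2L)
  expect_error(indelblock_distance("ACG", "ACGT"), "unequal")

  gt <- pulsatilla_mito_snps()
  expect_equal(indelblock_distance(gt["P9-133", ], gt["P13-1", ]), 5L)
})

test_that("indelblock distance is symmetric, zero iff identical, Hamming on gap-free pairs", {
  set.seed(5)
  for (rep in 1:20) {
    L <- 30
    a <- sample(c("A", "C", "G", "T", "-"), L, TRUE, prob = c(.22,.22,.22,.22,.12))
    b <- sample(c("A", "C", "G", "T", "-"), L, TRUE, prob = c(.22,.22,.22,.22,.12))
    expect_equal(indelblock_distance(a, b), indelblock_distance(b, a))
    expect_equal(indelblock_distance(a, a), 0L)
  }
  a <- sample(c("A", "C", "G", "T"), 50, TRUE)
  b <- sample(c("A", "C", "G", "T"), 50, TRUE)
  expect_equal(indelblock_distance(a, b), sum(a != b))
})

test_that("gap-block component agrees with the ape indel-block distance", {
  set.seed(8)
  for (rep in 1:10) {
    L <- 40
    base <- sample(c("A", "C", "G", "T"), L, TRUE)
    mk <- function() {
      x <- base
      for (k in seq_len(sample(0:3, 1))) {
        s <- sample(L - 4, 1); x[s:(s + sample(0:3, 1))] <- "-"
      }
      x
    }
    m <- rbind(a = mk(), b = mk())
    ours <- indelblock_distance(m["a", ], m["b", ])
    subs <- {
      both <- m["a", ] != "-" & m["b", ] != "-"
      sum(m["a", both] != m["b", both])
    }
    ape_blocks <- as.numeric(ape::dist.dna(ape::as.DNAbin(tolower(m)),
                                           model = "indelblock"))
    expect_equal(ours - subs, ape_blocks)
  }
})

test_that("rmst_network matches unique-MST and triangle oracles", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  net <- rmst_network(d, iterations = 300, seed = 2)
  expect_equal(organvar:::edge_keys(net$edges), c("A|B", "B|C"))
  expect_equal(net$edges$support, c(1, 1))
  expect_false(any(net$edges$alternative))

  eq <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(eq) <- 0
  net2 <- rmst_network(eq, iterations = 3000, seed = 2)
  expect_equal(organvar:::edge_keys(net2$edges), c("A|B", "A|C", "B|C"))
  expect_true(all(net2$edges$alternative))
  # each of the 3 spanning trees holds 2 of 3 edges: support -> 2/3
  expect_true(all(abs(net2$edges$support - 2 / 3) < 0.05))

  # two haplotypes: one edge, full support
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  net3 <- rmst_network(d2, iterations = 10, seed = 1)
  expect_equal(nrow(net3$edges), 1L)
  expect_equal(net3$edges$support, 1)
})

test_that("every rmst network contains a spanning tree of minimum weight", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- sample(1:3, n * (n - 1) / 2, TRUE)
    d <- d + t(d)
    dimnames(d) <- list(paste0("H", 1:n), paste0("H", 1:n))
    net <- rmst_network(d, iterations = 300, seed = rep)
    oracle <- mst_union_oracle(d)
    expect_equal(net$mst_weight, oracle$mst_weight)
    # the union never contains an edge outside the exhaustive MST union
    expect_true(all(organvar:::edge_keys(net$edges) %in%
                      organvar:::edge_keys(oracle$edges)))
  }
})

test_that("mst_union_oracle matches hand-enumerable cases and refuses n > 8", {
  # path-graph distances: unique MST = the path
  dp <- as.matrix(dist(1:4)); dimnames(dp) <- list(letters[1:4], letters[1:4])
  expect_equal(organvar:::edge_keys(mst_union_oracle(dp)$edges),
               c("a|b", "b|c", "c|d"))
  big <- matrix(1, 9, 9); diag(big) <- 0
  dimnames(big) <- list(letters[1:9], letters[1:9])
  expect_error(mst_union_oracle(big), "refused")
})

test_that("node composition tracks members and populations", {
  gt <- pulsatilla_mito_snps()
  hap <- collapse_haplotypes(gt)
  roster <- pulsatilla_samples()
  popmap <- setNames(roster$population, roster$sample)
  reps <- vapply(attr(hap, "classes"), `[`, character(1), 1L)
  d <- indelblock_dist_matrix(gt[reps, , drop = FALSE])
  net <- rmst_network(d, iterations = 200, seed = 4, haplotypes = hap,
                      popmap = popmap)
  expect_equal(sum(net$nodes$size), 16L)
  big <- net$nodes[net$nodes$haplotype == "P4-105", ]
  expect_equal(big$size, 9L)   # P4-105, P9-120, P9-122, the P13 trio, the P15 trio
  expect_match(big$populations, "P13:3")
})
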