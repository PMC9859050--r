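test_that("jc_distance matches its closed form and domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.01), -0.75 * log(1 - 0.04 / 3))
  expect_equal(round(jc_distance(0.01), 6), 0.010067)
  expect_error(jc_distance(0.75), "saturated")
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(jc_distance(p)) > 0))   # monotone
  # cross-check against the ape implementation on a random pair
  set.seed(1)
  a <- sample(c("a", "c", "g", "t"), 500, TRUE)
  b <- a; i <- sample(500, 60); b[i] <- sample(c("a", "c", "g", "t"), 60, TRUE)
  expect_equal(jc_distance(mean(a != b)),
               as.numeric(ape::dist.dna(ape::as.DNAbin(rbind(a, b)), "JC69")),
               tolerance = 1e-10)
})

test_that("hky_distance nests JC and matches the ape TN93 closed form", {
  expect_equal(hky_distance("ACGT", "ACGT"), 0)
  # mismatches spread uniformly over the 12 ordered substitution types
  a <- rep(c("A", "C", "G", "T"), each = 300)
  b <- a
  for (rb in c("A", "C", "G", "T")) {
    i <- which(a == rb)[1:18]
    b[i] <- rep(setdiff(c("A", "C", "G", "T"), rb), 6)
  }
  p <- mean(a != b)
  expect_equal(hky_distance(a, b), jc_distance(p), tolerance = 1e-10)

  set.seed(4)
  x <- sample(c("A", "C", "G", "T"), 2000, TRUE, prob = c(.3, .2, .2, .3))
  y <- x; i <- sample(2000, 150); y[i] <- sample(c("A", "C", "G", "T"), 150, TRUE)
  expect_equal(hky_distance(x, y),
               as.numeric(ape::dist.dna(ape::as.DNAbin(rbind(tolower(x), tolower(y))),
                                        "TN93")),
               tolerance = 1e-10)

  # simulated pair under strong transition bias recovers the branch length
  tr2 <- ape::read.tree(text = "(p:0.05,q:0.05);")
  set.seed(9)
  dat <- phangorn::simSeq(tr2, l = 10000, Q = c(1, 4, 1, 1, 4, 1),
                          bf = rep(0.25, 4))
  m <- toupper(as.character(dat))
  expect_equal(hky_distance(m["p", ], m["q", ]), 0.1, tolerance = 0.1)
})

test_that("matrix distance computations equal the pairwise closed forms", {
  set.seed(19)
  base <- sample(c("A", "C", "G", "T"), 400, TRUE)
  m <- do.call(rbind, lapply(1:6, function(i) {
    x <- base
    idx <- sample(400, 60)
    x[idx] <- sample(c("A", "C", "G", "T", "-", "N"), 60, TRUE)
    x
  }))
  rownames(m) <- paste0("t", 1:6)
  tab <- table(factor(m[m %in% c("A", "C", "G", "T")],
                      levels = c("A", "C", "G", "T")))
  fr <- as.numeric(prop.table(tab))
  dh <- dist_hky(m)
  dj <- dist_jc(m)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(dh[i, j], hky_distance(m[i, ], m[j, ], fr), tolerance = 1e-12)
    pc <- organvar:::pair_counts(m[i, ], m[j, ])
    expect_equal(dj[i, j], jc_distance(pc$P1 + pc$P2 + pc$Q), tolerance = 1e-12)
  }
})

test_that("3-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly recovers additive distance matrices", {
  set.seed(20)
  for (rep in 1:25) {
    tr <- ape::rtree(sample(4:12, 1), rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), est)), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)] - D)),
              1e-8)
  }
})

test_that("NJ agrees topologically with the ape implementation on noisy data", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 4), n)))
    dimnames(D) <- list(letters[1:n], letters[1:n])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ape::nj(as.dist(D))),
                                           nj_tree(D))), 0)
  }
})

test_that("bootstrap finds full support for perfectly compatible signal", {
  base <- rep("A", 120)
  mk <- function(sub) { x <- base; x[seq_along(sub)] <- sub; x }
  # 40 columns all supporting ab|cd
  m <- rbind(a = mk(rep("C", 40)), b = mk(rep("C", 40)),
             c = mk(rep("G", 40)), d = mk(rep("G", 40)))
  m[, 41:60] <- matrix(sample(c("A", "G"), 80, TRUE), 4)  # noise columns
  tr <- bootstrap_support(m, dist_jc, n_reps = 100, seed = 5)
  sup <- attr(tr, "supports")
  expect_equal(unname(sup[["c,d"]]), 100)
  # fixed seed reproduces identical supports; supports bounded in [0, 100]
  tr2 <- bootstrap_support(m, dist_jc, n_reps = 100, seed = 5)
  expect_identical(attr(tr2, "supports"), sup)
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("tree bipartitions agree with ape::prop.part", {
  set.seed(6)
  for (rep in 1:5) {
    tr <- ape::rtree(8, rooted = FALSE)
    keys <- tree_bipartitions(tr)
    pp <- ape::prop.part(tr)
    anchor <- sort(tr$tip.label)[1]
    oracle <- unique(vapply(pp[-1], function(idx) {
      tips <- tr$tip.label[idx]
      side <- if (anchor %in% tips) setdiff(tr$tip.label, tips) else tips
      paste(sort(side), collapse = ",")
    }, character(1)))
    oracle <- oracle[vapply(strsplit(oracle, ","), function(x)
      length(x) >= 2 && length(x) <= 6, logical(1))]
    expect_setequal(unname(keys), oracle)
  }
})

test_that("pruning log-likelihood matches the 2-sequence JC closed form", {
  t <- 0.15; n <- 400
  set.seed(2)
  a <- sample(c("A", "C", "G", "T"), n, TRUE)
  ps <- 0.25 + 0.75 * exp(-4 * t / 3)
  b <- vapply(a, function(x) if (runif(1) < ps) x else
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  k <- sum(a != b)
  tr <- ape::read.tree(text = sprintf("(x:%f,y:%f);", t / 2, t / 2))
  aln <- rbind(x = a, y = b)
  closed <- k * log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3))) +
    (n - k) * log(0.25 * ps)
  expect_equal(pruning_loglik(tr, aln, subst_model("JC")), closed,
               tolerance = 1e-8)
})

test_that("pruning log-likelihood is reroot-invariant and matches phangorn", {
  set.seed(3)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(10, 0.05, 0.3)
  dat <- phangorn::simSeq(tr, l = 300, Q = c(1, 4, 1, 1, 4, 1),
                          bf = c(.3, .2, .2, .3))
  m <- toupper(as.character(dat))
  model <- subst_model("HKY", kappa = 4, freqs = c(.3, .2, .2, .3))
  ll <- pruning_loglik(tr, m, model)
  fit <- phangorn::pml(tr, dat, model = "HKY", k = 1, bf = c(.3, .2, .2, .3),
                       Q = c(1, 4, 1, 1, 4, 1))
  expect_equal(ll, fit$logLik, tolerance = 1e-8)
  for (tip in tr$tip.label[1:3]) {
    rr <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    expect_equal(pruning_loglik(rr, m, model), ll, tolerance = 1e-8)
  }
  # star tree with zero branch lengths and identical sequences
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  alns <- rbind(a = c("A", "C"), b = c("A", "C"), c = c("A", "C"))
  expect_equal(pruning_loglik(star, alns, subst_model("JC")), 2 * log(0.25))
  badt <- tr; badt$edge.length[1] <- NaN
  expect_error(pruning_loglik(badt, m, model), "nonfinite")
})

test_that("gaps and ambiguity codes are missing data in the likelihood", {
  tr <- ape::read.tree(text = "(x:0.1,y:0.1);")
  aln1 <- rbind(x = c("A", "N"), y = c("A", "-"))
  aln2 <- rbind(x = c("A"), y = c("A"))
  ll_gap_only <- pruning_loglik(tr, rbind(x = "N", y = "-"), subst_model("JC"))
  expect_equal(ll_gap_only, 0)   # fully missing site contributes nothing
  expect_equal(pruning_loglik(tr, aln1, subst_model("JC")),
               pruning_loglik(tr, aln2, subst_model("JC")))
})

test_that("model selection respects nesting and recovers kappa", {
  set.seed(14)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 0.25)
  # composition-skewed HKY data: empirical frequencies pay off, so the
  # HKY likelihood dominates the JC one at the optima
  for (kappa in c(2, 4, 8)) {
    hats <- vapply(1:5, function(r) {
      set.seed(1000 * kappa + r)
      dat <- phangorn::simSeq(tr, l = 5000, Q = c(1, kappa, 1, 1, kappa, 1),
                              bf = c(.35, .15, .15, .35))
      m <- toupper(as.character(dat))
      s <- select_model(m, nj_tree(dist_jc(m)))
      expect_gte(s$fits$HKY$logL, s$fits$JC$logL - 1e-6)
      expect_equal(s$best, "HKY")
      s$fits$HKY$kappa
    }, numeric(1))
    expect_lt(max(abs(hats - kappa) / kappa), 0.15)
  }
})

test_that("outgroup rooting splits the pendant edge and preserves bipartitions", {
  tr <- parse_newick("(A:1,(B:2,C:3):4);")
  r <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(r))
  root_edges <- which(r$edge[, 1] == length(r$tip.label) + 1L)
  expect_equal(r$edge.length[root_edges], c(2.5, 2.5))
  expect_error(root_with_outgroup(tr, "Z"), "unknown leaf")

  set.seed(7)
  for (rep in 1:5) {
    tr <- ape::rtree(8, rooted = FALSE)
    leaf <- sample(tr$tip.label, 1)
    r <- root_with_outgroup(tr, leaf)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(r), tr)), 0)
  }
})

test_that("tree comparison reports RF distance and leaf associations", {
  t1 <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(compare_trees(t1, t1)$rf, 0)
  t2 <- parse_newick("((a:1,c:1):1,(b:1,d:1):1);")
  cmp <- compare_trees(t1, t2)
  expect_equal(cmp$rf, 2L)
  expect_equal(cmp$max_rf, 2L)
  expect_equal(nrow(cmp$association), 4L)
  t3 <- parse_newick("((a:1,b:1):1,(c:1,e:1):1);")
  expect_error(compare_trees(t1, t3), "mismatch")
  set.seed(8)
  for (rep in 1:5) {
    x <- ape::rtree(7, rooted = FALSE); y <- ape::rtree(7, rooted = FALSE)
    expect_lte(compare_trees(x, y)$rf, 2 * (7 - 3))
  }
})
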