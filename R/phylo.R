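#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - 4p/3)` for an observed proportion `p` of differing
#' sites.
#'
#' @param p proportion of differing sites, `0 <= p < 0.75` (vectorized).
#' @return corrected distance(s).
#' @export
jc_distance <- function(p) {
  if (any(p < 0)) stop("negative proportion")
  if (any(p >= 0.75)) stop("saturated: p >= 0.75 has no JC distance")
  -0.75 * log(1 - 4 * p / 3)
}

# Pairwise site-pattern proportions over sites where both sequences have
# unambiguous bases: P1 (A<->G), P2 (C<->T), Q (transversions).
pair_counts <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ok <- a %in% .BASES & b %in% .BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable sites")
  diff <- a != b
  ag <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A"))
  ct <- diff & ((a == "C" & b == "T") | (a == "T" & b == "C"))
  list(n = n, P1 = sum(ag) / n, P2 = sum(ct) / n,
       Q = sum(diff & !ag & !ct) / n,
       freqs = prop.table(table(factor(c(a, b), levels = .BASES))))
}

#' HKY-style corrected pairwise distance
#'
#' The closed-form distance of the TN93 family evaluated with the two
#' transition classes kept separate (the HKY constraint of a single kappa has
#' no simple exact pairwise formula; this is the standard closed form the
#' distance-based toolchain uses). Reduces to [jc_distance()] when base
#' frequencies are equal and transitions occur at the transversion rate.
#'
#' @param a,b equal-length gapped sequences (strings or character vectors);
#'   sites with gaps or ambiguity in either sequence are skipped.
#' @param freqs optional base frequencies (A, C, G, T); default empirical
#'   from the compared sites.
#' @return corrected distance.
#' @export
hky_distance <- function(a, b, freqs = NULL) {
  pc <- pair_counts(a, b)
  f <- freqs %||% as.numeric(pc$freqs)
  names(f) <- .BASES
  pR <- f["A"] + f["G"]; pY <- f["C"] + f["T"]
  k1 <- 2 * f["A"] * f["G"] / pR
  k2 <- 2 * f["T"] * f["C"] / pY
  k3 <- 2 * (pR * pY - f["A"] * f["G"] * pY / pR - f["T"] * f["C"] * pR / pY)
  w1 <- 1 - pc$P1 / k1 - pc$Q / (2 * pR)
  w2 <- 1 - pc$P2 / k2 - pc$Q / (2 * pY)
  w3 <- 1 - pc$Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    stop("saturated: log argument <= 0 in distance correction")
  unname(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
}

# All-pairs site-pattern counts via per-base indicator cross-products (BLAS),
# so bootstrap replicates stay cheap on full-length alignments.
.pattern_counts <- function(alignment) {
  X <- lapply(.BASES, function(b) (alignment == b) * 1)
  names(X) <- .BASES
  ok <- Reduce(`+`, X)
  N_ok <- tcrossprod(ok)
  match <- Reduce(`+`, lapply(X, tcrossprod))
  P1 <- tcrossprod(X$A, X$G); P1 <- P1 + t(P1)
  P2 <- tcrossprod(X$C, X$T); P2 <- P2 + t(P2)
  Q <- N_ok - match - P1 - P2
  list(n = N_ok, P1 = P1, P2 = P2, Q = Q)
}

#' Pairwise JC distance matrix from an alignment
#'
#' Proportions computed with pairwise deletion of gaps/ambiguity.
#'
#' @param alignment character matrix (samples x columns).
#' @return symmetric distance matrix.
#' @export
dist_jc <- function(alignment) {
  pc <- .pattern_counts(alignment)
  if (any(pc$n[upper.tri(pc$n)] == 0)) stop("no comparable sites")
  p <- (pc$P1 + pc$P2 + pc$Q) / pc$n
  diag(p) <- 0
  d <- jc_distance(p)
  dimnames(d) <- list(rownames(alignment), rownames(alignment))
  d
}

#' Pairwise HKY-style distance matrix from an alignment
#'
#' @param alignment character matrix.
#' @param freqs base frequencies; default empirical over the whole alignment.
#' @return symmetric distance matrix.
#' @export
dist_hky <- function(alignment, freqs = NULL) {
  if (is.null(freqs)) {
    tab <- table(factor(alignment[alignment %in% .BASES], levels = .BASES))
    freqs <- as.numeric(prop.table(tab))
  }
  f <- stats::setNames(freqs, .BASES)
  pc <- .pattern_counts(alignment)
  if (any(pc$n[upper.tri(pc$n)] == 0)) stop("no comparable sites")
  P1 <- pc$P1 / pc$n; P2 <- pc$P2 / pc$n; Q <- pc$Q / pc$n
  pR <- f["A"] + f["G"]; pY <- f["C"] + f["T"]
  k1 <- 2 * f["A"] * f["G"] / pR
  k2 <- 2 * f["T"] * f["C"] / pY
  k3 <- 2 * (pR * pY - f["A"] * f["G"] * pY / pR - f["T"] * f["C"] * pR / pY)
  w1 <- 1 - P1 / k1 - Q / (2 * pR)
  w2 <- 1 - P2 / k2 - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  if (any(w1[upper.tri(w1)] <= 0) || any(w2[upper.tri(w2)] <= 0) ||
      any(w3[upper.tri(w3)] <= 0))
    stop("saturated: log argument <= 0 in distance correction")
  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  diag(d) <- 0
  dimnames(d) <- list(rownames(alignment), rownames(alignment))
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically by cluster label order (a cluster is labelled by
#' its alphabetically first leaf). Negative branch lengths arising from the
#' estimation formulas are clamped to 0 with the deficit moved to the sister
#' branch, preserving the path length between the joined clusters.
#'
#' @param dmat symmetric distance matrix with >= 3 labelled taxa.
#' @return unrooted tree of class `phylo`.
#' @export
nj_tree <- function(dmat) {
  dmat <- .check_dmat(dmat)
  n <- nrow(dmat)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(dmat)
  frag <- labels                      # newick fragment per active cluster
  key <- labels                       # tie-break label (first leaf)
  d <- dmat
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(d) > 3L) {
    nn <- nrow(d)
    r <- rowSums(d)
    Qm <- (nn - 2) * d - outer(r, r, `+`)
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1L, function(ij)
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r"))
    pick <- cand[order(pair_keys)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    new_key <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
    dimnames(d2) <- NULL
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(v[1]), frag[2], fmt(v[2]),
                 frag[3], fmt(v[3]))
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One canonical key per internal edge: the leaf set on the side not
#' containing the alphabetically first leaf, sorted and comma-joined.
#'
#' @param tree a `phylo`.
#' @return named character vector of keys; names are the child node numbers
#'   of the defining edges.
#' @export
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)       # clades as tip index sets
  keys <- character(0)
  for (k in seq_along(parts)) {
    node <- ntip + k
    tips <- tree$tip.label[parts[[k]]]
    if (length(tips) < 2L || length(tips) > ntip - 2L) next
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys[as.character(node)] <- paste(sort(side), collapse = ",")
  }
  keys
}

#' Column-bootstrap supports for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate with `distance_fn`, and maps the percentage of replicates
#' containing each internal bipartition of the full-data tree onto that
#' tree's node labels.
#'
#' @param alignment character matrix.
#' @param distance_fn function(alignment matrix) -> distance matrix
#'   (e.g. [dist_jc()], [dist_hky()], [indelblock_dist_matrix()]).
#' @param n_reps bootstrap replicates.
#' @param seed integer seed; fixed seed implies identical supports.
#' @return the full-data `phylo` tree with `node.label` holding supports
#'   (0-100, empty for the root) and attribute `supports` keyed by
#'   bipartition.
#' @export
bootstrap_support <- function(alignment, distance_fn = dist_jc,
                              n_reps = 1000L, seed = 1L) {
  full <- nj_tree(distance_fn(alignment))
  bips <- tree_bipartitions(full)
  counts <- stats::setNames(numeric(length(bips)), bips)
  done <- 0L
  with_seed(seed, {
    attempts <- 0L
    while (done < n_reps && attempts < 4L * n_reps) {
      attempts <- attempts + 1L
      idx <- sample.int(ncol(alignment), replace = TRUE)
      rep_tree <- tryCatch(nj_tree(distance_fn(alignment[, idx, drop = FALSE])),
                           error = function(e) NULL)
      if (is.null(rep_tree)) next   # e.g. saturated replicate distances
      done <- done + 1L
      hit <- bips %in% tree_bipartitions(rep_tree)
      counts[hit] <- counts[hit] + 1
    }
  })
  if (done < n_reps) warning("only ", done, " of ", n_reps, " replicates usable")
  support <- 100 * counts / max(done, 1L)
  ntip <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  for (node_chr in names(bips)) {
    node <- as.integer(node_chr)
    labs[node - ntip] <- sprintf("%g", round(support[[bips[[node_chr]]]]))
  }
  full$node.label <- labs
  attr(full, "supports") <- support
  full
}

#' Nucleotide substitution model (JC or HKY)
#'
#' Builds the reversible rate matrix, normalized to one expected substitution
#' per unit branch length, with its eigendecomposition cached for transition
#' probabilities.
#'
#' @param name `"JC"` or `"HKY"`.
#' @param kappa transition/transversion rate ratio (HKY; > 0).
#' @param freqs base frequencies A, C, G, T (HKY; sum to 1).
#' @return object of class `subst_model`; `n_free` is 0 for JC and 4 for HKY
#'   (kappa + 3 free frequencies).
#' @export
subst_model <- function(name = c("JC", "HKY"), kappa = 1,
                        freqs = rep(0.25, 4)) {
  name <- match.arg(name)
  if (name == "JC") { kappa <- 1; freqs <- rep(0.25, 4) }
  stopifnot(kappa > 0, length(freqs) == 4, all(freqs > 0),
            abs(sum(freqs) - 1) < 1e-8)
  freqs <- stats::setNames(as.numeric(freqs) / sum(freqs), .BASES)
  Q <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  for (i in .BASES) for (j in .BASES) if (i != j)
    Q[i, j] <- freqs[j] * if (is_transition(i, j)) kappa else 1
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  sq <- sqrt(freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(name = name, kappa = kappa, freqs = freqs, Q = Q,
                 values = eig$values,
                 V = diag(1 / sq) %*% eig$vectors,
                 Vi = t(eig$vectors) %*% diag(sq),
                 n_free = if (name == "JC") 0L else 4L),
            class = "subst_model")
}

#' Transition probability matrix P(t) of a substitution model
#' @param model a `subst_model`.
#' @param t branch length (expected substitutions per site).
#' @return 4x4 matrix, rows = ancestral base.
#' @export
transition_probs <- function(model, t) {
  P <- model$V %*% (exp(model$values * t) * model$Vi)
  dimnames(P) <- list(.BASES, .BASES)
  # guard tiny negative entries from round-off
  P[P < 0] <- 0
  P
}

#' Felsenstein pruning log-likelihood
#'
#' Sums per-site log-likelihoods over the tree under the model's transition
#' probabilities. Gap, `N` and ambiguity characters are missing data at the
#' tip (partial likelihood 1 for every base). Site patterns are compressed;
#' per-node rescaling guards against underflow.
#'
#' @param tree a `phylo` with branch lengths (rooted or unrooted; an unrooted
#'   tree is evaluated at its basal multifurcation, which by reversibility
#'   and the pulley principle does not affect the result).
#' @param alignment character matrix whose rownames cover the tip labels.
#' @param model a `subst_model`.
#' @return total log-likelihood.
#' @export
pruning_loglik <- function(tree, alignment, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"))
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("nonfinite branch length")
  if (!all(tree$tip.label %in% rownames(alignment)))
    stop("alignment is missing tips: ",
         paste(setdiff(tree$tip.label, rownames(alignment)), collapse = ","))
  aln <- alignment[tree$tip.label, , drop = FALSE]
  keys <- apply(aln, 2L, paste, collapse = "")
  upat <- unique(keys)
  wt <- as.numeric(table(keys)[upat])
  pat <- aln[, match(upat, keys), drop = FALSE]
  npat <- ncol(pat)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  partial <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    Lt <- matrix(0, npat, 4)
    x <- pat[i, ]
    for (b in seq_along(.BASES)) Lt[x == .BASES[b], b] <- 1
    Lt[!(x %in% .BASES), ] <- 1
    partial[[i]] <- Lt
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]; child <- po$edge[k, 2]
    P <- transition_probs(model, po$edge.length[k])
    contrib <- partial[[child]] %*% t(P)
    if (is.null(partial[[parent]])) partial[[parent]] <- contrib
    else partial[[parent]] <- partial[[parent]] * contrib
  }
  root <- po$edge[nrow(po$edge), 1]
  lik <- as.numeric(partial[[root]] %*% model$freqs)
  if (any(lik <= 0)) return(-Inf)
  sum(wt * log(lik))
}

.scale_tree <- function(tree, s) { tree$edge.length <- tree$edge.length * s; tree }

#' Fit JC and HKY and select a substitution model by AIC
#'
#' Both models are fitted on the fixed NJ topology by maximizing the pruning
#' log-likelihood over a single global branch-length scale (and, for HKY,
#' kappa, by coordinate golden-section search to tolerance 1e-6, with
#' empirical base frequencies). Selection is by `AIC = 2k - 2 logL` with k =
#' 0 (JC) and 4 (HKY).
#'
#' @param alignment character matrix.
#' @param tree a `phylo` with branch lengths, typically from [nj_tree()].
#' @param max_iter maximum coordinate-descent rounds before the fit is
#'   flagged unconverged.
#' @return list: `best` ("JC"/"HKY"), `fits` (per-model logL, AIC, kappa,
#'   scale), `delta_aic` (AIC_JC - AIC_HKY), `converged`.
#' @export
select_model <- function(alignment, tree, max_iter = 200L) {
  tab <- table(factor(alignment[alignment %in% .BASES], levels = .BASES))
  freqs <- as.numeric(prop.table(tab))

  opt_scale <- function(model) {
    o <- stats::optimize(function(ls) -pruning_loglik(.scale_tree(tree, exp(ls)),
                                                      alignment, model),
                         c(log(1e-4), log(100)), tol = 1e-6)
    list(scale = exp(o$minimum), logL = -o$objective)
  }

  jc <- opt_scale(subst_model("JC"))
  fit_jc <- list(model = "JC", logL = jc$logL, k = 0L,
                 aic = 2 * 0 - 2 * jc$logL, kappa = NA_real_, scale = jc$scale)

  kappa <- 2; scale <- jc$scale; logL <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- subst_model("HKY", kappa, freqs)
    sc <- opt_scale(m)
    scale <- sc$scale
    ko <- stats::optimize(function(lk)
      -pruning_loglik(.scale_tree(tree, scale), alignment,
                      subst_model("HKY", exp(lk), freqs)),
      c(log(0.02), log(500)), tol = 1e-6)
    kappa <- exp(ko$minimum)
    newL <- -ko$objective
    if (is.finite(logL) && abs(newL - logL) < 1e-6) { logL <- newL; converged <- TRUE; break }
    logL <- newL
  }
  fit_hky <- list(model = "HKY", logL = logL, k = 4L, aic = 2 * 4 - 2 * logL,
                  kappa = kappa, scale = scale)

  best <- if (fit_jc$aic <= fit_hky$aic) "JC" else "HKY"
  list(best = best, fits = list(JC = fit_jc, HKY = fit_hky),
       delta_aic = fit_jc$aic - fit_hky$aic, converged = converged,
       freqs = stats::setNames(freqs, .BASES))
}

#' Root a tree on an outgroup leaf
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree an unrooted `phylo`.
#' @param leaf outgroup tip label.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, leaf) {
  if (!leaf %in% tree$tip.label) stop("unknown leaf: ", leaf)
  ro <- ape::root(ape::unroot(tree), outgroup = leaf, resolve.root = TRUE)
  root <- length(ro$tip.label) + 1L
  re <- which(ro$edge[, 1] == root)
  pend <- sum(ro$edge.length[re])
  ro$edge.length[re] <- pend / 2
  ro
}

#' Compare two trees on the same leaf set
#'
#' Robinson-Foulds distance (number of bipartitions present in exactly one
#' tree) plus the leaf association table used for tanglegram-style displays.
#'
#' @param t1,t2 `phylo` trees with identical leaf sets.
#' @return list: `rf` (integer), `max_rf` (= 2(n-3)), `association`
#'   (data.frame with one row per shared leaf).
#' @export
compare_trees <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf-set mismatch between trees")
  rf <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2), check.labels = TRUE)
  n <- length(t1$tip.label)
  list(rf = rf, max_rf = 2L * (n - 3L),
       association = data.frame(left = sort(t1$tip.label),
                                right = sort(t1$tip.label),
                                stringsAsFactors = FALSE))
}
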