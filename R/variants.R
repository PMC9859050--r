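#' Reference positions of alignment columns
#'
#' For every alignment column, the 1-based position of the reference base at
#' or before that column (0 before the first reference base). Columns where
#' the reference is gapped map to the preceding reference base.
#'
#' @param alignment character matrix from [read_alignment()].
#' @param reference_id row name of the designated reference sample.
#' @return integer vector of length `ncol(alignment)`.
#' @export
reference_positions <- function(alignment, reference_id) {
  if (!reference_id %in% rownames(alignment))
    stop("unknown reference: ", reference_id)
  cumsum(alignment[reference_id, ] != "-")
}

#' Project an alignment column onto the reference coordinate system
#'
#' @inheritParams reference_positions
#' @param column 1-based alignment column index (vectorized).
#' @return integer reference position(s).
#' @export
project_to_reference <- function(alignment, reference_id, column) {
  if (any(column < 1L | column > ncol(alignment)))
    stop("out of range: column outside alignment")
  reference_positions(alignment, reference_id)[column]
}

#' Trim the second inverted-repeat copy from a plastome alignment
#'
#' Removes every alignment column whose reference position falls inside the
#' later-starting of the two annotated IR copies, so the duplicated repeat is
#' counted once. With no IR features the alignment is returned unchanged.
#'
#' @inheritParams reference_positions
#' @param features reference features; must contain 0 or 2 rows of type `IR`.
#' @return the column-filtered alignment matrix.
#' @export
trim_second_ir <- function(alignment, features, reference_id) {
  ir <- features[features$type == "IR", , drop = FALSE]
  if (nrow(ir) == 0L) return(alignment)
  if (nrow(ir) != 2L) stop("unpaired IR: expected exactly 0 or 2 IR features")
  second <- ir[which.max(ir$start), ]
  pos <- reference_positions(alignment, reference_id)
  keep <- !(pos >= second$start & pos <= second$end)
  alignment[, keep, drop = FALSE]
}

.BASES <- c("A", "C", "G", "T")

# Per-column base counts (4 x L), gaps/N/ambiguity excluded.
.base_counts <- function(alignment) {
  out <- matrix(0L, 4L, ncol(alignment), dimnames = list(.BASES, NULL))
  for (b in .BASES) out[b, ] <- colSums(alignment == b)
  out
}

.empty_variants <- function(samples) {
  variant_table(data.frame(ref_position = integer(), col_start = integer(),
                           col_end = integer(), type = character(),
                           ref_allele = character(), alt_alleles = character(),
                           alt_count = integer(), stringsAsFactors = FALSE),
                matrix(character(), 0, length(samples),
                       dimnames = list(NULL, samples)))
}

#' Call SNPs from a multiple alignment
#'
#' One variant per column carrying at least two distinct bases among A/C/G/T.
#' Gaps, `N` and IUPAC ambiguity codes are missing data: excluded from allele
#' counts and never called as alternate. Multiallelic columns yield a single
#' variant with all alternate alleles retained. Alternate alleles are counted
#' against the majority base (ties broken in favour of the reference base,
#' then alphabetically).
#'
#' @inheritParams reference_positions
#' @param min_alt_count suppress variants carried by fewer samples.
#' @return a `variant_table` (SNP genotypes are bases; missing data is `N`).
#' @export
call_snps <- function(alignment, reference_id, min_alt_count = 1L) {
  if (!reference_id %in% rownames(alignment))
    stop("unknown reference: ", reference_id)
  counts <- .base_counts(alignment)
  refpos <- reference_positions(alignment, reference_id)
  cand <- which(colSums(counts > 0) >= 2L)
  core <- list(); gts <- list()
  for (col in cand) {
    bases <- alignment[, col]
    present <- counts[, col]
    ref_base <- alignment[reference_id, col]
    top <- max(present)
    tied <- .BASES[present == top]
    major <- if (ref_base %in% tied) ref_base else tied[1]
    alts <- .BASES[present > 0 & .BASES != major]
    alt_count <- sum(present[.BASES != major])
    if (alt_count < min_alt_count) next
    gt <- ifelse(bases %in% .BASES, bases, "N")
    core[[length(core) + 1L]] <- data.frame(
      ref_position = refpos[col], col_start = col, col_end = col,
      type = "SNP", ref_allele = if (ref_base %in% .BASES) ref_base else "-",
      alt_alleles = paste(alts, collapse = ","),
      alt_count = alt_count, stringsAsFactors = FALSE)
    gts[[length(gts) + 1L]] <- gt
  }
  if (!length(core)) return(.empty_variants(rownames(alignment)))
  gt <- do.call(rbind, gts)
  colnames(gt) <- rownames(alignment)
  variant_table(do.call(rbind, core), gt)
}

#' Call InDel events from a multiple alignment
#'
#' Gap-containing columns are grouped into events: an InDel event is a maximal
#' run of contiguous columns sharing an identical per-sample gap/base pattern,
#' and contributes exactly one variant regardless of length (simple indel
#' coding / indel-block semantics). Samples are scored `-` (gap block present)
#' or `+` (bases present); the alternate state is the minority one. The
#' reference position is the last reference base before the block.
#'
#' @inheritParams reference_positions
#' @param min_alt_count suppress events whose minority state has fewer samples.
#' @return a `variant_table`.
#' @export
call_indels <- function(alignment, reference_id, min_alt_count = 1L) {
  if (!reference_id %in% rownames(alignment))
    stop("unknown reference: ", reference_id)
  gap <- alignment == "-"
  if (any(colSums(!gap) == 0L))
    stop("null column: alignment contains an all-gap column")
  refpos <- reference_positions(alignment, reference_id)
  has_gap <- which(colSums(gap) > 0L)
  if (!length(has_gap)) return(.empty_variants(rownames(alignment)))
  pattern <- apply(gap[, has_gap, drop = FALSE], 2L,
                   function(x) paste(which(x), collapse = ","))
  new_block <- c(TRUE, diff(has_gap) != 1L | pattern[-1] != pattern[-length(pattern)])
  block_id <- cumsum(new_block)
  core <- list(); gts <- list()
  for (b in unique(block_id)) {
    cols <- has_gap[block_id == b]
    col_start <- cols[1]; col_end <- cols[length(cols)]
    gapped <- gap[, col_start]
    n_gap <- sum(gapped); n_base <- nrow(alignment) - n_gap
    alt_state <- if (n_gap <= n_base) "-" else "+"
    alt_count <- min(n_gap, n_base)
    if (alt_count < min_alt_count) next
    ref_gapped <- gap[reference_id, col_start]
    rp <- if (ref_gapped) refpos[col_start] else refpos[col_start] - 1L
    ref_allele <- if (ref_gapped) "-" else
      paste(alignment[reference_id, col_start:col_end], collapse = "")
    core[[length(core) + 1L]] <- data.frame(
      ref_position = rp, col_start = col_start, col_end = col_end,
      type = "InDel", ref_allele = ref_allele, alt_alleles = alt_state,
      alt_count = alt_count, stringsAsFactors = FALSE)
    gts[[length(gts) + 1L]] <- ifelse(gapped, "-", "+")
  }
  if (!length(core)) return(.empty_variants(rownames(alignment)))
  gt <- do.call(rbind, gts)
  colnames(gt) <- rownames(alignment)
  variant_table(do.call(rbind, core), gt)
}

#' Call SNPs and InDel events together
#'
#' @inheritParams call_snps
#' @return a `variant_table` with both variant types, ordered by position.
#' @export
call_variants <- function(alignment, reference_id, min_alt_count = 1L) {
  snps <- call_snps(alignment, reference_id, min_alt_count)
  indels <- call_indels(alignment, reference_id, min_alt_count)
  out <- rbind(snps, indels)
  out <- out[order(out$ref_position, out$col_start), ]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Compare called variants with a simulation truth table
#'
#' Variants are matched on (type, alignment-column span, affected sample
#' set): for SNPs the set of samples carrying a non-reference base, for InDel
#' events the set of gapped samples.
#'
#' @param variants a `variant_table` called on the true alignment.
#' @param truth a `simulation_truth` (or its `$variants` data.frame).
#' @return list with `recall`, `precision`, and the unmatched keys
#'   (`false_negatives`, `false_positives`).
#' @export
compare_to_truth <- function(variants, truth) {
  tv <- if (inherits(truth, "simulation_truth")) truth$variants else truth
  truth_keys <- vapply(seq_len(nrow(tv)), function(i) {
    affected <- if (tv$type[i] == "SNP") tv$carriers[i] else tv$gapped_samples[i]
    paste(tv$type[i], tv$col_start[i], tv$col_end[i], affected, sep = "|")
  }, character(1))
  gt <- variant_genotypes(variants)
  called_keys <- vapply(seq_len(nrow(variants)), function(i) {
    if (variants$type[i] == "SNP") {
      ref <- variants$ref_allele[i]
      affected <- colnames(gt)[gt[i, ] != ref & gt[i, ] != "N"]
    } else {
      affected <- colnames(gt)[gt[i, ] == "-"]
    }
    paste(variants$type[i], variants$col_start[i], variants$col_end[i],
          paste(sort(affected), collapse = ","), sep = "|")
  }, character(1))
  tp <- sum(called_keys %in% truth_keys)
  list(recall = if (length(truth_keys)) tp / length(truth_keys) else 1,
       precision = if (length(called_keys)) tp / length(called_keys) else 1,
       false_negatives = setdiff(truth_keys, called_keys),
       false_positives = setdiff(called_keys, truth_keys))
}
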