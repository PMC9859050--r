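.PAIR_CLASSES <- data.frame(
  class = c("A<->G", "C<->T", "A<->C", "A<->T", "G<->C", "G<->T"),
  kind = c("transition", "transition", rep("transversion", 4)),
  stringsAsFactors = FALSE)

pair_class <- function(a, b) {
  if (!all(c(a, b) %in% .BASES)) stop("unclassifiable: non-ACGT allele")
  key <- paste(sort(c(a, b)), collapse = "<->")
  # the G/C transversion is conventionally written G<->C
  c("A<->G" = "A<->G", "C<->T" = "C<->T", "A<->C" = "A<->C",
    "A<->T" = "A<->T", "C<->G" = "G<->C", "G<->T" = "G<->T")[[key]]
}

#' Substitution-spectrum breakdown of a SNP table
#'
#' Assigns each biallelic SNP to one of the six unordered base-pair classes
#' (two transitions A<->G, C<->T; four transversions A<->C, A<->T, G<->C,
#' G<->T). A multiallelic SNP contributes one unit split equally over its
#' alternate alleles' classes.
#'
#' @param variants a `variant_table` (only `type == "SNP"` rows are used).
#' @return data.frame of class `spectrum_table`: `class`, `kind`, `count`,
#'   `percent`, plus attributes `n_snps`, `transitions`, `transversions`.
#' @export
tstv_breakdown <- function(variants) {
  snps <- variants[variants$type == "SNP", , drop = FALSE]
  counts <- stats::setNames(numeric(nrow(.PAIR_CLASSES)), .PAIR_CLASSES$class)
  for (i in seq_len(nrow(snps))) {
    alts <- strsplit(snps$alt_alleles[i], ",", fixed = TRUE)[[1]]
    major <- snps$ref_allele[i]
    for (a in alts) {
      cls <- pair_class(major, a)
      counts[cls] <- counts[cls] + 1 / length(alts)
    }
  }
  out <- .PAIR_CLASSES
  out$count <- unname(counts[out$class])
  total <- sum(out$count)
  out$percent <- if (total > 0) 100 * out$count / total else 0
  attr(out, "n_snps") <- total
  attr(out, "transitions") <- sum(out$count[out$kind == "transition"])
  attr(out, "transversions") <- sum(out$count[out$kind == "transversion"])
  class(out) <- c("spectrum_table", "data.frame")
  out
}

#' Reconstruct integer class counts from printed percentages
#'
#' Inverts a rounded percentage breakdown: `round(percent / 100 * total)`.
#'
#' @param percent numeric vector of printed percentages.
#' @param total the printed total count.
#' @return integer vector of class counts.
#' @export
reconstruct_class_counts <- function(percent, total) {
  as.integer(round(percent / 100 * total))
}

#' Per-region variability summary
#'
#' For every region of the inventory, the SNP and InDel counts together with
#' both variability metrics in circulation: `share_of_total`
#' (= (SNP+InDel)/total mutations) and `per_bp_density` (= (SNP+InDel)/region
#' length). Regions are ranked by share.
#'
#' @param variants an annotated `variant_table`.
#' @param inventory a `region_inventory`.
#' @param total_mutations denominator for the share metric (defaults to
#'   `nrow(variants)`; shares are 0 when it is 0).
#' @return data.frame: `region`, `class`, `length`, `snps`, `indels`,
#'   `share_of_total`, `per_bp_density`, sorted by decreasing share.
#' @export
per_region_summary <- function(variants, inventory,
                               total_mutations = nrow(variants)) {
  # multi-exon genes tile as several spans sharing a name: aggregate them
  lens <- stats::aggregate(length ~ name + class, data = inventory, FUN = sum)
  lens <- lens[order(match(lens$name, inventory$name)), ]
  snp <- table(factor(variants$region_name[variants$type == "SNP"],
                      levels = lens$name))
  ind <- table(factor(variants$region_name[variants$type == "InDel"],
                      levels = lens$name))
  out <- data.frame(region = lens$name, class = lens$class,
                    length = lens$length,
                    snps = as.integer(snp), indels = as.integer(ind),
                    stringsAsFactors = FALSE)
  tot <- out$snps + out$indels
  out$share_of_total <- if (total_mutations > 0) tot / total_mutations else 0
  out$per_bp_density <- tot / out$length
  out <- out[order(-out$share_of_total, out$region), ]
  rownames(out) <- NULL
  out
}

#' Within-population polymorphism counts
#'
#' A SNP position (or InDel event) is counted for a population iff its
#' members carry at least two distinct non-missing alleles (or gap states) at
#' it. Populations with a single member cannot be polymorphic and are
#' reported with counts 0 and `flagged = TRUE`.
#'
#' @param variants a `variant_table`.
#' @param popmap named vector sample -> population covering every sample.
#' @return data.frame: `population`, `n_samples`, `snps`, `indels`, `flagged`.
#' @export
per_population_counts <- function(variants, popmap) {
  samples <- variant_samples(variants)
  popmap <- match_population_map(samples, popmap)
  gt <- variant_genotypes(variants)
  pops <- unique(unname(popmap))
  out <- lapply(pops, function(pop) {
    members <- samples[popmap == pop]
    if (length(members) < 2L)
      return(data.frame(population = pop, n_samples = length(members),
                        snps = 0L, indels = 0L, flagged = TRUE,
                        stringsAsFactors = FALSE))
    poly <- vapply(seq_len(nrow(variants)), function(i) {
      g <- gt[i, members]
      g <- g[g != "N"]
      length(unique(g)) >= 2L
    }, logical(1))
    data.frame(population = pop, n_samples = length(members),
               snps = sum(poly & variants$type == "SNP"),
               indels = sum(poly & variants$type == "InDel"),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overall mutation density
#'
#' @param total_mutations total SNP + InDel count.
#' @param dataset_length denominator in bp; the convention (full genome with
#'   both IRs, or trimmed alignment) is the caller's explicit choice.
#' @return mutations per bp.
#' @export
changes_per_bp <- function(total_mutations, dataset_length) {
  if (!is_count(dataset_length) || dataset_length <= 0)
    stop("dataset_length must be a positive integer")
  total_mutations / dataset_length
}
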