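#' Build a complete region inventory from reference features
#'
#' Partitions the reference into an ordered, non-overlapping tiling of exon
#' segments, introns and intergenic spacers. Gene-level features are `gene`,
#' `tRNA` and `rRNA` rows; `CDS`/`tRNA`/`rRNA` rows sharing a gene's name and
#' lying inside its span are its exon segments, and the within-gene gaps
#' between consecutive segments become introns. Everything outside genes is an
#' intergenic spacer named `"geneA--geneB"` from its flanking genes along the
#' forward strand (with `ter` standing in for the molecule ends).
#'
#' @param features data.frame from [read_features()]. `IR` features are ignored
#'   here (they are handled by [trim_second_ir()]).
#' @param reference_length length of the (possibly IR-trimmed) reference.
#' @return data.frame of class `region_inventory` with columns `name`, `class`
#'   (exon/intron/intergenic), `start`, `end`, `length`, and for exon/intron
#'   rows the owning `gene`.
#' @export
build_region_inventory <- function(features, reference_length) {
  stopifnot(is_count(reference_length), reference_length >= 1)
  features <- features[features$end <= reference_length, , drop = FALSE]
  genes <- features[features$type %in% c("gene", "tRNA", "rRNA"), , drop = FALSE]
  # standalone tRNA/rRNA rows count as gene-level unless nested in a gene span
  if (nrow(genes) > 1) {
    gene_rows <- genes$type == "gene"
    nested <- vapply(seq_len(nrow(genes)), function(i) {
      if (gene_rows[i]) return(FALSE)
      any(gene_rows & genes$start <= genes$start[i] & genes$end >= genes$end[i] &
            genes$name != genes$name[i])
    }, logical(1))
    genes <- genes[!nested, , drop = FALSE]
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  if (nrow(genes) > 1 && any(genes$start[-1] <= genes$end[-nrow(genes)]))
    stop("ambiguous annotation: overlapping genes")

  rows <- list()
  add <- function(name, class, start, end, gene = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, class = class, start = start, end = end,
      length = end - start + 1L, gene = gene, stringsAsFactors = FALSE)
  }
  spacer <- function(left, right, start, end) {
    if (end >= start) add(paste0(left, "--", right), "intergenic", start, end)
  }

  prev_end <- 0L
  prev_name <- "ter"
  segments_of <- function(g) {
    seg <- features[features$type %in% c("CDS", "tRNA", "rRNA") &
                      features$name == g$name &
                      features$start >= g$start & features$end <= g$end, ,
                    drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (!nrow(seg) || g$type != "gene")
      seg <- data.frame(name = g$name, type = g$type, start = g$start,
                        end = g$end, strand = g$strand, stringsAsFactors = FALSE)
    seg
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    spacer(prev_name, g$name, prev_end + 1L, g$start - 1L)
    seg <- segments_of(g)
    if (seg$start[1] > g$start || seg$end[nrow(seg)] < g$end)
      stop("ambiguous annotation: exon segments do not span gene ", g$name)
    n_intron <- 0L
    for (j in seq_len(nrow(seg))) {
      add(g$name, "exon", seg$start[j], seg$end[j], g$name)
      if (j < nrow(seg)) {
        n_intron <- n_intron + 1L
        iname <- if (nrow(seg) > 2) paste0(g$name, " intron ", n_intron)
                 else paste0(g$name, " intron")
        add(iname, "intron", seg$end[j] + 1L, seg$start[j + 1L] - 1L, g$name)
      }
    }
    prev_end <- g$end
    prev_name <- g$name
  }
  spacer(prev_name, "ter", prev_end + 1L, reference_length)
  inv <- do.call(rbind, rows)
  if (sum(inv$length) != reference_length || any(inv$start[-1] != inv$end[-nrow(inv)] + 1L))
    stop("internal error: inventory does not tile the reference")  # nocov
  rownames(inv) <- NULL
  class(inv) <- c("region_inventory", "data.frame")
  inv
}

#' Locate a reference position in a region inventory
#'
#' @param position integer vector of 1-based reference positions. An InDel
#'   block is located by its first reference base.
#' @param inventory a `region_inventory`.
#' @return data.frame with `region_name` and `region_type` per position.
#' @export
locate_variant <- function(position, inventory) {
  if (any(position < 1L | position > inventory$end[nrow(inventory)]))
    stop("out of range: position outside reference")
  idx <- findInterval(position, inventory$start)
  data.frame(region_name = inventory$name[idx],
             region_type = inventory$class[idx],
             stringsAsFactors = FALSE)
}

#' Genetic code tables by organelle
#'
#' @param code `"plastid"` (NCBI translation table 11), `"mito"` (plant
#'   mitochondria use the standard code, table 1), or an NCBI table id.
#' @return named character vector mapping codons to amino acids.
#' @export
genetic_code <- function(code = "plastid") {
  id <- switch(code, plastid = "11", mito = "1", code)
  Biostrings::getGeneticCode(id)
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  out <- unname(comp[rev(x)])
  out[is.na(out)] <- "N"
  out
}

# Spliced CDS of a gene: exon segments concatenated 5'->3' (minus strand
# reverse-complemented), plus the spliced coordinate of each genomic position.
spliced_cds <- function(gene_name, features, ref_chars) {
  seg <- features[features$type == "CDS" & features$name == gene_name, , drop = FALSE]
  if (!nrow(seg)) return(NULL)
  seg <- seg[order(seg$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(seg)), function(j) seg$start[j]:seg$end[j]))
  strand <- seg$strand[1]
  if (strand == "-") pos <- rev(pos)
  bases <- ref_chars[pos]
  if (strand == "-") bases <- unname(c(A = "T", C = "G", G = "C", T = "A")[bases])
  list(positions = pos, bases = bases, strand = strand)
}

#' Classify a coding SNP as synonymous or nonsynonymous
#'
#' Translates the reference and alternate codon of the spliced CDS (exons
#' concatenated, minus-strand genes reverse-complemented) under the configured
#' genetic code. SNPs outside any CDS — including tRNA/rRNA genes and introns —
#' are `"noncoding"`. A SNP creating or destroying a stop codon is reported
#' nonsynonymous with attribute `stop_involved`.
#'
#' @param position 1-based reference position of the SNP.
#' @param ref_base,alt_base reference and alternate bases (forward strand).
#' @param features reference features including `CDS` rows.
#' @param reference reference sequence (string or character vector).
#' @param code genetic code selector, see [genetic_code()].
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"noncoding"`.
#' @export
snp_effect <- function(position, ref_base, alt_base, features, reference,
                       code = "plastid") {
  ref_chars <- if (length(reference) == 1L) strsplit(reference, "")[[1]] else reference
  cds_genes <- unique(features$name[features$type == "CDS" &
                                      features$start <= position &
                                      features$end >= position])
  if (!length(cds_genes)) return("noncoding")
  gc_tab <- genetic_code(code)
  cds <- spliced_cds(cds_genes[1], features, ref_chars)
  if (length(cds$bases) %% 3L != 0L)
    stop("frame error: spliced CDS of ", cds_genes[1], " not divisible by 3")
  i <- match(position, cds$positions)
  base_ref <- ref_base
  base_alt <- alt_base
  if (cds$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    base_ref <- unname(comp[base_ref]); base_alt <- unname(comp[base_alt])
  }
  if (is.na(i) || unname(cds$bases[i]) != base_ref)
    stop("reference mismatch at position ", position, " in ", cds_genes[1])
  codon_idx <- (i - 1L) %/% 3L
  codon <- cds$bases[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)]
  codon_alt <- codon
  codon_alt[i - codon_idx * 3L] <- base_alt
  aa_ref <- unname(gc_tab[paste(codon, collapse = "")])
  aa_alt <- unname(gc_tab[paste(codon_alt, collapse = "")])
  if (is.na(aa_ref) || is.na(aa_alt)) return("noncoding")
  out <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
  if (xor(aa_ref == "*", aa_alt == "*")) attr(out, "stop_involved") <- TRUE
  out
}

#' Annotate a variant table with genomic context and coding effect
#'
#' Fills `region_name`, `region_type` and `effect` for every variant. InDel
#' blocks straddling a region boundary are assigned to the region containing
#' their first reference base. SNP effects are computed by [snp_effect()];
#' InDels and noncoding SNPs get effect `"noncoding"`.
#'
#' @param variants a `variant_table`.
#' @param features reference features.
#' @param reference reference sequence (IR-trimmed if the variants are).
#' @param code genetic code selector.
#' @param inventory optional precomputed `region_inventory`.
#' @return the annotated `variant_table`.
#' @export
annotate_variants <- function(variants, features, reference, code = "plastid",
                              inventory = NULL) {
  ref_chars <- if (length(reference) == 1L) strsplit(reference, "")[[1]] else reference
  if (is.null(inventory))
    inventory <- build_region_inventory(features, length(ref_chars))
  if (!nrow(variants)) return(variants)
  pos <- pmax(variants$ref_position, 1L)
  loc <- locate_variant(pos, inventory)
  variants$region_name <- loc$region_name
  variants$region_type <- loc$region_type
  effects <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    if (variants$type[i] != "SNP" || loc$region_type[i] != "exon") {
      effects[i] <- "noncoding"
      next
    }
    alts <- strsplit(variants$alt_alleles[i], ",", fixed = TRUE)[[1]]
    eff <- vapply(alts, function(a)
      as.character(snp_effect(variants$ref_position[i], variants$ref_allele[i],
                              a, features, ref_chars, code)), character(1))
    effects[i] <- if (any(eff == "nonsynonymous")) "nonsynonymous"
                  else if (any(eff == "synonymous")) "synonymous" else "noncoding"
  }
  variants$effect <- effects
  variants
}
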