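# Shared fixture builders: everything is generated in code at test time.

write_fasta_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

char_aln <- function(...) {
  seqs <- c(...)
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

# minimal feature table in the reader's output shape
feat <- function(name, type, start, end, strand = "+") {
  data.frame(name = name, type = type, start = as.integer(start),
             end = as.integer(end), strand = strand, stringsAsFactors = FALSE)
}

# two-gene reference with a spacer, used across annotate tests:
#   pos 1..10 spacer(ter--g1), 11..40 g1(+, single CDS), 41..60 spacer(g1--g2),
#   61..120 g2(+, 2 exons 61..90 / 106..120, intron 91..105), 121..140 trailing
two_gene_features <- function() {
  rbind(feat("g1", "gene", 11, 40), feat("g1", "CDS", 11, 40),
        feat("g2", "gene", 61, 120), feat("g2", "CDS", 61, 90),
        feat("g2", "CDS", 106, 120))
}

# deterministic random variant table for round-trip checks
random_variant_table <- function(n, samples = c("s1", "s2", "s3")) {
  core <- data.frame(
    ref_position = sort(sample.int(1000, n)),
    col_start = integer(n), col_end = integer(n),
    type = sample(c("SNP", "InDel"), n, TRUE),
    ref_allele = sample(c("A", "C", "G", "T"), n, TRUE),
    alt_alleles = sample(c("A", "C", "G,T", "T"), n, TRUE),
    alt_count = sample.int(3, n, TRUE),
    region_name = sample(c("g1", "g1--g2"), n, TRUE),
    region_type = sample(c("exon", "intergenic"), n, TRUE),
    effect = sample(c("synonymous", "noncoding"), n, TRUE),
    stringsAsFactors = FALSE)
  core$col_start <- core$ref_position
  core$col_end <- core$col_start + ifelse(core$type == "InDel", 2L, 0L)
  gt <- matrix(sample(c("A", "C", "G", "T", "-", "+"), n * length(samples), TRUE),
               nrow = n, dimnames = list(NULL, samples))
  variant_table(core, gt)
}
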