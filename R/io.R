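#' Read a gapped multi-FASTA alignment
#'
#' Reads an aligned multi-FASTA (as produced by MAFFT or similar) into a
#' character matrix with one row per sample and one column per alignment
#' column. Sequences are uppercased and RNA `U` is converted to `T`. Gaps are
#' `-`; `N` and IUPAC ambiguity codes are retained but treated as missing data
#' by all downstream callers.
#'
#' @param path path to a FASTA file.
#' @return character matrix (samples x columns); rownames are the first
#'   whitespace-delimited token of each FASTA header.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC-GT", ">b", "ACAGT"), f)
#' aln <- read_alignment(f)
#' dim(aln)
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no records in ", path)
  if (length(seqs) < 2L) stop("alignment requires at least two records")
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate sample id: ", ids[duplicated(ids)][1])
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop("ragged alignment: records have unequal lengths")
  chars <- toupper(as.character(seqs))
  chars <- gsub("U", "T", chars, fixed = TRUE)
  m <- do.call(rbind, strsplit(chars, "", fixed = TRUE))
  rownames(m) <- ids
  bad <- setdiff(unique(as.vector(m)), IUPAC_CHARS)
  if (length(bad)) stop("invalid character in alignment: ", paste(bad, collapse = " "))
  m
}

#' Write an alignment (or ungapped sequences) to FASTA
#'
#' @param x character matrix (samples x columns) or named character vector of
#'   sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  if (is.matrix(x)) x <- apply(x, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  invisible(path)
}

FEATURE_TYPES <- c("gene", "CDS", "tRNA", "rRNA", "intron", "IR", "intergenic")

# GFF3 type-column synonyms mapped into the internal vocabulary.
.gff_type_map <- c(
  gene = "gene", CDS = "CDS", exon = "CDS", tRNA = "tRNA", rRNA = "rRNA",
  intron = "intron", IR = "IR", inverted_repeat = "IR", repeat_region = "IR",
  intergenic = "intergenic", intergenic_region = "intergenic"
)

#' Read reference features from a GFF3-subset file
#'
#' Parses the 9-column tab-separated GFF3 subset used throughout the pipeline
#' (seqid, source, type, start, end, score, strand, phase, attributes).
#' Coordinates are 1-based inclusive. Feature names are taken from the `Name`
#' attribute, falling back to `ID`.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `name`, `type`, `start`, `end`, `strand`,
#'   sorted by `start`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(data.frame(name = character(), type = character(),
                                        start = integer(), end = integer(),
                                        strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) stop("malformed feature: expected 9 tab-separated columns")
  g <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(g) <- c("seqid", "source", "type", "start", "end", "score", "strand",
                "phase", "attributes")
  start <- suppressWarnings(as.integer(g$start))
  end <- suppressWarnings(as.integer(g$end))
  if (anyNA(start) || anyNA(end) || any(start < 1L))
    stop("malformed feature: non-numeric or non-positive coordinates")
  if (any(end < start)) stop("malformed feature: end < start")
  if (!all(g$strand %in% c("+", "-", "."))) stop("bad strand")
  type <- .gff_type_map[g$type]
  if (anyNA(type)) stop("unknown feature type: ", g$type[is.na(type)][1])
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
  }
  name <- attr_field(g$attributes, "Name")
  id <- attr_field(g$attributes, "ID")
  name <- ifelse(is.na(name), id, name)
  out <- data.frame(name = name, type = unname(type), start = start, end = end,
                    strand = g$strand, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write features to a GFF3-subset file
#'
#' @param features data.frame as returned by [read_features()].
#' @param path output path.
#' @param seqid sequence identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, seqid = "ref") {
  lines <- sprintf("%s\torganvar\t%s\t%d\t%d\t.\t%s\t.\tName=%s",
                   seqid, features$type, features$start, features$end,
                   features$strand, features$name)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Reads a TSV with sample ids in the first column and population ids in the
#' second. A header line is detected (and skipped) when the first field reads
#' like a column name ("sample", "id", ...).
#'
#' @param path path to the TSV.
#' @return named character vector: `popmap[sample_id] == population_id`.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("population map needs at least two columns")
  if (grepl("^(sample|id|individual)", tab[1, 1], ignore.case = TRUE))
    tab <- tab[-1, , drop = FALSE]
  if (any(!nzchar(tab[[2]]))) stop("empty population id")
  if (anyDuplicated(tab[[1]])) stop("duplicate sample in population map")
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Check that every sample of an alignment is mapped to a population
#'
#' @param samples character vector of sample ids (or an alignment matrix).
#' @param popmap named vector from [read_population_map()].
#' @return `popmap` restricted to `samples`, in their order.
#' @export
match_population_map <- function(samples, popmap) {
  if (is.matrix(samples)) samples <- rownames(samples)
  missing <- setdiff(samples, names(popmap))
  if (length(missing)) stop("unmapped sample: ", paste(missing, collapse = ", "))
  popmap[samples]
}

VARIANT_CORE_COLS <- c("ref_position", "col_start", "col_end", "type",
                       "ref_allele", "alt_alleles", "alt_count",
                       "region_name", "region_type", "effect")

#' Assemble a variant table
#'
#' Binds the per-variant core fields with the per-sample genotype matrix into
#' the flat data.frame used throughout the pipeline. Genotype columns follow
#' the core columns and are named after the samples; SNP genotypes are bases,
#' InDel genotypes are `"+"` (block present, i.e. bases) / `"-"` (gap).
#'
#' @param core data.frame with the columns in `VARIANT_CORE_COLS`.
#' @param genotypes character matrix, one row per variant, one column per sample.
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(core, genotypes) {
  stopifnot(nrow(core) == nrow(genotypes))
  for (col in setdiff(VARIANT_CORE_COLS, names(core)))
    core[[col]] <- rep(NA_character_, nrow(core))
  core <- core[VARIANT_CORE_COLS]
  out <- cbind(core, as.data.frame(genotypes, stringsAsFactors = FALSE,
                                   optional = TRUE))
  ord <- order(out$ref_position, out$col_start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Extract the per-sample genotype matrix from a variant table
#' @param variants a `variant_table`.
#' @return character matrix (variants x samples).
#' @export
variant_genotypes <- function(variants) {
  gt <- as.matrix(variants[setdiff(names(variants), VARIANT_CORE_COLS)])
  mode(gt) <- "character"
  gt
}

#' Sample ids covered by a variant table
#' @param variants a `variant_table`.
#' @export
variant_samples <- function(variants) setdiff(names(variants), VARIANT_CORE_COLS)

#' Write a variant table to TSV
#'
#' Rows are ordered by reference position, then alignment column; an empty
#' table yields a header-only file.
#'
#' @param variants a `variant_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant table written by [write_variant_table()]
#' @param path path to the TSV.
#' @return a `variant_table`.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!all(VARIANT_CORE_COLS %in% names(tab)))
    stop("not a variant table: missing core columns")
  for (col in c("ref_position", "col_start", "col_end", "alt_count"))
    tab[[col]] <- as.integer(tab[[col]])
  gt <- as.matrix(tab[setdiff(names(tab), VARIANT_CORE_COLS)])
  mode(gt) <- "character"
  variant_table(tab[VARIANT_CORE_COLS], gt)
}

#' Minimal VCF 4.2 export of a variant table
#'
#' Maps each variant to one haploid record: SNPs carry their alleles, InDel
#' block events are anchored at the last reference base before the block with
#' symbolic alleles (`<DEL>`/`<INS>`), since a block event is an
#' alignment-level object rather than a literal sequence edit. Genotypes are
#' `0` (reference / block state of the reference) and `1` (alternate).
#'
#' @param variants a `variant_table`.
#' @param path output path.
#' @param chrom chromosome name for column 1.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, chrom = "ref") {
  samples <- variant_samples(variants)
  gt <- variant_genotypes(variants)
  header <- c("##fileformat=VCFv4.2",
              "##ALT=<ID=DEL,Description=\"Alignment gap block absent from reference-like samples\">",
              "##ALT=<ID=INS,Description=\"Alignment gap block present only outside reference-like samples\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    if (variants$type[i] == "SNP") {
      ref <- variants$ref_allele[i]
      alt <- variants$alt_alleles[i]
      g <- match(gt[i, ], c(ref, strsplit(alt, ",")[[1]])) - 1L
      gstr <- ifelse(is.na(g), ".", g)
    } else {
      ref <- "N"
      alt <- if (variants$ref_allele[i] == "-") "<INS>" else "<DEL>"
      ref_state <- gt[i, , drop = TRUE]
      gstr <- ifelse(ref_state == (if (alt == "<DEL>") "+" else "-"), "0", "1")
    }
    paste(c(chrom, variants$ref_position[i], ".", ref, alt, ".", "PASS",
            paste0("TYPE=", variants$type[i]), "GT", gstr), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Parse a newick string into an `ape` tree
#'
#' Internal-node labels (bootstrap supports) and branch lengths are preserved.
#'
#' @param text newick string.
#' @return an object of class `phylo`.
#' @export
parse_newick <- function(text) {
  if (length(text) != 1L || !is.character(text)) stop("parse error: need a single string")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stop("parse error: unbalanced parentheses")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("parse error: ", text)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels")
  tr
}

#' Serialize an `ape` tree to a newick string
#' @param tree an object of class `phylo`.
#' @param digits significant digits for branch lengths.
#' @return newick string.
#' @export
newick_string <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Read a newick tree file
#' @param path path to a newick file.
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path) parse_newick(paste(readLines(path), collapse = ""))

#' Write a tree to a newick file
#' @param tree an object of class `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' Published mitochondrial SNP genotypes (worked example)
#'
#' The 16-individual by 8-position mitochondrial SNP genotype matrix for
#' Pulsatilla patens, as printed, with positions labelled
#' `<chromosome>-<position>` (e.g. `ChMt1-22156`).
#'
#' @return character matrix (16 samples x 8 positions).
#' @export
pulsatilla_mito_snps <- function() {
  path <- system.file("extdata", "mito_snp_genotypes.tsv", package = "organvar",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  m
}

#' Published sample roster (worked example)
#'
#' The 16-individual roster: sample codes, population ids and localities for
#' the five Pulsatilla patens populations P4, P8, P9, P13, P15.
#'
#' @return data.frame with columns `sample`, `population`, `locality`.
#' @export
pulsatilla_samples <- function() {
  path <- system.file("extdata", "sample_populations.tsv", package = "organvar",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
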