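#' Annotated reference genome
#'
#' @param sequence character vector of bases (or a single string).
#' @param features feature data.frame (see [read_features()]).
#' @param name molecule name.
#' @param kind `"plastome"` or `"mitogenome"`.
#' @param chromosome chromosome label (mitogenome regions).
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(sequence, features, name = "ref",
                             kind = "plastome", chromosome = NA_character_) {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1]]
  stopifnot(all(features$end <= length(sequence)), all(features$start >= 1L))
  structure(list(sequence = sequence, features = features, name = name,
                 kind = kind, chromosome = chromosome,
                 length = length(sequence)),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s (%s%s): %d bp, %d features\n",
              x$name, x$kind,
              if (is.na(x$chromosome)) "" else paste0(", ", x$chromosome),
              x$length, nrow(x$features)))
  invisible(x)
}

random_sequence <- function(n, freqs = c(A = 0.31, C = 0.19, G = 0.19, T = 0.31)) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# One gene laid down left-to-right: optional leading spacer, exon segments
# separated by introns. Exon lengths must keep the spliced CDS in frame.
.gene_spec <- function(name, pre, exons, introns = integer(), strand = "+",
                       type = "gene") {
  list(name = name, pre = pre, exons = exons, introns = introns,
       strand = strand, type = type)
}

.lay_genes <- function(specs, offset = 0L) {
  rows <- list(); pos <- offset
  for (s in specs) {
    pos <- pos + s$pre
    gstart <- pos + 1L
    for (j in seq_along(s$exons)) {
      seg_type <- if (s$type == "gene") "CDS" else s$type
      rows[[length(rows) + 1L]] <- data.frame(
        name = s$name, type = seg_type, start = pos + 1L,
        end = pos + s$exons[j], strand = s$strand, stringsAsFactors = FALSE)
      pos <- pos + s$exons[j]
      if (j <= length(s$introns)) pos <- pos + s$introns[j]
    }
    if (s$type == "gene")
      rows[[length(rows) + 1L]] <- data.frame(
        name = s$name, type = "gene", start = gstart, end = pos,
        strand = s$strand, stringsAsFactors = FALSE)
    else {
      # tRNA/rRNA rows double as their own gene-level feature
    }
  }
  list(features = do.call(rbind, rows), end = pos)
}

scale3 <- function(x, scale) pmax(3L, as.integer(3L * round(x * scale / 3)))

#' Build a synthetic organellar reference genome
#'
#' `"plastome"`: a circular-logic molecule with the canonical four-part
#' architecture LSC | IRa | SSC | IRb, where IRb is the exact reverse
#' complement of IRa; genes (some intron-containing, some on the minus strand)
#' and named intergenic spacers populate the single-copy regions, and the
#' hotspot spacers `ndhD--ccsA`, `rps4--rps16` and `trnL(UAG)--ndhF` are
#' present by construction. `"mitogenome"`: fourteen unlinked single-copy
#' regions assigned to three chromosomes (eight on chMt1, four on chMt2, two
#' on chMt3), returned as a list of `annotated_genome` objects.
#'
#' The default scale gives a ~20 kb plastome / ~26 kb region set: a
#' down-scaled architecture that keeps every structural element of the
#' full-size molecules.
#'
#' @param kind `"plastome"` or `"mitogenome"`.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param scale length multiplier for all structural elements.
#' @return an `annotated_genome` (plastome) or a list of them with class
#'   `annotated_genome_set` (mitogenome).
#' @export
build_reference <- function(kind = c("plastome", "mitogenome"), seed = 1L,
                            scale = 1) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "plastome") .build_plastome(scale) else .build_mitogenome(scale)
  })
}

.build_plastome <- function(scale) {
  s3 <- function(x) scale3(x, scale)
  si <- function(x) max(1L, as.integer(round(x * scale)))
  lsc_specs <- list(
    .gene_spec("psbA", si(200), s3(900)),
    .gene_spec("matK", si(400), s3(1506)),
    .gene_spec("rps4", si(500), s3(603)),
    .gene_spec("rps16", si(700), s3(c(198, 201)), si(800), strand = "-"),
    .gene_spec("atpA", si(600), s3(1524), strand = "-"),
    .gene_spec("rbcL", si(500), s3(1434)),
    .gene_spec("clpP", si(450), s3(c(69, 291, 228)), si(c(640, 520)), strand = "-"),
    .gene_spec("rps14", si(400), s3(303)))
  lsc <- .lay_genes(lsc_specs)
  lsc_len <- lsc$end + si(350)

  ira_specs <- list(.gene_spec("ycf2", si(300), s3(1200)))
  ira <- .lay_genes(ira_specs, offset = lsc_len)
  ira_len <- si(2500)
  ira_start <- lsc_len + 1L
  ira_end <- lsc_len + ira_len

  ssc_specs <- list(
    .gene_spec("trnL(UAG)", si(300), si(80), strand = "+", type = "tRNA"),
    .gene_spec("ndhF", si(600), s3(1110), strand = "-"),
    .gene_spec("ndhD", si(400), s3(750), strand = "-"),
    .gene_spec("ccsA", si(500), s3(642)))
  ssc <- .lay_genes(ssc_specs, offset = ira_end)
  ssc_end <- ssc$end + si(300)
  irb_start <- ssc_end + 1L
  irb_end <- ssc_end + ira_len
  total <- irb_end

  seq_sc <- random_sequence(ssc_end)
  ira_seq <- seq_sc[ira_start:ira_end]
  seq_full <- c(seq_sc, revcomp(ira_seq))
  stopifnot(length(seq_full) == total)

  features <- rbind(
    lsc$features, ira$features, ssc$features,
    data.frame(name = c("IRa", "IRb"), type = "IR",
               start = c(ira_start, irb_start), end = c(ira_end, irb_end),
               strand = c("+", "-"), stringsAsFactors = FALSE))
  features <- features[order(features$start, features$end), ]
  rownames(features) <- NULL
  annotated_genome(seq_full, features, name = "plastome", kind = "plastome")
}

.build_mitogenome <- function(scale) {
  s3 <- function(x) scale3(x, scale)
  si <- function(x) max(1L, as.integer(round(x * scale)))
  specs <- list(
    list("chMt1", .gene_spec("cox1", si(300), s3(1500))),
    list("chMt1", .gene_spec("nad1", si(300), s3(c(300, 300)), si(700))),
    list("chMt1", .gene_spec("atp1", si(300), s3(1200))),
    list("chMt1", .gene_spec("cob", si(300), s3(1140))),
    list("chMt1", .gene_spec("ccmB", si(300), s3(600))),
    list("chMt1", .gene_spec("rrn18", si(300), si(900), type = "rRNA")),
    list("chMt1", .gene_spec("nad4", si(300), s3(c(450, 450)), si(500), strand = "-")),
    list("chMt1", .gene_spec("matR", si(300), s3(1800))),
    list("chMt2", .gene_spec("cox2", si(300), s3(750))),
    list("chMt2", .gene_spec("nad5", si(300), s3(c(600, 600)), si(600))),
    list("chMt2", .gene_spec("atp6", si(300), s3(720), strand = "-")),
    list("chMt2", .gene_spec("rps3", si(300), s3(1599))),
    list("chMt3", .gene_spec("rps4", si(300), s3(1086))),
    list("chMt3", .gene_spec("nad2", si(300), s3(c(480, 480)), si(800))))
  regions <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    chrom <- specs[[i]][[1]]
    laid <- .lay_genes(specs[[i]][2])
    len <- laid$end + si(300)
    regions[[i]] <- annotated_genome(
      random_sequence(len), laid$features,
      name = sprintf("%s_r%02d", chrom, i), kind = "mitogenome",
      chromosome = chrom)
  }
  structure(regions, class = "annotated_genome_set")
}

#' Simulation configuration
#'
#' Defaults reproduce the sampling design and mutation structure of the study
#' system: five populations (P4, P8, P9 with four members, P13, P15) of
#' sixteen individuals plus a single divergent outgroup individual, a
#' transversion-rich SNP spectrum (transition share `kappa/(kappa+2)` = 0.31),
#' InDels confined to non-coding regions, and hotspot spacers mutating several
#' times faster than the background. Per-class rates are set so that the
#' default plastome yields on the order of 64 SNPs and 96 InDels and the
#' mitogenome region set ~8 SNPs and ~16 InDels.
#'
#' @param molecule `"plastome"` or `"mitogenome"` (selects default rates).
#' @param seed integer seed; identical (config, seed) implies identical output.
#' @param populations named integer vector: members per population.
#' @param snp_rate per-site SNP probability by region class
#'   (`exon`, `intron`, `spacer`).
#' @param indel_rate per-site InDel event probability by region class.
#' @param hotspot_regions named multipliers (>= 1) applied to both rates
#'   within the named regions.
#' @param kappa transition/transversion rate ratio (>= 0); a planted SNP is a
#'   transition with probability `kappa/(kappa+2)`.
#' @param indel_length_p geometric distribution parameter in (0, 1]; event
#'   length is `1 + rgeom(p)`.
#' @param carrier_prob probability that each member of the chosen population
#'   carries a mutation.
#' @param population_divergence expected number (Poisson mean) of extra
#'   population-fixed mutations per population.
#' @param outgroup_label sample id of the outgroup individual (NULL for none).
#' @param outgroup_population population id of the outgroup.
#' @param outgroup_mutations expected number of private outgroup mutations.
#' @param indel_classes region classes in which InDels may be planted.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(molecule = c("plastome", "mitogenome"),
                              seed = 1L,
                              populations = c(P4 = 3L, P8 = 3L, P9 = 4L,
                                              P13 = 3L, P15 = 3L),
                              snp_rate = NULL, indel_rate = NULL,
                              hotspot_regions = NULL,
                              kappa = 0.9, indel_length_p = 0.5,
                              carrier_prob = 0.8, population_divergence = 1,
                              outgroup_label = "P22-6",
                              outgroup_population = "P22",
                              outgroup_mutations = 25,
                              indel_classes = c("intron", "intergenic")) {
  molecule <- match.arg(molecule)
  if (molecule == "plastome") {
    snp_rate <- snp_rate %||% c(exon = 0.0011, intron = 0.0025, spacer = 0.0041)
    indel_rate <- indel_rate %||% c(exon = 0, intron = 0.0046, spacer = 0.0074)
    hotspot_regions <- hotspot_regions %||%
      c("ndhD--ccsA" = 8, "rps4--rps16" = 3, "trnL(UAG)--ndhF" = 2)
  } else {
    snp_rate <- snp_rate %||% c(exon = 1.5e-4, intron = 4e-4, spacer = 4e-4)
    indel_rate <- indel_rate %||% c(exon = 0, intron = 1.1e-3, spacer = 1.1e-3)
    hotspot_regions <- hotspot_regions %||% c("nad2 intron" = 6)
  }
  stopifnot(all(snp_rate >= 0 & snp_rate <= 1),
            all(indel_rate >= 0 & indel_rate <= 1),
            is.null(hotspot_regions) || all(hotspot_regions >= 1),
            kappa >= 0, indel_length_p > 0, indel_length_p <= 1,
            carrier_prob > 0, carrier_prob <= 1,
            all(populations >= 1), !is.null(names(populations)))
  structure(list(molecule = molecule, seed = as.integer(seed),
                 populations = populations, snp_rate = snp_rate,
                 indel_rate = indel_rate, hotspot_regions = hotspot_regions,
                 kappa = kappa, indel_length_p = indel_length_p,
                 carrier_prob = carrier_prob,
                 population_divergence = population_divergence,
                 outgroup_label = outgroup_label,
                 outgroup_population = outgroup_population,
                 outgroup_mutations = outgroup_mutations,
                 indel_classes = indel_classes),
            class = "simulation_config")
}

# Per-site rate vectors from the inventory, with hotspot multipliers applied
# and IR spans zeroed (both IR copies are treated as invariant, emulating
# concerted evolution of the repeat).
.site_rates <- function(reference, config) {
  inv <- build_region_inventory(reference$features, reference$length)
  class_key <- c(exon = "exon", intron = "intron", intergenic = "spacer")
  snp <- config$snp_rate[class_key[inv$class]]
  ind <- ifelse(inv$class %in% config$indel_classes,
                config$indel_rate[class_key[inv$class]], 0)
  mult <- rep(1, nrow(inv))
  hs <- config$hotspot_regions
  hit <- match(inv$name, names(hs))
  mult[!is.na(hit)] <- hs[hit[!is.na(hit)]]
  site_snp <- rep(snp * mult, inv$length)
  site_ind <- rep(ind * mult, inv$length)
  for (k in which(reference$features$type == "IR")) {
    span <- reference$features$start[k]:reference$features$end[k]
    site_snp[span] <- 0; site_ind[span] <- 0
  }
  list(inventory = inv, snp = site_snp, indel = site_ind)
}

.draw_alt_base <- function(ref_base, kappa) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")[[ref_base]]
  tv <- setdiff(c("A", "C", "G", "T"), c(ref_base, ts))
  if (is.infinite(kappa)) return(ts)
  sample(c(ts, tv), 1L, prob = c(kappa, 1, 1))
}

.draw_carriers <- function(samples_by_pop, carrier_prob) {
  repeat {
    pop <- sample(names(samples_by_pop), 1L)
    members <- samples_by_pop[[pop]]
    carry <- members[stats::runif(length(members)) < carrier_prob]
    if (length(carry)) return(carry)
  }
}

#' Simulate a population sample with planted mutations
#'
#' Plants SNPs and InDel events onto a reference at region-dependent rates and
#' returns the per-sample sequences, the true alignment (built directly from
#' the planted events — no aligner), and the truth table. Each mutation is
#' carried by a random subset of one population (each member independently
#' with `carrier_prob`); additional population-fixed mutations and private
#' outgroup mutations are planted on top. Events never overlap and are
#' separated by at least one untouched site, so every planted event is
#' recoverable exactly from the true alignment.
#'
#' @param reference an `annotated_genome` from [build_reference()].
#' @param config a `simulation_config`.
#' @return object of class `population_simulation`: list with `alignment`
#'   (character matrix, row `REF` first), `sequences` (ungapped, per sample),
#'   `truth` (variants data.frame + per-region counts), `popmap`, `reference`,
#'   `config`.
#' @export
simulate_population <- function(reference, config) {
  stopifnot(inherits(reference, "annotated_genome"),
            inherits(config, "simulation_config"))
  with_seed(config$seed, .simulate_population_impl(reference, config))
}

.simulate_population_impl <- function(reference, config) {
  L <- reference$length
  rates <- .site_rates(reference, config)
  exp_mutated <- sum(rates$snp) + sum(rates$indel) / config$indel_length_p
  if (exp_mutated > 0.5 * L)
    stop("saturation refused: configured rates would mutate >50% of sites")

  pops <- config$populations
  samples_by_pop <- lapply(seq_along(pops), function(i)
    paste0(names(pops)[i], "-", seq_len(pops[i])))
  names(samples_by_pop) <- names(pops)
  samples <- unlist(samples_by_pop, use.names = FALSE)
  popmap <- stats::setNames(rep(names(pops), pops), samples)
  og <- config$outgroup_label
  if (!is.null(og)) {
    samples <- c(samples, og)
    popmap[og] <- config$outgroup_population
  }

  occupied <- rep(FALSE, L + 2L)  # padded; events keep >=1 clear site apart
  reserve <- function(s, e) {
    s <- max(1L, s); e <- min(L, e)
    if (any(occupied[s:e])) return(FALSE)
    occupied[s:e] <<- TRUE
    TRUE
  }

  events <- list()
  push <- function(type, ref_start, ref_end, len, carriers, ref_allele,
                   alt_allele, ins_seq = NULL) {
    events[[length(events) + 1L]] <<- list(
      type = type, ref_start = ref_start, ref_end = ref_end, len = len,
      carriers = sort(carriers), ref_allele = ref_allele,
      alt_allele = alt_allele, ins_seq = ins_seq)
  }

  # InDel events first (they occupy spans), then SNPs.
  ind_sites <- which(stats::runif(L) < rates$indel)
  for (p in resample(ind_sites)) {
    len <- 1L + stats::rgeom(1L, config$indel_length_p)
    carriers <- .draw_carriers(samples_by_pop, config$carrier_prob)
    if (stats::runif(1) < 0.5) {  # deletion of reference span p..p+len-1
      e <- p + len - 1L
      if (e > L) next
      reg <- locate_variant(p, rates$inventory)
      reg_end <- rates$inventory$end[match(reg$region_name, rates$inventory$name)]
      if (e > reg_end) next  # do not cross region boundaries
      if (rates$indel[e] == 0) next
      if (!reserve(p - 1L, e + 1L)) next
      push("del", p, e, len, carriers,
           paste(reference$sequence[p:e], collapse = ""), "-")
    } else {  # insertion after reference base p
      if (!reserve(p, p + 1L)) next
      push("ins", p, p, len, carriers, "-",
           ins_seq = random_sequence(len),
           alt_allele = "+")
    }
  }

  snp_sites <- which(stats::runif(L) < rates$snp)
  for (p in resample(snp_sites)) {
    if (!reserve(p, p)) next
    ref_base <- reference$sequence[p]
    push("snp", p, p, 1L, .draw_carriers(samples_by_pop, config$carrier_prob),
         ref_base, .draw_alt_base(ref_base, config$kappa))
  }

  # Population-fixed extras: Poisson(population_divergence) SNPs per
  # population, carried by every member, at untouched non-IR noncoding sites.
  noncoding <- which(rates$snp > 0)
  nc_classes <- rates$inventory$class[findInterval(noncoding, rates$inventory$start)]
  noncoding <- noncoding[nc_classes != "exon"]
  for (pop in names(pops)) {
    k <- stats::rpois(1L, config$population_divergence)
    for (p in resample(noncoding, min(k * 4L, length(noncoding)))) {
      if (k == 0L) break
      if (!reserve(p, p)) next
      ref_base <- reference$sequence[p]
      push("snp", p, p, 1L, samples_by_pop[[pop]], ref_base,
           .draw_alt_base(ref_base, config$kappa))
      k <- k - 1L
    }
  }

  # Private outgroup mutations (60% SNPs, 40% single-base deletions).
  if (!is.null(og) && config$outgroup_mutations > 0) {
    m <- stats::rpois(1L, config$outgroup_mutations)
    n_snp <- round(0.6 * m)
    planted <- 0L
    for (p in resample(noncoding, min(m * 4L, length(noncoding)))) {
      if (planted >= m) break
      if (planted < n_snp) {
        if (!reserve(p, p)) next
        ref_base <- reference$sequence[p]
        push("snp", p, p, 1L, og, ref_base, .draw_alt_base(ref_base, config$kappa))
      } else {
        if (!reserve(p - 1L, p + 1L)) next
        push("del", p, p, 1L, og, reference$sequence[p], "-")
      }
      planted <- planted + 1L
    }
  }

  .assemble_simulation(reference, config, events, samples, popmap, rates)
}

.assemble_simulation <- function(reference, config, events, samples, popmap,
                                 rates) {
  L <- reference$length
  n <- length(samples)
  M <- matrix(rep(reference$sequence, each = n + 1L), nrow = n + 1L)
  rownames(M) <- c("REF", samples)

  ins <- Filter(function(e) e$type == "ins", events)
  ins_anchor <- vapply(ins, `[[`, numeric(1), "ref_start")
  ord <- order(ins_anchor)
  ins <- ins[ord]; ins_anchor <- ins_anchor[ord]
  ins_len <- vapply(ins, `[[`, numeric(1), "len")
  col_of <- function(p) {
    if (!length(ins)) return(p)
    p + vapply(p, function(pp) sum(ins_len[ins_anchor < pp]), numeric(1))
  }

  for (e in events) {
    if (e$type == "snp") M[e$carriers, e$ref_start] <- e$alt_allele
    else if (e$type == "del") M[e$carriers, e$ref_start:e$ref_end] <- "-"
  }

  if (length(ins)) {
    blocks <- list(); prev <- 0L
    for (j in seq_along(ins)) {
      p <- ins_anchor[j]
      blocks[[length(blocks) + 1L]] <- M[, (prev + 1L):p, drop = FALSE]
      blk <- matrix("-", nrow = n + 1L, ncol = ins_len[j],
                    dimnames = list(rownames(M), NULL))
      blk[ins[[j]]$carriers, ] <- matrix(rep(ins[[j]]$ins_seq,
                                             each = length(ins[[j]]$carriers)),
                                         nrow = length(ins[[j]]$carriers))
      blocks[[length(blocks) + 1L]] <- blk
      prev <- p
    }
    if (prev < L) blocks[[length(blocks) + 1L]] <- M[, (prev + 1L):L, drop = FALSE]
    aln <- do.call(cbind, blocks)
  } else aln <- M
  colnames(aln) <- NULL

  rows <- lapply(events, function(e) {
    if (e$type == "snp") {
      cs <- col_of(e$ref_start)
      data.frame(type = "SNP", ref_start = e$ref_start, ref_end = e$ref_end,
                 col_start = cs, col_end = cs, ref_allele = e$ref_allele,
                 alt_allele = e$alt_allele,
                 carriers = paste(e$carriers, collapse = ","),
                 gapped_samples = NA_character_, stringsAsFactors = FALSE)
    } else if (e$type == "del") {
      cs <- col_of(e$ref_start)
      data.frame(type = "InDel", ref_start = e$ref_start, ref_end = e$ref_end,
                 col_start = cs, col_end = cs + e$len - 1L,
                 ref_allele = e$ref_allele, alt_allele = "-",
                 carriers = paste(e$carriers, collapse = ","),
                 gapped_samples = paste(e$carriers, collapse = ","),
                 stringsAsFactors = FALSE)
    } else {
      cs <- col_of(e$ref_start) + 1L
      gapped <- sort(setdiff(rownames(aln), e$carriers))
      data.frame(type = "InDel", ref_start = e$ref_start, ref_end = e$ref_start,
                 col_start = cs, col_end = cs + e$len - 1L,
                 ref_allele = "-", alt_allele = paste(e$ins_seq, collapse = ""),
                 carriers = paste(e$carriers, collapse = ","),
                 gapped_samples = paste(gapped, collapse = ","),
                 stringsAsFactors = FALSE)
    }
  })
  truth_variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), ref_start = integer(), ref_end = integer(),
               col_start = integer(), col_end = integer(),
               ref_allele = character(), alt_allele = character(),
               carriers = character(), gapped_samples = character(),
               stringsAsFactors = FALSE)
  if (nrow(truth_variants)) {
    loc <- locate_variant(pmax(truth_variants$ref_start, 1L), rates$inventory)
    truth_variants$region_name <- loc$region_name
    truth_variants$region_class <- loc$region_type
    truth_variants <- truth_variants[order(truth_variants$col_start), ]
    rownames(truth_variants) <- NULL
    counts <- stats::aggregate(list(count = truth_variants$type),
                               by = list(region = truth_variants$region_name,
                                         type = truth_variants$type), length)
  } else counts <- data.frame(region = character(), type = character(),
                              count = integer())

  sequences <- vapply(samples, function(s)
    paste(aln[s, aln[s, ] != "-"], collapse = ""), character(1))

  structure(list(alignment = aln, sequences = sequences,
                 truth = structure(list(variants = truth_variants,
                                        per_region_counts = counts),
                                   class = "simulation_truth"),
                 popmap = popmap, reference = reference, config = config),
            class = "population_simulation")
}

#' Simulate a multi-region (mitogenome-like) population sample
#'
#' Runs [simulate_population()] independently on every region of an
#' `annotated_genome_set` (with per-region seeds split from `config$seed` and
#' the set-level Poisson means for population divergence and outgroup
#' mutations thinned by region length) and concatenates the per-region
#' alignments, shifting truth coordinates to the concatenated columns.
#'
#' @param reference_set an `annotated_genome_set` from [build_reference()].
#' @param config a `simulation_config`.
#' @return a `population_simulation` whose truth table carries a `region`
#'   column naming the source region; `$regions` holds the per-region results.
#' @export
simulate_regions <- function(reference_set, config) {
  stopifnot(inherits(reference_set, "annotated_genome_set"))
  lens <- vapply(reference_set, function(r) r$length, numeric(1))
  w <- lens / sum(lens)
  seeds <- split_seed(config$seed, length(reference_set))
  sims <- vector("list", length(reference_set))
  for (i in seq_along(reference_set)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    cfg_i$population_divergence <- config$population_divergence * w[i]
    cfg_i$outgroup_mutations <- config$outgroup_mutations * w[i]
    sims[[i]] <- simulate_population(reference_set[[i]], cfg_i)
  }
  aln <- do.call(cbind, lapply(sims, `[[`, "alignment"))
  col_off <- cumsum(c(0L, vapply(sims, function(s) ncol(s$alignment), integer(1))))
  ref_off <- cumsum(c(0L, lens))
  variants <- do.call(rbind, lapply(seq_along(sims), function(i) {
    v <- sims[[i]]$truth$variants
    if (!nrow(v)) return(NULL)
    v$col_start <- v$col_start + col_off[i]
    v$col_end <- v$col_end + col_off[i]
    v$ref_start <- v$ref_start + ref_off[i]
    v$ref_end <- v$ref_end + ref_off[i]
    v$region <- reference_set[[i]]$name
    v$chromosome <- reference_set[[i]]$chromosome
    v
  }))
  if (is.null(variants))
    variants <- cbind(sims[[1]]$truth$variants[0, ],
                      data.frame(region = character(), chromosome = character()))
  sequences <- vapply(rownames(aln)[-1], function(s)
    paste(aln[s, aln[s, ] != "-"], collapse = ""), character(1))
  structure(list(alignment = aln, sequences = sequences,
                 truth = structure(list(variants = variants,
                                        per_region_counts = NULL),
                                   class = "simulation_truth"),
                 popmap = sims[[1]]$popmap, reference = reference_set,
                 config = config, regions = sims),
            class = "population_simulation")
}
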