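#' Default pipeline configuration
#'
#' One master seed is split deterministically into independent per-stage
#' streams (simulation, network randomization, bootstrap), so re-running with
#' the same configuration is byte-reproducible and changing the seed never
#' alters variant calls on a fixed alignment.
#'
#' @param seed master integer seed.
#' @param scale genome scale passed to [build_reference()].
#' @param network_iterations randomized-MST iterations.
#' @param bootstrap_reps bootstrap replicates per tree.
#' @param min_alt_count variant-calling floor.
#' @param outgroup outgroup sample id used for rooting (NULL to skip).
#' @param ... overrides stored verbatim in the config.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, scale = 1, network_iterations = 200L,
                            bootstrap_reps = 1000L, min_alt_count = 1L,
                            outgroup = "P22-6", ...) {
  structure(list(seed = as.integer(seed), scale = scale,
                 network_iterations = network_iterations,
                 bootstrap_reps = bootstrap_reps,
                 min_alt_count = min_alt_count, outgroup = outgroup, ...),
            class = "pipeline_config")
}

.stage_log <- function(log, stage, t0, msg = "") {
  entry <- sprintf("%s\t%.2fs\t%s", stage,
                   as.numeric(Sys.time()) - as.numeric(t0), msg)
  c(log, entry)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains the stages: simulate (plastome and mitogenome region set) -> IR
#' trimming and variant calling on the true alignments -> annotation ->
#' summary statistics -> haplotype networks -> bootstrapped NJ trees with
#' model selection -> plastome-vs-mitogenome tree comparison. All outputs are
#' written as plain-text tables under `out_dir`, together with the echoed
#' configuration, a run log with stage timings, and a manifest of md5
#' checksums. Deterministic for a fixed configuration.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(config$seed, 6L)
  log <- character()
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    log <<- .stage_log(log, stage, t0)
    res
  }

  # --- simulate -------------------------------------------------------------
  sim <- run_stage("simulate", {
    cp_ref <- build_reference("plastome", seed = seeds[1], scale = config$scale)
    mt_ref <- build_reference("mitogenome", seed = seeds[1], scale = config$scale)
    cp <- simulate_population(cp_ref, simulation_config("plastome", seed = seeds[2]))
    mt <- simulate_regions(mt_ref, simulation_config("mitogenome", seed = seeds[3]))
    write_alignment(cp$alignment, file.path(out_dir, "plastome_true_alignment.fasta"))
    write_alignment(mt$alignment, file.path(out_dir, "mitogenome_true_alignment.fasta"))
    write_features(cp_ref$features, file.path(out_dir, "plastome.gff3"),
                   seqid = "plastome")
    utils::write.table(data.frame(sample = names(cp$popmap),
                                  population = unname(cp$popmap)),
                       file.path(out_dir, "population_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cp$truth$variants, file.path(out_dir, "plastome_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(mt$truth$variants, file.path(out_dir, "mitogenome_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(cp = cp, mt = mt, cp_ref = cp_ref, mt_ref = mt_ref)
  })

  # --- call -----------------------------------------------------------------
  called <- run_stage("call", {
    cp_aln <- trim_second_ir(sim$cp$alignment, sim$cp_ref$features, "REF")
    cp_var <- call_variants(cp_aln, "REF", config$min_alt_count)
    mt_var <- call_variants(sim$mt$alignment, "REF", config$min_alt_count)
    list(cp_aln = cp_aln, cp = cp_var, mt = mt_var)
  })

  # --- annotate -------------------------------------------------------------
  annotated <- run_stage("annotate", {
    ir <- sim$cp_ref$features[sim$cp_ref$features$type == "IR", ]
    second_len <- max(ir$end) - max(ir$start) + 1L
    trimmed_len <- sim$cp_ref$length - second_len
    cp_inv <- build_region_inventory(sim$cp_ref$features, trimmed_len)
    cp_var <- annotate_variants(called$cp, sim$cp_ref$features,
                                sim$cp_ref$sequence[seq_len(trimmed_len)],
                                code = "plastid", inventory = cp_inv)
    write_variant_table(cp_var, file.path(out_dir, "plastome_variants.tsv"))
    write_variant_table(called$mt, file.path(out_dir, "mitogenome_variants.tsv"))
    list(cp = cp_var, mt = called$mt, cp_inventory = cp_inv)
  })

  # --- summarize ------------------------------------------------------------
  summaries <- run_stage("summarize", {
    spectrum <- tstv_breakdown(annotated$cp)
    regions <- per_region_summary(annotated$cp, annotated$cp_inventory)
    cp_samples <- annotated$cp[setdiff(names(annotated$cp), "REF")]
    pops <- per_population_counts(cp_samples, sim$cp$popmap)
    density <- data.frame(
      molecule = c("plastome", "mitogenome"),
      mutations = c(nrow(annotated$cp), nrow(annotated$mt)),
      length = c(sim$cp_ref$length, ncol(sim$mt$alignment)),
      changes_per_bp = c(changes_per_bp(nrow(annotated$cp), sim$cp_ref$length),
                         changes_per_bp(nrow(annotated$mt), ncol(sim$mt$alignment))))
    utils::write.table(spectrum, file.path(out_dir, "spectrum.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(regions, file.path(out_dir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(pops, file.path(out_dir, "populations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(density, file.path(out_dir, "density.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(spectrum = spectrum, regions = regions, populations = pops,
         density = density)
  })

  # --- network --------------------------------------------------------------
  networks <- run_stage("network", {
    nets <- list()
    for (mol in c("cp", "mt")) {
      variants <- annotated[[mol]]
      smp <- sim[[mol]]
      hm <- haplotype_matrix(variants)
      hm <- hm[setdiff(rownames(hm), "REF"), , drop = FALSE]
      hap <- collapse_haplotypes(hm)
      reps <- vapply(attr(hap, "classes"), `[`, character(1), 1L)
      sub_aln <- smp$alignment[reps, , drop = FALSE]
      dmat <- indelblock_dist_matrix(sub_aln)
      net <- rmst_network(dmat, iterations = config$network_iterations,
                          seed = seeds[4], haplotypes = hap,
                          popmap = smp$popmap)
      prefix <- if (mol == "cp") "plastome" else "mitogenome"
      utils::write.table(net$nodes, file.path(out_dir, paste0(prefix, "_network_nodes.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(net$edges, file.path(out_dir, paste0(prefix, "_network_edges.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      igraph::write_graph(network_igraph(net),
                          file.path(out_dir, paste0(prefix, "_network.graphml")),
                          format = "graphml")
      nets[[prefix]] <- net
    }
    nets
  })

  # --- tree -----------------------------------------------------------------
  trees <- run_stage("tree", {
    out <- list()
    for (mol in c("cp", "mt")) {
      smp <- sim[[mol]]
      aln <- smp$alignment[setdiff(rownames(smp$alignment), "REF"), , drop = FALSE]
      dfn <- if (mol == "cp") dist_hky else dist_jc
      tr <- bootstrap_support(aln, dfn, n_reps = config$bootstrap_reps,
                              seed = seeds[5])
      sel <- select_model(aln, tr)
      if (!is.null(config$outgroup) && config$outgroup %in% tr$tip.label)
        tr <- root_with_outgroup(tr, config$outgroup)
      prefix <- if (mol == "cp") "plastome" else "mitogenome"
      write_newick(tr, file.path(out_dir, paste0(prefix, "_nj.nwk")))
      out[[prefix]] <- list(tree = tr, model = sel)
    }
    model_tab <- data.frame(
      molecule = names(out),
      best_model = vapply(out, function(x) x$model$best, character(1)),
      kappa = vapply(out, function(x) x$model$fits$HKY$kappa, numeric(1)),
      delta_aic = vapply(out, function(x) x$model$delta_aic, numeric(1)))
    utils::write.table(model_tab, file.path(out_dir, "model_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  # --- compare --------------------------------------------------------------
  comparison <- run_stage("compare", {
    cmp <- compare_trees(trees$plastome$tree, trees$mitogenome$tree)
    utils::write.table(data.frame(rf = cmp$rf, max_rf = cmp$max_rf),
                       file.path(out_dir, "tree_comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cmp$association, file.path(out_dir, "tree_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cmp
  })

  writeLines(log, file.path(out_dir, "run_log.tsv"))
  # the log carries wall-clock timings; everything else must be reproducible
  files <- setdiff(list.files(out_dir), c("manifest.tsv", "run_log.tsv"))
  sums <- tools::md5sum(file.path(out_dir, files))
  utils::write.table(data.frame(file = files, md5 = unname(sums)),
                     file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(simulation = sim, variants = annotated, summaries = summaries,
                 networks = networks, trees = trees, comparison = comparison))
}
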