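# End-to-end orchestration from a config: profiling -> differential
# expression (miRNA and mRNA) -> hairpin screening -> target scanning
# -> integration, with a manifest echoing every parameter and seed so
# reported results are self-describing. Single-process and
# deterministic; every stage output is a plain file, so any stage can
# be re-run standalone.

#' Pipeline configuration
#'
#' Input paths, thresholds and output directory for [run_pipeline()].
#' Threshold defaults are the published screen: DE at FDR <= 0.001
#' and |log2| >= 1; integration miRNAs at |log2| >= 3; hairpin MFE
#' < -18 kcal/mol, MFEI > 0.85, mature 16-30 nt, at most 10 genome
#' hits, 150 nt flanks; target penalty <= 4.0; enrichment P < 0.05
#' and FDR <= 0.05.
#'
#' @param mirna_counts,mrna_counts count-table paths.
#' @param mirna_totals,mrna_totals length-2 library totals.
#' @param mature_fasta,genome_fasta,utr_fasta FASTA paths.
#' @param hits_table genome-hit table path (tab-separated: locus,
#'   chrom, start, end, strand, mature, genome_hits).
#' @param gmt GMT pathway file path.
#' @param out_dir output directory.
#' @param seed integer seed echoed into the manifest.
#' @param fdr_max,log2_min,integration_abs_log2,mfe_max,mfei_min,mature_len,genome_hits_max,flank,target_max_penalty,enrich_p,enrich_fdr
#'   thresholds (see description).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mirna_counts, mirna_totals, mrna_counts,
                            mrna_totals, mature_fasta, genome_fasta,
                            hits_table, utr_fasta, gmt, out_dir,
                            seed = 1L, fdr_max = 0.001, log2_min = 1,
                            integration_abs_log2 = 3, mfe_max = -18,
                            mfei_min = 0.85, mature_len = c(16L, 30L),
                            genome_hits_max = 10L, flank = 150L,
                            target_max_penalty = 4.0, enrich_p = 0.05,
                            enrich_fdr = 0.05) {
  cfg <- list(mirna_counts = mirna_counts, mirna_totals = mirna_totals,
              mrna_counts = mrna_counts, mrna_totals = mrna_totals,
              mature_fasta = mature_fasta, genome_fasta = genome_fasta,
              hits_table = hits_table, utr_fasta = utr_fasta, gmt = gmt,
              out_dir = out_dir, seed = seed, fdr_max = fdr_max,
              log2_min = log2_min, integration_abs_log2 = integration_abs_log2,
              mfe_max = mfe_max, mfei_min = mfei_min,
              mature_len = mature_len, genome_hits_max = genome_hits_max,
              flank = flank, target_max_penalty = target_max_penalty,
              enrich_p = enrich_p, enrich_fdr = enrich_fdr)
  check_that(fdr_max > 0 && fdr_max <= 1 && enrich_p > 0 && enrich_p <= 1 &&
               enrich_fdr > 0 && enrich_fdr <= 1,
             "probability thresholds must lie in (0, 1]")
  check_that(mfe_max < 0 && mfei_min > 0 && log2_min >= 0 &&
               integration_abs_log2 >= 0,
             "threshold out of domain")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a `pipeline_config` list.
#' @export
read_config <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path),
             class = "caprimir_io_error")
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline
#'
#' Executes profiling, differential expression (miRNA and mRNA
#' tables), hairpin screening, target scanning and integration, and
#' writes every stage output plus a JSON manifest (versions, seed and
#' a full parameter echo) under `config$out_dir`. On a stage failure
#' the error is logged with the stage name and re-raised; partial
#' outputs are retained.
#'
#' @param config a `pipeline_config` from [pipeline_config()] or
#'   [read_config()].
#' @return the run report (named list of stage results), invisibly.
#' @export
run_pipeline <- function(config) {
  check_that(inherits(config, "pipeline_config"),
             "`config` must come from pipeline_config()/read_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list()
  stage <- "setup"
  res <- tryCatch({
    stage <- "profile"
    stage_log(stage, "sequence-composition profiling")
    mature <- read_fasta(config$mature_fasta)
    mir_counts <- read_count_table(config$mirna_counts, config$mirna_totals)
    reads <- tibble(seq = mature$seq,
                    count = mir_counts$count_lib1[
                      match(mature$id, mir_counts$feature)])
    reads$count[is.na(reads$count)] <- 1
    ld <- length_distribution(reads)
    fb <- first_nucleotide_bias(reads)
    pb <- positional_nucleotide_bias(reads)
    utils::write.table(as.data.frame(ld), out("length_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(fb), out("first_nt_bias.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(pb), out("position_bias.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$profile <- list(length_distribution = ld, first_nt = fb,
                           positional = pb)

    stage <- "de"
    stage_log(stage, "differential expression (miRNA + mRNA)")
    mir_de <- de_table(mir_counts, config$fdr_max, config$log2_min)
    mrna_counts <- read_count_table(config$mrna_counts, config$mrna_totals)
    mrna_de <- de_table(mrna_counts, config$fdr_max, config$log2_min)
    write_de_table(mir_de, out("mirna_de.tsv"))
    write_de_table(mrna_de, out("mrna_de.tsv"))
    report$de <- list(mirna = mir_de, mrna = mrna_de)

    stage <- "hairpin"
    stage_log(stage, "novel-miRNA hairpin screen")
    genome <- read_fasta(config$genome_fasta)
    hits <- as_tibble(utils::read.table(config$hits_table, sep = "\t",
                                        header = TRUE,
                                        stringsAsFactors = FALSE))
    windows <- extract_flanks(hits, genome, config$flank)
    hairpins <- evaluate_candidates(windows, mfe_max = config$mfe_max,
                                    mfei_min = config$mfei_min,
                                    mature_len = config$mature_len,
                                    genome_hits_max = config$genome_hits_max)
    utils::write.table(as.data.frame(dplyr::select(hairpins, -"window")),
                       out("hairpin_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_structures(hairpins, out("hairpin_structures.txt"))
    report$hairpin <- hairpins

    stage <- "targets"
    stage_log(stage, "target scanning for strongly DE miRNAs")
    sel <- select_de_mirnas(mir_de, config$integration_abs_log2)
    utrs <- read_fasta(config$utr_fasta)
    sel_mirnas <- mature[mature$id %in% sel, , drop = FALSE]
    sites <- scan_targets(sel_mirnas, utrs,
                          max_penalty = config$target_max_penalty)
    write_sites(sites, out("target_sites.tsv"))
    report$targets <- sites

    stage <- "integrate"
    stage_log(stage, "DE-target intersection, enrichment, networks")
    degs <- tibble(gene = mrna_de$feature,
                   direction = as.character(mrna_de$de_class))
    degs <- degs[degs$direction != "not_de", , drop = FALSE]
    det <- intersect_de_targets(sites, dplyr::filter(mir_de,
                                                     .data$feature %in% sel),
                                degs)
    pathways <- read_gmt(config$gmt)
    background <- unique(c(mrna_de$feature))
    enr <- enrich_pathways(unique(det$gene), pathways, background)
    write_enrichment(enr, out("pathway_enrichment.tsv"))
    top <- top_pathway_networks(enr, det, pathways, top = 10L)
    utils::write.table(as.data.frame(dplyr::select(top, -"network")),
                       out("top_pathways.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (i in seq_len(nrow(top))) {
      nw <- top$network[[i]]
      if (nrow(nw$edges) > 0) {
        write_edge_list(nw$edges,
                        out(sprintf("network_%s.tsv", top$pathway[i])))
      }
    }
    utils::write.table(as.data.frame(det), out("de_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$integrate <- list(de_targets = det, enrichment = enr, top = top)
    report
  }, error = function(e) {
    stage_log(stage, paste("ERROR:", conditionMessage(e)))
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "caprimir_pipeline_error", parent = e)
  })

  manifest <- list(
    package = "caprimir",
    version = as.character(utils::packageVersion("caprimir")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = unclass(config),
    outputs = list.files(config$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(res)
}

#' Generate a complete synthetic workspace and run the pipeline on it
#'
#' Simulates every input (miRNA and mRNA count tables, mature FASTA,
#' genome with embedded precursors and a hit table, 3'UTRs with
#' planted sites, pathways), writes them in the pipeline's file
#' dialects together with JSON-lines truth files, then runs
#' [run_pipeline()].
#'
#' @param dir workspace directory.
#' @param seed integer seed; all generator seeds derive from it.
#' @param n_mirnas,n_genes,n_hairpins,n_utrs scale of the workspace.
#' @return the run report, invisibly; the workspace is left in `dir`.
#' @export
make_demo <- function(dir = tempfile("caprimir-demo-"), seed = 1L,
                      n_mirnas = 150L, n_genes = 400L, n_hairpins = 12L,
                      n_utrs = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inp <- function(f) file.path(dir, f)
  seed <- as.integer(seed)

  sim_mir <- simulate_libraries(n_features = n_mirnas, de_fraction = 0.3,
                                effect_log2 = 4, seed = seed)
  sim_mrna <- simulate_libraries(n_features = n_genes, de_fraction = 0.3,
                                 effect_log2 = 2.5, sdlog = 1.0,
                                 mirna_fraction = 0.6, seed = seed + 1L)
  sim_mrna$counts$feature <- sub("^mir", "gene", sim_mrna$counts$feature)
  sim_mrna$truth$feature <- sub("^mir", "gene", sim_mrna$truth$feature)
  write_count_table(sim_mir$counts, inp("mirna_counts.tsv"))
  write_count_table(sim_mrna$counts, inp("mrna_counts.tsv"))

  # mature sequences for the count features
  reads <- simulate_mirna_reads(n_unique = n_mirnas, seed = seed + 2L)
  mature <- tibble(id = sim_mir$counts$feature, seq = reads$seq)
  write_fasta(mature, inp("mature.fa"))

  hp <- simulate_hairpins(n = n_hairpins, seed = seed + 3L)
  gen <- simulate_genome(hp, chrom_len = max(20000L, n_hairpins * 600L),
                         seed = seed + 4L)
  write_fasta(gen$genome, inp("genome.fa"))
  utils::write.table(as.data.frame(gen$hits), inp("hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # UTRs planted with sites of the strongly DE miRNAs
  mir_de <- de_table(sim_mir$counts)
  sel <- select_de_mirnas(mir_de, 3)
  if (length(sel) == 0) sel <- mature$id[1:3]
  utr_sim <- simulate_utrs(mature[mature$id %in% sel, ], n_utrs = n_utrs,
                           sites_per_utr = 1L, utr_len = 300L,
                           seed = seed + 5L)
  # name UTRs after mRNA genes so targets intersect the DEG table
  gene_ids <- sim_mrna$counts$feature[seq_len(n_utrs)]
  id_map <- setNames(gene_ids, utr_sim$utrs$id)
  utr_sim$utrs$id <- unname(id_map[utr_sim$utrs$id])
  utr_sim$truth$transcript <- unname(id_map[utr_sim$truth$transcript])
  write_fasta(utr_sim$utrs, inp("utrs.fa"))

  pw <- simulate_pathways(sim_mrna$counts$feature, n_pathways = 25L,
                          size_range = c(10L, 40L), n_enriched = 1L,
                          de_genes = unique(utr_sim$truth$transcript),
                          odds = 15, seed = seed + 6L)
  write_gmt(pw$pathways, inp("pathways.gmt"))

  for (tr in list(c("mirna_truth.jsonl", "sim_mir"),
                  c("mrna_truth.jsonl", "sim_mrna"))) {
    df <- get(tr[2])$truth
    writeLines(vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)
    }, character(1)), inp(tr[1]))
  }

  cfg <- pipeline_config(
    mirna_counts = inp("mirna_counts.tsv"),
    mirna_totals = library_totals(sim_mir$counts),
    mrna_counts = inp("mrna_counts.tsv"),
    mrna_totals = library_totals(sim_mrna$counts),
    mature_fasta = inp("mature.fa"), genome_fasta = inp("genome.fa"),
    hits_table = inp("hits.tsv"), utr_fasta = inp("utrs.fa"),
    gmt = inp("pathways.gmt"), out_dir = file.path(dir, "out"),
    seed = seed)
  write_config(cfg, inp("config.yaml"))
  invisible(run_pipeline(cfg))
}
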