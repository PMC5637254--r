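.manifest <- function(outdir, inputs, params, seed) {
  files <- unlist(inputs[vapply(inputs, function(x)
    is.character(x) && length(x) == 1L && file.exists(x), NA)])
  sums <- if (length(files)) as.list(tools::md5sum(files)) else list()
  man <- list(tool = "spliceflank",
              version = as.character(utils::packageVersion("spliceflank")),
              input_checksums = sums,
              parameters = params, seed = seed,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

.log_filter <- function(log, what, threshold, before, after) {
  msg <- sprintf("filter %-28s threshold=%-12s before=%d after=%d",
                 what, threshold, before, after)
  message(msg)
  c(log, msg)
}

#' Run the event / psi / region / motif pipeline
#'
#' Full downstream chain: event catalogue from the annotation, psi and
#' delta-psi statistics with the SAS filter, the 20 flanking-region classes
#' with sequences (all events as background, called events stratified by
#' delta-psi sign), and the motif enrichment table. Writes `events.tsv`,
#' `sas.tsv`, `regions.bed`, `regions.fa`, `motif_stats.tsv`, `run.log` and
#' `manifest.json` into `outdir`.
#'
#' @param gtf,genome,quant,conditions Input file paths (GTF annotation,
#'   FASTA genome, TPM quant TSV, condition map TSV).
#' @param motifs data.frame `name`, `pattern` or a path to a motif file.
#' @param outdir Output directory (created).
#' @param control,mutant Condition labels.
#' @param alpha,min_tpm SAS filter parameters.
#' @param window Flank window width.
#' @param test,n_perm,seed Significance test parameters (see [call_sas()]).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_sas_motif_pipeline <- function(gtf, genome, quant, conditions,
                                   motifs = sr45_motifs(), outdir,
                                   control = "control", mutant = "mutant",
                                   alpha = 0.05, min_tpm = 10, window = 50,
                                   test = "welch", n_perm = 10000, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(motifs)) motifs <- read_motifs(motifs)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  log <- character()
  tx <- stage("parse_gtf", parse_gtf(gtf))
  ev <- stage("build_events", build_events(tx))
  write_events(ev, file.path(outdir, "events.tsv"))
  qt <- stage("read_quant", read_quant(quant))
  cm <- stage("read_conditions", read_conditions(conditions))
  sas <- stage("call_sas",
               call_sas(ev, qt, cm, control = control, mutant = mutant,
                        alpha = alpha, min_tpm = min_tpm, test = test,
                        n_perm = n_perm, seed = seed))
  log <- .log_filter(log, "sas(p,total_mean_tpm)",
                     sprintf("p<%g,TPM>=%g", alpha, min_tpm),
                     nrow(sas), sum(sas$is_sas))
  write_sas_table(sas, file.path(outdir, "sas.tsv"))
  gb <- gene_bounds(tx)
  rg <- stage("extract_regions",
              extract_flank_regions(ev, gb, window = window))
  rg <- dedupe_regions(rg)
  rg <- stage("fetch_sequences", fetch_sequences(rg, genome))
  write_bed(rg, file.path(outdir, "regions.bed"))
  write_region_fasta(rg, file.path(outdir, "regions.fa"))
  strata <- sas_strata(sas)
  mt <- stage("motif_enrichment",
              motif_enrichment_table(rg, strata, motifs))
  write_tsv_strict(mt, file.path(outdir, "motif_stats.tsv"))
  writeLines(log, file.path(outdir, "run.log"))
  .manifest(outdir,
            list(gtf = gtf, genome = genome, quant = quant,
                 conditions = conditions),
            list(control = control, mutant = mutant, alpha = alpha,
                 min_tpm = min_tpm, window = window, test = test,
                 n_perm = n_perm), seed)
  invisible(list(events = ev, sas = sas, regions = rg, motif_stats = mt))
}

#' Run the consensus / enrichment set pipeline
#'
#' Applies the differential-expression filter per source and intersects
#' direction-wise; selects immunoprecipitation-enriched genes across
#' methods; tests the overlap of the two consensus results against an
#' optional reference set; and computes term enrichment for each output
#' set. Writes gene-set files, `enrichment_*.tsv`, `overlap.tsv`, `run.log`
#' and `manifest.json`.
#'
#' @param de_tables Named list of DE data.frames (or file paths).
#' @param rip_tables Named list of RIP data.frames (or file paths); may be
#'   NULL.
#' @param term_map data.frame `gene_id`, `term` (or path); may be NULL.
#' @param universe Character vector of gene ids (or path).
#' @param reference_set Optional gene-id vector for an overlap test against
#'   the selected RIP set.
#' @param outdir Output directory.
#' @param min_fc,max_sig Filter parameters.
#' @param seed Recorded in the manifest (the stage is deterministic).
#' @return Invisibly, list of results.
#' @export
run_set_pipeline <- function(de_tables = NULL, rip_tables = NULL,
                             term_map = NULL, universe, reference_set = NULL,
                             outdir, min_fc = 2, max_sig = 0.1, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(universe) && length(universe) == 1L &&
      file.exists(universe)) universe <- read_gene_set(universe)
  if (is.character(term_map)) term_map <- read_term_map(term_map)
  load_tabs <- function(tabs, reader)
    lapply(tabs, function(t) if (is.character(t)) reader(t) else t)
  log <- character()
  out <- list()
  if (!is.null(de_tables)) {
    de_tables <- load_tabs(de_tables, read_de_table)
    filt <- lapply(de_tables, filter_de, min_fc = min_fc, max_sig = max_sig)
    for (nm in names(filt))
      log <- .log_filter(log, paste0("de:", nm),
                         sprintf("fc>=%g,sig<%g", min_fc, max_sig),
                         nrow(de_tables[[nm]]),
                         length(filt[[nm]]$up_in_mutant) +
                           length(filt[[nm]]$down_in_mutant))
    cons <- consensus(filt)
    write_gene_set(cons$up_common, file.path(outdir, "up_in_mutant_common.txt"))
    write_gene_set(cons$down_common, file.path(outdir, "down_in_mutant_common.txt"))
    out$consensus <- cons
    if (!is.null(term_map)) {
      for (side in c("up_common", "down_common")) {
        te <- term_enrichment(cons[[side]], term_map, universe)
        write_tsv_strict(te, file.path(outdir,
                                       sprintf("enrichment_%s.tsv", side)))
        out[[paste0("enrichment_", side)]] <- te
      }
    }
  }
  if (!is.null(rip_tables)) {
    rip_tables <- load_tabs(rip_tables, read_rip_table)
    sars <- select_sars(rip_tables, min_fc = min_fc, max_sig = max_sig)
    for (nm in names(sars$per_method))
      log <- .log_filter(log, paste0("rip:", nm),
                         sprintf("fc>=%g,sig<%g both lines", min_fc, max_sig),
                         length(unique(rip_tables[[nm]]$gene_id)),
                         length(sars$per_method[[nm]]))
    write_gene_set(sars$genes, file.path(outdir, "sar_genes.txt"))
    out$sars <- sars
    if (!is.null(reference_set)) {
      ov <- fisher_overlap(sars$genes, intersect(reference_set, universe),
                           universe)
      write_tsv_strict(data.frame(odds_ratio = ov$odds_ratio,
                                  p_value = ov$p_value),
                       file.path(outdir, "overlap.tsv"))
      out$overlap <- ov
    }
    if (!is.null(term_map)) {
      te <- term_enrichment(sars$genes, term_map, universe)
      write_tsv_strict(te, file.path(outdir, "enrichment_sar.tsv"))
      out$enrichment_sar <- te
    }
  }
  writeLines(log, file.path(outdir, "run.log"))
  .manifest(outdir, list(),
            list(min_fc = min_fc, max_sig = max_sig), seed)
  invisible(out)
}
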