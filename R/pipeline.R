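#' Pipeline configuration
#'
#' Either a `simulate` block (a [sim_config()]) or paths to existing inputs
#' (`annotation`, per-sample `fragments` BED6 files, `sample_sheet` TSV,
#' optional `prompt_fasta`) must be provided. Module parameters are exposed
#' with the defaults used throughout the package.
#'
#' @param simulate a [sim_config()], or `NULL` when real inputs are given.
#' @param annotation BED12 annotation path (ignored when simulating).
#' @param fragments named character vector of per-sample BED6 paths.
#' @param sample_sheet sample sheet TSV path.
#' @param prompt_fasta FASTA of PROMPT sequences (optional; simulated when
#'   a simulate block is present).
#' @param motifs MEME minimal file of PWMs, or `NULL` to use the synthetic
#'   PRC2-like stand-ins.
#' @param offsets a [region_config()].
#' @param min_mapq,collapse_duplicates read filters
#'   (see [filter_fragments()]).
#' @param norm_method depth normalization used for differential stages:
#'   `"median_ratio"` (default; robust to the compositional library shift
#'   that asymmetric induction causes) or `"total"` (plain CPM).
#' @param p_threshold,lfc_threshold,unchanged_band differential thresholds.
#' @param g4_threshold,g4_window G4Hunter parameters.
#' @param motif_score_bits PWM scan threshold (bits).
#' @param pi_low,pi_high moderate-PI band.
#' @param metagene_bin,metagene_flank reference-point metagene parameters.
#' @param seed seed for any simulation requested.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            annotation = NULL, fragments = NULL,
                            sample_sheet = NULL, prompt_fasta = NULL,
                            motifs = NULL,
                            offsets = region_config(),
                            min_mapq = 50L, collapse_duplicates = FALSE,
                            norm_method = "median_ratio",
                            p_threshold = 0.05, lfc_threshold = 0.1,
                            unchanged_band = 0.05,
                            g4_threshold = 1.2, g4_window = 25L,
                            motif_score_bits = 6,
                            pi_low = 5, pi_high = 50,
                            metagene_bin = 5L, metagene_flank = 500L,
                            seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$simulate)) {
    need <- c("annotation", "fragments", "sample_sheet")
    missing <- need[vapply(cfg[need], is.null, TRUE)]
    if (length(missing))
      abort("config lacks a simulate block and input(s): %s",
            paste(missing, collapse = ", "))
  } else {
    stopifnot(inherits(cfg$simulate, "sim_config"))
    if (!is.null(seed)) cfg$simulate$seed <- as.integer(seed)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: (simulate ->) regions -> read processing -> counting ->
#' normalization -> differential testing (gene body, PROMPT) -> pause index
#' -> integration -> sequence features (G4, motif enrichment) -> metagene
#' profiles -> report. Every stage writes its TSV/BED/bedGraph artifact
#' under `out_dir` and the report is returned and written as JSON; given a
#' seed, outputs are byte-identical across reruns.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param write_artifacts write stage artifacts (disable for a fast
#'   in-memory run).
#' @param verbose message stage progress.
#' @return list of class `pipeline_result`: all stage outputs plus
#'   `report`.
#' @export
run_pipeline <- function(config, out_dir = "promptpause_run",
                         write_artifacts = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (write_artifacts) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  if (!is.null(config$simulate)) {
    say("stage simulate")
    gt <- simulate_genome_and_truth(config$simulate)
    genes <- gt$genes; truth <- gt$truth
    sim <- simulate_fragments(genes, truth, config$simulate, config$offsets)
    fragments <- sim$fragments
    sample_sheet <- sim$sample_sheet
    prompts <- simulate_prompt_sequences(genes, truth, config$simulate)
    if (write_artifacts)
      write_simulation(c(gt, sim), out_dir, sequences = prompts)
  } else {
    say("stage load")
    genes <- read_gene_bed12(config$annotation)
    sample_sheet <- as.data.frame(fread(config$sample_sheet))
    fragments <- rbindlist(lapply(names(config$fragments), function(s)
      read_fragments_bed(config$fragments[[s]], sample_id = s)))
    prompts <- if (!is.null(config$prompt_fasta))
      Biostrings::readDNAStringSet(config$prompt_fasta) else NULL
  }

  say("stage regions")
  regions <- derive_regions(genes, config$offsets)
  if (write_artifacts) write_regions_bed(regions, file.path(out_dir, "regions.bed"))

  say("stage process")
  filt <- filter_fragments(fragments, min_mapq = config$min_mapq,
                           collapse_duplicates = config$collapse_duplicates)
  removed <- attr(filt, "removed")
  lib <- table(filt$sample_id)
  library_sizes <- setNames(as.numeric(lib), names(lib))
  pol2 <- extract_3prime(filt)
  pol2 <- filter_splicing_intermediates(pol2, genes)
  removed_splicing <- attr(pol2, "removed")

  say("stage count")
  # gene bodies drop fragments spanning the GB of more than one gene;
  # promoter windows keep them (the featureCounts-style default)
  gb_reg <- regions[regions$kind %in% c("GB_DE", "GB_PI"), ]
  pp_reg <- regions[regions$kind %in% c("PPR", "PROMPT"), ]
  raw_gb <- count_overlaps(gb_reg, filt, same_strand = TRUE,
                           exclude_multigene = TRUE,
                           library_sizes = library_sizes)
  raw_pp <- count_overlaps(pp_reg, filt, same_strand = TRUE,
                           exclude_multigene = FALSE,
                           library_sizes = library_sizes)
  raw <- count_table(rbind(raw_gb$counts, raw_pp$counts), library_sizes)
  norm <- normalize_depth(raw, method = config$norm_method)
  if (write_artifacts) write_count_table(raw, file.path(out_dir, "counts.tsv"))

  say("stage diff")
  gb_diff <- diff_features(norm, sample_sheet, preset = "gene",
                           p_threshold = config$p_threshold,
                           lfc_threshold = config$lfc_threshold,
                           unchanged_band = config$unchanged_band)
  prompt_diff <- diff_features(norm, sample_sheet, preset = "prompt",
                               p_threshold = config$p_threshold,
                               lfc_threshold = config$lfc_threshold,
                               unchanged_band = config$unchanged_band)

  say("stage pause")
  pi_tab <- pause_index_table(norm, regions)
  pi_diff <- diff_pause_index(pi_tab, sample_sheet)
  pi_moderate <- select_moderate_pi(pi_diff, config$pi_low, config$pi_high)

  say("stage integrate")
  cls <- classify_genes(gb_diff, prompt_diff, pi_diff,
                        p_threshold = config$p_threshold)
  strat <- tryCatch(stratified_prompt_shift(prompt_diff, gb_diff),
                    error = function(e) NULL)

  say("stage features")
  features <- NULL
  if (!is.null(prompts)) {
    pwms <- if (!is.null(config$motifs)) read_meme_motifs(config$motifs) else
      synthetic_prc2_pwms()
    up_ids <- prompt_diff$feature_id[prompt_diff$status == "up"]
    un_ids <- prompt_diff$feature_id[prompt_diff$status == "unchanged"]
    up_ids <- intersect(up_ids, names(prompts))
    un_ids <- intersect(un_ids, names(prompts))
    if (length(up_ids) && length(un_ids)) {
      fg_g4 <- g4_predict_set(prompts[up_ids], window = config$g4_window,
                              threshold = config$g4_threshold)
      bg_g4 <- g4_predict_set(prompts[un_ids], window = config$g4_window,
                              threshold = config$g4_threshold)
      enr <- motif_enrichment(prompts[up_ids], prompts[un_ids], pwms,
                              threshold = config$motif_score_bits)
      features <- list(g4 = g4_group_compare(fg_g4, bg_g4),
                       g4_fg = fg_g4$table, g4_bg = bg_g4$table,
                       motif_enrichment = enr)
    }
  }

  say("stage metagene")
  track <- coverage_track(pol2, library_size = sum(library_sizes),
                          per_million = TRUE)
  mg_sense <- metagene_profile(track, genes, mode = "reference_point",
                               bin_size = config$metagene_bin,
                               flank = config$metagene_flank,
                               orientation = "sense")
  mg_anti <- metagene_profile(track, genes, mode = "reference_point",
                              bin_size = config$metagene_bin,
                              flank = config$metagene_flank,
                              orientation = "antisense")

  report <- build_report(config, sample_sheet, removed, removed_splicing,
                         library_sizes, gb_diff, prompt_diff, pi_diff,
                         pi_moderate, cls, strat, features, truth)

  if (write_artifacts) {
    fwrite(gb_diff, file.path(out_dir, "diff_gene_body.tsv"), sep = "\t")
    fwrite(prompt_diff, file.path(out_dir, "diff_prompt.tsv"), sep = "\t")
    fwrite(pi_diff, file.path(out_dir, "diff_pause_index.tsv"), sep = "\t")
    fwrite(pi_moderate, file.path(out_dir, "pause_index_moderate.tsv"), sep = "\t")
    fwrite(cls$records, file.path(out_dir, "integration.tsv"), sep = "\t")
    scatter <- cls$records[, c("gene_id", "gb_lfc", "pi_lfc", "prompt_lfc")]
    fwrite(scatter, file.path(out_dir, "scatter3d.tsv"), sep = "\t")
    if (!is.null(features)) {
      fwrite(features$motif_enrichment,
             file.path(out_dir, "motif_enrichment.tsv"), sep = "\t")
      fwrite(features$g4_fg, file.path(out_dir, "g4_upregulated.tsv"), sep = "\t")
      fwrite(features$g4_bg, file.path(out_dir, "g4_unchanged.tsv"), sep = "\t")
    }
    write_bedgraph(track, file.path(out_dir, "pol2"))
    write_metagene_profile(mg_sense, file.path(out_dir, "metagene_tss_sense.tsv"))
    write_metagene_profile(mg_anti, file.path(out_dir, "metagene_tss_antisense.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(genes = genes, truth = truth, sample_sheet = sample_sheet,
                 regions = regions, fragments = filt, positions = pol2,
                 counts_raw = raw, counts_norm = norm,
                 gb_diff = gb_diff, prompt_diff = prompt_diff,
                 pause_index = pi_tab, pi_diff = pi_diff,
                 pi_moderate = pi_moderate, integration = cls,
                 stratified = strat, features = features,
                 metagene_sense = mg_sense, metagene_antisense = mg_anti,
                 report = report),
            class = "pipeline_result")
}

# Internal: assemble the machine-readable run report
build_report <- function(config, sample_sheet, removed, removed_splicing,
                         library_sizes, gb_diff, prompt_diff, pi_diff,
                         pi_moderate, cls, strat, features, truth) {
  count_status <- function(d) as.list(table(d$status))
  rep_ <- list(
    run = list(
      n_samples = nrow(sample_sheet),
      seed = if (!is.null(config$simulate)) config$simulate$seed else NULL,
      simulated = !is.null(config$simulate)),
    filters = list(removed_low_mapq = unname(removed["low_mapq"]),
                   removed_duplicates = unname(removed["duplicate"]),
                   removed_splicing_intermediates = removed_splicing,
                   library_sizes = as.list(library_sizes)),
    gene_body = count_status(gb_diff),
    prompt = count_status(prompt_diff),
    pause_index = list(n_tested = nrow(pi_diff),
                       n_significant = sum(pi_diff$p < config$p_threshold),
                       n_significant_up = sum(pi_diff$p < config$p_threshold &
                                                pi_diff$log2fc > 0),
                       n_moderate = nrow(pi_moderate)),
    integration = cls$summary,
    stratified_prompt_shift = if (!is.null(strat))
      list(p = strat$p, U = strat$U) else NULL,
    sequence_features = if (!is.null(features)) list(
      g4_pct_upregulated = 100 * features$g4$fg_proportion,
      g4_pct_unchanged = 100 * features$g4$bg_proportion,
      g4_coverage_p = features$g4$comparison$p,
      motif_enrichment = features$motif_enrichment) else NULL)
  if (!is.null(truth)) {
    called <- cls$records$gene_id[cls$records$concordance_class ==
                                    "repressed_concordant"]
    planted <- truth$gene_id[truth$class == "repressed_prompt"]
    tp <- length(intersect(called, planted))
    rep_$truth_confusion <- list(
      n_planted_repressed = length(planted),
      n_called_concordant = length(called),
      true_positive = tp,
      false_positive = length(called) - tp,
      sensitivity = if (length(planted)) tp / length(planted) else NA,
      fdr = if (length(called)) (length(called) - tp) / length(called) else NA)
  }
  rep_
}
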