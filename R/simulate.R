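#' Simulation configuration
#'
#' Parameters of the synthetic nascent-transcription dataset. The generator
#' emulates the statistical structure the analysis assumes: per-gene sense
#' gene-body signal, a promoter-proximal pause peak, antisense PROMPT signal
#' in the 500 bp upstream window, negative-binomial replicate noise, and
#' condition-specific multiplicative effects applied in the irradiated (IR)
#' condition.
#'
#' Genes are planted in one of three classes: `repressed_prompt` (gene body
#' down, PROMPT and pause signal up upon IR — the coupled repression
#' signature), `upregulated` (gene body up, promoter signal unchanged) and
#' `null` (no effect; all true log2 fold changes exactly 0).
#'
#' @param n_genes number of genes.
#' @param chrom_length length of the single synthetic chromosome (bp).
#' @param gene_length_range min/max gene length (bp).
#' @param n_replicates_per_condition replicates per condition (IR / noIR).
#' @param target_fragments_per_sample if not `NA`, densities are rescaled so
#'   the expected total fragment count per sample equals this value.
#' @param nb_dispersion negative-binomial dispersion `a` in
#'   `var = mu + a * mu^2` (replicate CV of a deeply covered feature is
#'   about `sqrt(a)`).
#' @param baseline_gb_density expected gene-body fragments per kb per sample.
#' @param pause_enrichment multiplicative density factor of the PPR over the
#'   gene body (>= 1); equals the expected pause index of a null gene.
#' @param prompt_fraction expected PROMPT density relative to gene-body
#'   density.
#' @param class_proportions named fractions for
#'   `repressed_prompt`/`upregulated`/`null`; must sum to 1.
#' @param effects per-class log2 effects `c(gb=, prompt=, ppr=)` applied
#'   multiplicatively (as `2^effect`) in the IR condition.
#' @param fragment_length_range fragment length range (bp), clipped to the
#'   region; mirrors the small (<100 nt) size-selected RNA fraction of
#'   mNET-seq libraries.
#' @param prompt_seq_gc GC fraction of simulated PROMPT sequences.
#' @param g4_plant_prob per-class probability that a canonical G-quadruplex
#'   block is planted in the gene's PROMPT sequence.
#' @param motif_plant_prob per-class probability that a PWM consensus is
#'   planted in the gene's PROMPT sequence.
#' @param buffer_bp minimum spacing between gene spans (also the leading
#'   gap), so PROMPT windows and metagene flanks of neighbours never touch.
#' @param seed master seed; every derived output is deterministic given the
#'   full configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       chrom_length = 8e6,
                       gene_length_range = c(1500L, 6000L),
                       n_replicates_per_condition = 4L,
                       target_fragments_per_sample = NA,
                       nb_dispersion = 0.02,
                       baseline_gb_density = 150,
                       pause_enrichment = 10,
                       prompt_fraction = 1.0,
                       class_proportions = c(repressed_prompt = 0.1,
                                             upregulated = 0.1,
                                             null = 0.8),
                       effects = list(
                         repressed_prompt = c(gb = -1, prompt = 1.5, ppr = 1),
                         upregulated = c(gb = 1, prompt = 0, ppr = 1),
                         null = c(gb = 0, prompt = 0, ppr = 0)),
                       fragment_length_range = c(30L, 80L),
                       prompt_seq_gc = 0.5,
                       g4_plant_prob = c(repressed_prompt = 0.35,
                                         upregulated = 0.19,
                                         null = 0.19),
                       motif_plant_prob = c(repressed_prompt = 0.8,
                                            upregulated = 0.1,
                                            null = 0.1),
                       buffer_bp = 2000L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              chrom_length = as.numeric(chrom_length),
              gene_length_range = as.integer(gene_length_range),
              n_replicates_per_condition = as.integer(n_replicates_per_condition),
              target_fragments_per_sample = target_fragments_per_sample,
              nb_dispersion = nb_dispersion,
              baseline_gb_density = baseline_gb_density,
              pause_enrichment = pause_enrichment,
              prompt_fraction = prompt_fraction,
              class_proportions = class_proportions,
              effects = effects,
              fragment_length_range = as.integer(fragment_length_range),
              prompt_seq_gc = prompt_seq_gc,
              g4_plant_prob = g4_plant_prob,
              motif_plant_prob = motif_plant_prob,
              buffer_bp = as.integer(buffer_bp),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  cls <- c("repressed_prompt", "upregulated", "null")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    abort("class_proportions must sum to 1 (got %.12f)", sum(cfg$class_proportions))
  if (!all(names(cfg$class_proportions) %in% cls))
    abort("class_proportions names must be among: %s", paste(cls, collapse = ", "))
  if (cfg$nb_dispersion <= 0 || cfg$baseline_gb_density <= 0 ||
      cfg$prompt_fraction <= 0)
    abort("densities and dispersion must be > 0")
  if (cfg$pause_enrichment < 1) abort("pause_enrichment must be >= 1")
  if (cfg$gene_length_range[1] < 1L ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2])
    abort("invalid gene_length_range")
  probs <- c(cfg$class_proportions, cfg$g4_plant_prob, cfg$motif_plant_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  invisible(cfg)
}

# Internal: largest-remainder apportionment of n among proportions
apportion <- function(n, props) {
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- props * n - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1L
  }
  as.integer(base)
}

#' Simulate gene models and ground truth
#'
#' Places `n_genes` non-overlapping genes (with a `buffer_bp` spacing so
#' PROMPT windows never collide) on one synthetic chromosome, assigns each a
#' class per `class_proportions`, and records the planted per-gene truth:
#' class, true log2 effects (exactly 0 for the null class), and whether a
#' G-quadruplex block and/or a motif consensus will be planted in its PROMPT
#' sequence. Each gene carries 1–4 exons so splicing-intermediate filtering
#' is exercised. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (gene model data.frame with `exons` list
#'   column) and `truth` (data.frame: `gene_id`, `class`, `true_lfc_gb`,
#'   `true_lfc_prompt`, `true_lfc_ppr`, `g4_planted`, `motif_planted`).
#' @export
simulate_genome_and_truth <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  buf <- config$buffer_bp
  set.seed(derive_seed(config$seed, 0L))

  lens <- runif_int(n, config$gene_length_range[1], config$gene_length_range[2])
  need <- sum(as.numeric(lens)) + as.numeric(buf) * (n + 1)
  if (need > config$chrom_length)
    abort(paste0("cannot pack %d genes (+%d bp buffers) into %g bp; ",
                 "need at least %g bp"), n, buf, config$chrom_length, need)
  slack <- config$chrom_length - need
  w <- runif(n + 1)
  extra <- floor(w / sum(w) * slack)
  starts <- as.integer(buf + extra[1] +
                         c(0, cumsum(as.numeric(lens[-n]) + buf + extra[2:n])))
  if (n == 1L) starts <- as.integer(buf + extra[1])
  ends <- starts + lens
  strand <- sample(c("+", "-"), n, replace = TRUE)

  gene_id <- sprintf("g%04d", seq_len(n))
  exons <- lapply(seq_len(n), function(i) {
    k <- runif_int(1L, 1L, 4L)
    if (k == 1L || lens[i] < 2L * k)
      return(cbind(start = starts[i], end = ends[i]))
    cuts <- sort(sample((starts[i] + 1L):(ends[i] - 1L), 2L * (k - 1L)))
    bounds <- c(starts[i], cuts, ends[i])
    m <- matrix(bounds, ncol = 2L, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  })

  genes <- data.frame(gene_id = gene_id, chrom = "chrS", start = starts,
                      end = ends, strand = strand,
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  genes$exons <- exons

  cls_names <- names(config$class_proportions)
  counts <- apportion(n, config$class_proportions)
  class_vec <- sample(rep(cls_names, counts))
  eff <- do.call(rbind, lapply(class_vec, function(cl) config$effects[[cl]]))
  truth <- data.frame(gene_id = gene_id, class = class_vec,
                      true_lfc_gb = eff[, "gb"],
                      true_lfc_prompt = eff[, "prompt"],
                      true_lfc_ppr = eff[, "ppr"],
                      g4_planted = runif(n) < config$g4_plant_prob[class_vec],
                      motif_planted = runif(n) < config$motif_plant_prob[class_vec],
                      stringsAsFactors = FALSE)
  list(genes = genes, truth = truth)
}

#' Simulate stranded read fragments
#'
#' Per gene and sample, fragment counts in the gene body (`GB_DE`, sense),
#' promoter-proximal region (`PPR`, sense) and PROMPT window (`PROMPT`,
#' antisense) are drawn negative-binomially with mean
#' `density x region_length(kb) x depth factor`; the PPR mean carries the
#' additional `pause_enrichment` factor and IR samples multiply the gene
#' class's `2^effect`. Fragments are placed uniformly, fully inside their
#' region, with the strand of the region, so re-counting them with
#' [count_overlaps()] recovers the internal draws exactly. Each sample uses
#' its own RNG stream derived from the master seed, so adding samples never
#' perturbs existing ones.
#'
#' @param genes,truth from [simulate_genome_and_truth()].
#' @param config the same [sim_config()].
#' @param offsets [region_config()] used to derive the signal regions.
#' @return list with `fragments` (data.table: `chrom`, `start`, `end`,
#'   `strand`, `mapq`, `read_id`, `sample_id`), `library_sizes` (named
#'   total fragments per sample), `sample_sheet` (data.frame: `sample`,
#'   `condition`, `antibody`, `replicate`, `batch`; technical replicate i of
#'   both conditions shares batch i), `draws` (the internal per-gene counts)
#'   and `regions`.
#' @export
simulate_fragments <- function(genes, truth, config, offsets = region_config()) {
  validate_sim_config(config)
  if (!identical(genes$gene_id, truth$gene_id))
    abort("genes and truth must be aligned by gene_id")
  regions <- derive_regions(genes, offsets)
  reg <- as.data.table(regions[regions$kind %in% c("GB_DE", "PPR", "PROMPT") &
                                 !regions$flagged, ])
  reg[, len := end - start]
  reg <- merge(reg, as.data.table(truth)[, .(gene_id, class)], by = "gene_id",
               sort = FALSE)
  dens <- c(GB_DE = config$baseline_gb_density,
            PPR = config$baseline_gb_density * config$pause_enrichment,
            PROMPT = config$baseline_gb_density * config$prompt_fraction)
  reg[, mu0 := dens[kind] * len / 1000]
  f <- 1
  if (!is.na(config$target_fragments_per_sample))
    f <- config$target_fragments_per_sample / sum(reg$mu0)
  eff_kind <- c(GB_DE = "gb", PPR = "ppr", PROMPT = "prompt")
  reg[, delta := vapply(seq_len(.N), function(i)
    config$effects[[class[i]]][[eff_kind[[kind[i]]]]], 0)]

  nrep <- config$n_replicates_per_condition
  sheet <- data.frame(
    sample = c(paste0("noIR_rep", seq_len(nrep)), paste0("IR_rep", seq_len(nrep))),
    condition = rep(c("noIR", "IR"), each = nrep),
    antibody = "Y1P",
    replicate = rep(seq_len(nrep), 2L),
    batch = rep(seq_len(nrep), 2L),
    stringsAsFactors = FALSE)

  flr <- config$fragment_length_range
  frag_list <- vector("list", nrow(sheet))
  draw_list <- vector("list", nrow(sheet))
  for (s in seq_len(nrow(sheet))) {
    set.seed(derive_seed(config$seed, s))
    ir <- sheet$condition[s] == "IR"
    mu <- reg$mu0 * f * (if (ir) 2^reg$delta else 1)
    counts <- rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    idx <- rep(seq_len(nrow(reg)), counts)
    m <- length(idx)
    lens <- pmin(runif_int(m, flr[1], flr[2]), reg$len[idx])
    st <- reg$start[idx] + as.integer(floor(runif(m) * (reg$len[idx] - lens + 1L)))
    frag_list[[s]] <- data.table(chrom = reg$chrom[idx], start = st,
                                 end = st + lens, strand = reg$strand[idx],
                                 mapq = 60L, read_id = seq_len(m),
                                 sample_id = sheet$sample[s])
    draw_list[[s]] <- data.table(gene_id = reg$gene_id, kind = reg$kind,
                                 sample_id = sheet$sample[s], count = counts)
  }
  fragments <- rbindlist(frag_list)
  draws <- rbindlist(draw_list)
  lib <- vapply(frag_list, nrow, 0L)
  names(lib) <- sheet$sample
  list(fragments = fragments, library_sizes = lib, sample_sheet = sheet,
       draws = draws, regions = regions)
}

#' Simulate PROMPT sequences
#'
#' Emits one 500-nt sequence per gene at the configured GC content. Genes
#' whose truth row has `g4_planted` receive a canonical quadruplex block
#' (four runs of >= 3 G separated by 1–7 nt A/C/T spacers) in the second
#' half of the sequence; genes with `motif_planted` receive the exact
#' consensus of `pwm` in the first half, so the two plants never clobber
#' each other. Deterministic given the seed.
#'
#' @param genes,truth from [simulate_genome_and_truth()].
#' @param config the same [sim_config()].
#' @param pwm PWM whose consensus is planted; defaults to the GC-rich
#'   synthetic stand-in `synthetic_prc2_pwms()[["synthP14"]]`.
#' @param width sequence length (nt).
#' @return a [Biostrings::DNAStringSet] named by `gene_id`.
#' @export
simulate_prompt_sequences <- function(genes, truth, config, pwm = NULL,
                                      width = 500L) {
  validate_sim_config(config)
  if (is.null(pwm)) pwm <- synthetic_prc2_pwms()[["synthP14"]]
  set.seed(derive_seed(config$seed, 997L))
  gc <- config$prompt_seq_gc
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cons <- pwm_consensus(pwm)
  if (nchar(cons) > width) abort("planted motif longer than sequence")
  half <- width %/% 2L
  seqs <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    chars <- sample(names(base_prob), width, replace = TRUE, prob = base_prob)
    if (truth$g4_planted[i]) {
      block <- g4_block()
      if (nchar(block) > width) abort("planted G4 block longer than sequence")
      at <- runif_int(1L, min(half, width - nchar(block)), width - nchar(block))
      chars[(at + 1L):(at + nchar(block))] <- strsplit(block, "")[[1]]
    }
    if (truth$motif_planted[i]) {
      at <- runif_int(1L, 0L, max(0L, half - nchar(cons)))
      chars[(at + 1L):(at + nchar(cons))] <- strsplit(cons, "")[[1]]
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genes$gene_id
  out
}

# Internal: one canonical quadruplex block, e.g. GGGG-ac-GGG-t-GGG-ca-GGGG
g4_block <- function() {
  runs <- vapply(runif_int(4L, 3L, 4L), function(k)
    paste(rep("G", k), collapse = ""), "")
  spacers <- vapply(runif_int(3L, 1L, 7L), function(k)
    paste(sample(c("A", "C", "T"), k, replace = TRUE), collapse = ""), "")
  paste0(runs[1], spacers[1], runs[2], spacers[2], runs[3], spacers[3], runs[4])
}

#' Write all simulation artifacts to a directory
#'
#' Writes the annotation (BED12), per-sample fragment BED6 files, the sample
#' sheet and truth TSVs, and the PROMPT FASTA. All outputs are deterministic
#' given the configuration.
#'
#' @param sim list with `genes`, `truth`, and the [simulate_fragments()]
#'   output (`fragments`, `library_sizes`, `sample_sheet`).
#' @param dir output directory (created if absent).
#' @param sequences optional [simulate_prompt_sequences()] output.
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir, sequences = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- file.path(dir, "genes.bed12")
  write_gene_bed12(sim$genes, p); files <- c(files, p)
  p <- file.path(dir, "genes.gtf")
  write_gene_gtf(sim$genes, p); files <- c(files, p)
  for (s in unique(sim$fragments$sample_id)) {
    p <- file.path(dir, paste0("fragments_", s, ".bed"))
    write_fragments_bed(sim$fragments[sim$fragments$sample_id == s, ], p)
    files <- c(files, p)
  }
  p <- file.path(dir, "sample_sheet.tsv")
  fwrite(sim$sample_sheet, p, sep = "\t"); files <- c(files, p)
  p <- file.path(dir, "truth.tsv")
  fwrite(sim$truth, p, sep = "\t"); files <- c(files, p)
  if (!is.null(sequences)) {
    p <- file.path(dir, "prompts.fa")
    Biostrings::writeXStringSet(sequences, p); files <- c(files, p)
  }
  invisible(files)
}
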