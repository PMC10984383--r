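tiny_cfg <- function(...) {
  sim_config(n_genes = 10, chrom_length = 1e6, baseline_gb_density = 40,
             seed = 1, ...)
}

test_that("genome simulation packs buffered genes and assigns classes", {
  cfg <- tiny_cfg()
  gt <- simulate_genome_and_truth(cfg)
  expect_equal(nrow(gt$genes), 10L)
  expect_equal(nrow(gt$truth), 10L)
  g <- gt$genes[order(gt$genes$start), ]
  expect_true(all(g$start[-1] - g$end[-nrow(g)] >= cfg$buffer_bp))
  expect_true(all(g$start >= cfg$buffer_bp))
  expect_error(simulate_genome_and_truth(
    sim_config(n_genes = 100, chrom_length = 1e5, seed = 1)), "pack")
})

test_that("simulation is deterministic given the seed, down to written bytes", {
  cfg <- tiny_cfg()
  run <- function() {
    gt <- simulate_genome_and_truth(cfg)
    sim <- simulate_fragments(gt$genes, gt$truth, cfg)
    seqs <- simulate_prompt_sequences(gt$genes, gt$truth, cfg)
    dir <- withr::local_tempdir()
    write_simulation(c(gt, sim), dir, sequences = seqs)
    sapply(sort(list.files(dir, full.names = TRUE)), tools::md5sum)
  }
  expect_identical(unname(run()), unname(run()))
})

test_that("an all-null configuration plants no effects", {
  cfg <- sim_config(n_genes = 8, chrom_length = 5e5,
                    class_proportions = c(repressed_prompt = 0,
                                          upregulated = 0, null = 1),
                    seed = 2)
  gt <- simulate_genome_and_truth(cfg)
  expect_true(all(gt$truth$class == "null"))
  expect_true(all(gt$truth$true_lfc_gb == 0))
  expect_true(all(gt$truth$true_lfc_prompt == 0))
  expect_true(all(gt$truth$true_lfc_ppr == 0))
})

test_that("null genes show log2FC centered at zero at high depth", {
  cfg <- sim_config(n_genes = 400, chrom_length = 4e6,
                    gene_length_range = c(1500, 4000),
                    baseline_gb_density = 200,
                    class_proportions = c(repressed_prompt = 0,
                                          upregulated = 0, null = 1),
                    seed = 3)
  gt <- simulate_genome_and_truth(cfg)
  sim <- simulate_fragments(gt$genes, gt$truth, cfg)
  ct <- count_overlaps(sim$regions[sim$regions$kind == "GB_DE", ],
                       sim$fragments, library_sizes = sim$library_sizes)
  m <- as_count_matrix(normalize_depth(ct), "GB_DE")
  ctrl <- rowMeans(m[, paste0("noIR_rep", 1:4)])
  trt <- rowMeans(m[, paste0("IR_rep", 1:4)])
  lfc <- log2(trt / ctrl)
  expect_lt(abs(mean(lfc)), 0.05)
  # and within 3 standard errors of zero
  expect_lt(abs(mean(lfc)), 3 * sd(lfc) / sqrt(length(lfc)) + 1e-9)
})

test_that("planted PROMPT effects are recovered at adequate depth", {
  cfg <- sim_config(n_genes = 300, chrom_length = 3e6,
                    gene_length_range = c(1500, 4000),
                    baseline_gb_density = 150, prompt_fraction = 3,
                    class_proportions = c(repressed_prompt = 0.5,
                                          upregulated = 0, null = 0.5),
                    seed = 4)
  gt <- simulate_genome_and_truth(cfg)
  sim <- simulate_fragments(gt$genes, gt$truth, cfg)
  ct <- count_overlaps(sim$regions[sim$regions$kind == "PROMPT", ],
                       sim$fragments, library_sizes = sim$library_sizes)
  m <- as_count_matrix(ct, "PROMPT")
  expect_gte(mean(m), 200)  # the depth at which the check is stated
  # raw counts: every sample has the same expected depth by construction,
  # so the planted multiplicative effect is read off directly
  planted <- gt$truth$gene_id[gt$truth$class == "repressed_prompt"]
  lfc <- log2(rowMeans(m[planted, paste0("IR_rep", 1:4)]) /
                rowMeans(m[planted, paste0("noIR_rep", 1:4)]))
  expect_lt(abs(mean(lfc) - 1.5), 0.1)
})

test_that("PROMPT sequences are 500 nt with forced G4 plants when requested", {
  cfg <- sim_config(n_genes = 30, chrom_length = 1e6,
                    class_proportions = c(repressed_prompt = 1,
                                          upregulated = 0, null = 0),
                    g4_plant_prob = c(repressed_prompt = 1,
                                      upregulated = 0, null = 0),
                    seed = 5)
  gt <- simulate_genome_and_truth(cfg)
  seqs <- simulate_prompt_sequences(gt$genes, gt$truth, cfg)
  expect_true(all(Biostrings::width(seqs) == 500))
  scanned <- g4_predict_set(seqs, method = "quadparser")
  expect_true(all(scanned$table$has_g4))
})

test_that("without planting, the scan of emitted sequences is self-consistent", {
  cfg <- sim_config(n_genes = 40, chrom_length = 1.5e6,
                    g4_plant_prob = c(repressed_prompt = 0,
                                      upregulated = 0, null = 0),
                    motif_plant_prob = c(repressed_prompt = 0,
                                         upregulated = 0, null = 0),
                    seed = 6)
  gt <- simulate_genome_and_truth(cfg)
  expect_true(all(!gt$truth$g4_planted))
  seqs <- simulate_prompt_sequences(gt$genes, gt$truth, cfg)
  scanned <- g4_predict_set(seqs, method = "quadparser")
  # spontaneous rate as measured by the scan is the reported rate
  expect_equal(mean(scanned$table$has_g4),
               sum(scanned$table$n_windows > 0) / length(seqs))
})

test_that("class proportions are apportioned exactly", {
  cfg <- sim_config(n_genes = 20, chrom_length = 1.5e6,
                    class_proportions = c(repressed_prompt = 0.25,
                                          upregulated = 0.15, null = 0.6),
                    seed = 7)
  gt <- simulate_genome_and_truth(cfg)
  tab <- table(gt$truth$class)
  expect_equal(unname(tab[["repressed_prompt"]]), 5L)
  expect_equal(unname(tab[["upregulated"]]), 3L)
  expect_equal(unname(tab[["null"]]), 12L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_proportions = c(repressed_prompt = 0.5,
                                                upregulated = 0.4,
                                                null = 0.2)), "sum to 1")
  expect_error(sim_config(nb_dispersion = 0), "> 0")
  expect_error(sim_config(pause_enrichment = 0.5), ">= 1")
})
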