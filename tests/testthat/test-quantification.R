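test_that("overlap and strand semantics match bedtools-style counting", {
  reg <- data.frame(gene_id = "g", kind = "GB_DE", chrom = "c",
                    start = 1000L, end = 1500L, strand = "+", flagged = FALSE)
  fr <- rbind(frag("c", 1400, 1600, "+", read_id = 1L),
              frag("c", 1200, 1300, "-", read_id = 2L),
              frag("c", 900, 1000, "+", read_id = 3L))
  ct <- count_overlaps(reg, fr)
  expect_equal(ct$counts$count, 1L)  # strand and half-open overlap enforced
  ct2 <- count_overlaps(reg, fr, same_strand = FALSE)
  expect_equal(ct2$counts$count, 2L)
})

test_that("antisense PROMPT fragments count sense-to-region", {
  g <- data.frame(gene_id = "g", chrom = "c", start = 10000L, end = 20000L,
                  strand = "+")
  reg <- derive_regions(g)
  pr <- reg[reg$kind == "PROMPT", ]
  fr <- rbind(frag("c", 9600, 9650, "-", read_id = 1L),
              frag("c", 9600, 9650, "+", read_id = 2L))
  ct <- count_overlaps(pr, fr)
  expect_equal(ct$counts$count, 1L)  # only the antisense (-) fragment
})

test_that("counting equals the per-base brute-force oracle on random instances", {
  set.seed(7)
  for (trial in 1:40) {
    nr <- sample(3:8, 1); nf <- sample(10:60, 1)
    reg <- data.frame(gene_id = paste0("g", seq_len(nr)),
                      kind = "GB_DE", chrom = sample(c("c1", "c2"), nr, TRUE),
                      start = sample(0:500, nr, TRUE))
    reg$end <- reg$start + sample(10:200, nr, TRUE)
    reg$strand <- sample(c("+", "-"), nr, TRUE)
    reg$flagged <- FALSE
    fr <- data.table::data.table(
      chrom = sample(c("c1", "c2", "c3"), nf, TRUE),
      start = sample(0:600, nf, TRUE))
    fr[, end := start + sample(5:100, nf, TRUE)]
    fr[, strand := sample(c("+", "-"), nf, TRUE)]
    fr[, mapq := 60L]; fr[, read_id := seq_len(nf)]
    fr[, sample_id := sample(c("s1", "s2"), nf, TRUE)]
    ss <- sample(c(TRUE, FALSE), 1)
    expected <- suppressWarnings(oracle_count(reg, as.data.frame(fr), ss))
    got <- suppressWarnings(count_overlaps(reg, fr, same_strand = ss))
    gm <- as_count_matrix(got, "GB_DE")
    for (i in seq_len(nr)) {
      for (s in colnames(expected)) {
        expect_equal(unname(as.numeric(gm[reg$gene_id[i], s])),
                     as.numeric(expected[i, s]))
      }
    }
  }
})

test_that("counts are invariant to fragment order", {
  set.seed(11)
  reg <- data.frame(gene_id = c("g1", "g2"), kind = "PPR", chrom = "c",
                    start = c(100L, 400L), end = c(300L, 600L),
                    strand = c("+", "-"), flagged = FALSE)
  fr <- data.table::data.table(chrom = "c", start = sample(0:600, 100, TRUE))
  fr[, end := start + 20L][, strand := sample(c("+", "-"), 100, TRUE)]
  fr[, mapq := 60L][, read_id := .I][, sample_id := "s1"]
  a <- count_overlaps(reg, fr)
  b <- count_overlaps(reg, fr[sample(.N)])
  expect_equal(a$counts$count, b$counts$count)
})

test_that("multigene fragments are excluded from gene-body counting when requested", {
  reg <- data.frame(gene_id = c("g1", "g2"), kind = "GB_DE", chrom = "c",
                    start = c(100L, 260L), end = c(300L, 500L),
                    strand = "+", flagged = FALSE)
  fr <- rbind(frag("c", 250, 280, "+", read_id = 1L),   # spans both
              frag("c", 120, 150, "+", read_id = 2L))   # g1 only
  ct <- count_overlaps(reg, fr, exclude_multigene = TRUE)
  m <- as_count_matrix(ct, "GB_DE")
  expect_equal(unname(m["g1", "s1"]), 1)
  expect_equal(unname(m["g2", "s1"]), 0)
})

test_that("CPM normalization scales by library size and preserves zeros", {
  m <- matrix(c(10, 0), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  ct <- table_from_matrix(m, lib = c(s1 = 2e6), normalized = FALSE)
  norm <- normalize_depth(ct)
  nm <- as_count_matrix(norm, "PROMPT")
  expect_equal(unname(nm["g1", "s1"]), 5.0)
  expect_equal(unname(nm["g2", "s1"]), 0.0)
  # doubling counts and library sizes leaves CPM unchanged
  ct2 <- table_from_matrix(2 * m, lib = c(s1 = 4e6), normalized = FALSE)
  expect_equal(as_count_matrix(normalize_depth(ct2), "PROMPT"), nm)
  expect_error(normalize_depth(table_from_matrix(m, lib = c(s1 = 0),
                                                 normalized = FALSE)),
               "library")
})

test_that("re-counting simulated fragments reproduces the generator's draws exactly", {
  cfg <- sim_config(n_genes = 15, chrom_length = 2.5e5,
                    baseline_gb_density = 40, seed = 5)
  gt <- simulate_genome_and_truth(cfg)
  sim <- simulate_fragments(gt$genes, gt$truth, cfg)
  ct <- count_overlaps(sim$regions[sim$regions$kind != "GB_PI", ],
                       sim$fragments, library_sizes = sim$library_sizes)
  got <- merge(as.data.frame(ct$counts), as.data.frame(sim$draws),
               by = c("kind", "gene_id", "sample_id"),
               suffixes = c("_counted", "_drawn"))
  expect_equal(nrow(got), nrow(sim$draws))
  expect_identical(as.integer(got$count_counted), as.integer(got$count_drawn))
})

test_that("median-of-ratios scaling removes compositional library shift", {
  set.seed(97)
  n <- 200
  base <- rnbinom(n, mu = 500, size = 100)
  m <- cbind(s1 = base, s2 = base)
  # sample 2 gains a large induced block: totals shift, most genes do not
  m[1:20, "s2"] <- m[1:20, "s2"] * 8L
  rownames(m) <- paste0("g", seq_len(n))
  ct <- table_from_matrix(m, kind = "GB_DE",
                          lib = c(s1 = sum(m[, 1]), s2 = sum(m[, 2])),
                          normalized = FALSE)
  cpm <- as_count_matrix(normalize_depth(ct, method = "total"), "GB_DE")
  mr <- as_count_matrix(normalize_depth(ct, method = "median_ratio"), "GB_DE")
  null_genes <- 21:n
  bias_cpm <- median(log2(cpm[null_genes, "s2"] / cpm[null_genes, "s1"]))
  bias_mr <- median(log2(mr[null_genes, "s2"] / mr[null_genes, "s1"]))
  expect_gt(abs(bias_cpm), 0.05)     # totals are shifted by the block
  expect_lt(abs(bias_mr), 0.01)      # ratios are not
})
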