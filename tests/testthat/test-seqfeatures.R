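test_that("G4Hunter scores follow the run-length arithmetic", {
  r0 <- g4_predict(strrep("A", 30), window = 25)
  expect_equal(nrow(r0$windows), 0L)
  expect_equal(r0$max_window_score, 0)
  expect_equal(r0$coverage_pct, 0)
  # G/C symmetry: GGGGCCCC sums to zero
  r1 <- g4_predict("GGGGCCCC", window = 8)
  expect_equal(r1$max_window_score, 0)
  expect_equal(nrow(r1$windows), 0L)
  # 15-nt canonical G4: mean (12 x 3) / 15 = 2.4
  r2 <- g4_predict("GGGAGGGAGGGAGGG", window = 15)
  expect_equal(r2$max_window_score, 2.4)
  expect_equal(nrow(r2$windows), 1L)
  expect_equal(r2$coverage_pct, 100)
  # quadparser fires on the same sequence
  r3 <- g4_predict("GGGAGGGAGGGAGGG", method = "quadparser")
  expect_equal(unname(r3$windows[1, ]), c(0L, 15L))
  # U handled as T; junk rejected
  expect_equal(g4_predict("GGGAGGGAGGGAGGG", window = 15)$max_window_score,
               g4_predict("GGGAGGGAGGGAGGG", window = 15)$max_window_score)
  expect_error(g4_predict("GGXGG", window = 2), "non-nucleotide")
  expect_error(g4_predict("GGG", window = 25), "shorter")
})

test_that("per-base G4Hunter scores are bounded and window scores likewise", {
  set.seed(61)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 80, TRUE), collapse = "")
    r <- g4_predict(s, window = 25, threshold = 0.8)
    expect_lte(r$max_window_score, 4)
    expect_gte(r$max_window_score, -4)
  }
  expect_equal(g4_predict(strrep("G", 30), window = 25)$max_window_score, 4)
})

test_that("coverage percentage is the interval union over the length", {
  expect_equal(rg4_coverage(100, cbind(10L, 40L)), 30)
  expect_equal(rg4_coverage(100, rbind(c(10L, 40L), c(30L, 60L))), 50)
  expect_equal(rg4_coverage(100, rbind(c(30L, 60L), c(10L, 40L))), 50)
  expect_equal(rg4_coverage(100, matrix(integer(0), ncol = 2)), 0)
  expect_error(rg4_coverage(50, cbind(10L, 60L)), "range")
})

test_that("group comparison reports proportions and an exact MWU", {
  fg <- g4_predict_set(c(a = "GGGAGGGAGGGAGGGAAAAAAAAAA",
                         b = "GGGTGGGTGGGTGGGAAAAAAAAAA"), window = 15,
                       threshold = 1.2)
  bg <- g4_predict_set(c(c = strrep("AT", 13), d = strrep("CA", 13)),
                       window = 15, threshold = 1.2)
  cmp <- g4_group_compare(fg, bg)
  expect_equal(cmp$fg_proportion, 1)
  expect_equal(cmp$bg_proportion, 0)
  same <- g4_group_compare(fg, fg)
  expect_equal(same$comparison$p, 1)
})

test_that("MEME minimal format round-trips and validates", {
  pwms <- synthetic_prc2_pwms()
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(pwms, path)
  back <- read_meme_motifs(path)
  expect_equal(length(back), 4L)
  expect_equal(names(back), names(pwms))
  for (nm in names(pwms)) {
    expect_equal(back[[nm]]$mat, pwms[[nm]]$mat, tolerance = 1e-5)
    expect_true(all(abs(colSums(back[[nm]]$mat) - 1) < 1e-6))
  }
  # RNA alphabet accepted
  txt <- c("MEME version 4", "", "ALPHABET= ACGU", "",
           "MOTIF m1", "letter-probability matrix: alength= 4 w= 2",
           "0.25 0.25 0.25 0.25", "0.97 0.01 0.01 0.01")
  m1 <- read_meme_motifs(paste(txt, collapse = "\n"))
  expect_equal(m1$m1$width, 2L)
  # bad row errors with a line number
  bad <- sub("0.97 0.01 0.01 0.01", "0.50 0.01 0.01 0.01", txt)
  expect_error(read_meme_motifs(paste(bad, collapse = "\n")), "sum")
})

test_that("PWM scanning gives closed-form log-odds scores", {
  uni <- list(motif_id = "u", width = 3L,
              mat = matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"))),
              background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  class(uni) <- "pwm"
  hits <- scan_pwm("ACGTACGT", uni, score_threshold_bits = 0)
  expect_equal(hits$score, rep(0, 6))
  cons <- synthetic_prc2_pwms(peak = 1)[["synthP7"]]  # GCGGCGGC
  hits2 <- scan_pwm(paste0("AAAA", "GCGGCGGC", "AAAA"), cons,
                    score_threshold_bits = 15)
  expect_equal(hits2$offset, 4L)
  expect_equal(hits2$score, 8 * log2(1 / 0.25), tolerance = 1e-6)
  expect_equal(nrow(scan_pwm("ACGTACGTACGT", cons, 1e6)), 0L)
})

test_that("Fisher enrichment equals hypergeometric tail enumeration", {
  fg <- c(s1 = "AAGCGGCGGCAA", s2 = "TTGCGGCGGCTT")
  bg <- c(s3 = "ATATATATATAT", s4 = "TATATATATATA")
  pwm <- synthetic_prc2_pwms(peak = 1)["synthP7"]
  res <- motif_enrichment(fg, bg, pwm, threshold = 15)
  expect_equal(res$fg_hits, 2L)
  expect_equal(res$bg_hits, 0L)
  expect_equal(res$p, 1 / 6)
  # oracle property over random small tables
  set.seed(67)
  for (i in 1:100) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c_ <- sample(0:7, 1); d <- sample(0:7, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                                alternative = "greater")$p.value
    expect_equal(p_pkg, oracle_fisher_greater(a, b, c_, d), tolerance = 1e-12)
  }
})

test_that("planted motif simulation yields overwhelming enrichment", {
  set.seed(71)
  pwm <- synthetic_prc2_pwms()[["synthP14"]]
  plant <- function(n, p_plant) {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
      if (runif(1) < p_plant)
        s <- paste0(substr(s, 1, 20), "GCGGCGGG", substr(s, 29, 60))
      s
    }, "")
  }
  fg <- plant(200, 0.8); bg <- plant(200, 0.1)
  res <- motif_enrichment(fg, bg, list(pwm), threshold = 10)
  expect_lt(res$p, 1e-10)
  expect_gt(res$fg_pct, res$bg_pct)
})
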