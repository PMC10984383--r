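#' Predict RNA G-quadruplex-forming intervals in one sequence
#'
#' Two auditable scoring schemes standard in the G4 field:
#'
#' * `g4hunter`: each base scores `+min(run, 4)` if it is a G inside a
#'   G-run of length `run`, `-min(run, 4)` for a C in a C-run, 0 otherwise
#'   (N scores 0). Scores are averaged over a sliding window; windows whose
#'   mean is at least `threshold` are merged into predicted intervals. A
#'   positive threshold selects G-rich (forming) strands; the C-run penalty
#'   makes the score strand-skew aware.
#' * `quadparser`: the canonical pattern of four runs of >= 3 Gs separated
#'   by 1–7 nt loops, `G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+`; matches are merged.
#'
#' @param seq a character scalar or `XString` over A/C/G/T/U/N
#'   (case-insensitive; U is treated as T).
#' @param method `"g4hunter"` (default) or `"quadparser"`.
#' @param window sliding window length (g4hunter; sequence must be at least
#'   this long).
#' @param threshold minimum window mean (g4hunter; 1.2 is the field
#'   default).
#' @param sequence_id id carried into the result.
#' @return list of class `g4_result`: `sequence_id`, `windows` (merged
#'   matrix of 0-based half-open `start`,`end`), `max_window_score`,
#'   `coverage_pct`, `seq_length`.
#' @examples
#' g4_predict("GGGAGGGAGGGAGGG", window = 15)$max_window_score  # 2.4
#' @export
g4_predict <- function(seq, method = c("g4hunter", "quadparser"),
                       window = 25L, threshold = 1.2, sequence_id = "seq") {
  method <- match.arg(method)
  s <- toupper(as.character(seq))
  s <- gsub("U", "T", s, fixed = TRUE)
  if (grepl("[^ACGTN]", s)) abort("non-nucleotide character in sequence")
  n <- nchar(s)

  if (method == "g4hunter") {
    if (n < window) abort("sequence shorter than the scoring window")
    chars <- strsplit(s, "")[[1]]
    runs <- rle(chars)
    per_run <- ifelse(runs$values == "G", pmin(runs$lengths, 4L),
                      ifelse(runs$values == "C", -pmin(runs$lengths, 4L), 0L))
    base_scores <- rep(per_run, runs$lengths)
    cs <- c(0, cumsum(base_scores))
    wmeans <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
    hit <- which(wmeans >= threshold - 1e-12)
    windows <- merge_intervals(cbind(hit - 1L, hit - 1L + window))
    maxs <- if (length(wmeans)) max(wmeans) else 0
  } else {
    pat <- "G{3,}[ACTUN]{1,7}G{3,}[ACTUN]{1,7}G{3,}[ACTUN]{1,7}G{3,}"
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) {
      windows <- matrix(integer(0), ncol = 2L)
    } else {
      windows <- merge_intervals(cbind(as.integer(m) - 1L,
                                       as.integer(m) - 1L +
                                         attr(m, "match.length")))
    }
    maxs <- if (nrow(windows)) 1 else 0
  }
  colnames(windows) <- c("start", "end")
  structure(list(sequence_id = sequence_id, windows = windows,
                 max_window_score = maxs,
                 coverage_pct = rg4_coverage(n, windows),
                 seq_length = n),
            class = "g4_result")
}

#' Predict G4 intervals for a set of sequences
#'
#' @param seqs named character vector or `XStringSet`.
#' @param ... passed to [g4_predict()].
#' @return list with `results` (list of `g4_result`) and `table`
#'   (data.frame: `sequence_id`, `n_windows`, `has_g4`,
#'   `max_window_score`, `coverage_pct`).
#' @export
g4_predict_set <- function(seqs, ...) {
  sv <- as.character(seqs)
  ids <- names(sv) %||% paste0("seq", seq_along(sv))
  res <- lapply(seq_along(sv), function(i)
    g4_predict(sv[i], sequence_id = ids[i], ...))
  tab <- data.frame(
    sequence_id = ids,
    n_windows = vapply(res, function(r) nrow(r$windows), 0L),
    has_g4 = vapply(res, function(r) nrow(r$windows) > 0L, TRUE),
    max_window_score = vapply(res, function(r) r$max_window_score, 0),
    coverage_pct = vapply(res, function(r) r$coverage_pct, 0),
    stringsAsFactors = FALSE)
  list(results = res, table = tab)
}

# Internal: merge possibly-overlapping 0-based half-open intervals
merge_intervals <- function(iv) {
  if (is.null(dim(iv)) || nrow(iv) == 0L)
    return(matrix(integer(0), ncol = 2L))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

#' Percent of a sequence covered by predicted G4 intervals
#'
#' `100 x |union of windows| / seq_length`; invariant to window order and
#' to whether windows were pre-merged.
#'
#' @param seq_length sequence length (nt).
#' @param windows matrix of 0-based half-open `start`,`end` rows.
#' @return coverage percentage in `[0, 100]`.
#' @export
rg4_coverage <- function(seq_length, windows) {
  if (is.null(dim(windows)) || nrow(windows) == 0L) return(0)
  if (any(windows[, 1] < 0L) || any(windows[, 2] > seq_length))
    abort("window out of sequence range")
  merged <- merge_intervals(windows)
  100 * sum(merged[, 2] - merged[, 1]) / seq_length
}

#' Compare G4 prediction between two sequence groups
#'
#' Reports, per group, the proportion of sequences with at least one
#' predicted G4 interval, and a Mann-Whitney comparison of the per-sequence
#' coverage percentages.
#'
#' @param fg_results,bg_results outputs of [g4_predict_set()] (or their
#'   `table` components).
#' @return list: `fg_proportion`, `bg_proportion`, `fg_n`, `bg_n`,
#'   `comparison` ([compare_distributions()] on coverage_pct).
#' @export
g4_group_compare <- function(fg_results, bg_results) {
  tab <- function(x) if (is.data.frame(x)) x else x$table
  fg <- tab(fg_results); bg <- tab(bg_results)
  if (nrow(fg) == 0L || nrow(bg) == 0L) abort("both groups must be nonempty")
  list(fg_proportion = mean(fg$has_g4), bg_proportion = mean(bg$has_g4),
       fg_n = nrow(fg), bg_n = nrow(bg),
       comparison = compare_distributions(fg$coverage_pct, bg$coverage_pct))
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their letter-probability matrices; ACGU and
#' ACGT alphabets are unified by the U/T mapping. Row sums are validated to
#' 1 within 1e-6. Background letter frequencies are read when present
#' (uniform otherwise).
#'
#' @param path file path, or the text itself (character vector of lines or
#'   a single string with newlines).
#' @return named list of `pwm` objects: `motif_id`, `width`, `mat` (4 x
#'   width probability matrix, rows A/C/G/T), `background`.
#' @export
read_meme_motifs <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path))
    readLines(path) else unlist(strsplit(path, "\n"))
  lines <- trimws(lines)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(lines[bgl[1] + 1L], "\\s+")[[1]]
    if (length(toks) >= 8L) {
      vals <- as.numeric(toks[seq(2, 8, 2)])
      nm <- toupper(gsub("U", "T", toks[seq(1, 7, 2)]))
      bg[nm] <- vals
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) abort("no MOTIF blocks found")
  out <- list()
  for (s in starts) {
    motif_id <- strsplit(lines[s], "\\s+")[[1]][2]
    hdr <- s + which(grepl("^letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    if (is.na(hdr)) abort("MOTIF '%s': missing letter-probability header", motif_id)
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])))
    rows <- list(); i <- hdr + 1L
    while (i <= length(lines) && nzchar(lines[i]) &&
           grepl("^[0-9.eE+ \t-]+$", lines[i])) {
      vals <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
      if (length(vals) != 4L)
        abort("line %d: expected 4 probabilities, got %d", i, length(vals))
      if (abs(sum(vals) - 1) > 1e-6)
        abort("line %d: probabilities sum to %.8f, not 1", i, sum(vals))
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    if (!is.na(w) && length(rows) != w)
      abort("MOTIF '%s': header says w=%d but %d rows found", motif_id, w,
            length(rows))
    mat <- t(do.call(rbind, rows))
    rownames(mat) <- c("A", "C", "G", "T")
    out[[motif_id]] <- structure(list(motif_id = motif_id, width = ncol(mat),
                                      mat = mat, background = bg),
                                 class = "pwm")
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms named list of `pwm` objects.
#' @param path output file.
#' @param alphabet `"ACGT"` or `"ACGU"`.
#' @export
write_meme_motifs <- function(pwms, path, alphabet = "ACGT") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", sprintf("ALPHABET= %s", alphabet), "",
               "strands: +", "", "Background letter frequencies",
               paste(vapply(seq_len(4), function(i)
                 sprintf("%s %.5f", substr(alphabet, i, i),
                         pwms[[1]]$background[i]), ""), collapse = " "),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", p$width),
               con)
    apply(p$mat, 2L, function(col)
      writeLines(paste(sprintf("%.6f", col), collapse = " "), con))
    writeLines("", con)
  }
  invisible(path)
}

# Internal: consensus string (highest-probability base per column)
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$mat)[apply(pwm$mat, 2L, which.max)], collapse = "")
}

#' Synthetic PRC2-like motif stand-ins
#'
#' The published PRC2 RNA-binding motifs are available only as sequence
#' logos, so numeric matrices must be user-supplied; this constructor
#' builds clearly-labelled synthetic stand-ins with the same character —
#' three GC-rich motifs and one U-rich motif — for simulations, tests and
#' demos. They are not the published matrices.
#'
#' @param peak probability of the consensus base at each position (the
#'   rest spread uniformly).
#' @return named list of `pwm` objects (`synthP1` U-rich; `synthP7`,
#'   `synthP10`, `synthP14` GC-rich).
#' @export
synthetic_prc2_pwms <- function(peak = 0.85) {
  mk <- function(id, consensus) {
    chars <- strsplit(consensus, "")[[1]]
    mat <- vapply(chars, function(ch) {
      p <- rep((1 - peak) / 3, 4)
      names(p) <- c("A", "C", "G", "T")
      p[ch] <- peak
      p
    }, numeric(4))
    dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
    structure(list(motif_id = id, width = ncol(mat), mat = mat,
                   background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
              class = "pwm")
  }
  list(synthP1 = mk("synthP1", "TTTTCTTT"),
       synthP7 = mk("synthP7", "GCGGCGGC"),
       synthP10 = mk("synthP10", "GGCGGAGG"),
       synthP14 = mk("synthP14", "GCGGCGGG"))
}

#' Scan a sequence with a PWM
#'
#' Log2-odds score against the background at every offset of the given
#' strand (RNA transcripts are oriented, so no reverse complement is
#' scanned). Zero-probability cells are floored at 1e-4 before taking
#' logs.
#'
#' @param seq character scalar or `XString` (U treated as T; N scores as
#'   background, contributing 0 bits).
#' @param pwm a `pwm` object.
#' @param score_threshold_bits report offsets scoring at least this many
#'   bits.
#' @return data.frame: `offset` (0-based), `score` (bits), only rows
#'   passing the threshold.
#' @export
scan_pwm <- function(seq, pwm, score_threshold_bits = 6) {
  s <- toupper(as.character(seq))
  s <- gsub("U", "T", s, fixed = TRUE)
  n <- nchar(s)
  w <- pwm$width
  if (n < w) abort("sequence shorter than PWM width")
  mat <- pmax(pwm$mat, 1e-4)
  bg <- pmax(pwm$background[rownames(mat)], 1e-4)
  lod <- log2(mat / bg)
  lod <- rbind(lod, N = 0)  # ambiguous base contributes 0 bits
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T", "N"))
  n_off <- n - w + 1L
  scores <- numeric(n_off)
  for (j in seq_len(w)) {
    scores <- scores + lod[cbind(code[j:(j + n_off - 1L)], j)]
  }
  hit <- which(scores >= score_threshold_bits - 1e-12)
  data.frame(offset = hit - 1L, score = scores[hit])
}

#' Motif enrichment between two sequence sets
#'
#' A sequence is a hit for a motif if any scan offset reaches the score
#' threshold. Enrichment of the foreground over the background is tested
#' per motif with a one-sided Fisher exact test on the 2x2 hit table; hit
#' percentages and the sample odds ratio are reported. Optional Bonferroni
#' correction across motifs (off by default; per-motif p-values are the
#' primary readout).
#'
#' @param fg_seqs,bg_seqs named character vectors or `XStringSet`s.
#' @param pwms named list of `pwm` objects.
#' @param threshold bits threshold passed to [scan_pwm()].
#' @param bonferroni multiply p-values by the number of motifs (capped at 1).
#' @return data.frame: `motif_id`, `fg_hits`, `fg_total`, `bg_hits`,
#'   `bg_total`, `fg_pct`, `bg_pct`, `odds_ratio`, `p`.
#' @export
motif_enrichment <- function(fg_seqs, bg_seqs, pwms, threshold = 6,
                             bonferroni = FALSE) {
  fg <- as.character(fg_seqs); bg <- as.character(bg_seqs)
  if (length(fg) == 0L || length(bg) == 0L)
    abort("both sequence sets must be nonempty")
  one <- function(pwm) {
    fg_hit <- vapply(fg, function(s) nrow(scan_pwm(s, pwm, threshold)) > 0L, TRUE)
    bg_hit <- vapply(bg, function(s) nrow(scan_pwm(s, pwm, threshold)) > 0L, TRUE)
    a <- sum(fg_hit); b <- length(fg) - a
    c_ <- sum(bg_hit); d <- length(bg) - c_
    p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE),
                     alternative = "greater")$p.value
    orat <- if (b == 0L || c_ == 0L) Inf else (a * d) / (b * c_)
    if (a == 0L) orat <- 0
    data.frame(motif_id = pwm$motif_id, fg_hits = a, fg_total = length(fg),
               bg_hits = c_, bg_total = length(bg),
               fg_pct = 100 * a / length(fg), bg_pct = 100 * c_ / length(bg),
               odds_ratio = orat, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(pwms, one))
  rownames(out) <- NULL
  if (bonferroni) out$p <- pmin(1, out$p * nrow(out))
  out
}
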