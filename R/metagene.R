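#' Strand-resolved coverage tracks from polymerase positions
#'
#' Per strand, the value at a base is the number of 3'OH positions mapped
#' there, optionally scaled to events per million (`value * 1e6 /
#' library_size`). Bases absent from the sparse table have value 0.
#'
#' @param positions data.table from [extract_3prime()].
#' @param library_size total retained fragments of the sample (required for
#'   `per_million`).
#' @param per_million scale values per million.
#' @return list of class `coverage_track`: `plus` and `minus` data.tables
#'   (`chrom`, `pos`, `value`), plus `scale`.
#' @export
coverage_track <- function(positions, library_size = NULL, per_million = FALSE) {
  positions <- as.data.table(positions)
  mk <- function(str) {
    sub <- positions[strand == str, .(value = as.numeric(.N)), by = .(chrom, pos)]
    if (per_million) {
      if (is.null(library_size) || library_size <= 0)
        abort("per_million scaling requires a positive library_size")
      sub[, value := value * 1e6 / library_size]
    }
    setkey(sub, chrom, pos)
    sub[]
  }
  structure(list(plus = mk("+"), minus = mk("-"),
                 scale = if (per_million) "per-million" else "raw"),
            class = "coverage_track")
}

# Internal: per-base values of one track strand over [start, end) of one
# chromosome, zeros where absent (keyed binary-search lookup)
track_values <- function(track_dt, chrom_, start, end) {
  pos_vec <- seq.int(start, end - 1L)
  v <- track_dt[.(rep(chrom_, length(pos_vec)), pos_vec), value]
  v[is.na(v)] <- 0
  v
}

#' Metagene matrix and average profile
#'
#' deepTools-style binned signal around regions, 5' to 3' of each region's
#' strand:
#'
#' * `reference_point`: the window `[anchor - flank, anchor + flank)` around
#'   each region's 5' boundary base (TSS), binned at `bin_size`; minus-strand
#'   windows are read in decreasing genomic order so that bins always run
#'   5' to 3'.
#' * `scale_regions`: `flank` bp on each side binned natively and the region
#'   body linearly rescaled to `body_bins` bins; regions shorter than one
#'   body bin are skipped with a warning.
#'
#' Each bin value is the mean per-base track value over the bin, so
#' `bin value x bin_size` recovers the signal mass in the bin. Unmapped
#' flank bases count as zeros. The `orientation` pairs track strand with
#' region strand: `sense` reads the track on the region's own strand,
#' `antisense` the opposite one (PROMPT signal around a TSS is the
#' antisense profile).
#'
#' @param track a [coverage_track()].
#' @param regions data.frame with `gene_id`/`region_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param mode `"reference_point"` or `"scale_regions"`.
#' @param bin_size bin width in bp (default 5).
#' @param flank flank length in bp (must be divisible by `bin_size`);
#'   defaults: 500 for reference_point, 1000 for scale_regions.
#' @param body_bins number of bins the region body is rescaled to
#'   (scale_regions only).
#' @param orientation `"sense"` or `"antisense"`.
#' @return list of class `metagene_matrix`: `matrix` (regions x bins),
#'   `profile` (per-bin mean across regions), `bin_size`, `mode`,
#'   `orientation`.
#' @export
metagene_profile <- function(track, regions,
                             mode = c("reference_point", "scale_regions"),
                             bin_size = 5L, flank = NULL, body_bins = 200L,
                             orientation = c("sense", "antisense")) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(flank)) flank <- if (mode == "reference_point") 500L else 1000L
  if (flank %% bin_size != 0L) abort("flank must be divisible by bin_size")
  ids <- regions$gene_id %||% regions$region_id
  check_strand(regions$strand)

  bin_means <- function(v, nb) {
    colMeans(matrix(v, nrow = length(v) / nb, ncol = nb))
  }
  pick_track <- function(region_strand) {
    use <- if (orientation == "sense") region_strand else
      ifelse(region_strand == "+", "-", "+")
    if (use == "+") track$plus else track$minus
  }

  rows <- list(); kept <- character(0)
  for (i in seq_len(nrow(regions))) {
    str <- regions$strand[i]
    tr <- pick_track(str)
    if (mode == "reference_point") {
      anchor <- if (str == "+") regions$start[i] else regions$end[i] - 1L
      if (str == "+") {
        v <- track_values(tr, regions$chrom[i], anchor - flank, anchor + flank)
      } else {
        v <- rev(track_values(tr, regions$chrom[i],
                              anchor - flank + 1L, anchor + flank + 1L))
      }
      rows[[length(rows) + 1L]] <- bin_means(v, 2L * flank %/% bin_size)
      kept <- c(kept, ids[i])
    } else {
      L <- regions$end[i] - regions$start[i]
      if (L < body_bins) {
        warning(sprintf("region %s shorter than one body bin; skipped", ids[i]))
        next
      }
      up <- track_values(tr, regions$chrom[i],
                         regions$start[i] - flank, regions$start[i])
      body <- track_values(tr, regions$chrom[i], regions$start[i], regions$end[i])
      down <- track_values(tr, regions$chrom[i],
                           regions$end[i], regions$end[i] + flank)
      if (str == "-") {
        tmp <- rev(up); up <- rev(down); down <- tmp
        body <- rev(body)
      }
      hi <- floor(seq_len(body_bins) * L / body_bins)
      lo <- c(0L, hi[-body_bins])
      body_binned <- vapply(seq_len(body_bins), function(b)
        mean(body[(lo[b] + 1L):hi[b]]), 0)
      rows[[length(rows) + 1L]] <- c(bin_means(up, flank %/% bin_size),
                                     body_binned,
                                     bin_means(down, flank %/% bin_size))
      kept <- c(kept, ids[i])
    }
  }
  if (length(rows) == 0L) abort("no usable regions")
  mat <- do.call(rbind, rows)
  rownames(mat) <- kept
  structure(list(matrix = mat, profile = colMeans(mat), bin_size = bin_size,
                 mode = mode, orientation = orientation),
            class = "metagene_matrix")
}

#' Write a coverage track as bedGraph (one file per strand)
#'
#' Adjacent bases with equal values are merged into runs; zero-value runs
#' are omitted (absent bases are zeros by convention).
#'
#' @param track a [coverage_track()].
#' @param prefix output path prefix; writes `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph`.
#' @export
write_bedgraph <- function(track, prefix) {
  one <- function(dt, path) {
    if (nrow(dt) == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    d <- dt[order(chrom, pos)]
    # run-length merge of consecutive equal-valued bases
    d[, brk := cumsum(c(1L, (diff(pos) != 1L) |
                          (head(value, -1) != tail(value, -1)) |
                          (head(chrom, -1) != tail(chrom, -1)))), by = NULL]
    runs <- d[, .(chrom = chrom[1], start = pos[1], end = pos[.N] + 1L,
                  value = value[1]), by = brk][, brk := NULL]
    fwrite(runs[, .(chrom, start, end, value)], path, sep = "\t",
           col.names = FALSE)
    invisible(path)
  }
  one(track$plus, paste0(prefix, ".plus.bedgraph"))
  one(track$minus, paste0(prefix, ".minus.bedgraph"))
  invisible(prefix)
}

#' Read a strand pair of bedGraph files into a coverage track
#'
#' @param prefix path prefix as in [write_bedgraph()].
#' @param scale value scale label.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(prefix, scale = "raw") {
  one <- function(path) {
    if (!file.exists(path) || file.size(path) == 0)
      return(data.table(chrom = character(), pos = integer(), value = numeric(),
                        key = c("chrom", "pos")))
    bg <- fread(path, header = FALSE, sep = "\t",
                col.names = c("chrom", "start", "end", "value"))
    out <- bg[, .(pos = seq.int(start, end - 1L)), by = .(chrom, start, value)][
      , .(chrom, pos, value)]
    setkey(out, chrom, pos)
    out[]
  }
  structure(list(plus = one(paste0(prefix, ".plus.bedgraph")),
                 minus = one(paste0(prefix, ".minus.bedgraph")),
                 scale = scale),
            class = "coverage_track")
}

#' Export a metagene average profile as TSV
#'
#' Columns: bin index (1-based, 5' to 3'), bin midpoint offset for
#' reference_point mode, and the mean value.
#'
#' @param mg a [metagene_profile()] result.
#' @param path output file.
#' @export
write_metagene_profile <- function(mg, path) {
  nb <- length(mg$profile)
  out <- data.table(bin = seq_len(nb), value = mg$profile)
  if (mg$mode == "reference_point") {
    half <- nb %/% 2L
    out[, offset := (bin - half - 1L) * mg$bin_size + mg$bin_size / 2]
  }
  fwrite(out, path, sep = "\t")
  invisible(path)
}
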