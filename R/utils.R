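#' @import data.table
#' @importFrom stats rnbinom runif setNames p.adjust pnorm pt cor prcomp
#'   t.test fisher.test sd median
#' @importFrom utils combn head tail
NULL

# Internal: stop with a formatted message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Internal: derive a per-stream seed from a master seed. Streams are spaced
# with a large prime so adding streams never perturbs existing ones; kept
# below 2^31 - 1 to stay a valid R integer seed.
derive_seed <- function(master, stream) {
  as.integer((as.numeric(master) + 104729 * as.numeric(stream)) %% 2147483647)
}

# Internal: uniform random integers in [lo, hi]
runif_int <- function(n, lo, hi) {
  as.integer(floor(runif(n, lo, hi + 1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: check a strand vector
check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-")))
    abort("strand must be '+' or '-'")
  invisible(strand)
}
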