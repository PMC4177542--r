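#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @import Biostrings
#' @importFrom utils read.table write.table
NULL

# Smallest representable positive double; used to clamp underflowed tail
# probabilities so that 0 < p <= 1 always holds for peak P values.
.P_FLOOR <- .Machine$double.xmin

#' Derive a reproducible child seed for a named pipeline stage
#'
#' One global seed fans out to per-stage seeds so that individual stages
#' (genome, sites, each tag sample, tracks) can be regenerated independently
#' while the whole simulation stays deterministic.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label, e.g. `"tags_A"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483629 + 1)
}

#' Seqinfo for a genome held as a DNAStringSet
#' @param genome A named `DNAStringSet`.
#' @return A `Seqinfo` object with one entry per chromosome.
#' @export
genome_seqinfo <- function(genome) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome names in genome")
  Seqinfo(seqnames = names(genome), seqlengths = width(genome))
}

# Accept either a DNAStringSet genome or a named seqlengths vector and
# return the named integer seqlengths.
.as_seqlengths <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    stats::setNames(width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    stats::setNames(as.integer(genome), names(genome))
  } else if (is(genome, "Seqinfo")) {
    seqlengths(genome)
  } else {
    stop("expected a DNAStringSet genome or a named seqlengths vector")
  }
}

# An empty GRanges carrying the given seqinfo.
.empty_granges <- function(seqlens = NULL) {
  gr <- GRanges()
  if (!is.null(seqlens))
    seqinfo(gr) <- Seqinfo(names(seqlens), unname(as.integer(seqlens)))
  gr
}

# Sort key used everywhere ranks are assigned: P value ascending with ties
# broken by genomic order for reproducibility.
.order_by_p <- function(gr) {
  order(gr$p_value, as.integer(match(as.character(seqnames(gr)),
                                     seqlevels(gr))), start(gr))
}

.stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("%s must lie strictly between 0 and 1", name))
}
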