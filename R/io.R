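# File formats the pipeline touches.  Files are 0-based half-open BED /
# bedGraph; in memory everything lives in the Bioconductor containers
# (GRanges, 1-based closed; RleList for signal), and the 0/1-based
# conversion happens only here, at the parse/serialize boundary.

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return A named uppercase `DNAStringSet` (alphabet A/C/G/T/N).
#' @export
read_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g <- DNAStringSet(toupper(g))
  bad <- letterFrequency(g, "ACGTN")
  if (any(bad != width(g)))
    stop("genome contains letters outside A/C/G/T/N")
  g
}

#' Write a genome to FASTA
#' @param genome Named `DNAStringSet`.
#' @param path Output file.
#' @export
write_genome <- function(genome, path) {
  writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read aligned ChIP-seq tags from a BED-like file
#'
#' Accepts standard 6-column BED (`chrom start end name score strand`) or a
#' minimal 4-column dialect (`chrom start end strand`); the dialect is
#' auto-detected from the column count.  Coordinates in the file are 0-based
#' half-open and are converted to 1-based closed `GRanges`.
#'
#' Chromosomes listed in `exclude_chroms` are dropped (by default the sex
#' chromosomes, the usual practice when comparing autosomal binding between
#' samples of unmatched karyotype).  Rows with unparseable or inconsistent
#' coordinates are counted, reported via a warning, and skipped.
#'
#' @param path Tag file.
#' @param exclude_chroms Character vector of chromosome names to drop.
#' @param genome Optional `DNAStringSet` or named seqlengths vector; when
#'   supplied, tags on chromosomes absent from it raise an error naming the
#'   offending row, and seqlengths are attached to the result.
#' @return A stranded `GRanges` of tags.
#' @export
read_tags <- function(path, exclude_chroms = c("chrX", "chrY"),
                      genome = NULL) {
  seqlens <- if (!is.null(genome)) .as_seqlengths(genome)
  if (!file.exists(path)) stop("tag file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty tag file: ", path)
    return(.empty_granges(seqlens))
  }
  df <- read.table(path, header = FALSE, sep = "", quote = "",
                   stringsAsFactors = FALSE,
                   colClasses = "character", fill = TRUE)
  if (nrow(df) == 0) {
    warning("empty tag file: ", path)
    return(.empty_granges(seqlens))
  }
  nc <- ncol(df)
  if (nc >= 6) {
    raw <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                      strand = df[[6]], stringsAsFactors = FALSE)
  } else if (nc == 4) {
    raw <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                      strand = df[[4]], stringsAsFactors = FALSE)
  } else {
    stop("tag file must have >= 6 BED columns or the 4-column dialect ",
         "(chrom, start, end, strand); found ", nc, " columns")
  }
  bad_strand <- !(raw$strand %in% c("+", "-"))
  if (any(bad_strand))
    stop("invalid strand '", raw$strand[which(bad_strand)[1]],
         "' at row ", which(bad_strand)[1])
  start0 <- suppressWarnings(as.numeric(raw$start))
  end0 <- suppressWarnings(as.numeric(raw$end))
  malformed <- is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0
  if (any(malformed)) {
    warning(sum(malformed), " malformed row(s) skipped in ", path)
    raw <- raw[!malformed, , drop = FALSE]
    start0 <- start0[!malformed]; end0 <- end0[!malformed]
  }
  keep <- !(raw$chrom %in% exclude_chroms)
  raw <- raw[keep, , drop = FALSE]
  start0 <- start0[keep]; end0 <- end0[keep]
  if (!is.null(seqlens)) {
    unknown <- !(raw$chrom %in% names(seqlens))
    if (any(unknown))
      stop("unknown chromosome '", raw$chrom[which(unknown)[1]],
           "' at row ", which(unknown)[1])
    over <- end0 > seqlens[raw$chrom]
    if (any(over))
      stop("tag extends past end of ", raw$chrom[which(over)[1]],
           " at row ", which(over)[1])
  }
  gr <- GRanges(raw$chrom, IRanges(start0 + 1, end0), strand = raw$strand)
  if (!is.null(seqlens)) {
    seqlevels(gr) <- names(seqlens)
    seqlengths(gr) <- unname(seqlens)
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write tags as 6-column BED
#' @param tags Stranded `GRanges`.
#' @param path Output file.
#' @export
write_tags <- function(tags, path) {
  df <- data.frame(chrom = as.character(seqnames(tags)),
                   start = start(tags) - 1L, end = end(tags),
                   name = ".", score = 0L,
                   strand = as.character(strand(tags)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Peak files are BED6+: the score column holds -log10(P) for browser
# convenience; exact values live in dedicated columns so that
# write -> read is lossless.
.PEAK_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                "summit_offset", "height", "n_tags", "p_value")

#' Write called peaks to a BED6+ file
#'
#' Columns: chrom, start, end, name, -log10(P) score, strand (`.`),
#' summit offset from peak start (0-based), height (max coverage),
#' deduplicated tag count, and the exact P value.  Round-trips losslessly
#' through [read_peaks()].
#'
#' @param peaks Peak `GRanges` (mcols `name`, `summit`, `height`,
#'   `n_tags`, `p_value`).
#' @param path Output file.
#' @export
write_peaks <- function(peaks, path) {
  if (length(peaks) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  o <- order(as.integer(match(as.character(seqnames(peaks)),
                              seqlevels(peaks))), start(peaks))
  peaks <- peaks[o]
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = if (!is.null(peaks$name)) peaks$name else
      paste0("peak_", seq_along(peaks)),
    score = sprintf("%.4f", -log10(peaks$p_value)),
    strand = ".",
    summit_offset = peaks$summit - start(peaks),
    height = peaks$height,
    n_tags = peaks$n_tags,
    p_value = sprintf("%.17g", peaks$p_value))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks written by [write_peaks()]
#' @param path Peak BED6+ file.
#' @param genome Optional genome / seqlengths to attach.
#' @return Peak `GRanges` sorted by P value ascending.
#' @export
read_peaks <- function(path, genome = NULL) {
  seqlens <- if (!is.null(genome)) .as_seqlengths(genome)
  if (file.size(path) == 0 ||
      length(readLines(path, n = 1L, warn = FALSE)) == 0)
    return(.empty_granges(seqlens))
  df <- read.table(path, header = FALSE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE,
                   col.names = .PEAK_COLS)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr) <- DataFrame(name = df$name,
                         summit = df$start + 1L + df$summit_offset,
                         height = df$height,
                         n_tags = df$n_tags,
                         p_value = df$p_value)
  if (!is.null(seqlens)) {
    seqlevels(gr) <- names(seqlens)
    seqlengths(gr) <- unname(seqlens)
  }
  gr[.order_by_p(gr)]
}

#' Read a bedGraph signal track into a dense per-base RleList
#'
#' Uncovered bases are 0.  Overlapping intervals and negative values are
#' rejected: the carriers this package reads (coverage, acetylation,
#' DNase hypersensitivity) are non-negative single-valued tracks.
#'
#' @param path bedGraph file.
#' @param genome `DNAStringSet` or named seqlengths vector giving the
#'   chromosome lengths of the track.
#' @return A named `RleList`, one run-length-encoded numeric vector per
#'   chromosome, each of the declared chromosome length.
#' @export
read_signal <- function(path, genome) {
  seqlens <- .as_seqlengths(genome)
  empty <- as(stats::setNames(
    lapply(seqlens, function(l) Rle(0, l)), names(seqlens)), "RleList")
  if (file.size(path) == 0) return(empty)
  df <- read.table(path, header = FALSE, sep = "", quote = "",
                   stringsAsFactors = FALSE)
  df <- df[!grepl("^(track|#)", df[[1]]), , drop = FALSE]
  if (nrow(df) == 0) return(empty)
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  if (any(df$value < 0)) stop("negative values in signal track ", path)
  unknown <- !(df$chrom %in% names(seqlens))
  if (any(unknown))
    stop("unknown chromosome '", df$chrom[which(unknown)[1]], "' in ", path)
  if (any(df$end > seqlens[df$chrom]))
    stop("interval past chromosome end in ", path)
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping intervals on ", ch, " in ", path)
  }
  out <- lapply(names(seqlens), function(ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) return(Rle(0, seqlens[[ch]]))
    cov <- coverage(IRanges(d$start + 1L, d$end),
                    weight = d$value, width = seqlens[[ch]])
    cov
  })
  as(stats::setNames(out, names(seqlens)), "RleList")
}

#' Write a signal track as bedGraph (nonzero runs only)
#' @param track Named `RleList`.
#' @param path Output file.
#' @export
write_signal <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    r <- track[[ch]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r)     # 0-based starts
    keep <- runValue(r) != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.10g", ch, starts[keep], ends[keep],
                       runValue(r)[keep]), con)
  }
  invisible(path)
}

#' Read a BED12 gene model
#'
#' Delegates to `rtracklayer`; returns gene spans with exon blocks.
#'
#' @param path BED12 file.
#' @param genome Optional genome / seqlengths to attach.
#' @return `GRanges` with mcols `name` and `blocks` (an `IRangesList` of
#'   exon ranges relative to each gene start).
#' @export
read_genes <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genome)) {
    seqlens <- .as_seqlengths(genome)
    seqlevels(gr) <- union(seqlevels(gr), names(seqlens))
    seqlevels(gr) <- names(seqlens)
    seqlengths(gr) <- unname(seqlens)
  }
  gr
}

#' Write a BED12 gene model
#' @param genes `GRanges` with `name` and `blocks` mcols.
#' @param path Output file.
#' @export
write_genes <- function(genes, path) {
  rtracklayer::export(genes, path, format = "BED")
  invisible(path)
}

#' Transcription start sites of a gene model
#' @param genes Stranded gene `GRanges`.
#' @return `GRanges` of width-1 TSS positions (one per gene).
#' @export
gene_tss <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
  GRanges(seqnames(genes), IRanges(pos, width = 1L),
          strand = strand(genes), seqinfo = seqinfo(genes))
}
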