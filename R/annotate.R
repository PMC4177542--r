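# Genomic-location annotation: each peak receives every category whose
# region it overlaps (multi-label), except intergenic, which is the
# exclusive fallback.  Category fractions therefore may sum above 1.

.LOCATION_CATS <- c("promoter", "proximal_promoter", "three_prime",
                    "exon", "intron", "upstream", "downstream",
                    "intergenic")

#' Default annotation distance parameters
#'
#' @param promoter Half-width of the promoter window around the TSS (bp).
#' @param proximal Half-width of the proximal-promoter window (bp).
#' @param three_prime Half-width of the 3' window around the TES (bp).
#' @param updown Extent of the upstream/downstream flanks beyond the gene
#'   span (bp).
#' @return Named list of validated parameters.
#' @export
annotation_params <- function(promoter = 2000, proximal = 10000,
                              three_prime = 2000, updown = 1e5) {
  p <- list(promoter = promoter, proximal = proximal,
            three_prime = three_prime, updown = updown)
  if (any(unlist(p) <= 0))
    stop("annotation distance parameters must be positive")
  p
}

# Build the absolute category regions from a gene model.
.location_regions <- function(genes, params) {
  if (length(genes) == 0) {
    e <- GRanges()
    return(stats::setNames(rep(list(e), 7), setdiff(.LOCATION_CATS,
                                                    "intergenic")))
  }
  minus <- as.character(strand(genes)) == "-"
  tss <- ifelse(minus, end(genes), start(genes))
  tes <- ifelse(minus, start(genes), end(genes))
  ch <- seqnames(genes)
  win <- function(center, d)
    GRanges(ch, IRanges(pmax(1, center - d), center + d))
  up <- GRanges(ch, IRanges(
    ifelse(minus, end(genes) + 1, pmax(1, start(genes) - params$updown)),
    ifelse(minus, end(genes) + params$updown,
           pmax(1, start(genes) - 1))))
  down <- GRanges(ch, IRanges(
    ifelse(minus, pmax(1, start(genes) - params$updown), end(genes) + 1),
    ifelse(minus, pmax(1, start(genes) - 1),
           end(genes) + params$updown)))
  if (!is.null(genes$blocks)) {
    exons <- GRanges(rep(ch, lengths(genes$blocks)),
                     shift(unlist(genes$blocks), rep(start(genes) - 1L,
                                                     lengths(genes$blocks))))
    introns <- GenomicRanges::setdiff(
      GRanges(ch, ranges(genes)), exons, ignore.strand = TRUE)
  } else {
    exons <- GRanges(ch, ranges(genes))
    introns <- GRanges()
  }
  list(promoter = win(tss, params$promoter),
       proximal_promoter = win(tss, params$proximal),
       three_prime = win(tes, params$three_prime),
       exon = exons, intron = introns, upstream = up, downstream = down)
}

#' Assign genomic-location categories to peaks
#'
#' A peak is labeled with every category whose region it overlaps by at
#' least one base: promoter (TSS +/- `promoter`), proximal promoter (TSS
#' +/- `proximal`), 3' (TES +/- `three_prime`), exon and intron (block
#' overlap within gene spans), upstream / downstream (`updown` bases 5' /
#' 3' of the gene span, strand-aware).  A peak overlapping none of these
#' is intergenic — the only exclusive label.  A peak reaching two genes
#' receives the union of labels from both.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene model `GRanges` (strand, `blocks` mcol as from
#'   [generate_gene_models()] / [read_genes()]).
#' @param params [annotation_params()].
#' @return Logical matrix, peaks x 8 categories.
#' @export
assign_locations <- function(peaks, genes,
                             params = annotation_params()) {
  regions <- .location_regions(genes, params)
  m <- vapply(regions, function(r)
    overlapsAny(peaks, r, ignore.strand = TRUE),
    logical(length(peaks)))
  if (length(peaks) == 1) m <- matrix(m, nrow = 1,
                                      dimnames = list(NULL, names(regions)))
  m <- cbind(m, intergenic = rowSums(m) == 0)
  rownames(m) <- if (!is.null(peaks$name)) peaks$name else NULL
  m
}

#' Per-category fractions of peaks
#'
#' @param peaks Non-empty peak `GRanges`.
#' @param genes Gene model `GRanges`.
#' @param params [annotation_params()].
#' @return List: `fractions` (named numeric over the 8 categories; the
#'   non-intergenic entries may sum above 1 because labels are not
#'   exclusive), `n` (number of peaks), `params`.
#' @export
location_fractions <- function(peaks, genes,
                               params = annotation_params()) {
  if (length(peaks) == 0) stop("no peaks to annotate")
  m <- assign_locations(peaks, genes, params)
  list(fractions = colMeans(m), n = length(peaks), params = params)
}
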