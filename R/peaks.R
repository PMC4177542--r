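# Peak calling: deduplication, directional 200-base tag extension,
# per-base coverage, a negative-binomial background model fitted on
# non-overlapping windows, window-level upper-tail P values, merging of
# significant windows into peaks, and subtraction of control peaks.

#' Remove duplicate tags
#'
#' At most one tag is kept per (chromosome, start, strand), the standard
#' guard against PCR amplification artifacts.  The result is independent
#' of input order.
#'
#' @param tags Stranded tag `GRanges`.
#' @return Deduplicated, sorted tag `GRanges`.
#' @export
deduplicate <- function(tags) {
  if (length(tags) == 0) return(tags)
  key <- paste(as.character(seqnames(tags)), start(tags),
               as.character(strand(tags)))
  tags <- tags[!duplicated(key)]
  o <- order(as.integer(match(as.character(seqnames(tags)),
                              seqlevels(tags))),
             start(tags), end(tags), as.integer(strand(tags)))
  tags[o]
}

#' Extend tags in the sequencing orientation
#'
#' Each tag is extended to a total of `L` bases in its sequencing
#' orientation: a plus-strand tag keeps its start, a minus-strand tag keeps
#' its end.  Extensions are clipped to the chromosome bounds.
#'
#' @param tags Stranded tag `GRanges` with seqlengths set (or pass
#'   `genome`).
#' @param L Fragment length in bases (default 200); must be at least the
#'   tag length.
#' @param genome Optional `DNAStringSet` / seqlengths to attach for
#'   clipping.
#' @return Unstranded-extent `GRanges` of fragment intervals.
#' @export
extend_tags <- function(tags, L = 200, genome = NULL) {
  if (!is.null(genome)) {
    seqlens <- .as_seqlengths(genome)
    seqlevels(tags) <- names(seqlens)
    seqlengths(tags) <- unname(seqlens)
  }
  if (length(tags) > 0 && L < max(width(tags)))
    stop("extension length L is shorter than the longest tag")
  ext <- suppressWarnings(resize(tags, width = L, fix = "start"))
  trim(ext)
}

#' Per-base coverage of a set of intervals
#'
#' @param intervals `GRanges` with seqlengths set.
#' @return Named `RleList`: coverage at every base of every chromosome.
#' @export
interval_coverage <- function(intervals) {
  if (any(is.na(seqlengths(intervals))))
    stop("seqlengths must be set to compute full-genome coverage")
  coverage(intervals)
}

#' Fit a negative-binomial background from window counts
#'
#' Method-of-moments fit (`mu = mean`, `size = mu^2/(var - mu)`) with a
#' signal-contamination guard: windows that the background model itself
#' deems signal-like are excluded by an iteratively re-trimmed cap.  The
#' cap starts near the count median (`2 * median + 5`), the NB is fitted
#' to the windows at or below the cap, the cap is moved to the fitted
#' upper 10^-4 quantile (never above the `trim_quantile` empirical
#' quantile), and the fit is repeated until the cap stabilises.  Starting
#' low keeps heavily contaminated data (where even the upper percentiles
#' of the raw counts are signal) from inflating the dispersion; on clean
#' background the cap expands to retain essentially all windows.
#' `trim_quantile = 1` disables trimming entirely (plain method of
#' moments).
#'
#' When the retained counts are underdispersed (`var <= mean`) the NB
#' degenerates and a Poisson fallback is flagged (`size = Inf`).
#'
#' @param window_counts Integer vector of tag counts per window (>= 100
#'   windows).
#' @param trim_quantile Upper bound, as an empirical quantile, for the
#'   contamination cap; `1.0` disables trimming.
#' @param window Window width in bases (recorded in the fit).
#' @return An `nb_background` list: `mu`, `size`, `poisson` (fallback
#'   flag), `window`, `n_windows` (windows retained by the final fit).
#' @export
fit_background <- function(window_counts, trim_quantile = 0.99,
                           window = 200) {
  stopifnot(length(window_counts) >= 100)
  if (all(window_counts == 0))
    stop("all window counts are zero: no background signal to fit")
  mom <- function(x) {
    mu <- mean(x)
    v <- stats::var(x)
    poisson <- !is.finite(v) || v <= mu
    list(mu = mu, size = if (poisson) Inf else mu^2 / (v - mu),
         poisson = poisson, n = length(x))
  }
  if (trim_quantile >= 1) {
    f <- mom(window_counts)
  } else {
    upper <- stats::quantile(window_counts, trim_quantile, names = FALSE)
    cap <- min(2 * stats::median(window_counts) + 5, upper)
    for (i in seq_len(30)) {
      f <- mom(window_counts[window_counts <= cap])
      newcap <- if (f$poisson) stats::qpois(1 - 1e-4, f$mu) else
        stats::qnbinom(1 - 1e-4, size = f$size, mu = f$mu)
      newcap <- min(newcap, upper)
      if (newcap == cap) break
      cap <- newcap
    }
  }
  structure(list(mu = f$mu, size = f$size, poisson = f$poisson,
                 window = window, n_windows = f$n),
            class = "nb_background")
}

#' @export
print.nb_background <- function(x, ...) {
  cat(sprintf(
    "Negative-binomial background: mu = %.4g, size = %.4g%s (%d windows of %d bp)\n",
    x$mu, x$size, if (x$poisson) " [Poisson fallback]" else "",
    x$n_windows, x$window))
  invisible(x)
}

#' Upper-tail background probability of a window count
#'
#' `P(X >= k)` under the fitted background; Poisson tail when the fit fell
#' back.  Clamped away from zero so downstream `0 < p <= 1` invariants hold
#' under floating-point underflow.
#'
#' @param k Observed count(s).
#' @param bg An `nb_background`.
#' @return Numeric vector of tail probabilities in `(0, 1]`.
#' @export
nb_tail_p <- function(k, bg) {
  p <- if (is.finite(bg$size)) {
    pnbinom(k - 1, size = bg$size, mu = bg$mu, lower.tail = FALSE)
  } else {
    ppois(k - 1, lambda = bg$mu, lower.tail = FALSE)
  }
  pmax(pmin(p, 1), .P_FLOOR)
}

# Tile every chromosome into non-overlapping windows of width w (last
# window may be shorter).
.tile_windows <- function(seqlens, w) {
  GenomicRanges::tileGenome(seqlens, tilewidth = w,
                            cut.last.tile.in.chrom = TRUE)
}

#' Call peaks against a negative-binomial background
#'
#' The full path from raw tags to ranked peaks: deduplicate, extend each
#' tag to `extension` bases in its orientation, tile the genome into
#' non-overlapping `window`-width windows, score each window by the number
#' of extended tags overlapping it, fit the background from those counts
#' (unless a fit is supplied), compute the NB upper-tail P value per
#' window, keep windows with `P <= p_cutoff`, merge kept windows separated
#' by at most one window's gap, trim each merged region to its covered
#' extent, and report one peak per region with the minimum window P value,
#' the leftmost coverage-maximum summit, the maximum coverage as height,
#' and the deduplicated tag count in the interval.
#'
#' @param tags Stranded tag `GRanges`.
#' @param genome `DNAStringSet` or named seqlengths vector.
#' @param p_cutoff Window P-value threshold, strictly in (0, 1).
#' @param window Background window width (bases).
#' @param extension Fragment extension length (bases).
#' @param bg Optional pre-fitted `nb_background`; fitted from this sample's
#'   windows when `NULL`.
#' @param trim_quantile Trim quantile passed to [fit_background()].
#' @return Peak `GRanges` sorted by P value ascending (ties by genomic
#'   order), with mcols `name`, `summit`, `height`, `n_tags`, `p_value`;
#'   the fitted background is attached as `metadata(x)$background`.
#' @export
call_peaks <- function(tags, genome, p_cutoff = 1e-5, window = 200,
                       extension = 200, bg = NULL, trim_quantile = 0.99) {
  .stopifnot_prob(p_cutoff, "p_cutoff")
  seqlens <- .as_seqlengths(genome)
  tags <- deduplicate(tags)
  empty <- .empty_granges(seqlens)
  mcols(empty) <- DataFrame(name = character(0), summit = integer(0),
                            height = integer(0), n_tags = integer(0),
                            p_value = numeric(0))
  if (length(tags) == 0) return(empty)
  seqlevels(tags) <- names(seqlens)
  seqlengths(tags) <- unname(seqlens)
  ext <- extend_tags(tags, L = extension)
  cov <- interval_coverage(ext)
  windows <- .tile_windows(seqlens, window)
  counts <- countOverlaps(windows, ext)
  if (is.null(bg)) bg <- fit_background(counts, trim_quantile, window)
  pvals <- nb_tail_p(counts, bg)
  sig <- windows[pvals <= p_cutoff]
  if (length(sig) == 0) {
    metadata(empty)$background <- bg
    return(empty)
  }
  sig_p <- pvals[pvals <= p_cutoff]
  merged <- reduce(sig, min.gapwidth = window + 1L, with.revmap = TRUE)
  peak_p <- vapply(merged$revmap, function(i) min(sig_p[i]), numeric(1))
  # trim each merged region to its covered extent and locate the summit
  res <- lapply(seq_along(merged), function(i) {
    r <- merged[i]
    ch <- as.character(seqnames(r))
    v <- Views(cov[[ch]], start(r), end(r))[[1]]
    vi <- as.integer(v)
    nz <- which(vi > 0)
    if (length(nz) == 0) return(NULL)
    s <- start(r) + nz[1] - 1L
    e <- start(r) + nz[length(nz)] - 1L
    summit <- start(r) + which.max(vi) - 1L
    c(start = s, end = e, summit = summit, height = max(vi))
  })
  keep <- !vapply(res, is.null, logical(1))
  res <- do.call(rbind, res[keep])
  peaks <- GRanges(seqnames(merged)[keep],
                   IRanges(res[, "start"], res[, "end"]),
                   seqinfo = Seqinfo(names(seqlens),
                                     unname(as.integer(seqlens))))
  mcols(peaks) <- DataFrame(name = NA_character_,
                            summit = as.integer(res[, "summit"]),
                            height = as.integer(res[, "height"]),
                            n_tags = countOverlaps(peaks, tags,
                                                   ignore.strand = TRUE),
                            p_value = peak_p[keep])
  peaks <- peaks[.order_by_p(peaks)]
  peaks$name <- paste0("peak_", seq_along(peaks))
  metadata(peaks)$background <- bg
  peaks
}

#' Remove peaks overlapping control peaks
#'
#' Any peak sharing at least one base with a control peak at
#' `P <= control_cutoff` is discarded — the no-antibody control filter.
#'
#' @param peaks Peak `GRanges`.
#' @param control_peaks Control-sample peak `GRanges`.
#' @param control_cutoff Control peak P-value threshold (default `1e-5`).
#' @return Filtered peak `GRanges` (order preserved).
#' @export
subtract_control <- function(peaks, control_peaks, control_cutoff = 1e-5) {
  if (length(peaks) == 0 || length(control_peaks) == 0) return(peaks)
  ctrl <- control_peaks[control_peaks$p_value <= control_cutoff]
  if (length(ctrl) == 0) return(peaks)
  hit <- overlapsAny(peaks, ctrl, ignore.strand = TRUE)
  peaks[!hit]
}

#' Count peaks surviving each P-value cutoff
#'
#' @param peaks Peak `GRanges` with `p_value`.
#' @param cutoffs Numeric vector of thresholds (default the conventional
#'   `1e-5`, `1e-7`, `1e-10`).
#' @return Named integer vector of counts (non-increasing as cutoffs
#'   tighten).
#' @export
count_peaks_at_cutoffs <- function(peaks, cutoffs = c(1e-5, 1e-7, 1e-10)) {
  stats::setNames(vapply(cutoffs, function(ct)
    sum(peaks$p_value <= ct), integer(1)),
    format(cutoffs, scientific = TRUE))
}
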