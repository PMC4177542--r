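# Chromatin-context association: per-peak signal statistics (AcH4 on the
# square-root scale), TSS-distance stratification, Mann-Whitney
# between-class comparison, and DNase-hypersensitivity overlap fractions
# and cumulative distributions.

#' Signal statistic over peak intervals
#'
#' @param peaks Peak `GRanges`.
#' @param track Named `RleList` covering the peaks' chromosomes.
#' @param stat One of `"mean"` (default), `"max"`, `"sum"`.
#' @return Numeric vector, one value per peak.
#' @export
peak_signal <- function(peaks, track, stat = c("mean", "max", "sum")) {
  stat <- match.arg(stat)
  out <- numeric(length(peaks))
  for (ch in unique(as.character(seqnames(peaks)))) {
    if (!(ch %in% names(track)))
      stop("track does not cover chromosome ", ch)
    on <- which(as.character(seqnames(peaks)) == ch)
    if (any(start(peaks)[on] < 1) ||
        any(end(peaks)[on] > length(track[[ch]])))
      stop("peak outside track bounds on ", ch)
    v <- Views(track[[ch]], start(peaks)[on], end(peaks)[on])
    out[on] <- switch(stat, mean = viewMeans(v), max = viewMaxs(v),
                      sum = viewSums(v))
  }
  out
}

#' Distance from peak summits to the nearest TSS
#'
#' Unsigned base-pair distance `min |summit - tss|` over the TSSs of the
#' summit's chromosome; 0 when the summit sits on a TSS.  A peak on a
#' chromosome with no TSS gets `Inf` with a warning.
#'
#' @param peaks Peak `GRanges` with `summit`.
#' @param tss `GRanges` of width-1 TSS positions (see [gene_tss()]); must
#'   be non-empty.
#' @return Numeric vector of distances.
#' @export
tss_distance <- function(peaks, tss) {
  if (length(tss) == 0) stop("TSS list is empty")
  out <- rep(Inf, length(peaks))
  for (ch in unique(as.character(seqnames(peaks)))) {
    on <- which(as.character(seqnames(peaks)) == ch)
    tp <- sort(start(tss)[as.character(seqnames(tss)) == ch])
    if (length(tp) == 0) next
    s <- peaks$summit[on]
    i <- findInterval(s, tp)
    lo <- ifelse(i >= 1, abs(s - tp[pmax(i, 1)]), Inf)
    hi <- ifelse(i < length(tp), abs(tp[pmin(i + 1, length(tp))] - s), Inf)
    out[on] <- pmin(lo, hi)
  }
  if (any(!is.finite(out)))
    warning(sum(!is.finite(out)),
            " peak(s) on chromosomes without a TSS (distance Inf)")
  out
}

#' Stratify records by TSS distance
#'
#' Partitions into half-open bins `[0, b1), [b1, b2), ..., [bk, Inf)`.
#'
#' @param tss_dist Numeric vector of TSS distances.
#' @param breaks Increasing positive break points in bases
#'   (default 2 kb, 10 kb, 100 kb).
#' @return Factor of bin labels, ordered near to far.
#' @export
stratify_by_tss <- function(tss_dist, breaks = c(2e3, 1e4, 1e5)) {
  if (any(diff(breaks) <= 0) || any(breaks <= 0))
    stop("breaks must be positive and strictly increasing")
  fmt <- function(b) format(b, scientific = FALSE, trim = TRUE)
  lab <- c(paste0("<", fmt(breaks[1])),
           if (length(breaks) > 1)
             paste0(fmt(breaks[-length(breaks)]), "-", fmt(breaks[-1])),
           paste0(">=", fmt(breaks[length(breaks)])))
  cut(tss_dist, c(0, breaks, Inf), labels = lab, right = FALSE,
      include.lowest = TRUE)
}

#' Compare a signal statistic between two peak classes
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test on the square roots
#' of the per-peak signal values; exact P for small untied samples, normal
#' approximation with tie correction otherwise.  The square-root transform
#' matches how acetylation enrichment is conventionally displayed and
#' leaves the rank test unchanged; it is applied for interpretability of
#' the accompanying location shift.
#'
#' @param values_x,values_y Non-negative per-peak signal values for the
#'   two classes (each of length >= 2).
#' @param transform Apply `sqrt` before testing (default `TRUE`).
#' @return List: `statistic` (U), `p_value`, `n` (c(n_x, n_y)),
#'   `median_x`, `median_y` (on the transformed scale).
#' @export
compare_classes <- function(values_x, values_y, transform = TRUE) {
  if (length(values_x) < 2 || length(values_y) < 2)
    stop("each class needs at least 2 values")
  x <- if (transform) sqrt(values_x) else values_x
  y <- if (transform) sqrt(values_y) else values_y
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = max(wt$p.value, 0),
       n = c(length(x), length(y)),
       median_x = stats::median(x), median_y = stats::median(y))
}

#' Fraction of peaks with nonzero DNase-hypersensitivity signal
#'
#' The per-peak statistic is the maximum HSS score over the peak interval;
#' the reported fraction is `1 -` the fraction of peaks whose score is
#' exactly 0, so it depends only on the zero/nonzero pattern of the track.
#'
#' @param peaks Peak `GRanges`.
#' @param hss Named `RleList` of HSS scores.
#' @return A single fraction in `[0, 1]` (`NaN` for an empty peak list).
#' @export
hss_overlap_fraction <- function(peaks, hss) {
  mean(peak_signal(peaks, hss, stat = "max") > 0)
}

#' Empirical CDF of per-peak DNase-hypersensitivity scores
#'
#' @param peaks Peak `GRanges`.
#' @param hss Named `RleList` of HSS scores.
#' @return Data frame `value`, `fraction`: at each distinct per-peak max
#'   HSS score, the fraction of peaks with a score `<=` that value.
#'   `fraction[value == 0]` equals `1 - hss_overlap_fraction()`.
#' @export
hss_cdf <- function(peaks, hss) {
  v <- peak_signal(peaks, hss, stat = "max")
  xs <- sort(unique(v))
  data.frame(value = xs,
             fraction = vapply(xs, function(t) mean(v <= t), numeric(1)))
}

#' Per-peak chromatin-context records
#'
#' Convenience assembly of the per-peak quantities the context analysis
#' consumes: AcH4 statistic and its square root, TSS distance, and max
#' HSS score.
#'
#' @param peaks Peak `GRanges` (with `summit`, optional `label`).
#' @param ach4,hss Named `RleList` tracks.
#' @param tss TSS `GRanges`.
#' @param stat AcH4 statistic (default `"mean"`).
#' @return Data frame with one row per peak.
#' @export
context_records <- function(peaks, ach4, hss, tss, stat = "mean") {
  a <- peak_signal(peaks, ach4, stat = stat)
  data.frame(name = if (!is.null(peaks$name)) peaks$name else
    paste0("peak_", seq_along(peaks)),
    label = if (!is.null(peaks$label)) peaks$label else NA_character_,
    ach4_value = a, sqrt_ach4 = sqrt(a),
    tss_distance = tss_distance(peaks, tss),
    hss_score = peak_signal(peaks, hss, stat = "max"),
    stringsAsFactors = FALSE)
}
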