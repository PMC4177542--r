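# Comparison of two factors' peak lists: interval overlap, the cumulative
# rank-binned overlap-fraction matrix, dual-cutoff specific/shared
# classification, and recovery scoring against planted truth.

#' Do two intervals overlap?
#'
#' True iff the intervals are on the same chromosome and share at least
#' one base.  Vectorised over pairs.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1) a <- rep(a, n)
  if (length(b) == 1) b <- rep(b, n)
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    start(a) <= end(b) & start(b) <= end(a)
}

# Rank peaks: P ascending, ties by genomic order.
.rank_peaks <- function(peaks) peaks[.order_by_p(peaks)]

#' Cumulative rank-binned overlap-fraction matrix
#'
#' Peaks in each list are ranked by P value (ties broken by genomic
#' order) and grouped into cumulative rank bins of `bin` (top 3,000, top
#' 6,000, ... up to `max_rank`).  Entry `(x, y)` is the fraction of the
#' top `x` peaks of `peaks1` that overlap at least one of the top `y`
#' peaks of `peaks2`, computed for `y >= x`.  When a list is shorter than
#' `max_rank` the bins truncate at the list length and the denominator is
#' `min(x, length)`.
#'
#' Overlap is many-to-one, so the matrix is direction-specific: compute
#' both `overlap_fraction_matrix(a, b)` and `(b, a)` for the full picture.
#'
#' @param peaks1,peaks2 Peak `GRanges` with `p_value`.
#' @param bin Rank bin size (default 3000).
#' @param max_rank Largest cumulative rank considered (default 30000).
#' @return Numeric matrix with rows `x` (bins of `peaks1`) and columns
#'   `y` (bins of `peaks2`); cells with `y < x` are `NA`.
#' @export
overlap_fraction_matrix <- function(peaks1, peaks2, bin = 3000,
                                    max_rank = 30000) {
  if (!is.numeric(bin) || bin <= 0) stop("bin must be a positive number")
  p1 <- .rank_peaks(peaks1)
  p2 <- .rank_peaks(peaks2)
  xs <- seq(bin, max_rank, by = bin)
  m <- matrix(NA_real_, length(xs), length(xs),
              dimnames = list(x = xs, y = xs))
  if (length(p1) == 0) return(m)
  # earliest rank in p2 of any overlap partner, per p1 peak
  hits <- suppressWarnings(findOverlaps(p1, p2, ignore.strand = TRUE))
  min_partner <- rep(Inf, length(p1))
  if (length(hits) > 0) {
    agg <- tapply(subjectHits(hits), queryHits(hits), min)
    min_partner[as.integer(names(agg))] <- agg
  }
  for (i in seq_along(xs)) {
    x_eff <- min(xs[i], length(p1))
    for (j in seq_along(xs)) {
      if (xs[j] < xs[i]) next
      y_eff <- min(xs[j], length(p2))
      m[i, j] <- sum(min_partner[seq_len(x_eff)] <= y_eff) / x_eff
    }
  }
  m
}

#' Classify peaks as factor-specific, shared, or unclassified
#'
#' Dual-cutoff rule: a peak of factor A is `A_specific` when it is present
#' at `P <= present_cutoff` and overlaps no B peak at `P <= absent_cutoff`;
#' it is `shared` when present at `present_cutoff` and overlapping at
#' least one B peak also at `present_cutoff`; anything else (including a
#' partner present at `absent_cutoff` but not at `present_cutoff`) is
#' `unclassified`.  The symmetric labels are assigned on the B list.
#'
#' Both input lists should be called at a cutoff no tighter than
#' `absent_cutoff`, otherwise "absent" cannot be established.
#'
#' @param peaks_A,peaks_B Peak `GRanges` with `p_value`.
#' @param present_cutoff P value at which a peak counts as present
#'   (default `1e-10`).
#' @param absent_cutoff P value at which the partner factor counts as
#'   absent when no overlapping peak reaches it (default `1e-4`).
#' @return List with `A` and `B` (the input `GRanges` plus a `label`
#'   mcol) and `counts` (named vector of label counts across both lists;
#'   `shared` counted on the A side).
#' @export
classify_peaks <- function(peaks_A, peaks_B, present_cutoff = 1e-10,
                           absent_cutoff = 1e-4) {
  lab <- function(px, py) {
    present <- px$p_value <= present_cutoff
    partner_any <- overlapsAny(px, py[py$p_value <= absent_cutoff],
                               ignore.strand = TRUE)
    partner_strong <- overlapsAny(px, py[py$p_value <= present_cutoff],
                                  ignore.strand = TRUE)
    ifelse(present & !partner_any, "specific",
           ifelse(present & partner_strong, "shared", "unclassified"))
  }
  la <- lab(peaks_A, peaks_B)
  lb <- lab(peaks_B, peaks_A)
  peaks_A$label <- ifelse(la == "specific", "A_specific", la)
  peaks_B$label <- ifelse(lb == "specific", "B_specific", lb)
  counts <- c(A_specific = sum(peaks_A$label == "A_specific"),
              B_specific = sum(peaks_B$label == "B_specific"),
              shared = sum(peaks_A$label == "shared"),
              unclassified = sum(peaks_A$label == "unclassified") +
                sum(peaks_B$label == "unclassified"))
  list(A = peaks_A, B = peaks_B, counts = counts)
}

#' Score classifier labels against planted truth
#'
#' Matches classified peaks to planted sites by interval overlap and
#' reports per-class precision and recall plus the site-by-label confusion
#' matrix.  Truth classes are `A`, `B`, `shared`; the classifier labels
#' `A_specific`, `B_specific`, `shared` map onto them.
#'
#' @param classified Result of [classify_peaks()].
#' @param truth_sites Planted site `GRanges` with a `class` mcol.
#' @return List: `confusion` (truth class x predicted label matrix over
#'   sites), `precision`, `recall` (named vectors; `NA` where a class has
#'   no truth or no predictions).
#' @export
truth_table_recovery <- function(classified, truth_sites) {
  labelled <- c(classified$A[classified$A$label == "A_specific"],
                classified$B[classified$B$label == "B_specific"],
                classified$A[classified$A$label == "shared"])
  pred_class <- sub("_specific", "", labelled$label)
  truth_cls <- c("A", "B", "shared")
  # per-site predicted label: union of labels of overlapping peaks;
  # a site counts as recovered for its class if any overlapping peak
  # carries the matching label
  confusion <- matrix(0L, 3, 3, dimnames = list(truth = truth_cls,
                                                predicted = truth_cls))
  site_hit <- logical(length(truth_sites))
  for (pc in truth_cls) {
    pk <- labelled[pred_class == pc]
    ov <- overlapsAny(truth_sites, pk, ignore.strand = TRUE)
    for (tc in truth_cls)
      confusion[tc, pc] <- sum(ov & truth_sites$class == tc)
  }
  recall <- vapply(truth_cls, function(cl) {
    n <- sum(truth_sites$class == cl)
    if (n == 0) return(NA_real_)
    confusion[cl, cl] / n
  }, numeric(1))
  precision <- vapply(truth_cls, function(cl) {
    pk <- labelled[pred_class == cl]
    if (length(pk) == 0) return(NA_real_)
    ok <- overlapsAny(pk, truth_sites[truth_sites$class == cl],
                      ignore.strand = TRUE)
    mean(ok)
  }, numeric(1))
  list(confusion = confusion, precision = precision, recall = recall)
}
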