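# E-box scanning, flanking-nucleotide profiling, and discriminative de
# novo motif discovery.  Motifs are IUPAC consensus strings scored by the
# log odds ratio of sequence-hit fractions between a foreground and a
# background set, refined greedily by single-position IUPAC generalisation
# and +/-1 extension.

.IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

#' Reverse complement of IUPAC consensus strings
#' @param x Character vector of IUPAC strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(.COMPLEMENT[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# canonical (strand-collapsed) form of a consensus
.canonical <- function(x) pmin(x, revcomp(x))

.check_iupac <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- !(letters %in% names(.IUPAC_MAP))
  if (any(bad))
    stop("invalid IUPAC symbol '", letters[which(bad)[1]], "' in '",
         consensus, "'")
  invisible(letters)
}

#' Scan a sequence for E-boxes (CANNTG)
#'
#' Reports every forward-strand position matching `CANNTG`.  The E-box
#' pattern is its own reverse complement, so a forward scan covers both
#' strands; palindromic-frame matches are reported once, at the forward
#' coordinate.  `N` bases never match.
#'
#' @param seq A DNA sequence (character or `DNAString`); case-insensitive.
#' @return Data frame with one row per match: `position` (0-based start of
#'   the 6-mer), `core` (the CANNTG instance), `central` (the NN
#'   dinucleotide), `flank_m2`, `flank_m1`, `flank_p1`, `flank_p2` (bases
#'   at -2, -1, +1, +2 in the forward frame; `NA` outside the sequence),
#'   and `orientation` (initially `"+"`).
#' @export
scan_eboxes <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  empty <- data.frame(position = integer(0), core = character(0),
                      central = character(0), flank_m2 = character(0),
                      flank_m1 = character(0), flank_p1 = character(0),
                      flank_p2 = character(0), orientation = character(0))
  if (n < 6) return(empty)
  hits <- matchPattern("CANNTG", DNAString(s), fixed = "subject")
  pos1 <- start(hits)                 # 1-based
  if (length(pos1) == 0) return(empty)
  # ambiguity letters in the subject must never count as matches
  pos1 <- pos1[!grepl("[^ACGT]", substring(s, pos1, pos1 + 5L))]
  if (length(pos1) == 0) return(empty)
  flank <- function(off) {
    p <- pos1 + off
    ifelse(p >= 1 & p <= n, substring(s, p, p), NA_character_)
  }
  data.frame(position = pos1 - 1L,
             core = substring(s, pos1, pos1 + 5L),
             central = substring(s, pos1 + 2L, pos1 + 3L),
             flank_m2 = flank(-2L), flank_m1 = flank(-1L),
             flank_p1 = flank(6L), flank_p2 = flank(7L),
             orientation = rep("+", length(pos1)),
             stringsAsFactors = FALSE)
}

# Column layout of a position profile: flanks -2, -1; core 1..6; +1, +2.
.PROFILE_COLS <- c("m2", "m1", paste0("c", 1:6), "p1", "p2")

.empty_profile <- function() {
  matrix(0L, 4, 10, dimnames = list(base = c("A", "C", "G", "T"),
                                    position = .PROFILE_COLS))
}

# 10-mer around one oriented match, or NA if flanks incomplete.
.match_10mer <- function(m) {
  if (any(is.na(c(m$flank_m2, m$flank_m1, m$flank_p1, m$flank_p2))))
    return(NA_character_)
  fwd <- paste0(m$flank_m2, m$flank_m1, m$core, m$flank_p1, m$flank_p2)
  if (m$orientation == "-") revcomp(fwd) else fwd
}

#' Choose match orientation by flank likelihood
#'
#' The E-box core frame is strand-ambiguous (`CANNTG` matches its own
#' reverse complement pattern), so each match can be read in the forward
#' or the reverse-complement frame.  This picks, per match, the frame
#' whose four flanking bases have the higher log-likelihood under a
#' running position profile (with add-one smoothing).  An empty profile
#' leaves matches forward; exact ties stay forward.
#'
#' @param matches Data frame from [scan_eboxes()].
#' @param profile A profile matrix from [build_position_profile()] (or
#'   [`.empty_profile`][build_position_profile] shape) used as reference.
#' @return `matches` with `orientation` set to `"+"` or `"-"`.
#' @export
orient_matches <- function(matches, profile) {
  if (nrow(matches) == 0 || sum(profile) == 0) return(matches)
  pr <- sweep(profile + 1, 2, colSums(profile + 1), "/")
  ll <- function(tenmer) {
    b <- strsplit(tenmer, "")[[1]]
    sum(log(pr[cbind(b, .PROFILE_COLS)]))
  }
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    m$orientation <- "+"
    fwd <- .match_10mer(m)
    if (is.na(fwd)) next
    rev10 <- revcomp(fwd)
    matches$orientation[i] <- if (ll(rev10) > ll(fwd)) "-" else "+"
  }
  matches
}

#' Flanking-nucleotide profile of peak E-boxes
#'
#' Each peak contributes the E-box nearest its summit within
#' `+/- window` bases (one E-box per peak, so long peaks cannot
#' dominate); peaks without one are skipped.  Base counts are tallied at
#' the six core positions and `flank_width` positions on either side,
#' after two orientation passes: an all-forward build, then re-orientation
#' of every match against that profile and a rebuild.
#'
#' @param peaks Peak `GRanges` with a `summit` mcol.
#' @param genome Named `DNAStringSet`.
#' @param flank_width Flanking positions per side profiled (fixed layout
#'   supports 2).
#' @param window Summit distance within which an E-box is accepted.
#' @return A 4 x 10 count matrix (rows A/C/G/T; columns `m2`, `m1`,
#'   `c1`..`c6`, `p1`, `p2`); every column sums to the number of
#'   contributing peaks.
#' @export
build_position_profile <- function(peaks, genome, flank_width = 2,
                                   window = 50) {
  stopifnot(flank_width == 2)
  picked <- list()
  for (i in seq_along(peaks)) {
    ch <- as.character(seqnames(peaks))[i]
    summit <- peaks$summit[i]
    len <- width(genome)[match(ch, names(genome))]
    s0 <- max(1L, summit - window - 2L)
    e0 <- min(len, summit + window + 7L)
    seq_i <- as.character(subseq(genome[[ch]], s0, e0))
    m <- scan_eboxes(seq_i)
    if (nrow(m) == 0) next
    # absolute center of each 6-mer vs the summit
    center <- s0 + m$position + 2.5
    m <- m[abs(center - summit) <= window + 3, , drop = FALSE]
    if (nrow(m) == 0) next
    center <- s0 + m$position + 2.5
    best <- which.min(abs(center - summit))
    picked[[length(picked) + 1L]] <- m[best, , drop = FALSE]
  }
  if (length(picked) == 0) return(.empty_profile())
  matches <- do.call(rbind, picked)
  tally <- function(mm) {
    prof <- .empty_profile()
    for (i in seq_len(nrow(mm))) {
      t10 <- .match_10mer(mm[i, ])
      if (is.na(t10)) next
      b <- strsplit(t10, "")[[1]]
      ok <- b %in% rownames(prof)
      idx <- cbind(b[ok], .PROFILE_COLS[ok])
      prof[idx] <- prof[idx] + 1L
    }
    prof
  }
  prof1 <- tally(matches)
  matches2 <- orient_matches(matches, prof1)
  tally(matches2)
}

#' Find matches of an IUPAC consensus in a sequence
#'
#' Both strands are searched; ambiguity codes are interpreted in the
#' consensus only, never in the subject.
#'
#' @param seq DNA sequence (character or `DNAString`); case-insensitive.
#' @param consensus IUPAC consensus string.
#' @return Data frame `position` (0-based start), `strand` (`+`/`-`).
#'   Positions where the consensus is self-reverse-complementary appear
#'   once, on `+`.
#' @export
match_iupac <- function(seq, consensus) {
  .check_iupac(consensus)
  s <- toupper(as.character(seq))
  w <- nchar(consensus)
  if (nchar(s) < w)
    return(data.frame(position = integer(0), strand = character(0)))
  subj <- DNAString(s)
  clean <- function(pos0) {
    if (length(pos0) == 0) return(pos0)
    pos0[!grepl("[^ACGT]", substring(s, pos0 + 1L, pos0 + w))]
  }
  fwd <- clean(start(matchPattern(consensus, subj,
                                  fixed = "subject")) - 1L)
  rc <- revcomp(consensus)
  if (rc == toupper(consensus)) {
    rev <- integer(0)
  } else {
    rev <- clean(start(matchPattern(rc, subj, fixed = "subject")) - 1L)
    rev <- setdiff(rev, fwd)
  }
  out <- rbind(data.frame(position = fwd,
                          strand = rep("+", length(fwd))),
               data.frame(position = rev,
                          strand = rep("-", length(rev))))
  out[order(out$position), , drop = FALSE]
}

# number of sequences (DNAStringSet) with >= 1 match of consensus on
# either strand, and the total match count
.consensus_hits <- function(consensus, seqs) {
  ok <- width(seqs) >= nchar(consensus)
  if (!any(ok)) return(list(n_hit = 0L, n_match = 0L))
  cf <- vcountPattern(consensus, seqs[ok], fixed = "subject")
  rc <- revcomp(consensus)
  cr <- if (rc == consensus) 0L else
    vcountPattern(rc, seqs[ok], fixed = "subject")
  list(n_hit = sum((cf + cr) > 0), n_match = sum(cf) + sum(cr))
}

.motif_score <- function(h_fg, n_fg, h_bg, n_bg) {
  log(((h_fg + 0.5) / (n_fg - h_fg + 0.5)) /
        ((h_bg + 0.5) / (n_bg - h_bg + 0.5)))
}

.motif_score_se <- function(h_fg, n_fg, h_bg, n_bg) {
  sqrt(1 / (h_fg + 0.5) + 1 / (n_fg - h_fg + 0.5) +
         1 / (h_bg + 0.5) + 1 / (n_bg - h_bg + 0.5))
}

# per-sequence unique canonical k-mer hit counts; named integer vector
.kmer_hit_table <- function(seqs_chr, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seqs_chr) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    if (length(km) == 0) next
    for (x in unique(.canonical(unique(km)))) {
      env[[x]] <- (if (is.null(env[[x]])) 0L else env[[x]]) + 1L
    }
  }
  out <- as.list(env)
  stats::setNames(as.integer(unlist(out)), names(out))
}

# IUPAC codes that are strict supersets of a given code
.superset_codes <- function(code) {
  bases <- .IUPAC_MAP[[code]]
  cand <- names(.IUPAC_MAP)[vapply(.IUPAC_MAP, function(b)
    all(bases %in% b) && length(b) > length(bases), logical(1))]
  cand
}

#' Discriminative de novo motif discovery
#'
#' Finds IUPAC consensus motifs that separate a foreground sequence set
#' from a background set.  The motif score is the log odds ratio of
#' sequence-hit fractions with 0.5 pseudocounts; because that raw score
#' rewards rare zero-background words out of proportion to the evidence
#' (a handful of foreground hits with an empty background cell outscores
#' a motif present in most of the foreground), seeds are ranked by the
#' score's Wald z-statistic (score divided by its standard error), the
#' same quantity the significance gate tests.
#'
#' Every k-mer (`k_min`..`k_max`, both strands collapsed to a canonical
#' form) is evaluated; the best seed is refined greedily — at each step
#' the single change (replace one position by an IUPAC superset code, or
#' extend by one position on either side with any code) that most
#' improves the raw score while also improving the z-statistic is
#' accepted, until no such change exists; requiring both keeps the climb
#' from drifting into rare over-specific words (raw score alone) or
#' near-vacuous degenerate codes (z alone).
#' The refined motif is reported, its matches are masked out of the
#' foreground, and the search repeats, up to `max_motifs` motifs or until
#' the best seed fails the gate (`z > score_se_mult`).
#'
#' @param fg_seqs,bg_seqs Foreground / background sequences (character
#'   vector or `DNAStringSet`); both non-empty.
#' @param k_min,k_max Seed k-mer width range (defaults 6..10).
#' @param max_motifs Maximum motifs reported.
#' @param score_se_mult Significance gate in Wald SEs of the seed score.
#' @return Data frame, one row per motif: `consensus` (canonical IUPAC
#'   string), `width`, `score` (log odds ratio), `z` (Wald z), `fg_frac`,
#'   `bg_frac`, `ratio` (pseudocount odds ratio), `match_count_fg`,
#'   `match_count_bg`.  Zero rows when nothing passes the gate.
#' @export
discriminative_motif_search <- function(fg_seqs, bg_seqs, k_min = 6,
                                        k_max = 10, max_motifs = 5,
                                        score_se_mult = 2) {
  if (k_min > k_max) stop("k_min must be <= k_max")
  fg <- toupper(as.character(fg_seqs))
  bg <- toupper(as.character(bg_seqs))
  if (length(fg) == 0 || length(bg) == 0)
    stop("foreground and background sequence sets must be non-empty")
  n_fg <- length(fg)
  n_bg <- length(bg)
  bg_set <- DNAStringSet(bg)
  zstat <- function(hf, hb) {
    .motif_score(hf, n_fg, hb, n_bg) /
      .motif_score_se(hf, n_fg, hb, n_bg)
  }
  results <- list()
  for (round in seq_len(max_motifs)) {
    fg_set <- DNAStringSet(fg)
    # ---- seed: best canonical k-mer by z-statistic of sequence hits
    best_seed <- NULL
    best_z <- -Inf
    for (k in seq(k_min, k_max)) {
      tf <- .kmer_hit_table(fg, k)
      if (length(tf) == 0) next
      tb <- .kmer_hit_table(bg, k)
      h_bg <- ifelse(names(tf) %in% names(tb), tb[names(tf)], 0L)
      z <- zstat(tf, h_bg)
      o <- order(-z, names(tf))
      if (z[o[1]] > best_z) {
        best_z <- z[o[1]]
        best_seed <- names(tf)[o[1]]
      }
    }
    if (is.null(best_seed) || best_z <= score_se_mult) break
    # ---- greedy refinement: a change is accepted only when it improves
    # both the raw score (effect size) and its z-statistic (evidence);
    # either objective alone walks into degenerate optima (the raw score
    # into rare zero-background words, the z into near-vacuous codes)
    cur <- best_seed
    sh <- .consensus_hits(cur, fg_set)
    sb <- .consensus_hits(cur, bg_set)
    cur_score <- .motif_score(sh$n_hit, n_fg, sb$n_hit, n_bg)
    cur_z <- zstat(sh$n_hit, sb$n_hit)
    repeat {
      letters <- strsplit(cur, "")[[1]]
      cands <- character(0)
      for (i in seq_along(letters)) {
        for (code in .superset_codes(letters[i])) {
          nl <- letters; nl[i] <- code
          cands <- c(cands, paste(nl, collapse = ""))
        }
      }
      for (code in names(.IUPAC_MAP)) {
        cands <- c(cands, paste0(code, cur), paste0(cur, code))
      }
      cands <- unique(.canonical(cands))
      ev <- vapply(cands, function(cc) {
        hf <- .consensus_hits(cc, fg_set)$n_hit
        hb <- .consensus_hits(cc, bg_set)$n_hit
        c(.motif_score(hf, n_fg, hb, n_bg), zstat(hf, hb))
      }, numeric(2))
      ok <- ev[1, ] > cur_score + 1e-12 & ev[2, ] > cur_z + 1e-12
      if (!any(ok)) break
      o <- order(-ev[1, ], cands)
      o <- o[ok[o]]
      cur <- cands[o[1]]
      cur_score <- ev[1, o[1]]
      cur_z <- ev[2, o[1]]
    }
    cur <- .canonical(cur)
    hf <- .consensus_hits(cur, fg_set)
    hb <- .consensus_hits(cur, bg_set)
    score <- .motif_score(hf$n_hit, n_fg, hb$n_hit, n_bg)
    cur_z <- zstat(hf$n_hit, hb$n_hit)
    results[[round]] <- data.frame(
      consensus = cur, width = nchar(cur), score = score, z = cur_z,
      fg_frac = hf$n_hit / n_fg, bg_frac = hb$n_hit / n_bg,
      ratio = exp(score),
      match_count_fg = hf$n_match, match_count_bg = hb$n_match,
      stringsAsFactors = FALSE)
    # ---- mask foreground matches and continue
    fg <- .mask_matches(fg, cur)
  }
  if (length(results) == 0) {
    return(data.frame(consensus = character(0), width = integer(0),
                      score = numeric(0), z = numeric(0),
                      fg_frac = numeric(0),
                      bg_frac = numeric(0), ratio = numeric(0),
                      match_count_fg = integer(0),
                      match_count_bg = integer(0)))
  }
  do.call(rbind, results)
}

# replace every match of consensus (both strands) with Ns
.mask_matches <- function(seqs_chr, consensus) {
  w <- nchar(consensus)
  vapply(seqs_chr, function(s) {
    m <- match_iupac(s, consensus)
    if (nrow(m) == 0) return(s)
    for (p in m$position)
      substr(s, p + 1L, p + w) <- strrep("-", w)
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Extract peak sequences around summits
#'
#' @param peaks Peak `GRanges` with `summit`.
#' @param genome Named `DNAStringSet`.
#' @param flank Bases either side of the summit (default 100).
#' @return Character vector of `2 * flank + 1`-mer sequences (shorter at
#'   chromosome ends), named by peak name.
#' @export
extract_peak_sequences <- function(peaks, genome, flank = 100) {
  vapply(seq_along(peaks), function(i) {
    ch <- as.character(seqnames(peaks))[i]
    len <- width(genome)[match(ch, names(genome))]
    s <- max(1L, peaks$summit[i] - flank)
    e <- min(len, peaks$summit[i] + flank)
    as.character(subseq(genome[[ch]], s, e))
  }, character(1))
}

#' Bundled gel-shift probe sequences
#'
#' Seven double-stranded oligo probes (forward strands) used in
#' electrophoretic mobility shift assays on MSC/MyoD E-box binding,
#' bundled as worked-example inputs for [scan_eboxes()]: the MSC-preferred
#' CCAGCTGG probe, four single/double flank mutants, a CG-core E-box, and
#' a CACCTG-core control.
#'
#' @return Named character vector of probe sequences.
#' @export
emsa_probes <- function() {
  c(msc_specific      = "cggccgaccagctggagatcct",
    minus1_mut        = "cggccgagcagctggagatcct",
    minus1_plus1_mut  = "cggccgagcagctgcagatcct",
    msc_specific_Tmut = "cggccgtccagctggagatcct",
    minus1_plus1_Tmut = "cggccgtgcagctgcagatcct",
    cg_ebox           = "cggccgaccacgtggagatcct",
    B1                = "gatccccccaacacctgctgcctga")
}
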