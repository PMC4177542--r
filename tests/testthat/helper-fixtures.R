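# Shared fixtures and independent oracles used across test files.
# Expensive simulations are cached per session so several test files can
# reuse them without re-running the generator.

.fixture_env <- new.env(parent = emptyenv())

# The default study-condition simulation (1 Mb, 300 sites, occupancy 10).
fixture_sim <- function(seed = 1) {
  key <- paste0("sim_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_experiment(sim_config(seed = seed))
  .fixture_env[[key]]
}

# Peaks called on the fixture at the loose working cutoff.
fixture_peaks <- function(seed = 1, factor = "A") {
  key <- paste0("peaks_", seed, "_", factor)
  if (is.null(.fixture_env[[key]])) {
    sim <- fixture_sim(seed)
    .fixture_env[[key]] <- call_peaks(sim$tags[[factor]], sim$genome,
                                      p_cutoff = 1e-4)
  }
  .fixture_env[[key]]
}

# A small genome/tag fixture for I/O and unit tests.
tiny_genome <- function(lens = c(chr1 = 2000L, chr2 = 1500L), seed = 99) {
  set.seed(seed)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
          collapse = ""), character(1))
  Biostrings::DNAStringSet(seqs)
}

# Random peak list on a virtual genome, for overlap-matrix tests.
random_peaks <- function(n, seqlens = c(chr1 = 1e6, chr2 = 1e6),
                         width_range = c(100, 600), seed = 1) {
  set.seed(seed)
  ch <- sample(names(seqlens), n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(seqlens[[ch[i]]] - w[i], 1L), numeric(1))
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, width = w))
  GenomeInfoDb::seqlevels(gr) <- names(seqlens)
  GenomeInfoDb::seqlengths(gr) <- unname(seqlens)
  gr$p_value <- 10^(-runif(n, 2, 30))
  gr$summit <- (start(gr) + end(gr)) %/% 2
  gr$name <- paste0("rp_", seq_len(n))
  gr
}

# O(n * m) brute-force overlap-fraction oracle.  For every peak of list 1
# a full vector comparison against list 2 finds the earliest-ranked
# overlap partner; cumulative-bin fractions follow by counting.
oracle_overlap_matrix <- function(p1, p2, bin, max_rank) {
  ord <- function(gr) {
    gr[order(gr$p_value,
             as.integer(match(as.character(GenomicRanges::seqnames(gr)),
                              GenomeInfoDb::seqlevels(gr))),
             GenomicRanges::start(gr))]
  }
  p1 <- ord(p1); p2 <- ord(p2)
  xs <- seq(bin, max_rank, by = bin)
  m <- matrix(NA_real_, length(xs), length(xs),
              dimnames = list(x = xs, y = xs))
  c1 <- as.character(GenomicRanges::seqnames(p1))
  c2 <- as.character(GenomicRanges::seqnames(p2))
  s1 <- GenomicRanges::start(p1); e1 <- GenomicRanges::end(p1)
  s2 <- GenomicRanges::start(p2); e2 <- GenomicRanges::end(p2)
  first_partner <- vapply(seq_along(p1), function(a) {
    hit <- which(c1[a] == c2 & s1[a] <= e2 & s2 <= e1[a])
    if (length(hit) == 0) Inf else hit[1]
  }, numeric(1))
  for (i in seq_along(xs)) {
    x_eff <- min(xs[i], length(p1))
    for (j in seq_along(xs)) {
      if (xs[j] < xs[i]) next
      y_eff <- min(xs[j], length(p2))
      m[i, j] <- sum(first_partner[seq_len(x_eff)] <= y_eff) / x_eff
    }
  }
  m
}

# Random DNA sequence generator for motif tests.
random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# Plant a motif at a random position inside a sequence.
plant_motif <- function(s, motif) {
  pos <- sample.int(nchar(s) - nchar(motif) + 1L, 1L)
  substr(s, pos, pos + nchar(motif) - 1L) <- motif
  s
}

# Does an IUPAC consensus contain the reference word at >= min_match of
# its positions, at the best ungapped offset?
consensus_matches_word <- function(consensus, word, min_match) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  check_one <- function(cons) {
    cl <- strsplit(cons, "")[[1]]
    wl <- strsplit(word, "")[[1]]
    if (length(cl) < length(wl)) return(0L)
    best <- 0L
    for (off in 0:(length(cl) - length(wl))) {
      hits <- sum(vapply(seq_along(wl), function(i)
        wl[i] %in% codes[[cl[off + i]]], logical(1)))
      best <- max(best, hits)
    }
    best
  }
  max(check_one(consensus), check_one(eboxchip::revcomp(consensus))) >=
    min_match
}
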