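# E-box scanning, IUPAC matching, position profiles, and discriminative
# motif discovery.

test_that("scan_eboxes locates the single E-box in each bundled probe
           with the expected core and flanks", {
  probes <- emsa_probes()
  scans <- lapply(probes, scan_eboxes)
  expect_true(all(vapply(scans, nrow, integer(1)) == 1L))
  msc <- scans$msc_specific
  expect_equal(msc$position, 8L)
  expect_equal(msc$core, "CAGCTG")
  expect_equal(msc$central, "GC")
  expect_equal(msc$flank_m1, "C")
  expect_equal(msc$flank_p1, "G")
  # the 8-mer around the core reads the full preferred motif
  expect_equal(paste0(msc$flank_m1, msc$core, msc$flank_p1), "CCAGCTGG")
  expect_equal(scans$cg_ebox$position, 8L)
  expect_equal(scans$cg_ebox$core, "CACGTG")
  expect_equal(scans$cg_ebox$central, "CG")
  expect_equal(scans$B1$position, 11L)
  expect_equal(scans$B1$core, "CACCTG")
  # N never matches; empty and short sequences are fine
  expect_equal(nrow(scan_eboxes("CANNTG")), 0L)
  expect_equal(nrow(scan_eboxes("ACGT")), 0L)
})

test_that("the preferred 8-mer is its own reverse complement and
           revcomp handles IUPAC codes", {
  expect_equal(revcomp("CCAGCTGG"), "CCAGCTGG")
  expect_equal(revcomp("CANNTG"), "CANNTG")
  expect_equal(revcomp("ACGTRY"), "RYACGT")
  expect_equal(revcomp(c("AAA", "CGT")), c("TTT", "ACG"))
})

test_that("match_iupac equals a naive scan on random sequence and
           rejects invalid codes", {
  expect_equal(match_iupac("AACAGCTGAA", "CANNTG")$position, 2L)
  expect_equal(match_iupac("ccagctgg", "CCAGCTGG")$position, 0L)
  expect_error(match_iupac("ACGT", "CAXNTG"), "IUPAC")
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  cons <- "CANNTG"
  got <- match_iupac(s, cons)
  # naive oracle: regex on both strands
  re <- "CA[ACGT][ACGT]TG"
  naive <- function(x, re, k) {
    out <- integer(0); from <- 1
    repeat {
      m <- regexpr(re, substring(x, from))
      if (m == -1) break
      out <- c(out, from + m - 2L)   # 0-based
      from <- from + m
    }
    out
  }
  fwd <- naive(s, re, 6)
  rc <- naive(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), re, 6)
  rc_pos <- sort(10000 - rc - 6)
  expect_equal(got$position, sort(unique(c(fwd, rc_pos))))
})

test_that("orientation: symmetric flanks stay forward and a skewed
           profile flips the reverse frame", {
  m <- scan_eboxes("GACCAGCTGGTC")    # CCAGCTGG context, self-revcomp
  prof <- matrix(5L, 4, 10, dimnames = list(c("A", "C", "G", "T"),
                                            c("m2", "m1", paste0("c", 1:6),
                                              "p1", "p2")))
  o <- orient_matches(m, prof)        # flat profile: tie -> forward
  expect_equal(o$orientation, "+")
  # profile strongly favouring T flanks: a match whose forward frame
  # reads A at the -1/+1 flanks flips to the reverse-complement frame
  # (forward 10-mer AACAGCTGAA, reverse frame TTCAGCTGTT)
  m2 <- scan_eboxes("CAACAGCTGAAC")
  expect_equal(m2$flank_m1, "A")
  prof["T", "m1"] <- 500L; prof["T", "p1"] <- 500L
  o2 <- orient_matches(m2, prof)
  expect_equal(o2$orientation, "-")
})

test_that("build_position_profile recovers planted flank preferences and
           leaves uniform flanks near 25% per base", {
  sim <- fixture_sim(1)
  pb <- fixture_peaks(1, "B")
  cls <- classify_peaks(fixture_peaks(1, "A"), pb)
  bsp <- cls$B[cls$B$label == "B_specific"]
  prof <- build_position_profile(bsp, sim$genome)
  expect_true(all(colSums(prof) == colSums(prof)[1]))
  # planted B model: C at -1 (p 0.7), G at +1 (p 0.7)
  expect_equal(rownames(prof)[which.max(prof[, "m1"])], "C")
  expect_equal(rownames(prof)[which.max(prof[, "p1"])], "G")
  n <- sum(prof[, "m1"])
  expect_gt(prof["C", "m1"] / n, 0.7 - 3 * sqrt(0.21 / n))
  # uniform flanks (A-specific sites, +2 position is uniform in both
  # models): all bases within the binomial band of 0.25
  asp <- cls$A[cls$A$label == "A_specific"]
  prof_a <- build_position_profile(asp, sim$genome)
  na <- sum(prof_a[, "p2"])
  half <- 3 * sqrt(0.25 * 0.75 / na)
  expect_true(all(abs(prof_a[, "p2"] / na - 0.25) < half + 0.02))
  # no peaks -> empty profile
  expect_equal(sum(build_position_profile(bsp[0], sim$genome)), 0)
})

test_that("seed scoring equals an independent 2x2 contingency
           computation", {
  set.seed(32)
  fg <- random_dna(80, 40)
  bg <- random_dna(80, 40)
  for (i in 1:40) fg[i] <- plant_motif(fg[i], "GATCGAT")
  res <- discriminative_motif_search(fg, bg, k_min = 6, k_max = 8,
                                     max_motifs = 1)
  expect_equal(nrow(res), 1L)
  hits_in <- function(seqs, cons) {
    sum(vapply(seqs, function(s) nrow(match_iupac(s, cons)) > 0,
               logical(1)))
  }
  h_fg <- hits_in(fg, res$consensus)
  h_bg <- hits_in(bg, res$consensus)
  n <- length(fg)
  expect_equal(res$fg_frac, h_fg / n)
  expect_equal(res$bg_frac, h_bg / n)
  expect_equal(res$score,
               log(((h_fg + 0.5) / (n - h_fg + 0.5)) /
                     ((h_bg + 0.5) / (n - h_bg + 0.5))))
  expect_equal(res$ratio, exp(res$score))
})

test_that("a planted 7-mer is recovered with an odds ratio near the
           construction's truth, and identical sets yield no motif", {
  set.seed(33)
  fg <- random_dna(150, 50)
  bg <- random_dna(150, 50)
  for (i in 1:75) fg[i] <- plant_motif(fg[i], "GTACGTA")
  for (i in 1:8) bg[i] <- plant_motif(bg[i], "GTACGTA")
  res <- discriminative_motif_search(fg, bg, k_min = 6, k_max = 8,
                                     max_motifs = 1)
  expect_equal(nrow(res), 1L)
  expect_true(consensus_matches_word(res$consensus, "GTACGTA", 6))
  # fg_frac near 0.5 and odds ratio within a wide CI of the planted 2x2
  expect_gt(res$fg_frac, 0.5 - 3 * sqrt(0.25 / 150))
  true_or <- (0.5 / 0.5) / ((8 / 150) / (142 / 150))
  expect_gt(res$ratio, true_or / 3)
  expect_lt(res$ratio, true_or * 3)
  # null: identical sets
  expect_equal(nrow(discriminative_motif_search(fg, fg, k_min = 6,
                                                k_max = 8)), 0L)
  expect_error(discriminative_motif_search(character(0), bg), "non-empty")
  expect_error(discriminative_motif_search(fg, bg, k_min = 8, k_max = 6),
               "k_min")
})

test_that("motif discovery is closed under reverse complementing every
           input sequence", {
  set.seed(34)
  fg <- random_dna(100, 40)
  bg <- random_dna(100, 40)
  for (i in 1:55) fg[i] <- plant_motif(fg[i], "CCAGGTTG")
  res <- discriminative_motif_search(fg, bg, k_min = 6, k_max = 8,
                                     max_motifs = 2)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  res_rc <- discriminative_motif_search(rc(fg), rc(bg), k_min = 6,
                                        k_max = 8, max_motifs = 2)
  expect_equal(res$consensus, res_rc$consensus)
  expect_equal(res$fg_frac, res_rc$fg_frac)
  expect_equal(res$score, res_rc$score)
})
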