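# Peak calling: deduplication, directional extension, coverage, the NB
# background fit, window P values, merging/summits, control subtraction.

test_that("deduplicate keeps one tag per (chrom, start, strand) and is
           order-independent", {
  g <- tiny_genome()
  tg <- GRanges(c("chr1", "chr1", "chr1", "chr1", "chr2"),
                IRanges(c(100, 100, 100, 100, 100), width = 36),
                strand = c("+", "+", "+", "-", "+"))
  seqlevels(tg) <- names(g); seqlengths(tg) <- width(g)
  dd <- deduplicate(tg)
  expect_length(dd, 3)   # chr1:+ / chr1:- / chr2:+
  set.seed(1)
  rnd <- GRanges("chr1",
                 IRanges(sample(1:500, 1000, replace = TRUE), width = 36),
                 strand = sample(c("+", "-"), 1000, replace = TRUE))
  seqlevels(rnd) <- names(g); seqlengths(rnd) <- width(g)
  key <- paste(start(rnd), strand(rnd))
  expect_length(deduplicate(rnd), length(unique(key)))
  perm <- rnd[sample(length(rnd))]
  expect_identical(as.data.frame(deduplicate(rnd)),
                   as.data.frame(deduplicate(perm)))
})

test_that("extend_tags extends in the sequencing orientation and clips
           at chromosome bounds", {
  g <- tiny_genome()
  tg <- GRanges(c("chr1", "chr1", "chr1"),
                IRanges(c(101, 501, 11), c(136, 536, 46)),
                strand = c("+", "-", "-"))
  seqlevels(tg) <- names(g); seqlengths(tg) <- width(g)
  ext <- extend_tags(tg, L = 200)
  # (+, 0-based 100-136) -> 0-based (100, 300)
  expect_equal(c(start(ext)[1], end(ext)[1]), c(101, 300))
  # (-, 0-based 500-536) -> (336, 536)
  expect_equal(c(start(ext)[2], end(ext)[2]), c(337, 536))
  # (-, 0-based 10-46) -> clipped (0, 46)
  expect_equal(c(start(ext)[3], end(ext)[3]), c(1, 46))
  expect_error(extend_tags(tg, L = 10), "shorter")
})

test_that("interval_coverage equals the brute-force per-base count", {
  g <- tiny_genome()
  iv <- GRanges(c("chr1", "chr1"), IRanges(c(1, 6), c(10, 15)))
  seqlevels(iv) <- names(g); seqlengths(iv) <- width(g)
  cov <- interval_coverage(iv)
  expect_equal(as.numeric(cov$chr1)[1:16],
               c(rep(1, 5), rep(2, 5), rep(1, 5), 0))
  set.seed(2)
  n <- 500
  s <- sample(1:1900, n, replace = TRUE)
  iv2 <- GRanges("chr1", IRanges(s, width = sample(5:100, n, TRUE)))
  iv2 <- GRanges("chr1", IRanges(start(iv2), pmin(end(iv2), 2000L)))
  seqlevels(iv2) <- names(g); seqlengths(iv2) <- width(g)
  brute <- integer(2000)
  for (i in seq_len(n))
    brute[start(iv2)[i]:end(iv2)[i]] <- brute[start(iv2)[i]:end(iv2)[i]] + 1L
  expect_equal(as.integer(as.numeric(interval_coverage(iv2)$chr1)), brute)
  expect_equal(sum(as.numeric(interval_coverage(iv2)$chr1)),
               sum(width(iv2)))
})

test_that("fit_background recovers NB parameters by plain moments and
           flags degenerate/Poisson data", {
  set.seed(3)
  counts <- rnbinom(1e5, size = 2, mu = 5)
  fit <- fit_background(counts, trim_quantile = 1.0)
  expect_gt(fit$mu, 4.9); expect_lt(fit$mu, 5.1)
  expect_gt(fit$size, 1.8); expect_lt(fit$size, 2.2)
  expect_false(fit$poisson)
  # constant counts: zero variance -> Poisson fallback
  cfit <- fit_background(rep(3L, 200))
  expect_true(cfit$poisson)
  expect_identical(cfit$size, Inf)
  # Poisson-distributed counts trip the fallback in most replicate fits
  flags <- vapply(1:20, function(s) {
    set.seed(s)
    fit_background(rpois(2000, 5))$poisson
  }, logical(1))
  expect_gte(mean(flags), 0.5)
  expect_error(fit_background(rep(0L, 500)), "zero")
  expect_error(fit_background(1:50))   # too few windows
})

test_that("the robust fit resists signal contamination that overwhelms a
           fixed upper-quantile trim", {
  set.seed(4)
  counts <- rnbinom(5000, size = 2, mu = 5)
  contaminated <- counts
  idx <- sample(5000, 600)             # 12% signal windows
  contaminated[idx] <- contaminated[idx] + rpois(600, 150)
  fit <- fit_background(contaminated, trim_quantile = 0.99)
  expect_lt(abs(fit$mu - 5) / 5, 0.15)
  expect_lt(fit$size, 4)               # dispersion not collapsed to huge
})

test_that("nb_tail_p is a valid clamped upper tail", {
  bg <- structure(list(mu = 5, size = 2, poisson = FALSE, window = 200,
                       n_windows = 1000), class = "nb_background")
  expect_equal(nb_tail_p(0, bg), 1)
  expect_equal(nb_tail_p(3, bg),
               pnbinom(2, size = 2, mu = 5, lower.tail = FALSE))
  expect_gt(nb_tail_p(1e6, bg), 0)     # clamped, never exactly 0
  bgp <- structure(list(mu = 5, size = Inf, poisson = TRUE, window = 200,
                        n_windows = 1000), class = "nb_background")
  expect_equal(nb_tail_p(3, bgp),
               ppois(2, 5, lower.tail = FALSE))
})

test_that("call_peaks finds exactly one peak per isolated planted site
           and none on an empty tag set", {
  cfg <- sim_config(genome_length = 1e5, n_chroms = 1,
                    n_sites = c(A = 1, B = 0, shared = 0), seed = 13)
  res <- plant_sites(generate_genome(cfg), cfg)
  tg <- simulate_tags(res$sites, res$genome, cfg, "A")
  pk <- call_peaks(tg, res$genome, p_cutoff = 1e-5)
  expect_length(pk, 1)
  expect_true(overlapsAny(res$sites, pk))
  expect_lt(pk$p_value, 1e-10)
  expect_true(pk$summit >= start(pk) && pk$summit <= end(pk))
  expect_gte(pk$height, 1)
  # empty input
  empty <- GRanges()
  seqlevels(empty) <- names(res$genome)
  seqlengths(empty) <- width(res$genome)
  expect_length(call_peaks(empty, res$genome), 0)
  expect_error(call_peaks(tg, res$genome, p_cutoff = 2), "p_cutoff")
})

test_that("increasing site occupancy never worsens its peak P value on a
           fixed background", {
  pvals <- vapply(c(3, 6, 12), function(aff) {
    cfg <- sim_config(genome_length = 1e5, n_chroms = 1,
                      n_sites = c(A = 1, B = 0, shared = 0),
                      affinity = aff, seed = 14)
    res <- plant_sites(generate_genome(cfg), cfg)
    tg <- simulate_tags(res$sites, res$genome, cfg, "A")
    pk <- call_peaks(tg, res$genome, p_cutoff = 1e-3)
    min(pk$p_value[overlapsAny(pk, res$sites)])
  }, numeric(1))
  expect_true(all(diff(pvals) <= 0))
})

test_that("subtract_control removes only peaks overlapping sufficiently
           significant control peaks", {
  g <- tiny_genome(c(chr1 = 5000L))
  mk <- function(s, e, p) {
    gr <- GRanges("chr1", IRanges(s, e))
    seqlevels(gr) <- names(g); seqlengths(gr) <- width(g)
    gr$name <- "x"; gr$summit <- (s + e) %/% 2L
    gr$height <- 10L; gr$n_tags <- 10L; gr$p_value <- p
    gr
  }
  peaks <- mk(101, 400, 1e-12)
  # one shared base with a strong control peak -> removed
  expect_length(subtract_control(peaks, mk(400, 600, 1e-6)), 0)
  # abutting but not overlapping -> retained
  expect_length(subtract_control(peaks, mk(401, 600, 1e-6)), 1)
  # control peak too weak -> retained
  expect_length(subtract_control(peaks, mk(400, 600, 1e-3)), 1)
  # empty control -> unchanged
  expect_identical(subtract_control(peaks, peaks[0]), peaks)
})

test_that("count_peaks_at_cutoffs matches brute-force threshold counts
           and is monotone", {
  g <- tiny_genome(c(chr1 = 1e6L))
  set.seed(5)
  p <- 10^(-runif(1000, 0, 15))
  pk <- GRanges("chr1", IRanges(seq(1, by = 700, length.out = 1000),
                                width = 300))
  seqlevels(pk) <- names(g); seqlengths(pk) <- width(g)
  pk$p_value <- p
  counts <- count_peaks_at_cutoffs(pk)
  expect_equal(unname(counts),
               c(sum(p <= 1e-5), sum(p <= 1e-7), sum(p <= 1e-10)))
  expect_true(all(diff(counts) <= 0))
  expect_equal(unname(count_peaks_at_cutoffs(pk[0])), c(0L, 0L, 0L))
  pk3 <- pk[1:3]; pk3$p_value <- c(1e-6, 1e-8, 1e-11)
  expect_equal(unname(count_peaks_at_cutoffs(pk3)), c(3L, 2L, 1L))
})

test_that("the peak pipeline is deterministic for fixed inputs", {
  sim <- fixture_sim(1)
  pk1 <- call_peaks(sim$tags$A, sim$genome, p_cutoff = 1e-4)
  pk2 <- call_peaks(sim$tags$A, sim$genome, p_cutoff = 1e-4)
  expect_identical(as.data.frame(pk1), as.data.frame(pk2))
})
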