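# Synthetic-data generator: determinism, planted composition recovered
# within binomial sampling error, structural invariants.

test_that("generate_genome hits the configured GC content and is
           deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 1e5, n_chroms = 1, gc_content = 0.5,
                    seed = 2)
  g <- generate_genome(cfg)
  gc <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / sum(width(g))
  # 3-sigma binomial band around 0.5 at n = 1e5 is ~0.005
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
  expect_identical(as.character(g), as.character(generate_genome(cfg)))
  expect_error(sim_config(gc_content = 1.0), "gc_content")
  expect_error(sim_config(gc_content = 0), "gc_content")
})

test_that("plant_sites writes the drawn 10-mers into the genome with the
           required spacing, and a forced model plants CCAGCTGG", {
  cfg <- sim_config(genome_length = 3e5, n_chroms = 1,
                    n_sites = c(A = 0, B = 30, shared = 0), seed = 5)
  # degenerate B model: certain C at -1, G at +1, GC core
  fp <- matrix(0, 4, 4, dimnames = list(c("m2", "m1", "p1", "p2"),
                                        c("A", "C", "G", "T")))
  fp["m2", ] <- c(1, 0, 0, 0); fp["m1", ] <- c(0, 1, 0, 0)
  fp["p1", ] <- c(0, 0, 1, 0); fp["p2", ] <- c(1, 0, 0, 0)
  mB <- flank_model(core = c(GC = 1, GG = 0, other = 0), flank_probs = fp)
  res <- plant_sites(generate_genome(cfg), cfg, model_B = mB)
  expect_length(res$sites, 30)
  expect_true(all(grepl("CCAGCTGG", res$sites$ebox, fixed = TRUE)))
  # genome truly mutated at the planted interval
  for (i in 1:5) {
    s <- res$sites[i]
    seq_i <- as.character(Biostrings::subseq(
      res$genome[[as.character(seqnames(s))]], start(s), end(s)))
    expect_identical(seq_i, s$ebox)
  }
  # spacing >= 2 * extension between site centers
  cen <- sort((start(res$sites) + end(res$sites)) %/% 2)
  expect_true(all(diff(cen) >= 2 * cfg$extension))
  # zero sites leaves the genome untouched
  cfg0 <- sim_config(genome_length = 3e4, n_chroms = 1,
                     n_sites = c(A = 0, B = 0, shared = 0), seed = 5)
  g0 <- generate_genome(cfg0)
  res0 <- plant_sites(g0, cfg0)
  expect_identical(as.character(res0$genome), as.character(g0))
  expect_length(res0$sites, 0)
  # overcrowded genome errors
  expect_error(plant_sites(generate_genome(cfg0),
                           sim_config(genome_length = 3e4, n_chroms = 1,
                                      n_sites = c(A = 500, B = 0,
                                                  shared = 0))),
               "too small")
})

test_that("planted flank frequencies recover the model probabilities
           within the binomial confidence band", {
  cfg <- sim_config(genome_length = 4e6, n_chroms = 4,
                    n_sites = c(A = 1000, B = 0, shared = 0), seed = 6)
  fp <- matrix(0.25, 4, 4, dimnames = list(c("m2", "m1", "p1", "p2"),
                                           c("A", "C", "G", "T")))
  fp["m1", ] <- c(A = 0.2, C = 0.1, G = 0.6, T = 0.1)
  mA <- flank_model(flank_probs = fp)
  res <- plant_sites(generate_genome(cfg), cfg, model_A = mA)
  m1 <- substr(res$sites$ebox, 2, 2)
  phat <- mean(m1 == "G")
  half <- 3 * sqrt(0.6 * 0.4 / 1000)       # ~0.046
  expect_gt(phat, 0.6 - half)
  expect_lt(phat, 0.6 + half)
})

test_that("simulate_tags background matches the NB mean and site tags
           cover their site after extension", {
  cfg <- sim_config(genome_length = 2e4, n_chroms = 1,
                    n_sites = c(A = 1, B = 0, shared = 0),
                    mu_bg = 5, seed = 8)
  res <- plant_sites(generate_genome(cfg), cfg)
  ctrl <- simulate_tags(res$sites, res$genome, cfg, "control")
  nwin <- 2e4 / cfg$window
  # control = pure background: mean count per window within 3 SE of mu_bg
  se <- sqrt((cfg$mu_bg + cfg$mu_bg^2 / cfg$r_bg) / nwin)
  expect_lt(abs(length(ctrl) / nwin - cfg$mu_bg), 3 * se)
  # factor A tags at the site: ~ affinity * tags_per_unit = 200 extra
  tga <- simulate_tags(res$sites, res$genome, cfg, "A")
  ext <- extend_tags(tga, cfg$extension, res$genome)
  cov_site <- countOverlaps(res$sites, ext)
  lam <- cfg$affinity * cfg$tags_per_unit_occupancy
  expect_gt(cov_site, lam - 4 * sqrt(lam) - 20)
  # every site-derived fragment covers the whole site: coverage at both
  # site edges exceeds background by a wide margin
  hits <- ext[overlapsAny(ext, res$sites)]
  covers <- start(hits) <= start(res$sites) & end(hits) >= end(res$sites)
  expect_gt(mean(covers), 0.9)
  # affinity zero => background only
  cfg0 <- sim_config(genome_length = 2e4, n_chroms = 1,
                     n_sites = c(A = 0, B = 1, shared = 0), seed = 8)
  res0 <- plant_sites(generate_genome(cfg0), cfg0)
  tgA0 <- simulate_tags(res0$sites, res0$genome, cfg0, "A")
  exp_bg <- cfg0$mu_bg * (2e4 / cfg0$window)
  expect_lt(length(tgA0), exp_bg + 4 * sqrt(exp_bg * 3.5))
  # determinism
  expect_identical(as.data.frame(tga),
                   as.data.frame(simulate_tags(res$sites, res$genome,
                                               cfg, "A")))
})

test_that("background-only window counts recover (mu_bg, r_bg) within
           10% at 1e4+ windows", {
  cfg <- sim_config(genome_length = 4e6, n_chroms = 2,
                    n_sites = c(A = 0, B = 0, shared = 0), seed = 9)
  set.seed(derive_seed(cfg$seed, "check"))
  counts <- rnbinom(2e4, size = cfg$r_bg, mu = cfg$mu_bg)
  fit <- fit_background(counts, trim_quantile = 1.0)
  expect_lt(abs(fit$mu - cfg$mu_bg) / cfg$mu_bg, 0.1)
  expect_lt(abs(fit$size - cfg$r_bg) / cfg$r_bg, 0.1)
})

test_that("gene models are non-overlapping, exons nest inside spans, and
           empty models are handled", {
  cfg <- sim_config(genome_length = 1e6, n_chroms = 2, n_genes = 50,
                    seed = 10)
  g <- generate_genome(cfg)
  genes <- generate_gene_models(g, cfg)
  expect_length(genes, 50)
  # non-overlap oracle: pairwise interval check within chromosomes
  ov <- findOverlaps(genes, genes, ignore.strand = TRUE)
  expect_true(all(queryHits(ov) == subjectHits(ov)))
  for (i in seq_along(genes))
    expect_true(all(start(genes$blocks[[i]]) >= 1 &
                      end(genes$blocks[[i]]) <= width(genes)[i]))
  cfg0 <- sim_config(genome_length = 2e4, n_chroms = 1, n_genes = 0,
                     n_sites = c(A = 0, B = 0, shared = 0))
  empty <- generate_gene_models(generate_genome(cfg0), cfg0)
  expect_length(empty, 0)
})

test_that("context tracks honour f_hss and the TSS proximity boost", {
  base <- function(f, seed) sim_config(genome_length = 4e5, n_chroms = 2,
                                       n_sites = c(A = 30, B = 30,
                                                   shared = 30),
                                       n_genes = 10, f_hss = f,
                                       seed = seed)
  for (f in c(0, 1)) {
    cfg <- base(f, 11)
    res <- plant_sites(generate_genome(cfg), cfg)
    genes <- generate_gene_models(res$genome, cfg)
    tr <- simulate_context_tracks(res$sites, genes, res$genome, cfg)
    mx <- peak_signal(res$sites, tr$hss, stat = "max")
    if (f == 0) expect_true(all(mx == 0)) else expect_true(all(mx > 0))
  }
  # near-TSS boost: planted amplitude ratio ~ ach4_tss_boost
  cfg <- sim_config(genome_length = 2e6, n_chroms = 2,
                    n_sites = c(A = 150, B = 0, shared = 0),
                    n_genes = 60, ach4_noise_sd = 0.2,
                    ach4_tss_boost = 4, seed = 12)
  res <- plant_sites(generate_genome(cfg), cfg)
  genes <- generate_gene_models(res$genome, cfg)
  tr <- simulate_context_tracks(res$sites, genes, res$genome, cfg)
  d <- tss_distance(GRanges(seqnames(res$sites),
                            ranges(res$sites),
                            summit = (start(res$sites) +
                                        end(res$sites)) %/% 2),
                    gene_tss(genes))
  amp <- peak_signal(res$sites, tr$ach4, stat = "max")
  near <- d < 2000
  skip_if(sum(near) < 10 || sum(!near) < 10)
  ratio <- mean(amp[near]) / mean(amp[!near])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)
})
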