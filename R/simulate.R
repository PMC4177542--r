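# Synthetic-data generator: a toy genome with planted E-box binding sites
# for two bHLH-like factors, tag sets with a negative-binomial background,
# a gene model, and chromatin-context tracks (acetylation bumps, sparse
# DNase-hypersensitivity signal).  Everything is a pure function of the
# SimConfig, including its seed.

.IUPAC_BASES <- c("A", "C", "G", "T")

#' E-box flanking-nucleotide model
#'
#' Describes how a factor's planted sites draw the 10-mer written into the
#' genome: the E-box core CANNTG with a distribution over the central
#' dinucleotide, and independent per-position nucleotide distributions for
#' the two bases on either side of the core.
#'
#' @param core Named probabilities over the central dinucleotide classes
#'   `GC`, `GG` and `other` (any other NN, drawn uniformly). Must sum to 1.
#' @param flank_probs 4x4 numeric matrix; rows `m2`, `m1`, `p1`, `p2`
#'   (positions -2, -1, +1, +2), columns A/C/G/T; each row sums to 1.
#' @return A `flank_model` list.
#' @export
flank_model <- function(core = c(GC = 0.5, GG = 0.4, other = 0.1),
                        flank_probs = matrix(0.25, 4, 4,
                          dimnames = list(c("m2", "m1", "p1", "p2"),
                                          .IUPAC_BASES))) {
  stopifnot(abs(sum(core) - 1) < 1e-8,
            all(c("GC", "GG", "other") %in% names(core)),
            is.matrix(flank_probs), nrow(flank_probs) == 4,
            ncol(flank_probs) == 4,
            all(abs(rowSums(flank_probs) - 1) < 1e-8))
  rownames(flank_probs) <- c("m2", "m1", "p1", "p2")
  colnames(flank_probs) <- .IUPAC_BASES
  structure(list(core = core, flank_probs = flank_probs),
            class = "flank_model")
}

#' Default flank model for the tolerant-core factor (factor A)
#'
#' G/A preferred at the -1 and -2 positions, unbiased downstream flanks —
#' the preference typical of MyoD-class dimers.
#' @return A `flank_model`.
#' @export
flank_model_A <- function() {
  fp <- matrix(0.25, 4, 4, dimnames = list(c("m2", "m1", "p1", "p2"),
                                           .IUPAC_BASES))
  fp["m2", ] <- c(A = 0.35, C = 0.15, G = 0.35, T = 0.15)
  fp["m1", ] <- c(A = 0.35, C = 0.15, G = 0.35, T = 0.15)
  flank_model(core = c(GC = 0.45, GG = 0.45, other = 0.10),
              flank_probs = fp)
}

#' Default flank model for the C(-1)/G(+1) factor (factor B)
#'
#' Strong preference for C immediately before and G immediately after a GC
#' core, i.e. the CCAGCTGG-style 8-mer typical of MSC-class dimers.
#' @return A `flank_model`.
#' @export
flank_model_B <- function() {
  fp <- matrix(0.25, 4, 4, dimnames = list(c("m2", "m1", "p1", "p2"),
                                           .IUPAC_BASES))
  fp["m1", ] <- c(A = 0.1, C = 0.7, G = 0.1, T = 0.1)
  fp["p1", ] <- c(A = 0.1, C = 0.1, G = 0.7, T = 0.1)
  flank_model(core = c(GC = 0.8, GG = 0.1, other = 0.1),
              flank_probs = fp)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic experiment.  The defaults define
#' the standard study conditions used throughout the package's validation:
#' a 1 Mb two-chromosome genome, 300 planted sites (100 per class) with
#' occupancy 10 and 20 tags per occupancy unit, a negative-binomial
#' background with mean 5 and size 2 per 200 bp window, 200-base fragment
#' extension, and 36 bp tags.
#'
#' @param genome_length Total genome length in bases (split over chroms).
#' @param n_chroms Number of chromosomes.
#' @param gc_content Genome GC fraction, strictly in (0, 1).
#' @param n_sites Named integer vector: planted sites per class
#'   (`A`, `B`, `shared`).
#' @param affinity Occupancy weight given to a bound factor at its sites;
#'   class affinities are (A: `c(a,0)`), (B: `c(0,a)`), (shared: `c(a,a)`).
#' @param tags_per_unit_occupancy Expected site tags per occupancy unit.
#' @param mu_bg,r_bg Negative-binomial background mean and size per window.
#' @param extension Fragment extension length L in bases.
#' @param tag_length Sequenced tag length in bases.
#' @param window Background window width in bases.
#' @param n_genes Genes in the synthetic gene model.
#' @param f_hss Fraction of planted sites given nonzero DNase HSS signal.
#' @param ach4_class_amp Named amplitudes of the acetylation bump by site
#'   class; the default plants a 4-fold shared vs A-specific contrast.
#' @param ach4_tss_boost Multiplier applied to bumps within 2 kb of a TSS.
#' @param ach4_noise_sd Log-normal sd of per-site amplitude noise.
#' @param seed Master seed; all stages derive child seeds from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6, n_chroms = 2, gc_content = 0.41,
                       n_sites = c(A = 100, B = 100, shared = 100),
                       affinity = 10, tags_per_unit_occupancy = 20,
                       mu_bg = 5, r_bg = 2, extension = 200,
                       tag_length = 36, window = 200, n_genes = 40,
                       f_hss = 0.7,
                       ach4_class_amp = c(A = 2, B = 2, shared = 8),
                       ach4_tss_boost = 4, ach4_noise_sd = 0.5,
                       seed = 1) {
  .stopifnot_prob(gc_content, "gc_content")
  stopifnot(genome_length >= 10000 * n_chroms, n_chroms >= 1,
            all(n_sites >= 0), affinity >= 0,
            tags_per_unit_occupancy >= 0, mu_bg > 0, r_bg > 0,
            extension >= tag_length, tag_length > 0, window > 0,
            n_genes >= 0, f_hss >= 0, f_hss <= 1)
  ns <- c(A = 0, B = 0, shared = 0)
  ns[names(n_sites)] <- n_sites
  structure(list(genome_length = genome_length, n_chroms = n_chroms,
                 gc_content = gc_content, n_sites = ns, affinity = affinity,
                 tags_per_unit_occupancy = tags_per_unit_occupancy,
                 mu_bg = mu_bg, r_bg = r_bg, extension = extension,
                 tag_length = tag_length, window = window,
                 n_genes = n_genes, f_hss = f_hss,
                 ach4_class_amp = ach4_class_amp,
                 ach4_tss_boost = ach4_tss_boost,
                 ach4_noise_sd = ach4_noise_sd, seed = seed),
            class = "sim_config")
}

#' Generate a random genome
#'
#' I.i.d. bases at the configured GC content, split into `n_chroms`
#' equal-length chromosomes named `chr1`, `chr2`, ...
#'
#' @param config A [sim_config()].
#' @return Named `DNAStringSet`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  len <- floor(config$genome_length / config$n_chroms)
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(config$n_chroms), function(i) {
    paste(sample(.IUPAC_BASES, len, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_chroms))
  DNAStringSet(seqs)
}

# Draw one E-box 10-mer (-2 -1 CA NN TG +1 +2) from a flank model.
.draw_ebox_10mer <- function(n, model) {
  fp <- model$flank_probs
  draw <- function(row) sample(.IUPAC_BASES, n, replace = TRUE,
                               prob = fp[row, ])
  cls <- sample(names(model$core), n, replace = TRUE, prob = model$core)
  nn <- character(n)
  nn[cls == "GC"] <- "GC"
  nn[cls == "GG"] <- "GG"
  other <- cls == "other"
  if (any(other)) {
    pool <- as.vector(outer(.IUPAC_BASES, .IUPAC_BASES, paste0))
    pool <- setdiff(pool, c("GC", "GG"))
    nn[other] <- sample(pool, sum(other), replace = TRUE)
  }
  paste0(draw("m2"), draw("m1"), "CA", nn, "TG", draw("p1"), draw("p2"))
}

#' Plant factor-binding E-box sites into a genome
#'
#' Chooses site centers at least `2 * extension` apart and at least
#' `extension` from chromosome ends, overwrites the genome with a drawn
#' 10-mer (E-box plus two flanking bases each side) at each center, and
#' records the class and per-factor occupancy of every site.
#' A-specific sites and shared sites draw from `model_A`; B-specific sites
#' draw from `model_B`, so the B-specific class carries the discriminative
#' flanking signal.
#'
#' @param genome `DNAStringSet` from [generate_genome()].
#' @param config A [sim_config()].
#' @param model_A,model_B [flank_model()]s for the two factors.
#' @return List with `sites` (a `GRanges` of the planted 10-mers with mcols
#'   `class`, `affinity_A`, `affinity_B`, `ebox`) and `genome` (the mutated
#'   `DNAStringSet`).
#' @export
plant_sites <- function(genome, config, model_A = flank_model_A(),
                        model_B = flank_model_B()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "sites"))
  L <- config$extension
  n_total <- sum(config$n_sites)
  si <- genome_seqinfo(genome)
  if (n_total == 0) {
    sites <- .empty_granges(stats::setNames(seqlengths(si), seqnames(si)))
    mcols(sites) <- DataFrame(class = character(0),
                              affinity_A = numeric(0),
                              affinity_B = numeric(0),
                              ebox = character(0))
    return(list(sites = sites, genome = genome))
  }
  # Grid of candidate centers with jitter.  The step is kept well above
  # the 2L minimum so that neighbouring sites' fragment pileups stay
  # separate peaks (merging two sites into one peak is a crowding
  # artifact, not a property of the caller).
  step <- max(2 * L + 850, 3000)
  jit <- 300L
  cand <- do.call(rbind, lapply(names(genome), function(ch) {
    len <- width(genome)[match(ch, names(genome))]
    centers <- seq(L + jit + 50, len - L - jit - 50, by = step)
    if (length(centers) == 0) return(NULL)
    data.frame(chrom = ch, center = centers)
  }))
  if (is.null(cand) || nrow(cand) < n_total)
    stop("genome too small to place ", n_total,
         " sites at spacing >= ", 2 * L)
  pick <- cand[sample(nrow(cand), n_total), ]
  pick$center <- pick$center + sample(seq(-jit, jit), n_total,
                                      replace = TRUE)
  cls <- rep(c("A", "B", "shared"), times = config$n_sites)
  cls <- sample(cls)      # interleave classes across the genome
  a <- config$affinity
  aff_A <- ifelse(cls %in% c("A", "shared"), a, 0)
  aff_B <- ifelse(cls %in% c("B", "shared"), a, 0)
  ebox <- character(n_total)
  from_B <- cls == "B"
  ebox[!from_B] <- .draw_ebox_10mer(sum(!from_B), model_A)
  if (any(from_B)) ebox[from_B] <- .draw_ebox_10mer(sum(from_B), model_B)
  gstart <- pick$center - 4L       # 10-mer covering center
  sites <- GRanges(pick$chrom, IRanges(gstart, width = 10L),
                   seqinfo = si,
                   class = cls, affinity_A = aff_A, affinity_B = aff_B,
                   ebox = ebox)
  o <- order(as.integer(match(as.character(seqnames(sites)),
                              seqlevels(sites))), start(sites))
  sites <- sites[o]
  sites$name <- paste0("site_", seq_along(sites), "_", sites$class)
  for (ch in names(genome)) {
    s <- sites[seqnames(sites) == ch]
    if (length(s) == 0) next
    genome[[ch]] <- replaceAt(genome[[ch]], ranges(s),
                              as(s$ebox, "DNAStringSet"))
  }
  list(sites = sites, genome = genome)
}

#' Simulate a stranded tag set for one sample
#'
#' Background: the genome is tiled into `window`-width windows and each
#' window receives a negative-binomial `NB(mu_bg, r_bg)` number of tags
#' placed uniformly within it with random strand.  Sites: each planted site
#' contributes `Poisson(affinity * tags_per_unit_occupancy)` tags whose
#' placement guarantees that the `extension`-length fragment covers the
#' whole site (plus-strand tags start within `[site_end - L, site_start]`;
#' minus-strand tags end within `[site_end, site_start + L]`).  The control
#' sample has zero site occupancy everywhere and so is background only.
#'
#' @param sites Planted site `GRanges` from [plant_sites()].
#' @param genome `DNAStringSet`.
#' @param config A [sim_config()].
#' @param factor One of `"A"`, `"B"`, `"control"`.
#' @return Stranded tag `GRanges` (duplicates possible, as in real data).
#' @export
simulate_tags <- function(sites, genome, config,
                          factor = c("A", "B", "control")) {
  stopifnot(inherits(config, "sim_config"))
  factor <- match.arg(factor)
  set.seed(derive_seed(config$seed, paste0("tags_", factor)))
  si <- genome_seqinfo(genome)
  tl <- config$tag_length
  L <- config$extension
  parts <- list()
  # background
  for (ch in names(genome)) {
    len <- width(genome)[match(ch, names(genome))]
    nwin <- ceiling(len / config$window)
    counts <- rnbinom(nwin, size = config$r_bg, mu = config$mu_bg)
    tot <- sum(counts)
    if (tot == 0) next
    win0 <- rep((seq_len(nwin) - 1L) * config$window, counts)
    wlen <- pmin(config$window, len - win0)
    s <- win0 + floor(runif(tot) * pmax(wlen, 1)) + 1L
    e <- pmin(s + tl - 1L, len)
    s <- pmax(1L, pmin(s, e))
    parts[[length(parts) + 1L]] <-
      GRanges(ch, IRanges(s, e), seqinfo = si,
              strand = sample(c("+", "-"), tot, replace = TRUE))
  }
  # site tags
  aff <- switch(factor, A = sites$affinity_A, B = sites$affinity_B,
                control = rep(0, length(sites)))
  if (length(sites) > 0 && any(aff > 0)) {
    n_site <- rpois(length(sites), aff * config$tags_per_unit_occupancy)
    idx <- rep(seq_along(sites), n_site)
    if (length(idx) > 0) {
      tot <- length(idx)
      ch <- as.character(seqnames(sites))[idx]
      s_start <- start(sites)[idx]
      s_end <- end(sites)[idx]
      len <- seqlengths(si)[ch]
      str <- sample(c("+", "-"), tot, replace = TRUE)
      # fragment [f_start, f_start + L - 1] must cover [s_start, s_end]
      f_plus <- s_end - L + sample.int(L - 9L, tot, replace = TRUE)
      f_minus_end <- s_end + sample.int(L - 9L, tot, replace = TRUE) - 1L
      tag_s <- ifelse(str == "+", f_plus, f_minus_end - tl + 1L)
      tag_e <- tag_s + tl - 1L
      tag_s <- pmax(1L, tag_s)
      tag_e <- pmin(as.integer(len), pmax(tag_e, tag_s))
      parts[[length(parts) + 1L]] <-
        GRanges(ch, IRanges(tag_s, tag_e), strand = str, seqinfo = si)
    }
  }
  if (length(parts) == 0) return(.empty_granges(
    stats::setNames(seqlengths(si), seqnames(si))))
  GenomicRanges::sort(do.call(c, parts), ignore.strand = TRUE)
}

#' Generate a non-overlapping synthetic gene model
#'
#' Genes are placed in uniformly spaced slots along each chromosome, each
#' with 2-5 exons inside its span, random strand, and a TSS at the
#' strand-appropriate end.
#'
#' @param genome `DNAStringSet`.
#' @param config A [sim_config()].
#' @return `GRanges` with mcols `name` and `blocks` (exon `IRangesList`
#'   relative to gene start), suitable for [write_genes()].
#' @export
generate_gene_models <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genes"))
  n <- config$n_genes
  si <- genome_seqinfo(genome)
  if (n == 0) {
    gr <- .empty_granges(stats::setNames(seqlengths(si), seqnames(si)))
    mcols(gr) <- DataFrame(name = character(0),
                           blocks = IRangesList())
    return(gr)
  }
  per_chrom <- diff(floor(seq(0, n, length.out = config$n_chroms + 1)))
  parts <- list()
  gi <- 0L
  for (k in seq_along(names(genome))) {
    ch <- names(genome)[k]
    len <- width(genome)[k]
    ng <- per_chrom[k]
    if (ng == 0) next
    slot <- floor(len / ng)
    if (slot < 6000)
      stop("genome too crowded: ", ng, " genes on ", ch, " (", len, " bp)")
    glen <- sample(3000:min(15000, slot - 2000), ng, replace = TRUE)
    gstart <- (seq_len(ng) - 1L) * slot +
      vapply(slot - glen - 1000, function(m)
        sample.int(max(m, 1), 1L) + 500L, numeric(1))
    for (j in seq_len(ng)) {
      gi <- gi + 1L
      nex <- sample(2:5, 1L)
      # split the span into exon/intron alternation
      cuts <- sort(sample.int(glen[j] - 2L, 2L * nex - 2L)) + 1L
      bounds <- c(1L, cuts, glen[j])
      ex_start <- bounds[seq(1, length(bounds), by = 2)]
      ex_end <- bounds[seq(2, length(bounds), by = 2)]
      parts[[gi]] <- list(chrom = ch, start = gstart[j],
                          end = gstart[j] + glen[j] - 1L,
                          strand = sample(c("+", "-"), 1L),
                          blocks = IRanges(ex_start, ex_end))
    }
  }
  gr <- GRanges(vapply(parts, `[[`, character(1), "chrom"),
                IRanges(vapply(parts, `[[`, numeric(1), "start"),
                        vapply(parts, `[[`, numeric(1), "end")),
                strand = vapply(parts, `[[`, character(1), "strand"),
                seqinfo = si)
  mcols(gr) <- DataFrame(name = paste0("gene_", seq_along(gr)),
                         blocks = IRangesList(lapply(parts, `[[`, "blocks")))
  gr
}

#' Simulate chromatin-context signal tracks
#'
#' AcH4: a smoothed (triangular, half-width 300 bp) bump at every planted
#' site, with amplitude `ach4_class_amp[class] * boost * exp(N(0, sd))`,
#' where the boost applies to sites within 2 kb of a TSS.  HSS: a random
#' fraction `f_hss` of sites receive a constant nonzero score over the site
#' interval widened by 50 bp; the track is zero elsewhere.
#'
#' @param sites Planted site `GRanges`.
#' @param genes Gene model `GRanges` (may be empty; then no TSS boost).
#' @param genome `DNAStringSet`.
#' @param config A [sim_config()].
#' @return List with elements `ach4` and `hss`, both named `RleList`s.
#' @export
simulate_context_tracks <- function(sites, genes, genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "context"))
  si <- genome_seqinfo(genome)
  seqlens <- stats::setNames(seqlengths(si), seqnames(si))
  zero <- lapply(seqlens, function(l) Rle(0, l))
  ach4 <- zero
  hss <- zero
  if (length(sites) > 0) {
    centers <- (start(sites) + end(sites)) %/% 2
    tssd <- rep(Inf, length(sites))
    if (length(genes) > 0) {
      tss <- gene_tss(genes)
      for (ch in names(seqlens)) {
        on <- which(as.character(seqnames(sites)) == ch)
        tp <- start(tss)[as.character(seqnames(tss)) == ch]
        if (length(on) == 0 || length(tp) == 0) next
        tssd[on] <- vapply(centers[on],
                           function(p) min(abs(p - tp)), numeric(1))
      }
    }
    amp <- config$ach4_class_amp[sites$class] *
      ifelse(tssd < 2000, config$ach4_tss_boost, 1) *
      exp(rnorm(length(sites), 0, config$ach4_noise_sd))
    hw <- 300L
    kernel <- 1 - abs(seq(-hw, hw)) / (hw + 1)     # triangular bump
    for (ch in names(seqlens)) {
      on <- which(as.character(seqnames(sites)) == ch)
      if (length(on) == 0) next
      v <- numeric(seqlens[[ch]])
      for (i in on) {
        pos <- centers[i] + seq(-hw, hw)
        ok <- pos >= 1 & pos <= length(v)
        v[pos[ok]] <- v[pos[ok]] + amp[i] * kernel[ok]
      }
      ach4[[ch]] <- Rle(round(v, 6))
    }
    on_hss <- runif(length(sites)) < config$f_hss
    score <- round(runif(length(sites), 0.5, 5), 3)
    if (any(on_hss)) {
      wide <- suppressWarnings(trim(resize(sites, width(sites) + 100L,
                                           fix = "center")))
      for (ch in names(seqlens)) {
        on <- which(as.character(seqnames(sites)) == ch & on_hss)
        if (length(on) == 0) next
        v <- numeric(seqlens[[ch]])
        for (i in on) v[start(wide)[i]:end(wide)[i]] <- score[i]
        hss[[ch]] <- Rle(v)
      }
    }
  }
  list(ach4 = as(ach4, "RleList"), hss = as(hss, "RleList"))
}

#' Run the whole generator
#'
#' Convenience wrapper producing every synthetic input the pipeline needs.
#'
#' @param config A [sim_config()].
#' @param model_A,model_B Flank models for the two factors.
#' @return List: `config`, `genome`, `sites`, `genes`, `tags` (list with
#'   `A`, `B`, `control`), `ach4`, `hss`.
#' @export
simulate_experiment <- function(config = sim_config(),
                                model_A = flank_model_A(),
                                model_B = flank_model_B()) {
  genome0 <- generate_genome(config)
  planted <- plant_sites(genome0, config, model_A, model_B)
  genes <- generate_gene_models(planted$genome, config)
  tags <- list(A = simulate_tags(planted$sites, planted$genome, config, "A"),
               B = simulate_tags(planted$sites, planted$genome, config, "B"),
               control = simulate_tags(planted$sites, planted$genome,
                                       config, "control"))
  tracks <- simulate_context_tracks(planted$sites, genes,
                                    planted$genome, config)
  list(config = config, genome = planted$genome, sites = planted$sites,
       genes = genes, tags = tags, ach4 = tracks$ach4, hss = tracks$hss)
}
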