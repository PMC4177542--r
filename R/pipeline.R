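# End-to-end orchestration: simulate (or load) inputs, call peaks for the
# two factors and the control, subtract control peaks, compare and
# classify, run discriminative motif discovery, associate with chromatin
# context, annotate genomic locations, and write a deterministic report.

#' Pipeline configuration
#'
#' Exactly one of `simulate` (a [sim_config()]) or `paths` (a named list
#' of input files: `genome`, `tags_a`, `tags_b`, `control`, and
#' optionally `genes`, `ach4`, `hss`, `sites`) must be given.
#'
#' @param simulate A [sim_config()] describing a synthetic experiment.
#' @param paths Named list of input file paths (see above).
#' @param window,extension Peak-caller window and tag extension (bases).
#' @param call_cutoff Window P cutoff for the working peak lists; kept no
#'   tighter than `absent_cutoff` so "absent" is decidable.
#' @param report_cutoffs Cutoffs for the peak-count table.
#' @param control_cutoff Control-peak P cutoff for subtraction.
#' @param present_cutoff,absent_cutoff Dual classification cutoffs.
#' @param bin,max_rank Overlap-matrix rank binning.
#' @param k_min,k_max,max_motifs Motif search parameters.
#' @param motif_flank Bases either side of summits for motif sequences.
#' @param tss_breaks TSS-distance strata breaks (bases).
#' @param annotation [annotation_params()].
#' @param exclude_chroms Chromosomes dropped when reading tag files.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(), paths = NULL,
                            window = 200, extension = 200,
                            call_cutoff = 1e-4,
                            report_cutoffs = c(1e-5, 1e-7, 1e-10),
                            control_cutoff = 1e-5,
                            present_cutoff = 1e-10, absent_cutoff = 1e-4,
                            bin = 3000, max_rank = 30000,
                            k_min = 6, k_max = 10, max_motifs = 3,
                            motif_flank = 100,
                            tss_breaks = c(2e3, 1e4, 1e5),
                            annotation = annotation_params(),
                            exclude_chroms = character(0)) {
  if (is.null(simulate) == is.null(paths))
    stop("give exactly one of 'simulate' or 'paths'")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stop("'simulate' must be a sim_config")
  if (!is.null(paths)) {
    need <- c("genome", "tags_a", "tags_b", "control")
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0)
      stop("paths block is missing: ", paste(miss, collapse = ", "))
    missing_files <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing_files) > 0)
      stop("input file not found: ", missing_files[1])
  }
  .stopifnot_prob(call_cutoff, "call_cutoff")
  if (call_cutoff < absent_cutoff)
    stop("call_cutoff must be no tighter than absent_cutoff")
  structure(list(simulate = simulate, paths = paths, window = window,
                 extension = extension, call_cutoff = call_cutoff,
                 report_cutoffs = report_cutoffs,
                 control_cutoff = control_cutoff,
                 present_cutoff = present_cutoff,
                 absent_cutoff = absent_cutoff, bin = bin,
                 max_rank = max_rank, k_min = k_min, k_max = k_max,
                 max_motifs = max_motifs, motif_flank = motif_flank,
                 tss_breaks = tss_breaks, annotation = annotation,
                 exclude_chroms = exclude_chroms),
            class = "pipeline_config")
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.matrix_tsv <- function(m, path) {
  df <- data.frame(x = rownames(m), m, check.names = FALSE)
  .write_tsv(df, path)
}

#' Run the full comparative ChIP-seq pipeline
#'
#' Executes every stage on the configured inputs and writes all
#' intermediate and summary files into `out_dir`.  The run is a pure
#' function of the configuration: rerunning with the same config produces
#' byte-identical outputs, and a checksum manifest is written to make
#' that checkable.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage log messages.
#' @return (Invisibly) a list with the in-memory results of every stage
#'   and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  fp <- function(...) file.path(out_dir, ...)

  # ---- inputs -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    say("simulating synthetic experiment (seed ", config$simulate$seed, ")")
    sim <- stage("simulate", simulate_experiment(config$simulate))
    genome <- sim$genome; genes <- sim$genes
    tags <- sim$tags; ach4 <- sim$ach4; hss <- sim$hss
    sites <- sim$sites
    stage("write inputs", {
      write_genome(genome, fp("genome.fa"))
      write_tags(tags$A, fp("tags_A.bed"))
      write_tags(tags$B, fp("tags_B.bed"))
      write_tags(tags$control, fp("tags_control.bed"))
      if (length(genes) > 0) write_genes(genes, fp("genes.bed12"))
      write_signal(ach4, fp("ach4.bedGraph"))
      write_signal(hss, fp("hss.bedGraph"))
      truth <- data.frame(chrom = as.character(seqnames(sites)),
                          start = start(sites) - 1L, end = end(sites),
                          name = sites$name, score = 0,
                          strand = "+")
      write.table(truth, fp("sites_truth.bed"), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    })
  } else {
    p <- config$paths
    say("reading inputs")
    genome <- stage("read genome", read_genome(p$genome))
    tags <- stage("read tags", list(
      A = read_tags(p$tags_a, config$exclude_chroms, genome),
      B = read_tags(p$tags_b, config$exclude_chroms, genome),
      control = read_tags(p$control, config$exclude_chroms, genome)))
    genes <- if (!is.null(p$genes))
      stage("read genes", read_genes(p$genes, genome)) else GRanges()
    ach4 <- if (!is.null(p$ach4))
      stage("read ach4", read_signal(p$ach4, genome)) else NULL
    hss <- if (!is.null(p$hss))
      stage("read hss", read_signal(p$hss, genome)) else NULL
    sites <- NULL
  }

  # ---- peak calling -----------------------------------------------------
  say("calling peaks (window ", config$window, ", extension ",
      config$extension, ")")
  pk <- stage("call peaks", lapply(tags, call_peaks, genome = genome,
                                   p_cutoff = config$call_cutoff,
                                   window = config$window,
                                   extension = config$extension))
  say("control subtraction at P <= ", config$control_cutoff)
  peaks_A <- subtract_control(pk$A, pk$control, config$control_cutoff)
  peaks_B <- subtract_control(pk$B, pk$control, config$control_cutoff)
  write_peaks(peaks_A, fp("peaks_A.bed"))
  write_peaks(peaks_B, fp("peaks_B.bed"))
  write_peaks(pk$control, fp("peaks_control.bed"))
  counts <- rbind(A = count_peaks_at_cutoffs(peaks_A,
                                             config$report_cutoffs),
                  B = count_peaks_at_cutoffs(peaks_B,
                                             config$report_cutoffs))
  .write_tsv(data.frame(factor = rownames(counts), counts,
                        check.names = FALSE), fp("peak_counts.tsv"))

  # ---- comparison & classification -------------------------------------
  say("overlap matrix (bin ", config$bin, ")")
  m_ab <- overlap_fraction_matrix(peaks_A, peaks_B, config$bin,
                                  config$max_rank)
  m_ba <- overlap_fraction_matrix(peaks_B, peaks_A, config$bin,
                                  config$max_rank)
  .matrix_tsv(m_ab, fp("overlap_A_in_B.tsv"))
  .matrix_tsv(m_ba, fp("overlap_B_in_A.tsv"))
  say("classifying peaks (present ", config$present_cutoff, ", absent ",
      config$absent_cutoff, ")")
  cls <- classify_peaks(peaks_A, peaks_B, config$present_cutoff,
                        config$absent_cutoff)
  labelled <- c(cls$A[cls$A$label == "A_specific"],
                cls$B[cls$B$label == "B_specific"],
                cls$A[cls$A$label == "shared"])
  cls_bed <- data.frame(chrom = as.character(seqnames(labelled)),
                        start = start(labelled) - 1L, end = end(labelled),
                        name = paste0(labelled$label, ":", labelled$name),
                        score = sprintf("%.4f", -log10(labelled$p_value)),
                        strand = ".")
  write.table(cls_bed[order(cls_bed$chrom, cls_bed$start), ],
              fp("classes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  recovery <- if (!is.null(sites) && length(sites) > 0)
    truth_table_recovery(cls, sites) else NULL

  # ---- motif analysis ---------------------------------------------------
  fg_peaks <- cls$B[cls$B$label == "B_specific"]
  bg_peaks <- c(cls$A[cls$A$label %in% c("shared", "A_specific")])
  motifs <- NULL
  profile_fg <- NULL
  if (length(fg_peaks) >= 10 && length(bg_peaks) >= 10) {
    say("discriminative motif search (", length(fg_peaks), " fg vs ",
        length(bg_peaks), " bg peaks)")
    fg_seqs <- extract_peak_sequences(fg_peaks, genome, config$motif_flank)
    bg_seqs <- extract_peak_sequences(bg_peaks, genome, config$motif_flank)
    motifs <- stage("motif search",
                    discriminative_motif_search(fg_seqs, bg_seqs,
                                                config$k_min, config$k_max,
                                                config$max_motifs))
    .write_tsv(motifs, fp("motifs.tsv"))
    profile_fg <- build_position_profile(fg_peaks, genome)
    .write_tsv(data.frame(base = rownames(profile_fg), profile_fg,
                          check.names = FALSE),
               fp("ebox_profile_B_specific.tsv"))
  } else say("skipping motif search: too few classified peaks")

  # ---- chromatin context ------------------------------------------------
  context <- NULL
  if (!is.null(ach4) && !is.null(hss) && length(genes) > 0 &&
      length(labelled) > 0) {
    say("chromatin-context association")
    rec <- context_records(labelled, ach4, hss, gene_tss(genes))
    rec$tss_bin <- as.character(stratify_by_tss(rec$tss_distance,
                                                config$tss_breaks))
    .write_tsv(rec, fp("context_records.tsv"))
    pairs <- list(c("shared", "A_specific"), c("shared", "B_specific"),
                  c("A_specific", "B_specific"))
    comp <- do.call(rbind, lapply(pairs, function(pr) {
      x <- rec$ach4_value[rec$label == pr[1]]
      y <- rec$ach4_value[rec$label == pr[2]]
      if (length(x) < 2 || length(y) < 2) return(NULL)
      cc <- compare_classes(x, y)
      data.frame(class_x = pr[1], class_y = pr[2],
                 n_x = cc$n[1], n_y = cc$n[2],
                 U = cc$statistic, p_value = cc$p_value,
                 median_sqrt_x = cc$median_x, median_sqrt_y = cc$median_y)
    }))
    hss_frac <- vapply(split(rec$hss_score, rec$label),
                       function(v) mean(v > 0), numeric(1))
    context <- list(records = rec, comparisons = comp,
                    hss_fraction = hss_frac)
    if (!is.null(comp)) .write_tsv(comp, fp("context_comparisons.tsv"))
    .write_tsv(data.frame(label = names(hss_frac),
                          hss_overlap_fraction = hss_frac),
               fp("context_hss_fractions.tsv"))
  }

  # ---- annotation -------------------------------------------------------
  annot <- NULL
  if (length(genes) >= 0 && length(peaks_A) > 0 && length(peaks_B) > 0) {
    say("genomic-location annotation")
    fa <- location_fractions(peaks_A, genes, config$annotation)
    fb <- location_fractions(peaks_B, genes, config$annotation)
    annot <- rbind(A = fa$fractions, B = fb$fractions)
    .write_tsv(data.frame(factor = rownames(annot), round(annot, 4),
                          check.names = FALSE),
               fp("annotation_fractions.tsv"),
               comment = paste0("distances: promoter=",
                                config$annotation$promoter, " proximal=",
                                config$annotation$proximal, " three_prime=",
                                config$annotation$three_prime, " updown=",
                                config$annotation$updown))
  }

  # ---- report & manifest ------------------------------------------------
  rep_lines <- c(
    "comparative ChIP-seq pipeline report",
    "",
    paste0("peaks A (post-control): ", length(peaks_A),
           "; peaks B: ", length(peaks_B),
           "; control peaks at ", config$control_cutoff, ": ",
           sum(pk$control$p_value <= config$control_cutoff)),
    paste0("peak counts per cutoff [A]: ",
           paste(colnames(counts), counts["A", ], sep = "=",
                 collapse = ", ")),
    paste0("peak counts per cutoff [B]: ",
           paste(colnames(counts), counts["B", ], sep = "=",
                 collapse = ", ")),
    paste0("class counts: ",
           paste(names(cls$counts), cls$counts, sep = "=",
                 collapse = ", ")),
    if (!is.null(motifs) && nrow(motifs) > 0)
      paste0("top motif: ", motifs$consensus[1],
             " (fg.frac ", sprintf("%.3f", motifs$fg_frac[1]),
             ", bg.frac ", sprintf("%.3f", motifs$bg_frac[1]),
             ", ratio ", sprintf("%.2f", motifs$ratio[1]), ")"),
    if (!is.null(context) && !is.null(context$comparisons))
      paste0("AcH4 ", context$comparisons$class_x, " vs ",
             context$comparisons$class_y, ": P = ",
             sprintf("%.3g", context$comparisons$p_value)),
    if (!is.null(context))
      paste0("HSS overlap fractions: ",
             paste(names(context$hss_fraction),
                   sprintf("%.3f", context$hss_fraction),
                   sep = "=", collapse = ", ")),
    if (!is.null(recovery))
      paste0("truth recovery recall: ",
             paste(names(recovery$recall),
                   sprintf("%.3f", recovery$recall),
                   sep = "=", collapse = ", ")))
  writeLines(rep_lines, fp("report.txt"))
  cfg_echo <- config
  cfg_echo$simulate <- if (!is.null(config$simulate))
    unclass(config$simulate)
  yaml::write_yaml(lapply(unclass(cfg_echo), function(x)
    if (is.null(x)) NULL else x), fp("config.yaml"))
  outs <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(file = outs,
                         md5 = unname(tools::md5sum(fp(outs))))
  .write_tsv(manifest, fp("manifest.tsv"))
  say("done; outputs in ", out_dir)
  invisible(list(out_dir = out_dir, genome = genome, genes = genes,
                 sites = sites, peaks = list(A = peaks_A, B = peaks_B,
                                             control = pk$control),
                 counts = counts, overlap = list(AB = m_ab, BA = m_ba),
                 classes = cls, recovery = recovery, motifs = motifs,
                 profile = profile_fg, context = context,
                 annotation = annot))
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate` mapping is passed to [sim_config()], a `paths` mapping is
#' used verbatim.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in setdiff(names(y), c("simulate", "paths", "annotation")))
    if (is.list(y[[k]])) y[[k]] <- unlist(y[[k]])
  if (!is.null(y$simulate)) {
    ns <- y$simulate$n_sites
    if (!is.null(ns)) y$simulate$n_sites <- unlist(ns)
    amp <- y$simulate$ach4_class_amp
    if (!is.null(amp)) y$simulate$ach4_class_amp <- unlist(amp)
    y$simulate <- do.call(sim_config, y$simulate)
  }
  if (!is.null(y$annotation))
    y$annotation <- do.call(annotation_params, y$annotation)
  do.call(pipeline_config, y)
}
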