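# End-to-end orchestration: simulate -> map -> catalog -> noise metrics ->
# motifs, with per-stage seeds derived from one master seed, plus fixture
# presets and truth-level shortcuts used by the statistical property
# analyses.

#' Junction table directly from an isoform pool (no sequencing)
#'
#' Builds the junction read-count table a perfect mapper would produce:
#' every splice junction of every isoform receives a Poisson read count
#' with mean `reads_per_copy` per transcript copy. Used by analyses that
#' need many replicates of the junction-level statistics without paying for
#' read simulation and mapping each time; the full read path is exercised
#' by [discover_junctions()].
#'
#' @param genome named character vector (for dinucleotide classes).
#' @param truth a `truth_set`.
#' @param pool an `isoform_pool`.
#' @param reads_per_copy expected junction-spanning reads per transcript
#'   copy and junction.
#' @param seed integer seed.
#' @return aggregated-junction-style table (`chrom`, `start`, `end`,
#'   `strand`, `reads`, `dinuc_class`, ...).
#' @export
junctions_from_truth <- function(genome, truth, pool, reads_per_copy = 1,
                                 seed = 1L) {
  set.seed(seed)
  iso <- pool$isoforms
  gene_copies <- iso[, .(copies = sum(count)), by = gene]
  ev <- pool$events
  if (nrow(ev) > 0L) {
    ev2 <- merge(ev, iso[, .(iso_id, count)], by = "iso_id")
  } else {
    ev2 <- data.table::data.table(iso_id = character(0), gene = character(0),
                                  intron_id = character(0),
                                  type = character(0), jt_start = integer(0),
                                  jt_end = integer(0), count = integer(0))
  }
  # true junction copies: gene copies minus copies with an event on the
  # intron
  ev_per_intron <- ev2[, .(err_copies = sum(count)), by = intron_id]
  tj <- data.table::copy(truth$introns)
  tj[gene_copies, copies := i.copies, on = "gene"]
  tj[is.na(copies), copies := 0L]
  tj[ev_per_intron, copies := copies - i.err_copies, on = "intron_id"]
  true_tab <- tj[copies > 0L, .(chrom, strand, start, end, copies,
                                is_true = TRUE)]
  # error junction copies (retention events yield no junction)
  err <- ev2[type != "retention"]
  if (nrow(err) > 0L) {
    coord <- local_interval_to_genomic(truth, err$gene, err$jt_start,
                                       err$jt_end)
    gm <- truth$genes[match(err$gene, truth$genes$gene)]
    err_tab <- data.table::data.table(
      chrom = gm$chrom, strand = gm$strand,
      start = coord$start, end = coord$end,
      copies = err$count)[, .(copies = sum(copies), is_true = FALSE),
                          by = .(chrom, strand, start, end)]
    tab <- data.table::rbindlist(list(true_tab, err_tab), use.names = TRUE)
  } else {
    tab <- true_tab
  }
  tab[, reads := stats::rpois(.N, copies * reads_per_copy)]
  tab <- tab[reads > 0L]
  tab[, dinuc_class := junction_dinuc_class(genome, chrom, start, end,
                                            strand)]
  tab[, `:=`(n_placements = 1L, n_ambiguous = 0L, mean_mm = 0)]
  data.table::setorder(tab, chrom, start, end)
  tab[]
}

#' Dinucleotide class of intron intervals
#'
#' Classifies each interval over its genomic shift-equivalence run
#' (repeated boundary sequence), on both strand readings, with the mapper's
#' precedence: GT-AG, then GC-AG, then the control pairs, then other.
#'
#' @param genome named character vector.
#' @param chrom,start,end junction coordinates (0-based half-open).
#' @param strand optional; unused for classification (both readings are
#'   always checked) but kept for interface symmetry.
#' @param max_shift cap on boundary shifts examined.
#' @return character vector: `"GT-AG"`, `"GC-AG"`, `"control"`, `"other"`.
#' @export
junction_dinuc_class <- function(genome, chrom, start, end, strand = NULL,
                                 max_shift = 10L) {
  n <- length(start)
  code <- rep(3L, n)
  # reverse complement of a 2-character string, vectorized, no XString
  # machinery needed at this scale
  rc2 <- function(x) {
    y <- chartr("ACGT", "TGCA", x)
    paste0(substr(y, 2L, 2L), substr(y, 1L, 1L))
  }
  pair_code <- function(d5, d3) {
    fwd <- data.table::fifelse(
      d5 == "GT" & d3 == "AG", 0L,
      data.table::fifelse(d5 == "GC" & d3 == "AG", 1L,
                          data.table::fifelse((d5 == "GT" | d5 == "GC") &
                                                d3 == "TC", 2L, 3L)))
    r5 <- rc2(d3); r3 <- rc2(d5)
    rev <- data.table::fifelse(
      r5 == "GT" & r3 == "AG", 0L,
      data.table::fifelse(r5 == "GC" & r3 == "AG", 1L,
                          data.table::fifelse((r5 == "GT" | r5 == "GC") &
                                                r3 == "TC", 2L, 3L)))
    out <- pmin(fwd, rev)
    out[is.na(out)] <- 3L
    out
  }
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    g <- genome[[ch]]
    L <- nchar(g)
    a <- start[sel]; e <- end[sel]
    char_at <- function(p) {
      x <- rep(NA_character_, length(p))
      ok <- p >= 0L & p < L
      x[ok] <- substring(g, p[ok] + 1L, p[ok] + 1L)
      x
    }
    # maximal equal-base runs at the boundaries (shift-equivalence)
    m <- length(sel)
    v <- rep(0L, m); run <- rep(TRUE, m)
    for (t in 0:(max_shift - 1L)) {
      eq <- char_at(a + t) == char_at(e + t)
      eq[is.na(eq)] <- FALSE
      run <- run & eq
      v <- v + as.integer(run)
    }
    u <- rep(0L, m); run <- rep(TRUE, m)
    for (t in 1:max_shift) {
      eq <- char_at(a - t) == char_at(e - t)
      eq[is.na(eq)] <- FALSE
      run <- run & eq
      u <- u + as.integer(run)
    }
    best <- rep(99L, m)
    for (s in (-max_shift):max_shift) {
      allowed <- s >= -u & s <= v
      if (!any(allowed)) next
      d5 <- paste0(char_at(a + s), char_at(a + s + 1L))
      d3 <- paste0(char_at(e + s - 2L), char_at(e + s - 1L))
      cls <- pair_code(d5, d3)
      best[allowed] <- pmin(best[allowed], cls[allowed])
    }
    code[sel] <- best
  }
  class_label(pmin(code, 3L))
}

#' Inject random artifact junctions into a junction table
#'
#' Artifacts are uniform random intron intervals (length within the
#' mapper's bounds) with small read counts; their dinucleotide classes are
#' whatever the genome happens to contain, so a known fraction of them
#' lands in the canonical and control classes, which is what the
#' control-dinucleotide FDR estimator is calibrated against.
#'
#' @param junctions junction table to extend.
#' @param genome named character vector.
#' @param n number of artifacts.
#' @param seed integer seed.
#' @return list with `junctions` (extended table) and `artifacts` (the
#'   injected rows, with an `artifact` flag also present in the table).
#' @export
inject_artifact_junctions <- function(junctions, genome, n, seed = 1L) {
  set.seed(seed)
  chroms <- names(genome)
  clens <- nchar(unlist(genome, use.names = FALSE))
  ch <- sample.int(length(chroms), n, replace = TRUE,
                   prob = clens / sum(clens))
  len <- sample(51:2000, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(clens[ch[i]] - len[i] - 1L, 1L), integer(1))
  art <- data.table::data.table(
    chrom = chroms[ch], start = as.double(start),
    end = as.double(start + len), strand = "+",
    reads = 1L + stats::rpois(n, 1), n_placements = 1L, n_ambiguous = 0L,
    mean_mm = 0)
  art[, dinuc_class := junction_dinuc_class(genome, chrom, start, end)]
  art[, artifact := TRUE]
  j <- data.table::copy(data.table::as.data.table(junctions))
  j[, artifact := FALSE]
  list(junctions = data.table::rbindlist(list(j, art), use.names = TRUE,
                                         fill = TRUE),
       artifacts = art)
}

#' Fixture presets for tests and demonstrations
#'
#' Presets: `tiny` (a handful of genes, small enough for brute-force mapper
#' oracles), `default` (the standard study conditions), `null` (error rate
#' 0, no NMD), `frame-biased` (elevated error rate, frame-disrupting
#' isoforms thinned), `confounded-expression` (error rate increasing with
#' intron length, expression anti-correlated with length).
#'
#' @param preset preset name.
#' @param seed master seed.
#' @return list with `config` (a [sim_config()]), `n_transcripts` and
#'   `preset`.
#' @export
make_fixture <- function(preset = c("tiny", "default",
                                    "confounded-expression", "frame-biased",
                                    "null"),
                         seed = 1L) {
  preset <- match.arg(preset)
  out <- switch(preset,
    tiny = list(
      config = sim_config(n_genes = 6L, n_chroms = 1L, mean_exons = 3.5,
                          intron_meanlog = log(150), intron_sdlog = 0.4,
                          depth = 8, per_intron_error_rate = 0.02,
                          sequencing_error_rate = 0, seed = seed),
      n_transcripts = 2000L),
    default = list(
      config = sim_config(n_genes = 20L, seed = seed),
      n_transcripts = 20000L),
    null = list(
      config = sim_config(n_genes = 20L, per_intron_error_rate = 0,
                          frame_bias = 1, seed = seed),
      n_transcripts = 20000L),
    `frame-biased` = list(
      config = sim_config(n_genes = 30L, per_intron_error_rate = 0.02,
                          frame_bias = 0.5, depth = 50, seed = seed),
      n_transcripts = 50000L),
    `confounded-expression` = list(
      config = sim_config(
        n_genes = 150L, n_chroms = 2L,
        per_intron_error_rate = function(len)
          pmin(0.25, pmax(0.001, -0.028 + 0.016 * log10(len))),
        expression_length_coupling = 1.5,
        intron_sdlog = 1.1, depth = 50, seed = seed),
      n_transcripts = 300000L))
  out$preset <- preset
  out
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in dependency order — simulate (genome, conservation
#' track, variants, transcript pool, reads), map (junction discovery),
#' catalog (dinucleotide classes, FDR, five-way annotation classes, site
#' usage), noise metrics (conservation labels, per-intron error rates,
#' frame periodicity, per-gene mis-splicing) and optionally motifs — and
#' returns a run report holding every headline statistic together with the
#' configuration echo and seed. With `out_dir` set, the external
#' representations (FASTA, GTF, BED12, bedGraph, FASTQ, TSV) are written.
#'
#' @param config a [sim_config()].
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param n_transcripts transcript copies to simulate.
#' @param n_reads reads to simulate (default derived from `config$depth`).
#' @param junction_spanning_only restrict simulated reads to
#'   junction-spanning windows.
#' @param run_motifs run the motif-enrichment stage.
#' @param t_hi,unconserved_max conservation label thresholds.
#' @param trend_bins bins used for the length-trend summary (needs at least
#'   that many reference introns).
#' @param usage_min_coverage coverage threshold of the site-usage summary.
#' @param verbose emit one structured log line per stage with input/output
#'   counts.
#' @param out_dir optional output directory.
#' @return a `splice_report` list.
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         n_transcripts = 20000L, n_reads = NULL,
                         junction_spanning_only = FALSE,
                         run_motifs = FALSE, t_hi = 1.5,
                         unconserved_max = 0.5, trend_bins = 20L,
                         usage_min_coverage = 50L, out_dir = NULL,
                         verbose = FALSE) {
  log_stage <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  sim <- generate_genome(config, derive_seed(seed, "genome"))
  genome <- sim$genome
  truth <- sim$truth
  log_stage("simulate", "genome %d bp, %d genes, %d introns",
            sum(nchar(genome)), nrow(truth$genes), nrow(truth$introns))
  track <- generate_conservation_track(genome, truth, config,
                                       derive_seed(seed, "conservation"))
  variants <- generate_variants(genome, truth, config,
                                derive_seed(seed, "variants"))
  pool <- simulate_transcripts(genome, truth, config,
                               derive_seed(seed, "transcripts"),
                               n_transcripts = n_transcripts)
  log_stage("simulate", "%d isoforms (%d error) from %d transcript copies",
            nrow(pool$isoforms), sum(pool$isoforms$is_error), n_transcripts)
  reads <- simulate_reads(truth, pool, config, derive_seed(seed, "reads"),
                          n_reads = n_reads,
                          junction_spanning_only = junction_spanning_only)
  log_stage("simulate", "%d reads of %d bp", nrow(reads),
            config$read_length)

  index <- build_index(genome, k = 20L)
  disc <- discover_junctions(reads, index)
  junc <- disc$junctions
  log_stage("map", "%s",
            paste(names(disc$status), as.integer(disc$status),
                  sep = "=", collapse = ", "))

  fc <- filter_canonical(junc)
  fdr <- if (fc$n_canonical > 0) estimate_fdr(fc$n_canonical, fc$n_control)
         else NA_real_
  log_stage("catalog", "%d junctions: %d canonical, %d control, %d other",
            nrow(junc), fc$n_canonical, fc$n_control, fc$n_other)
  annotation <- annotation_from_truth(truth)
  classified <- classify_junctions(fc$canonical, annotation)
  usage <- splice_site_usage(fc$canonical,
                             min_coverage = usage_min_coverage,
                             annotation = annotation)

  site_tab <- junction_site_table(fc$canonical)
  labels <- label_conservation(site_tab, track, t_hi = t_hi,
                               unconserved_max = unconserved_max)
  err <- intron_error_rate(fc$canonical, labels)
  period <- periodicity_profile(fc$canonical, annotation, genome,
                                side = "3")
  n_ref <- if (is.null(nrow(err$introns))) 0L else nrow(err$introns)
  log_stage("noise", "%d reference introns, global error rate %.5f",
            n_ref, err$global_rate)
  trend <- if (n_ref >= trend_bins)
    bin_and_trend(err$introns, "length", n_bins = trend_bins) else NULL
  mean_introns <- mean(truth$genes$n_exons - 1L)
  missplice <- if (!is.na(err$global_rate))
    per_gene_missplice(err$global_rate, 3L) else NA_real_

  motifs <- NULL
  if (run_motifs) {
    motifs <- tryCatch({
      nd <- select_noise_and_decoy(fc$canonical, labels, annotation, genome)
      res <- lapply(c(donor = "donor", acceptor = "acceptor"), function(ty) {
        sub <- nd[type == ty]
        if (nrow(sub) == 0L) return(NULL)
        fl_n <- extract_flanks(sub, genome)
        dec <- data.table::copy(sub)[, boundary := decoy_boundary]
        fl_d <- extract_flanks(dec, genome)
        list(exonic = enrichment_test(hexamer_counts(fl_n$exonic),
                                      hexamer_counts(fl_d$exonic)),
             intronic = enrichment_test(hexamer_counts(fl_n$intronic),
                                        hexamer_counts(fl_d$intronic)))
      })
      res$n_noise_sites <- nrow(nd)
      res
    }, error = function(e) list(error = conditionMessage(e)))
  }

  report <- list(
    seed = seed,
    config = config,
    thresholds = list(t_hi = t_hi, unconserved_max = unconserved_max,
                      min_coverage_usage = usage_min_coverage,
                      min_reads_periodicity = 20L,
                      near_bp = 50L, intron_bounds = c(51L, 20000L),
                      end_length = 20L, min_overhang = 10L),
    n_reads = nrow(reads),
    read_status = disc$status,
    n_junctions = nrow(junc),
    n_canonical = fc$n_canonical,
    n_control = fc$n_control,
    n_other = fc$n_other,
    fdr = fdr,
    class_counts = if (nrow(classified) > 0L)
      table(classified$annotation_class) else NULL,
    classification_summary = attr(classified, "summary"),
    mean_partners = usage$mean_partners,
    mean_major_fraction = usage$mean_major_fraction,
    global_error_rate = err$global_rate,
    global_error_rate_unweighted = err$global_rate_unweighted,
    n_reference_introns = n_ref,
    in_frame_fraction = period$in_frame_fraction,
    in_frame_p = period$p_value,
    length_trend_spearman = if (!is.null(trend)) trend$spearman else NA_real_,
    per_gene_missplice = missplice,
    mean_splicing_reactions = mean_introns,
    motifs = motifs)
  class(report) <- "splice_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
    write_gene_models_gtf(truth, file.path(out_dir, "genes.gtf"))
    write_gene_models_bed12(truth, file.path(out_dir, "genes.bed12"))
    write_conservation_bedgraph(track, file.path(out_dir,
                                                 "conservation.bedGraph"))
    write_reads_fastq(reads, file.path(out_dir, "reads.fastq"))
    write_junctions_tsv(junc, file.path(out_dir, "junctions.tsv"))
    write_junctions_bed12(junc, file.path(out_dir, "junctions.bed12"))
    utils::write.table(truth$introns[, .(intron_id, gene, chrom, strand,
                                         start, end, length, epsilon)],
                       file.path(out_dir, "truth_introns.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(variants, file.path(out_dir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.splice_report <- function(x, ...) {
  cat("splice pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  reads: %d; junctions: %d (canonical %d, control %d, other %d)\n",
              x$n_reads, x$n_junctions, x$n_canonical, x$n_control,
              x$n_other))
  cat(sprintf("  control-dinucleotide FDR: %.4f\n", x$fdr))
  if (!is.null(x$class_counts)) {
    cat("  annotation classes: ",
        paste(names(x$class_counts), as.integer(x$class_counts),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  mean partners: %.2f; mean major fraction: %.4f\n",
              x$mean_partners %||% NA_real_,
              x$mean_major_fraction %||% NA_real_))
  cat(sprintf("  global error rate: %.5f (unweighted %.5f) over %d introns\n",
              x$global_error_rate, x$global_error_rate_unweighted,
              x$n_reference_introns))
  cat(sprintf("  in-frame minor-site fraction: %.3f (p = %.3g)\n",
              x$in_frame_fraction, x$in_frame_p))
  cat(sprintf("  per-gene mis-splicing (3 reactions): %.4f\n",
              x$per_gene_missplice))
  invisible(x)
}
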