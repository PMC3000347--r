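#' File input/output for the pipeline's external formats
#'
#' Genome sequences travel as FASTA and reads as FASTQ (via Biostrings);
#' gene models as GTF and BED12, and conservation tracks as bedGraph (via
#' rtracklayer); junction tables, truth tables and hexamer lists as plain
#' TSV/text.
#'
#' @param genome named character vector of chromosome sequences.
#' @param path file path.
#' @name splice-io
NULL

#' @rdname splice-io
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname splice-io
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname splice-io
#' @param reads a `read_set` from [simulate_reads()] (or any data.table with
#'   `read_id` and `seq`).
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname splice-io
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table::data.table(read_id = names(x), seq = as.character(x))
}

# GRanges of exon (and CDS) features from a truth annotation.
annotation_granges <- function(truth) {
  ex <- truth$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- ex$gene
  S4Vectors::mcols(gr)$transcript_id <- paste0(ex$gene, ".t1")
  if (nrow(truth$cds) > 0L) {
    cds <- truth$cds
    gr2 <- GenomicRanges::GRanges(
      seqnames = cds$chrom,
      ranges = IRanges::IRanges(start = cds$start + 1L, end = cds$end),
      strand = cds$strand)
    S4Vectors::mcols(gr2)$type <- "CDS"
    S4Vectors::mcols(gr2)$gene_id <- cds$gene
    S4Vectors::mcols(gr2)$transcript_id <- paste0(cds$gene, ".t1")
    S4Vectors::mcols(gr)$phase <- NA_integer_
    S4Vectors::mcols(gr2)$phase <- 0L
    gr <- c(gr, gr2)
  }
  gr
}

#' @rdname splice-io
#' @param truth a `truth_set`.
#' @export
write_gene_models_gtf <- function(truth, path) {
  rtracklayer::export(annotation_granges(truth), path, format = "gtf")
  invisible(path)
}

#' @rdname splice-io
#' @export
write_gene_models_bed12 <- function(truth, path) {
  ex <- data.table::copy(truth$exons)
  data.table::setorder(ex, gene, start)
  bed <- ex[, {
    g0 <- min(start)
    list(chrom = chrom[1], start = g0, end = max(end), name = gene[1],
         score = 0L, strand = strand[1], thickStart = g0, thickEnd = max(end),
         rgb = "0,0,0", blockCount = .N,
         blockSizes = paste0(paste(end - start, collapse = ","), ","),
         blockStarts = paste0(paste(start - g0, collapse = ","), ","))
  }, by = gene][, -1L]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname splice-io
#' @return `read_annotation()` returns a list of data.tables (`exons`,
#'   `introns`, `cds`) in 0-based half-open coordinates, built from the
#'   union of one or more GTF/BED12 inputs.
#' @param paths one or more annotation file paths (GTF or BED12, mixed ok).
#' @export
read_annotation <- function(paths) {
  exs <- list(); cdss <- list()
  for (p in paths) {
    fmt <- if (grepl("\\.bed12?$", p, ignore.case = TRUE)) "bed" else "gtf"
    gr <- rtracklayer::import(p, format = fmt)
    if (fmt == "bed") {
      blocks <- rtracklayer::blocks(gr)
      fl <- unlist(blocks)
      genes <- rep(names(blocks), S4Vectors::elementNROWS(blocks))
      strands <- rep(as.character(GenomicRanges::strand(gr)),
                     S4Vectors::elementNROWS(blocks))
      exs[[p]] <- data.table::data.table(
        gene = genes,
        chrom = as.character(GenomicRanges::seqnames(fl)),
        strand = strands,
        start = GenomicRanges::start(fl) - 1L,
        end = GenomicRanges::end(fl))
    } else {
      typ <- as.character(S4Vectors::mcols(gr)$type)
      ex <- gr[typ == "exon"]
      exs[[p]] <- data.table::data.table(
        gene = as.character(S4Vectors::mcols(ex)$gene_id),
        chrom = as.character(GenomicRanges::seqnames(ex)),
        strand = as.character(GenomicRanges::strand(ex)),
        start = GenomicRanges::start(ex) - 1L,
        end = GenomicRanges::end(ex))
      cd <- gr[typ == "CDS"]
      if (length(cd) > 0L)
        cdss[[p]] <- data.table::data.table(
          gene = as.character(S4Vectors::mcols(cd)$gene_id),
          chrom = as.character(GenomicRanges::seqnames(cd)),
          strand = as.character(GenomicRanges::strand(cd)),
          start = GenomicRanges::start(cd) - 1L,
          end = GenomicRanges::end(cd))
    }
  }
  exons <- unique(data.table::rbindlist(exs))
  cds <- if (length(cdss)) unique(data.table::rbindlist(cdss)) else
    data.table::data.table(gene = character(0), chrom = character(0),
                           strand = character(0), start = integer(0),
                           end = integer(0))
  list(exons = exons, introns = introns_from_exons(exons), cds = cds)
}

# Intron set (union over genes) from an exon table.
introns_from_exons <- function(exons) {
  ex <- data.table::copy(exons)
  data.table::setorder(ex, gene, start)
  intr <- ex[, if (.N > 1L) list(chrom = chrom[-1L], strand = strand[-1L],
                                 start = end[-.N], end = start[-1L]),
             by = gene]
  unique(intr[end > start])
}

#' @rdname splice-io
#' @param track a `conservation_track`.
#' @export
write_conservation_bedgraph <- function(track, path) {
  lens <- vapply(track, length, integer(1))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(names(track), lens),
    ranges = IRanges::IRanges(unlist(lapply(lens, seq_len),
                                     use.names = FALSE), width = 1L),
    score = unlist(track, use.names = FALSE))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname splice-io
#' @export
read_conservation_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  out <- lapply(split(seq_along(gr), chroms), function(idx) {
    sub <- gr[idx]
    n <- max(GenomicRanges::end(sub))
    v <- rep(NA_real_, n)
    pos <- IRanges::IRanges(GenomicRanges::start(sub),
                            GenomicRanges::end(sub))
    v[unlist(Map(seq, GenomicRanges::start(sub), GenomicRanges::end(sub)))] <-
      rep(S4Vectors::mcols(sub)$score, GenomicRanges::width(sub))
    v
  })
  class(out) <- "conservation_track"
  out
}

#' @rdname splice-io
#' @param junctions an aggregated junction table.
#' @export
write_junctions_tsv <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname splice-io
#' @param overhang block size drawn on each side of the junction.
#' @export
write_junctions_bed12 <- function(junctions, path, overhang = 20L) {
  j <- junctions
  bed <- data.table::data.table(
    chrom = j$chrom, start = j$start - overhang, end = j$end + overhang,
    name = sprintf("junc%06d", seq_len(nrow(j))),
    score = j$reads, strand = j$strand,
    thickStart = j$start - overhang, thickEnd = j$end + overhang,
    rgb = "0,0,0", blockCount = 2L,
    blockSizes = sprintf("%d,%d,", overhang, overhang),
    blockStarts = sprintf("0,%d,", j$end - (j$start - overhang)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname splice-io
#' @param config a [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  if (is.function(cfg$per_intron_error_rate))
    cfg$per_intron_error_rate <- paste(
      deparse(cfg$per_intron_error_rate), collapse = "\n")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname splice-io
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.character(cfg$per_intron_error_rate))
    cfg$per_intron_error_rate <- eval(parse(
      text = cfg$per_intron_error_rate))
  do.call(sim_config, cfg)
}

#' @rdname splice-io
#' @return `read_hexamer_list()` returns an uppercase character vector of
#'   hexamers; malformed entries are rejected with an error.
#' @export
read_hexamer_list <- function(path) {
  x <- toupper(trimws(readLines(path)))
  x <- x[nzchar(x)]
  bad <- !grepl("^[ACGT]{6}$", x)
  if (any(bad)) stop("malformed hexamers in list: ",
                     paste(utils::head(x[bad], 5), collapse = ", "))
  x
}
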