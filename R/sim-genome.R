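#' Generate a synthetic genome with annotated multi-exon genes
#'
#' Builds a miniature genome of non-overlapping genes on random-sequence
#' chromosomes. Every annotated intron begins `GT` (or `GC` with probability
#' `gc_fraction`) and ends `AG` in transcript orientation; exon counts are
#' truncated-geometric with the configured mean, exon lengths uniform,
#' intron lengths log-normal clamped to the configured support, and gene
#' expression weights follow a power law. For every intron the full support
#' of the cryptic-site proposal kernel (GT positions for donor-side errors,
#' AG positions for acceptor-side errors, within the intron plus
#' `exon_flank` bases of flanking exon, geometric decay with distance) is
#' precomputed and recorded in the truth set, so the conservation track can
#' mark those bases as unconserved before any transcripts are drawn.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; identical `(config, seed)` pairs reproduce
#'   byte-identical output.
#' @return a list with elements `genome` (named character vector of
#'   chromosome sequences) and `truth` (a `truth_set`: gene models, introns
#'   with per-intron error probabilities, cryptic-site candidates, CDS
#'   intervals and per-gene pre-mRNA sequences).
#' @export
generate_genome <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  cfg <- config
  n <- cfg$n_genes

  n_exons <- 2L + stats::rgeom(n, prob = 1 / (cfg$mean_exons - 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom_of <- sort(rep_len(seq_len(cfg$n_chroms), n))
  expr <- stats::runif(n)^(-1 / cfg$expression_alpha)

  genes <- vector("list", n)
  for (g in seq_len(n)) {
    ne <- n_exons[g]
    exl <- sample(cfg$exon_length[1]:cfg$exon_length[2], ne, replace = TRUE)
    utr5 <- sample(cfg$utr_padding[1]:cfg$utr_padding[2], 1L)
    utr3 <- sample(cfg$utr_padding[1]:cfg$utr_padding[2], 1L)
    exl[1] <- exl[1] + utr5
    exl[ne] <- exl[ne] + utr3
    inl <- round(stats::rlnorm(ne - 1L, cfg$intron_meanlog, cfg$intron_sdlog))
    inl <- pmin(pmax(inl, cfg$intron_range[1]), cfg$intron_range[2])
    tx_len <- sum(exl) + sum(inl)
    seqv <- sample(c("A", "C", "G", "T"), tx_len, replace = TRUE)
    # local exon/intron layout (transcript orientation, 0-based half-open)
    starts <- cumsum(c(0L, as.integer(rbind(exl[-ne], inl))))
    ex_start <- starts[seq(1L, by = 2L, length.out = ne)]
    ex_end <- ex_start + exl
    in_start <- ex_end[-ne]
    in_end <- ex_start[-1L]
    gc <- stats::runif(ne - 1L) < cfg$gc_fraction
    for (i in seq_len(ne - 1L)) {
      seqv[in_start[i] + 1L] <- "G"
      seqv[in_start[i] + 2L] <- if (gc[i]) "C" else "T"
      seqv[in_end[i] - 1L] <- "A"
      seqv[in_end[i]] <- "G"
    }
    premrna <- paste(seqv, collapse = "")
    genes[[g]] <- list(ne = ne, utr5 = utr5, utr3 = utr3, tx_len = tx_len,
                       ex_start = ex_start, ex_end = ex_end,
                       in_start = in_start, in_end = in_end,
                       gc = gc, premrna = premrna)
  }

  if (cfg$expression_length_coupling != 0) {
    mean_ilen <- vapply(genes, function(gi)
      mean(gi$in_end - gi$in_start), numeric(1))
    expr <- expr * (mean_ilen / stats::median(mean_ilen))^
      (-cfg$expression_length_coupling)
  }

  # place genes on chromosomes with intergenic spacers
  chrom_seqs <- character(cfg$n_chroms)
  gene_tab <- vector("list", n)
  exon_tab <- intron_tab <- cryptic_tab <- cds_tab <- vector("list", n)
  premrna <- character(n)
  gene_ids <- sprintf("g%04d", seq_len(n))
  for (ch in seq_len(cfg$n_chroms)) {
    parts <- character(0)
    cursor <- 0L
    for (g in which(chrom_of == ch)) {
      gi <- genes[[g]]
      spacer_len <- sample(cfg$intergenic[1]:cfg$intergenic[2], 1L)
      parts <- c(parts, random_dna(spacer_len))
      cursor <- cursor + spacer_len
      gseg <- if (strand[g] == "+") gi$premrna else revcomp_chr(gi$premrna)
      parts <- c(parts, gseg)
      g0 <- cursor
      cursor <- cursor + gi$tx_len
      chrom_name <- paste0("chr", ch)
      loc2gen <- make_loc2gen(g0, gi$tx_len, strand[g])
      res <- gene_truth_rows(gene_ids[g], chrom_name, strand[g], g0, gi, cfg,
                             loc2gen, expr[g])
      gene_tab[[g]] <- res$gene
      exon_tab[[g]] <- res$exons
      intron_tab[[g]] <- res$introns
      cryptic_tab[[g]] <- res$cryptic
      cds_tab[[g]] <- res$cds
      premrna[g] <- gi$premrna
    }
    tail_len <- sample(cfg$intergenic[1]:cfg$intergenic[2], 1L)
    parts <- c(parts, random_dna(tail_len))
    chrom_seqs[ch] <- paste(parts, collapse = "")
  }
  names(chrom_seqs) <- paste0("chr", seq_len(cfg$n_chroms))
  names(premrna) <- gene_ids

  truth <- list(genes = data.table::rbindlist(gene_tab),
                exons = data.table::rbindlist(exon_tab),
                introns = data.table::rbindlist(intron_tab),
                cryptic = data.table::rbindlist(cryptic_tab),
                cds = data.table::rbindlist(cds_tab),
                premrna = premrna,
                config = cfg)
  truth$introns[, epsilon := intron_error_probs(cfg, length)]
  class(truth) <- "truth_set"
  list(genome = chrom_seqs, truth = truth)
}

# Closure mapping local transcript-orientation half-open intervals to
# genomic forward-strand half-open intervals.
make_loc2gen <- function(g0, tx_len, strand) {
  if (strand == "+") {
    function(t1, t2) cbind(start = g0 + t1, end = g0 + t2)
  } else {
    function(t1, t2) cbind(start = g0 + tx_len - t2, end = g0 + tx_len - t1)
  }
}

gene_truth_rows <- function(gid, chrom, strand, g0, gi, cfg, loc2gen, expr) {
  ne <- gi$ne
  # CDS: usually starts in the first exon past the 5' UTR padding and ends
  # before the 3' padding; occasionally shifted one exon inward so some
  # splice sites fall in UTRs.
  cds_start_loc <- gi$utr5
  if (ne >= 3L && stats::runif(1) < 0.2) cds_start_loc <- gi$ex_start[2] + 5L
  cds_end_loc <- gi$tx_len - gi$utr3
  if (ne >= 3L && stats::runif(1) < 0.2) cds_end_loc <- gi$ex_end[ne - 1L] - 5L

  ex <- loc2gen(gi$ex_start, gi$ex_end)
  exons <- data.table::data.table(gene = gid, chrom = chrom, strand = strand,
                                  start = ex[, 1], end = ex[, 2],
                                  rank = if (strand == "+") seq_len(ne) else rev(seq_len(ne)))
  gene_row <- data.table::data.table(
    gene = gid, chrom = chrom, strand = strand,
    start = min(ex[, 1]), end = max(ex[, 2]),
    tx_len = gi$tx_len, n_exons = ne, expression = expr,
    cds_start_loc = cds_start_loc, cds_end_loc = cds_end_loc)

  intr <- loc2gen(gi$in_start, gi$in_end)
  intron_ids <- sprintf("%s.i%d", gid, seq_len(ne - 1L))
  introns <- data.table::data.table(
    intron_id = intron_ids, gene = gid, chrom = chrom, strand = strand,
    start = intr[, 1],
    end = intr[, 2],
    t_start = gi$in_start, t_end = gi$in_end,
    length = gi$in_end - gi$in_start,
    donor_dinuc = ifelse(gi$gc, "GC", "GT"))

  cryptic <- cryptic_candidates(gid, chrom, strand, gi, cfg, loc2gen,
                                intron_ids)

  # CDS genomic intervals: exons clipped to [cds_start_loc, cds_end_loc)
  cs <- pmax(gi$ex_start, cds_start_loc)
  cevec <- pmin(gi$ex_end, cds_end_loc)
  keep <- cs < cevec
  cds <- if (any(keep)) {
    cg <- loc2gen(cs[keep], cevec[keep])
    data.table::data.table(gene = gid, chrom = chrom, strand = strand,
                           start = cg[, 1], end = cg[, 2])
  } else {
    data.table::data.table(gene = character(0), chrom = character(0),
                           strand = character(0), start = integer(0),
                           end = integer(0))
  }
  list(gene = gene_row, exons = exons, introns = introns, cryptic = cryptic,
       cds = cds)
}

# All cryptic-site proposal candidates for one gene, in transcript-local
# coordinates, with geometric kernel weights. Candidates are restricted so
# the resulting intron stays within the mapper's length constraints and at
# least min_cryptic_offset away from the true site.
cryptic_candidates <- function(gid, chrom, strand, gi, cfg, loc2gen,
                               intron_ids) {
  out <- vector("list", gi$ne - 1L)
  seqc <- gi$premrna
  min_intron <- 51L
  for (i in seq_len(gi$ne - 1L)) {
    t1 <- gi$in_start[i]; t2 <- gi$in_end[i]
    # donor-side: GT positions d, candidate intron [d, t2)
    d_lo <- max(t1 - cfg$exon_flank, gi$ex_start[i])
    d_hi <- t2 - min_intron
    d_cand <- integer(0)
    if (d_hi >= d_lo) {
      win <- substr(seqc, d_lo + 1L, d_hi + 2L)
      hits <- gregexpr("GT", win, fixed = TRUE)[[1]]
      if (hits[1] != -1L) d_cand <- d_lo + as.integer(hits) - 1L
    }
    d_off <- d_cand - t1
    keepd <- abs(d_off) >= cfg$min_cryptic_offset & (t2 - d_cand) <= cfg$intron_range[2]
    d_cand <- d_cand[keepd]; d_off <- d_off[keepd]
    # acceptor-side: AG ending at e', candidate intron [t1, e')
    a_lo <- t1 + min_intron
    a_hi <- min(t2 + cfg$exon_flank, gi$ex_end[i + 1L])
    a_cand <- integer(0)
    if (a_hi >= a_lo) {
      win <- substr(seqc, a_lo - 1L, a_hi)
      hits <- gregexpr("AG", win, fixed = TRUE)[[1]]
      if (hits[1] != -1L) a_cand <- (a_lo - 2L) + as.integer(hits) + 1L
    }
    a_off <- a_cand - t2
    keepa <- abs(a_off) >= cfg$min_cryptic_offset & (a_cand - t1) <= cfg$intron_range[2]
    a_cand <- a_cand[keepa]; a_off <- a_off[keepa]

    n_d <- length(d_cand); n_a <- length(a_cand)
    if (n_d + n_a == 0L) {
      out[[i]] <- NULL
      next
    }
    side <- c(rep("donor", n_d), rep("acceptor", n_a))
    t_pos <- c(d_cand, a_cand)
    offset <- c(d_off, a_off)
    jt1 <- ifelse(side == "donor", t_pos, t1)
    jt2 <- ifelse(side == "donor", t2, t_pos)
    gcoord <- loc2gen(jt1, jt2)
    out[[i]] <- data.table::data.table(
      intron_id = intron_ids[i], gene = gid, chrom = chrom, strand = strand,
      side = side, t_pos = t_pos, offset = offset,
      jt_start = jt1, jt_end = jt2,
      g_start = gcoord[, 1], g_end = gcoord[, 2],
      weight = (1 - cfg$error_kernel_decay)^abs(offset),
      in_frame = offset %% 3L == 0L)
  }
  data.table::rbindlist(out)
}

#' Generate a synthetic variant (polymorphism) set
#'
#' Draws polymorphic positions uniformly at the configured per-base density,
#' excluding the canonical dinucleotides of true splice sites (annotated
#' sites are under purifying selection; cryptic sites are not), which
#' produces the expected dip of polymorphism directly intronic of annotated
#' sites and no dip at cryptic sites.
#'
#' @param genome named character vector of chromosome sequences.
#' @param truth a `truth_set`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.table with columns `chrom`, `pos` (0-based).
#' @export
generate_variants <- function(genome, truth, config, seed) {
  set.seed(seed)
  protected <- truth$introns[, {
    d <- site_canonical_positions("donor", strand,
                                  ifelse(strand == "+", start, end))
    a <- site_canonical_positions("acceptor", strand,
                                  ifelse(strand == "+", end, start))
    list(pos = c(d, a))
  }, by = .(chrom, intron_id)][, .(chrom, pos)]
  out <- lapply(names(genome), function(ch) {
    L <- nchar(genome[[ch]])
    pos <- which(stats::runif(L) < config$variant_density) - 1L
    bad <- protected[chrom == ch, pos]
    data.table::data.table(chrom = ch, pos = setdiff(pos, bad))
  })
  data.table::rbindlist(out)
}
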