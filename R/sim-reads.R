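#' Materialize isoform sequences and junction positions
#'
#' Builds the spliced sequence of every isoform in a pool by removing its
#' spliced intervals from the gene's pre-mRNA, and records each splice
#' junction's transcript-local position together with its genomic
#' coordinates.
#'
#' @param pool an `isoform_pool` from [simulate_transcripts()].
#' @param truth the matching `truth_set`.
#' @return list with `isoforms` (iso_id, gene, count, seq, len) and
#'   `junctions` (iso_id, local_pos, chrom, strand, start, end, is_true).
#' @export
isoform_sequences <- function(pool, truth) {
  iso <- data.table::copy(pool$isoforms)
  intr <- truth$introns[, .(gene, intron_id, t_start, t_end)]
  # removal intervals per isoform: correct splicing for introns without an
  # event; the event's interval otherwise (retention removes nothing)
  base <- merge(iso[, .(iso_id, gene)], intr, by = "gene",
                allow.cartesian = TRUE)
  ev <- pool$events
  if (nrow(ev) > 0L) {
    base[ev, `:=`(etype = i.type, e1 = i.jt_start, e2 = i.jt_end),
         on = c("iso_id", "intron_id")]
  } else {
    base[, `:=`(etype = NA_character_, e1 = NA_integer_, e2 = NA_integer_)]
  }
  rem <- base[is.na(etype) | etype != "retention"]
  rem[, `:=`(r_start = ifelse(is.na(etype), t_start, e1),
             r_end = ifelse(is.na(etype), t_end, e2))]
  data.table::setorder(rem, iso_id, r_start)
  rem[, removed_before := cumsum(data.table::shift(r_end - r_start, fill = 0L)),
      by = iso_id]
  rem[, local_pos := r_start - removed_before]

  # spliced sequences: keep the complement of the removal intervals
  tx_len <- truth$genes$tx_len[match(iso$gene, truth$genes$gene)]
  premrna <- truth$premrna[iso$gene]
  segs <- rem[, {
    ks <- c(0L, r_end)
    ke <- c(r_start, tx_len[match(iso_id[1], iso$iso_id)])
    list(k_start = ks, k_end = ke)
  }, by = iso_id]
  segs <- segs[k_end > k_start]
  segs[, gene := iso$gene[match(iso_id, iso$iso_id)]]
  segs[, piece := substring(truth$premrna[gene], k_start + 1L, k_end)]
  seqs <- segs[, .(seq = paste(piece, collapse = "")), by = iso_id]
  iso[seqs, seq := i.seq, on = "iso_id"]
  # isoforms with no removals at all (single intron fully retained)
  iso[is.na(seq), seq := truth$premrna[gene]]
  iso[, len := nchar(seq)]

  coord <- local_interval_to_genomic(truth, rem$gene, rem$r_start, rem$r_end)
  gm <- truth$genes[match(rem$gene, truth$genes$gene)]
  junctions <- data.table::data.table(
    iso_id = rem$iso_id, gene = rem$gene, local_pos = rem$local_pos,
    chrom = gm$chrom, strand = gm$strand,
    start = coord$start, end = coord$end,
    is_true = is.na(rem$etype))
  list(isoforms = iso[, .(iso_id, gene, count, is_error, frame_preserving,
                          seq, len)],
       junctions = junctions)
}

#' Simulate short single-end reads from an isoform pool
#'
#' Read start positions are uniform along each transcript, weighted by
#' isoform abundance; each base is substituted independently at the
#' configured sequencing error rate; read ids encode the source isoform and
#' start position for truth tracing. With `junction_spanning_only = TRUE`
#' the start positions are restricted to the windows from which a read
#' covers at least one splice junction, which is the informative subset for
#' every junction-level analysis.
#'
#' The default number of reads is chosen so the mean number of
#' junction-spanning reads per true junction equals `config$depth`.
#'
#' @param truth a `truth_set`.
#' @param pool an `isoform_pool`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_reads total reads to draw (default from `config$depth`).
#' @param junction_spanning_only sample only junction-spanning reads.
#' @return a data.table (class `read_set`) with columns `read_id`, `seq`,
#'   `iso_id`, `start`.
#' @export
simulate_reads <- function(truth, pool, config, seed, n_reads = NULL,
                           junction_spanning_only = FALSE) {
  set.seed(seed)
  L <- config$read_length
  im <- isoform_sequences(pool, truth)
  iso <- im$isoforms
  junc <- im$junctions
  short <- iso[len < L]
  if (nrow(short) > 0L) {
    warning(sprintf("%d isoform(s) shorter than the read length skipped",
                    nrow(short)))
    iso <- iso[len >= L]
    junc <- junc[iso_id %in% iso$iso_id]
  }
  if (nrow(iso) == 0L) stop("no isoform is long enough to sequence")
  junc[iso, `:=`(count = i.count, len = i.len), on = "iso_id"]

  if (junction_spanning_only) {
    win <- junc[, .(iso_id, local_pos, count, len, is_true,
                    w_start = pmax(0L, local_pos - L + 1L),
                    w_end = pmin(local_pos - 1L, len - L))]
    win <- win[w_end >= w_start]
    win[, wsize := w_end - w_start + 1L]
    win[, weight := as.double(count) * wsize]
    if (is.null(n_reads)) {
      key <- junc[is_true == TRUE, .(w = sum(as.double(count) * (L - 1))),
                  by = .(chrom, strand, start, end)]
      n_reads <- max(1L, round(config$depth * sum(win$weight) /
                                 mean(key$w)))
    }
    ridx <- sample.int(nrow(win), n_reads, replace = TRUE,
                       prob = win$weight)
    rd <- win[ridx, .(iso_id, w_start, wsize)]
    rd[, start := w_start + as.integer(floor(stats::runif(.N) * wsize))]
  } else {
    iso[, weight := as.double(count) * (len - L + 1L)]
    if (is.null(n_reads)) {
      key <- junc[is_true == TRUE, .(w = sum(as.double(count))),
                  by = .(chrom, strand, start, end)]
      n_reads <- max(1L, round(config$depth * sum(iso$weight) /
                                 ((L - 1) * mean(key$w))))
    }
    ridx <- sample.int(nrow(iso), n_reads, replace = TRUE, prob = iso$weight)
    rd <- iso[ridx, .(iso_id, len)]
    rd[, start := as.integer(floor(stats::runif(.N) * (len - L + 1L)))]
  }
  rd[, seq := substring(iso$seq[match(iso_id, iso$iso_id)], start + 1L,
                        start + L)]
  rd[, read_id := sprintf("r%07d;%s;%d", .I, iso_id, start)]

  rd[, seq := add_sequencing_errors(seq, L, config$sequencing_error_rate)]
  out <- rd[, .(read_id, seq, iso_id, start)]
  class(out) <- c("read_set", class(out))
  out
}

# Flat-rate per-base substitution errors, vectorized.
add_sequencing_errors <- function(seqs, L, rate) {
  if (rate <= 0) return(seqs)
  k <- stats::rbinom(length(seqs), L, rate)
  hit <- which(k > 0L)
  if (length(hit) == 0L) return(seqs)
  rows <- rep(hit, k[hit])
  pos <- sample.int(L, length(rows), replace = TRUE)
  alphabet <- c("A", "C", "G", "T")
  err <- data.table::data.table(row = rows, pos = pos)
  # apply one substitution per read per round (multiple hits are rare)
  while (nrow(err) > 0L) {
    first <- err[!duplicated(row)]
    cur <- substring(seqs[first$row], first$pos, first$pos)
    shift <- sample.int(3L, nrow(first), replace = TRUE)
    newb <- alphabet[(match(cur, alphabet) - 1L + shift) %% 4L + 1L]
    newb[is.na(newb)] <- "N"
    seqs[first$row] <- paste0(substr(seqs[first$row], 1L, first$pos - 1L),
                              newb,
                              substr(seqs[first$row], first$pos + 1L, L))
    err <- err[duplicated(row)]
  }
  seqs
}
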