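#' Simulate an error-bearing transcript pool
#'
#' Draws transcript copies per gene in proportion to power-law expression
#' weights, then lets every intron of every copy splice correctly with
#' probability `1 - epsilon(intron)`. On error, a cryptic donor GT or
#' acceptor AG from the precomputed proposal kernel replaces the true site;
#' with probability `double_error_fraction` the event instead retains the
#' intron and splices out an internal segment between a cryptic GT and a
#' cryptic AG, producing a junction with no annotated end. Introns with no
#' available cryptic dinucleotide fall back to flagged intron retention.
#' Frame-disrupting error transcripts survive with probability `frame_bias`
#' relative to frame-preserving ones (NMD proxy).
#'
#' @param genome named character vector (unused directly; kept for interface
#'   symmetry and validation).
#' @param truth a `truth_set` from [generate_genome()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_transcripts total number of transcript copies to draw.
#' @return an `isoform_pool`: list with `isoforms` (gene, iso_id, count,
#'   is_error, frame_preserving, n_events, retained flag) and `events`
#'   (iso_id, intron_id, type, local spliced interval, offset, genomic
#'   junction coordinates).
#' @export
simulate_transcripts <- function(genome, truth, config, seed,
                                 n_transcripts = 10000L) {
  set.seed(seed)
  cfg <- config
  genes <- truth$genes
  introns <- truth$introns
  m <- as.vector(stats::rmultinom(1, n_transcripts, prob = genes$expression))
  names(m) <- genes$gene

  # error events: per (gene, intron), binomial count, assigned to distinct
  # copies of that gene
  ev <- introns[, {
    mg <- m[[gene[1]]]
    k <- stats::rbinom(1L, mg, epsilon)
    if (k > 0L) list(copy = sample.int(mg, k)) else list(copy = integer(0))
  }, by = .(intron_id, gene)]

  if (nrow(ev) > 0L) {
    ev <- assign_cryptic_events(ev, truth, cfg)
  } else {
    ev <- data.table::data.table(intron_id = character(0), gene = character(0),
                                 copy = integer(0), type = character(0),
                                 jt_start = integer(0), jt_end = integer(0),
                                 offset = integer(0), shift = integer(0))
  }

  # collapse copies into isoforms
  ev[, ev_str := paste(intron_id, type, jt_start, jt_end, sep = "@")]
  copy_keys <- ev[order(intron_id),
                  .(key = paste(ev_str, collapse = ";"),
                    shift = sum(shift), n_events = .N),
                  by = .(gene, copy)]
  iso_err <- copy_keys[, .(count = .N, shift = shift[1],
                           n_events = n_events[1]), by = .(gene, key)]
  iso_err[, frame_preserving := shift %% 3L == 0L]
  # NMD proxy: thin frame-disrupting error isoform copies
  if (cfg$frame_bias < 1 && nrow(iso_err) > 0L) {
    iso_err[frame_preserving == FALSE,
            count := stats::rbinom(.N, count, cfg$frame_bias)]
    iso_err <- iso_err[count > 0L]
  }
  n_err_copies <- copy_keys[, .(n = .N), by = gene]
  correct <- data.table::data.table(gene = genes$gene,
                                    count = as.integer(m))
  correct[n_err_copies, count := count - i.n, on = "gene"]
  correct <- correct[count > 0L]
  correct[, `:=`(key = "", shift = 0L, n_events = 0L,
                 frame_preserving = TRUE)]
  isoforms <- data.table::rbindlist(list(correct, iso_err), use.names = TRUE)
  isoforms[, is_error := n_events > 0L]
  data.table::setorder(isoforms, gene, key)
  isoforms[, iso_id := sprintf("%s.iso%05d", gene, seq_len(.N) - 1L),
           by = gene]

  events <- if (nrow(ev) > 0L) {
    ekey <- unique(ev[, .(gene, copy)])
    ekey[copy_keys, key := i.key, on = c("gene", "copy")]
    ev[ekey, key := i.key, on = c("gene", "copy")]
    ev[isoforms, iso_id := i.iso_id, on = c("gene", "key")]
    unique(ev[!is.na(iso_id),
              .(iso_id, gene, intron_id, type, jt_start, jt_end, offset,
                shift)])
  } else {
    data.table::data.table(iso_id = character(0), gene = character(0),
                           intron_id = character(0), type = character(0),
                           jt_start = integer(0), jt_end = integer(0),
                           offset = integer(0), shift = integer(0))
  }
  pool <- list(isoforms = isoforms[, .(gene, iso_id, count, is_error,
                                       frame_preserving, n_events)],
               events = events,
               n_requested = n_transcripts)
  class(pool) <- "isoform_pool"
  pool
}

# Choose a cryptic outcome for every error event.
assign_cryptic_events <- function(ev, truth, cfg) {
  cr <- truth$cryptic
  intr <- truth$introns
  ev[, u_dbl := stats::runif(.N)]
  out <- ev[, {
    ii <- intron_id[1]
    cand <- cr[intron_id == ii]
    it <- intr[intron_id == ii]
    n <- .N
    type <- character(n); jt1 <- integer(n); jt2 <- integer(n)
    off <- integer(n); shf <- integer(n)
    # internal (pseudo-splice) candidates: cryptic donor and acceptor both
    # strictly inside the intron
    dint <- cand[side == "donor" & offset > 0L]
    aint <- cand[side == "acceptor" & offset < 0L]
    for (j in seq_len(n)) {
      done <- FALSE
      if (u_dbl[j] < cfg$double_error_fraction &&
          nrow(dint) > 0L && nrow(aint) > 0L) {
        d <- dint[sample.int(nrow(dint), 1L, prob = dint$weight)]
        ok <- aint[t_pos - d$t_pos >= 51L]
        if (nrow(ok) > 0L) {
          a <- ok[sample.int(nrow(ok), 1L, prob = ok$weight)]
          type[j] <- "internal"
          jt1[j] <- d$t_pos; jt2[j] <- a$t_pos
          off[j] <- NA_integer_
          shf[j] <- it$length - (a$t_pos - d$t_pos)
          done <- TRUE
        }
      }
      if (!done) {
        if (nrow(cand) == 0L) {
          type[j] <- "retention"
          jt1[j] <- NA_integer_; jt2[j] <- NA_integer_
          off[j] <- NA_integer_; shf[j] <- it$length
        } else {
          cidx <- sample.int(nrow(cand), 1L, prob = cand$weight)
          cc <- cand[cidx]
          type[j] <- cc$side
          jt1[j] <- cc$jt_start; jt2[j] <- cc$jt_end
          off[j] <- cc$offset
          shf[j] <- if (cc$side == "donor") cc$offset else -cc$offset
        }
      }
    }
    list(copy = copy, type = type, jt_start = jt1, jt_end = jt2,
         offset = off, shift = shf)
  }, by = .(intron_id, gene)]
  out
}

#' True and error junction keys of a simulation
#'
#' @param truth a `truth_set`.
#' @param pool optionally, an `isoform_pool`; when supplied, realized error
#'   junctions are returned as well.
#' @return list with `true_junctions` and (if `pool` given) `error_junctions`
#'   data.tables keyed by (chrom, strand, start, end); the two sets are
#'   disjoint.
#' @export
truth_junctions <- function(truth, pool = NULL) {
  tj <- truth$introns[, .(chrom, strand, start, end, intron_id, gene)]
  out <- list(true_junctions = tj)
  if (!is.null(pool)) {
    ev <- pool$events[type %in% c("donor", "acceptor", "internal")]
    if (nrow(ev) > 0L) {
      gm <- truth$genes[, .(gene, g_strand = strand, chrom)]
      ev2 <- merge(ev, gm, by = "gene")
      coord <- local_interval_to_genomic(truth, ev2$gene, ev2$jt_start,
                                         ev2$jt_end)
      ej <- unique(data.table::data.table(
        chrom = ev2$chrom, strand = ev2$g_strand,
        start = coord$start, end = coord$end,
        intron_id = ev2$intron_id, type = ev2$type, offset = ev2$offset))
      out$error_junctions <- ej[!tj, on = c("chrom", "strand", "start", "end")]
    } else {
      out$error_junctions <- data.table::data.table(
        chrom = character(0), strand = character(0),
        start = integer(0), end = integer(0))
    }
  }
  out
}

# Map transcript-local half-open intervals to genomic coordinates, given
# gene ids (vectorized).
local_interval_to_genomic <- function(truth, gene, t1, t2) {
  row_idx <- match(gene, truth$genes$gene)
  gm <- truth$genes[row_idx, ]
  plus <- gm$strand == "+"
  start <- ifelse(plus, gm$start + t1, gm$start + gm$tx_len - t2)
  end <- ifelse(plus, gm$start + t2, gm$start + gm$tx_len - t1)
  list(start = start, end = end)
}
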