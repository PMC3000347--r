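#' Generate a per-base conservation track
#'
#' Emulates the conservation structure around splice sites: exonic bases and
#' the canonical dinucleotides of true splice sites are drawn from a high
#' (conserved) score distribution, while intronic/intergenic background and
#' the dinucleotides of every cryptic-site proposal candidate are drawn from
#' a near-zero distribution. Averaged over sites, the track therefore shows
#' the expected step profile: an exonic plateau, a spike at the splice-site
#' dinucleotides, and background deep in the intron — and a flat background
#' profile at cryptic sites.
#'
#' @param genome named character vector of chromosome sequences.
#' @param truth a `truth_set`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a `conservation_track`: named list of per-base numeric vectors
#'   (position `i + 1` of the vector is 0-based coordinate `i`).
#' @export
generate_conservation_track <- function(genome, truth, config, seed) {
  set.seed(seed)
  cfg <- config
  track <- lapply(genome, function(s)
    stats::rnorm(nchar(s), cfg$cons_bg_mean, cfg$cons_bg_sd))
  # exonic plateau
  for (i in seq_len(nrow(truth$exons))) {
    e <- truth$exons[i]
    idx <- (e$start + 1L):e$end
    track[[e$chrom]][idx] <- stats::rnorm(length(idx), cfg$cons_high_mean,
                                          cfg$cons_high_sd)
  }
  # true splice-site dinucleotides (first/last two intronic bases)
  sp <- truth$introns[, .(chrom,
                          pos = c(start, start + 1L, end - 2L, end - 1L)),
                      by = intron_id]
  for (ch in unique(sp$chrom)) {
    idx <- sp[chrom == ch, pos] + 1L
    track[[ch]][idx] <- stats::rnorm(length(idx), cfg$cons_high_mean,
                                     cfg$cons_high_sd)
  }
  # cryptic candidate dinucleotides: background, even when exonic
  cr <- truth$cryptic
  if (nrow(cr) > 0L) {
    donor_first <- (cr$side == "donor") == (cr$strand == "+")
    p1 <- ifelse(donor_first, cr$g_start, cr$g_end - 2L)
    cp <- data.table::data.table(chrom = rep(cr$chrom, 2L),
                                 pos = c(p1, p1 + 1L))
    for (ch in unique(cp$chrom)) {
      idx <- cp[chrom == ch, pos] + 1L
      track[[ch]][idx] <- stats::rnorm(length(idx), cfg$cons_bg_mean,
                                       cfg$cons_bg_sd)
    }
  }
  class(track) <- "conservation_track"
  track
}

#' Look up conservation scores at 0-based positions
#'
#' @param track a `conservation_track` (or any named list of numeric
#'   vectors).
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions.
#' @return numeric scores; `NA` outside the track.
#' @export
track_values <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    v <- track[[ch]]
    if (is.null(v)) next
    p <- pos[sel] + 1L
    ok <- p >= 1L & p <= length(v)
    res <- rep(NA_real_, sum(sel))
    res[ok] <- v[p[ok]]
    out[sel] <- res
  }
  out
}
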