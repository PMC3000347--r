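# Splicing-noise metrics: conservation profiles and labels, frame
# periodicity of minor splice sites, per-intron splicing error rates and
# their correlates, polymorphism profiles.

# Genomic position of signed offset o from a splice site, with o >= 0 on
# the intronic side (o = 0 is the first intronic base) and o < 0 exonic.
site_offset_positions <- function(type, strand, boundary, o) {
  into_intron <- (type == "donor") == (strand == "+")
  ifelse(into_intron, boundary + o, boundary - 1L - o)
}

#' Transcript-orientation dinucleotide of a candidate splice site
#'
#' Donor sites report their first two intronic bases, acceptors their last
#' two, read 5' to 3' along the transcript (vectorized).
#'
#' @param genome named character vector.
#' @param chrom,strand,type,boundary site key vectors.
#' @return character vector of dinucleotides (NA out of range).
#' @export
site_dinuc <- function(genome, chrom, strand, type, boundary) {
  p <- site_canonical_positions_vec(type, strand, boundary)
  lo <- pmin(p$p1, p$p2)
  out <- rep(NA_character_, length(boundary))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    L <- nchar(genome[[ch]])
    ok <- sel[lo[sel] >= 0L & lo[sel] + 1L < L]
    out[ok] <- substr(rep(genome[[ch]], length(ok)), lo[ok] + 1L, lo[ok] + 2L)
  }
  flip <- strand == "-"
  out[flip & !is.na(out)] <- revcomp_chr(out[flip & !is.na(out)])
  out
}

# Vectorized canonical-base positions; p1 is the first intronic base in
# transcript orientation, p2 the second.
site_canonical_positions_vec <- function(type, strand, boundary) {
  donor <- type == "donor"
  plus <- strand == "+"
  p1 <- ifelse(donor,
               ifelse(plus, boundary, boundary - 1L),
               ifelse(plus, boundary - 2L, boundary + 1L))
  p2 <- ifelse(donor,
               ifelse(plus, boundary + 1L, boundary - 2L),
               ifelse(plus, boundary - 1L, boundary))
  list(p1 = p1, p2 = p2)
}

#' Mean conservation profile around splice sites
#'
#' Averages the conservation track at each signed offset around a set of
#' splice sites, with offset 0 at the first intronic base, positive offsets
#' intronic and negative offsets exonic (strand- and type-aware). Sites
#' with partial track coverage are averaged over the available bases and
#' flagged.
#'
#' @param sites data.table with `chrom`, `strand`, `type`
#'   (donor/acceptor), `boundary`.
#' @param track a `conservation_track`.
#' @param window half-window in bp.
#' @return data.table with `offset`, `side`, `mean_score`, `n_sites`,
#'   `partial` flag.
#' @export
conservation_profile <- function(sites, track, window = 100L) {
  s <- data.table::as.data.table(sites)
  offs <- seq(-window, window - 1L)
  grid <- s[rep(seq_len(nrow(s)), each = length(offs))]
  grid[, offset := rep(offs, nrow(s))]
  grid[, pos := site_offset_positions(type, strand, boundary, offset)]
  grid[, score := track_values(track, chrom, pos)]
  prof <- grid[, .(mean_score = mean(score, na.rm = TRUE),
                   n_sites = sum(!is.na(score)),
                   partial = anyNA(score)), by = offset]
  prof[, side := ifelse(offset >= 0L, "intronic", "exonic")]
  data.table::setorder(prof, offset)
  prof[]
}

#' Conservation label of splice sites
#'
#' The mean score over the two canonical intronic bases classifies each
#' site as conserved (mean >= `t_hi`), unconserved (mean <= `unconserved_max`)
#' or intermediate. Sites with missing scores are intermediate and flagged.
#'
#' @param sites data.table with `chrom`, `strand`, `type`, `boundary`.
#' @param track a `conservation_track`.
#' @param t_hi highly-conserved threshold (default 1.5; must exceed
#'   `unconserved_max`).
#' @param unconserved_max unconserved threshold (default 0.5).
#' @return the sites table with `site_score` and `label`.
#' @export
label_conservation <- function(sites, track, t_hi = 1.5,
                               unconserved_max = 0.5) {
  if (t_hi <= unconserved_max) stop("t_hi must exceed unconserved_max")
  s <- data.table::copy(data.table::as.data.table(sites))
  p <- site_canonical_positions_vec(s$type, s$strand, s$boundary)
  sc1 <- track_values(track, s$chrom, p$p1)
  sc2 <- track_values(track, s$chrom, p$p2)
  s[, site_score := (sc1 + sc2) / 2]
  s[, label := data.table::fcase(
    is.na(site_score), "intermediate",
    site_score >= t_hi, "conserved",
    site_score <= unconserved_max, "unconserved",
    default = "intermediate")]
  s[, score_missing := is.na(site_score)]
  s[]
}

#' Frame periodicity of minor splice sites near major protein-coding sites
#'
#' Anchors are splice sites covered by at least `min_reads` reads, spliced
#' to at least two partners, whose most-used partner carries at least
#' `major_fraction` of the reads, and whose exonic side lies in annotated
#' coding sequence. For `side = "3"` the anchors are donors and the
#' partners are 3' (acceptor) sites; for `side = "5"` vice versa. At every
#' offset from the major partner (excluding -`exclude`..+`exclude`), the
#' number of minor splice sites is compared to the number of AG (resp. GT)
#' dinucleotides that could form a splice site at that offset; the in-frame
#' fraction of minor sites is tested against 1/3 by a one-sided exact
#' binomial test.
#'
#' @param junctions aggregated junction table.
#' @param annotation annotation list (for coding-sequence filtering).
#' @param genome named character vector.
#' @param side `"3"` (minor acceptors near coding donors) or `"5"`.
#' @param window max |offset| in bp.
#' @param min_reads anchor coverage threshold (default 20).
#' @param major_fraction major-form share threshold (default 0.9).
#' @param exclude half-width of the ambiguity exclusion zone (default 2).
#' @return list with `profile` (offset, minor_count, opportunities, ratio,
#'   in_frame), `n_minor`, `n_in_frame`, `in_frame_fraction`, `p_value`.
#' @export
periodicity_profile <- function(junctions, annotation, genome,
                                side = c("3", "5"), window = 100L,
                                min_reads = 20L, major_fraction = 0.9,
                                exclude = 2L) {
  side <- match.arg(side)
  anchor_type <- if (side == "3") "donor" else "acceptor"
  partner_type <- if (side == "3") "acceptor" else "donor"
  j <- data.table::as.data.table(junctions)
  sites <- junction_sites(j)
  long <- data.table::data.table(
    chrom = j$chrom, strand = j$strand,
    anchor = if (side == "3") sites$donor else sites$acceptor,
    partner = if (side == "3") sites$acceptor else sites$donor,
    reads = j$reads)
  grp <- long[, .(total = sum(reads), partners = .N,
                  major = partner[which.max(reads)],
                  major_share = max(reads) / sum(reads)),
              by = .(chrom, strand, anchor)]
  grp <- grp[total >= min_reads & partners >= 2L &
               major_share >= major_fraction]
  if (nrow(grp) > 0L) {
    # anchors (and their major partner) must be annotated protein-coding
    ann <- annotated_sites(annotation)
    akey <- data.table::data.table(chrom = grp$chrom, strand = grp$strand,
                                   type = anchor_type, boundary = grp$anchor)
    mkey <- data.table::data.table(chrom = grp$chrom, strand = grp$strand,
                                   type = partner_type, boundary = grp$major)
    a_ann <- !is.na(ann[akey, on = c("chrom", "strand", "type", "boundary"),
                        which = TRUE, mult = "first"])
    m_ann <- !is.na(ann[mkey, on = c("chrom", "strand", "type", "boundary"),
                        which = TRUE, mult = "first"])
    a_cds <- site_region(akey, annotation) == "CDS"
    m_cds <- site_region(mkey, annotation) == "CDS"
    grp <- grp[a_ann & m_ann & a_cds & m_cds]
  }
  offs <- setdiff(seq(-window, window), seq(-exclude, exclude))
  if (nrow(grp) == 0L) {
    return(list(profile = data.table::data.table(
      offset = offs, minor_count = 0L, opportunities = 0L,
      ratio = NA_real_, in_frame = offs %% 3L == 0L),
      n_minor = 0L, n_in_frame = 0L, in_frame_fraction = NA_real_,
      p_value = NA_real_))
  }
  # minor sites and their transcript-orientation offsets from the major
  minors <- long[grp, on = c("chrom", "strand", "anchor")][partner != major]
  minors[, offset := ifelse(strand == "+", partner - major,
                            major - partner)]
  minors <- minors[abs(offset) > exclude & abs(offset) <= window]
  # dinucleotide opportunities at each offset around each major site
  need <- if (side == "3") "AG" else "GT"
  opp <- grp[rep(seq_len(nrow(grp)), each = length(offs))]
  opp[, offset := rep(offs, nrow(grp))]
  opp[, cand := ifelse(strand == "+", major + offset, major - offset)]
  opp[, dinuc := site_dinuc(genome, chrom, strand,
                            rep(partner_type, .N), cand)]
  opp_count <- opp[dinuc == need, .N, by = offset]
  minor_count <- minors[, .N, by = offset]
  prof <- data.table::data.table(offset = offs)
  prof[opp_count, opportunities := i.N, on = "offset"]
  prof[minor_count, minor_count := i.N, on = "offset"]
  prof[is.na(opportunities), opportunities := 0L]
  prof[is.na(minor_count), minor_count := 0L]
  prof[, ratio := ifelse(opportunities > 0L, minor_count / opportunities,
                         NA_real_)]
  prof[, in_frame := offset %% 3L == 0L]
  n_minor <- nrow(minors)
  n_if <- sum(minors$offset %% 3L == 0L)
  pv <- if (n_minor > 0L)
    stats::binom.test(n_if, n_minor, p = 1 / 3,
                      alternative = "greater")$p.value else NA_real_
  list(profile = prof[], n_minor = n_minor, n_in_frame = n_if,
       in_frame_fraction = if (n_minor > 0L) n_if / n_minor else NA_real_,
       p_value = pv)
}

#' Per-intron splicing error rates from conservation labels
#'
#' For every junction whose donor and acceptor are both highly conserved
#' (the reference introns), counts the fraction of reads involving either
#' of its splice sites that splice to an unconserved partner site. A read
#' of the reference junction itself involves both ends but is counted once;
#' junctions to intermediate-conservation partners are excluded from both
#' numerator and denominator (an alternative rate including them in the
#' denominator is also reported).
#'
#' @param junctions aggregated junction table.
#' @param labels site label table from [label_conservation()] covering all
#'   junction sites.
#' @return list with `introns` (per reference intron: counts, `error_rate`,
#'   `length`), `global_rate` (read-weighted), `global_rate_unweighted`,
#'   and `global_rate_incl_intermediate`.
#' @export
intron_error_rate <- function(junctions, labels) {
  j <- data.table::copy(data.table::as.data.table(junctions))
  j[, jid := .I]
  sites <- junction_sites(j)
  lab <- data.table::as.data.table(labels)
  get_label <- function(type, boundary) {
    q <- data.table::data.table(chrom = j$chrom, strand = j$strand,
                                type = type, boundary = boundary)
    lab[q, on = c("chrom", "strand", "type", "boundary"), label,
        mult = "first"]
  }
  j[, donor_boundary := sites$donor]
  j[, acceptor_boundary := sites$acceptor]
  j[, donor_label := get_label("donor", donor_boundary)]
  j[, acceptor_label := get_label("acceptor", acceptor_boundary)]
  j[is.na(donor_label), donor_label := "intermediate"]
  j[is.na(acceptor_label), acceptor_label := "intermediate"]

  # per-site sums of reads by the label of the junction's *other* end
  site_long <- data.table::rbindlist(list(
    j[, .(chrom, strand, type = "donor", boundary = donor_boundary,
          other = acceptor_label, reads, jid)],
    j[, .(chrom, strand, type = "acceptor", boundary = acceptor_boundary,
          other = donor_label, reads, jid)]))
  site_sum <- site_long[, .(unc = sum(reads[other == "unconserved"]),
                            cons = sum(reads[other == "conserved"]),
                            inter = sum(reads[other == "intermediate"])),
                        by = .(chrom, strand, type, boundary)]

  ref <- j[donor_label == "conserved" & acceptor_label == "conserved" &
             reads > 0L]
  if (nrow(ref) == 0L) {
    return(list(introns = ref, global_rate = NA_real_,
                global_rate_unweighted = NA_real_,
                global_rate_incl_intermediate = NA_real_))
  }
  dsum <- site_sum[ref[, .(chrom, strand, type = "donor",
                           boundary = donor_boundary)],
                   on = c("chrom", "strand", "type", "boundary")]
  asum <- site_sum[ref[, .(chrom, strand, type = "acceptor",
                           boundary = acceptor_boundary)],
                   on = c("chrom", "strand", "type", "boundary")]
  ref[, reads_to_unconserved := dsum$unc + asum$unc]
  # the reference junction's own reads appear in the conserved sums at both
  # of its ends; count them once
  ref[, reads_to_conserved := dsum$cons + asum$cons - reads]
  ref[, reads_intermediate := dsum$inter + asum$inter]
  ref[, denom := reads_to_conserved + reads_to_unconserved]
  ref <- ref[denom > 0L]
  ref[, error_rate := reads_to_unconserved / denom]
  ref[, length := end - start]
  list(introns = ref[],
       global_rate = sum(ref$reads_to_unconserved) / sum(ref$denom),
       global_rate_unweighted = mean(ref$error_rate),
       global_rate_incl_intermediate =
         sum(ref$reads_to_unconserved) /
         sum(ref$denom + ref$reads_intermediate))
}

#' Bin a per-intron table by a covariate and measure the trend
#'
#' Introns are split into `n_bins` equal-count bins of the covariate (ties
#' broken deterministically by table order); per bin, the mean error rate
#' and mean log10 covariate are computed. The monotone trend statistic is
#' the Spearman correlation of the bin means, and a cubic smoothing spline
#' (generalized cross-validation) is fitted as an overlay.
#'
#' @param tab per-intron table (e.g. `intron_error_rate()$introns`).
#' @param covariate name of the covariate column (`length`, `expression`,
#'   ...).
#' @param n_bins number of equal-count bins (default 100).
#' @param rate_col name of the response column.
#' @return list with `bins` (bin table), `spearman`, `spline` (the fit),
#'   `n`.
#' @export
bin_and_trend <- function(tab, covariate, n_bins = 100L,
                          rate_col = "error_rate") {
  t2 <- data.table::as.data.table(tab)
  if (nrow(t2) < n_bins)
    stop("need at least n_bins introns (", n_bins, "), got ", nrow(t2))
  ord <- order(t2[[covariate]])
  t2 <- t2[ord]
  n <- nrow(t2)
  t2[, bin := floor((seq_len(n) - 1L) * n_bins / n) + 1L]
  bins <- t2[, .(n = .N,
                 mean_rate = mean(get(rate_col)),
                 mean_log10_cov = mean(log10(get(covariate)))),
             by = bin]
  sp <- if (stats::sd(bins$mean_rate) == 0) 0 else suppressWarnings(
    stats::cor(bins$mean_log10_cov, bins$mean_rate, method = "spearman"))
  fit <- stats::smooth.spline(bins$mean_log10_cov, bins$mean_rate)
  list(bins = bins[], spearman = sp, spline = fit, n = n)
}

#' Gene expression as reads per exonic base, maximized over samples
#'
#' For each sample, the number of contiguously mapped reads starting in a
#' gene's exons is divided by the gene's total exonic length; the maximum
#' across samples is returned as the gene's expression level.
#'
#' @param annotation annotation list with `exons`.
#' @param alignments a single data.table (or list of them, one per sample)
#'   of contiguous alignments with `chrom` and `pos` (0-based start).
#' @return data.table `gene`, `expression`, and per-sample columns.
#' @export
expression_level <- function(annotation, alignments) {
  if (data.table::is.data.table(alignments)) alignments <- list(alignments)
  ex <- data.table::copy(annotation$exons)
  exlen <- ex[, .(exonic_length = sum(end - start)), by = gene]
  data.table::setorder(exlen, gene)
  if (any(exlen$exonic_length <= 0))
    stop("gene with zero-length exon set")
  ex2 <- ex[, .(chrom, start, end, gene)]
  data.table::setkey(ex2, chrom, start, end)
  vals <- lapply(alignments, function(al) {
    q <- data.table::data.table(chrom = al$chrom, start = al$pos,
                                end = al$pos + 1L)
    ov <- data.table::foverlaps(q, ex2, type = "within", nomatch = NULL)
    cnt <- ov[, .(n_reads = .N), by = gene]
    out <- merge(exlen, cnt, by = "gene", all.x = TRUE)
    out[is.na(n_reads), n_reads := 0L]
    out[, n_reads / exonic_length]
  })
  out <- data.table::copy(exlen)
  for (i in seq_along(vals)) out[, paste0("sample_", i) := vals[[i]]]
  out[, expression := do.call(pmax, vals)]
  out[]
}

#' Residual correction of one covariate association for another
#'
#' Regresses the error rate on `log10(covariate_a)` and re-examines the
#' association of the residuals with `covariate_b`, binning both raw and
#' residual rates. Removes the part of an association explained by a
#' confounding covariate.
#'
#' @param tab per-intron table.
#' @param covariate_a covariate to correct for.
#' @param covariate_b covariate whose association is re-examined.
#' @param n_bins bins for the trend summaries.
#' @param rate_col response column name.
#' @return list with `raw` and `corrected` trend lists (as from
#'   [bin_and_trend()]) and the fitted `model`.
#' @export
residual_correction <- function(tab, covariate_a, covariate_b,
                                n_bins = 100L, rate_col = "error_rate") {
  t2 <- data.table::copy(data.table::as.data.table(tab))
  for (cv in c(covariate_a, covariate_b)) {
    if (length(unique(t2[[cv]])) < 2L)
      stop("degenerate (constant) covariate: ", cv)
  }
  t2[, .log_a := log10(get(covariate_a))]
  fit <- stats::lm(stats::reformulate(".log_a", rate_col), data = t2)
  t2[, .resid := stats::residuals(fit)]
  raw <- bin_and_trend(t2, covariate_b, n_bins = n_bins,
                       rate_col = rate_col)
  corrected <- bin_and_trend(t2, covariate_b, n_bins = n_bins,
                             rate_col = ".resid")
  list(raw = raw, corrected = corrected, model = fit)
}

#' Polymorphism profile around splice sites
#'
#' Fraction of sites carrying a variant at each signed offset (same offset
#' convention as [conservation_profile()]).
#'
#' @param sites data.table with `chrom`, `strand`, `type`, `boundary`.
#' @param variants data.table with `chrom`, `pos` (0-based).
#' @param window half-window in bp.
#' @return data.table `offset`, `side`, `fraction_polymorphic`, `n_sites`.
#' @export
polymorphism_profile <- function(sites, variants, window = 100L) {
  s <- data.table::as.data.table(sites)
  v <- unique(data.table::as.data.table(variants)[, .(chrom, pos)])
  offs <- seq(-window, window - 1L)
  grid <- s[rep(seq_len(nrow(s)), each = length(offs))]
  grid[, offset := rep(offs, nrow(s))]
  grid[, pos := site_offset_positions(type, strand, boundary, offset)]
  grid[, hit := !is.na(v[grid, on = c("chrom", "pos"), which = TRUE,
                         mult = "first"])]
  prof <- grid[, .(fraction_polymorphic = mean(hit), n_sites = .N),
               by = offset]
  prof[, side := ifelse(offset >= 0L, "intronic", "exonic")]
  data.table::setorder(prof, offset)
  prof[]
}

#' Expected fraction of transcripts with at least one splicing error
#'
#' With per-splicing-reaction error rate `r` and `n` independent reactions,
#' the expected mis-spliced transcript fraction is `1 - (1 - r)^n`.
#'
#' @param r per-intron (per-reaction) error rate in `[0, 1]`.
#' @param n number of splicing reactions.
#' @return expected mis-spliced fraction.
#' @export
per_gene_missplice <- function(r, n) {
  stopifnot(all(r >= 0 & r <= 1), all(n >= 0))
  1 - (1 - r)^n
}
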