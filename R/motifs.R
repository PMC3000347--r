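# Hexamer enrichment near unconserved "noise" splice sites versus matched
# unused decoy sites, ESE-list overlap, and positional profiles around
# constitutive exons.

#' Select noise splice sites and matched decoy sites
#'
#' Noise sites are the unannotated ends of junctions whose other end is
#' annotated, restricted to unconserved sites more than `min_dist` bases
#' from any annotated splice site. Each noise site is matched with a decoy:
#' the nearest unused GT (for donor-type sites) or AG (acceptor-type)
#' dinucleotide lying between the noise site and its nearest annotated
#' site, never observed as a spliced site in the junction table. Sites
#' without an eligible decoy are dropped.
#'
#' @param junctions aggregated junction table.
#' @param labels site conservation labels from [label_conservation()].
#' @param annotation annotation list.
#' @param genome named character vector.
#' @param min_dist exclusion distance from annotated sites (default 50).
#' @return data.table of noise sites (`chrom`, `strand`, `type`,
#'   `boundary`, `partner_boundary`, `decoy_boundary`), with counts of
#'   dropped sites in attributes.
#' @export
select_noise_and_decoy <- function(junctions, labels, annotation, genome,
                                   min_dist = 50L) {
  cls <- classify_junctions(junctions, annotation, near_bp = min_dist)
  one_end <- cls[annotation_class %in% c("new_3ss", "new_5ss")]
  if (nrow(one_end) == 0L)
    stop("no junction with exactly one annotated end; cannot build a ",
         "noise site set (", nrow(cls), " junctions supplied)")
  noise <- data.table::rbindlist(list(
    one_end[annotation_class == "new_3ss",
            .(chrom, strand, type = "acceptor", boundary = acceptor_boundary,
              partner_boundary = donor_boundary, dist = acceptor_dist)],
    one_end[annotation_class == "new_5ss",
            .(chrom, strand, type = "donor", boundary = donor_boundary,
              partner_boundary = acceptor_boundary, dist = donor_dist)]))
  noise <- unique(noise, by = c("chrom", "strand", "type", "boundary"))
  # distance to nearest annotated site of either type
  ann <- annotated_sites(annotation)
  noise[, any_dist := {
    d <- rep(NA_real_, .N)
    for (key in unique(paste(chrom, strand))) {
      parts <- strsplit(key, " ")[[1]]
      sel <- chrom == parts[1] & strand == parts[2]
      av <- sort(ann[chrom == parts[1] & strand == parts[2], boundary])
      if (length(av) == 0L) next
      idx <- findInterval(boundary[sel], av)
      lo <- av[pmax(idx, 1L)]
      hi <- av[pmin(idx + 1L, length(av))]
      d[sel] <- pmin(abs(boundary[sel] - lo), abs(boundary[sel] - hi))
    }
    d
  }]
  lab <- data.table::as.data.table(labels)
  noise[lab, label := i.label, on = c("chrom", "strand", "type", "boundary")]
  n0 <- nrow(noise)
  noise <- noise[label == "unconserved" & !is.na(any_dist) &
                   any_dist > min_dist]
  n_dropped_filter <- n0 - nrow(noise)
  if (nrow(noise) == 0L)
    stop("no unconserved noise site survives the distance filter (",
         n0, " candidate sites, ", n_dropped_filter, " dropped)")

  # used sites of each type, to exclude from decoy candidacy
  sites <- junction_sites(junctions)
  used <- unique(data.table::data.table(
    chrom = rep(junctions$chrom, 2L), strand = rep(junctions$strand, 2L),
    type = rep(c("donor", "acceptor"), each = nrow(junctions)),
    boundary = c(sites$donor, sites$acceptor)))

  need <- ifelse(noise$type == "donor", "GT", "AG")
  decoy <- rep(NA_integer_, nrow(noise))
  for (i in seq_len(nrow(noise))) {
    b <- noise$boundary[i]
    # nearest annotated site (same chrom/strand), on either side
    av <- ann[chrom == noise$chrom[i] & strand == noise$strand[i], boundary]
    if (length(av) == 0L) next
    nearest <- av[which.min(abs(av - b))]
    lo <- min(b, nearest) + 1L
    hi <- max(b, nearest) - 1L
    if (hi < lo) next
    cand <- lo:hi
    dn <- site_dinuc(genome, rep(noise$chrom[i], length(cand)),
                     rep(noise$strand[i], length(cand)),
                     rep(noise$type[i], length(cand)), cand)
    cand <- cand[!is.na(dn) & dn == need[i]]
    if (length(cand) == 0L) next
    u <- used[chrom == noise$chrom[i] & strand == noise$strand[i] &
                type == noise$type[i], boundary]
    cand <- setdiff(cand, u)
    if (length(cand) == 0L) next
    decoy[i] <- cand[which.min(abs(cand - b))]
  }
  noise[, decoy_boundary := decoy]
  n_no_decoy <- sum(is.na(decoy))
  out <- noise[!is.na(decoy_boundary),
               .(chrom, strand, type, boundary, partner_boundary,
                 decoy_boundary)]
  data.table::setattr(out, "n_dropped_filter", n_dropped_filter)
  data.table::setattr(out, "n_no_decoy", n_no_decoy)
  out
}

#' Extract exonic and intronic flanking windows around splice sites
#'
#' Takes `window` bases around each site, split as `window/2` exonic and
#' `window/2` intronic, removes the type-specific exclusion zones (donor:
#' 5 intronic + 5 exonic; acceptor: 20 intronic + 2 exonic), and returns
#' the two sub-windows strand-oriented so the exonic side reads 5' to 3'
#' along the transcript. Windows truncated at contig edges are flagged.
#'
#' @param sites data.table with `chrom`, `strand`, `type`, `boundary`.
#' @param genome named character vector.
#' @param window total window size (default 100).
#' @param donor_excl,acceptor_excl 2-vectors `(intronic, exonic)` exclusion
#'   widths.
#' @return list with `exonic`, `intronic` character vectors and `truncated`
#'   flags.
#' @export
extract_flanks <- function(sites, genome, window = 100L,
                           donor_excl = c(5L, 5L),
                           acceptor_excl = c(20L, 2L)) {
  s <- data.table::as.data.table(sites)
  half <- window %/% 2L
  excl_in <- ifelse(s$type == "donor", donor_excl[1], acceptor_excl[1])
  excl_ex <- ifelse(s$type == "donor", donor_excl[2], acceptor_excl[2])
  get_win <- function(o_from, o_to) {
    p1 <- site_offset_positions(s$type, s$strand, s$boundary, o_from)
    p2 <- site_offset_positions(s$type, s$strand, s$boundary, o_to)
    glo <- pmin(p1, p2)
    ghi <- pmax(p1, p2) + 1L
    chrlen <- nchar(unlist(genome[s$chrom], use.names = FALSE))
    trunc <- glo < 0L | ghi > chrlen
    glo2 <- pmax(glo, 0L)
    ghi2 <- pmin(ghi, chrlen)
    seqs <- unname(substr(unlist(genome[s$chrom], use.names = FALSE),
                          glo2 + 1L, ghi2))
    flip <- p1 > p2
    seqs[flip] <- revcomp_chr(seqs[flip])
    list(seq = seqs, trunc = unname(trunc))
  }
  ex <- get_win(-half, -(excl_ex + 1L))
  intr <- get_win(excl_in, half - 1L)
  list(exonic = ex$seq, intronic = intr$seq,
       truncated = ex$trunc | intr$trunc)
}

#' Overlapping hexamer counts
#'
#' Counts every overlapping 6-mer over a set of sequences (windows
#' containing non-ACGT letters are skipped), over the full 4096-hexamer
#' alphabet.
#'
#' @param sequences character vector.
#' @return named integer vector of length 4096.
#' @export
hexamer_counts <- function(sequences) {
  sequences <- sequences[nchar(sequences) >= 6L]
  if (length(sequences) == 0L) {
    hex <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6L)
    return(stats::setNames(integer(4096L), hex))
  }
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences), width = 6L)
  colSums(m)
}

#' Per-hexamer enrichment test: noise versus decoy windows
#'
#' For every hexamer, a 2x2 table (this hexamer vs all others, noise vs
#' decoy) is tested by a chi-square test with 1 df (no continuity
#' correction); when any expected cell is below 5 the p-value falls back to
#' Fisher's exact test (flagged). The log2 enrichment is the ratio of
#' hexamer frequencies with a pseudocount of 1 on all four cells (ratio
#' only, not the test). Significance is Bonferroni-corrected over the 4096
#' hexamers.
#'
#' @param counts_noise,counts_decoy named counts from [hexamer_counts()].
#' @param alpha family-wise significance level (default 0.05).
#' @return data.table: `hexamer`, counts, `log2_enrichment`, `chi2`, `p`,
#'   `p_adj`, `significant`, `exact` flag.
#' @export
enrichment_test <- function(counts_noise, counts_decoy, alpha = 0.05) {
  stopifnot(length(counts_noise) == length(counts_decoy))
  tn <- sum(counts_noise)
  td <- sum(counts_decoy)
  if (tn <= 0 || td <= 0) stop("empty count vector")
  a <- as.double(counts_noise); cc <- as.double(counts_decoy)
  b <- tn - a; d <- td - cc
  n <- tn + td
  chi2 <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  chi2[!is.finite(chi2)] <- 0
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  # expected cells under independence
  e_min <- pmin((a + cc) * tn, (a + cc) * td, (b + d) * tn, (b + d) * td) / n
  exact <- e_min < 5
  if (any(exact)) {
    p[exact] <- vapply(which(exact), function(i) {
      stats::fisher.test(matrix(c(a[i], b[i], cc[i], d[i]), 2L))$p.value
    }, numeric(1))
  }
  log2_enr <- log2(((a + 1) / (tn + 2)) / ((cc + 1) / (td + 2)))
  p_adj <- pmin(1, p * length(a))
  data.table::data.table(
    hexamer = names(counts_noise), count_noise = as.integer(a),
    count_decoy = as.integer(cc), log2_enrichment = log2_enr,
    chi2 = chi2, p = p, p_adj = p_adj,
    significant = p_adj < alpha, exact = exact)
}

#' Overlap of enriched hexamers with an ESE reference list
#'
#' Fraction of reference exonic-splicing-enhancer hexamers positively
#' enriched exonic of both the 5' and the 3' noise splice sites, with a
#' chi-square test of ESE membership against the both-positive enrichment
#' sign.
#'
#' @param enrich_5ex,enrich_3ex [enrichment_test()] tables for the exonic
#'   windows of 5' and 3' noise sites.
#' @param ese_list character vector of ESE hexamers.
#' @return list with `fraction`, `background_fraction`, `p_value`, `table`.
#' @export
ese_overlap <- function(enrich_5ex, enrich_3ex, ese_list) {
  bad <- !grepl("^[ACGT]{6}$", ese_list)
  if (any(bad)) stop("malformed hexamers in ESE list")
  stopifnot(identical(enrich_5ex$hexamer, enrich_3ex$hexamer))
  both_pos <- enrich_5ex$log2_enrichment > 0 & enrich_3ex$log2_enrichment > 0
  is_ese <- enrich_5ex$hexamer %in% ese_list
  if (!any(is_ese)) {
    return(list(fraction = 0, background_fraction = mean(both_pos),
                p_value = NA_real_, table = table(is_ese, both_pos)))
  }
  tab <- table(factor(is_ese, c(FALSE, TRUE)),
               factor(both_pos, c(FALSE, TRUE)))
  pv <- tryCatch(stats::chisq.test(tab, correct = FALSE)$p.value,
                 warning = function(w)
                   suppressWarnings(stats::chisq.test(tab,
                                                      correct = FALSE)$p.value))
  list(fraction = mean(both_pos[is_ese]),
       background_fraction = mean(both_pos[!is_ese]),
       p_value = pv, table = tab)
}

#' Constitutive internal exons from a junction table
#'
#' Internal exons whose two flanking splice sites each show a single
#' observed junction partner.
#'
#' @param junctions aggregated junction table.
#' @param annotation annotation list.
#' @return data.table of exons (`gene`, `chrom`, `strand`, `start`, `end`).
#' @export
constitutive_exons <- function(junctions, annotation) {
  j <- data.table::as.data.table(junctions)
  sites <- junction_sites(j)
  long <- data.table::data.table(
    chrom = rep(j$chrom, 2L), strand = rep(j$strand, 2L),
    type = rep(c("donor", "acceptor"), each = nrow(j)),
    boundary = c(sites$donor, sites$acceptor))
  pc <- long[, .(partners = .N), by = .(chrom, strand, type, boundary)]
  ex <- data.table::copy(annotation$exons)
  data.table::setorder(ex, gene, start)
  ex[, idx := seq_len(.N), by = gene]
  ex[, n := .N, by = gene]
  internal <- ex[idx > 1L & idx < n]
  if (nrow(internal) == 0L) return(internal)
  # acceptor feeds the exon start side on '+', donor its end side
  up_type <- ifelse(internal$strand == "+", "acceptor", "donor")
  dn_type <- ifelse(internal$strand == "+", "donor", "acceptor")
  q_up <- data.table::data.table(chrom = internal$chrom,
                                 strand = internal$strand, type = up_type,
                                 boundary = internal$start)
  q_dn <- data.table::data.table(chrom = internal$chrom,
                                 strand = internal$strand, type = dn_type,
                                 boundary = internal$end)
  p_up <- pc[q_up, partners, on = c("chrom", "strand", "type", "boundary"),
             mult = "first"]
  p_dn <- pc[q_dn, partners, on = c("chrom", "strand", "type", "boundary"),
             mult = "first"]
  internal[!is.na(p_up) & p_up == 1L & !is.na(p_dn) & p_dn == 1L,
           .(gene, chrom, strand, start, end)]
}

#' Positional profile of a hexamer set around exon boundaries
#'
#' For each position relative to an exon boundary (transcript orientation;
#' negative offsets upstream of the anchor), the fraction of exons whose
#' hexamer starting at that position belongs to the given set. Exons
#' shorter than the window are skipped.
#'
#' @param hexamer_set character vector of hexamers.
#' @param exons data.table of exons (e.g. from [constitutive_exons()]).
#' @param genome named character vector.
#' @param window half-window in bp.
#' @param anchor `"start"` (exon 5' boundary) or `"end"`.
#' @return data.table `offset`, `fraction`, `n_exons`.
#' @export
positional_profile <- function(hexamer_set, exons, genome, window = 50L,
                               anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  ex <- data.table::as.data.table(exons)
  ex <- ex[end - start >= window]
  offs <- seq(-window, window - 1L)
  if (nrow(ex) == 0L)
    return(data.table::data.table(offset = offs, fraction = NA_real_,
                                  n_exons = 0L))
  hexset <- unique(toupper(hexamer_set))
  grid <- ex[rep(seq_len(nrow(ex)), each = length(offs))]
  grid[, offset := rep(offs, nrow(ex))]
  plus <- grid$strand == "+"
  at_start <- anchor == "start"
  g0 <- if (at_start) ifelse(plus, grid$start, grid$end) else
    ifelse(plus, grid$end, grid$start)
  hstart <- ifelse(plus, g0 + grid$offset, g0 - grid$offset - 6L)
  grid[, hexamer := {
    out <- rep(NA_character_, .N)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      L <- nchar(genome[[ch]])
      ok <- sel[hstart[sel] >= 0L & hstart[sel] + 6L <= L]
      out[ok] <- substr(rep(genome[[ch]], length(ok)), hstart[ok] + 1L,
                        hstart[ok] + 6L)
    }
    out[!plus & !is.na(out)] <- revcomp_chr(out[!plus & !is.na(out)])
    out
  }]
  prof <- grid[!is.na(hexamer),
               .(fraction = mean(hexamer %in% hexset), n_exons = .N),
               by = offset]
  data.table::setorder(prof, offset)
  prof[]
}
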