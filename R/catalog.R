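#' Split junctions into canonical, control and other dinucleotide classes
#'
#' A junction is canonical when any placement in its shift-equivalence class
#' has intron dinucleotides GT-AG or GC-AG (on either strand reading);
#' control when some placement matches the control pairs GT-TC or GC-TC
#' (the complement of the acceptor consensus) and none is canonical;
#' otherwise other. Canonical takes precedence over control.
#'
#' @param junctions aggregated junction table with a `dinuc_class` column
#'   (as produced by [aggregate_junctions()], whose per-junction class
#'   already encodes the best placement in the equivalence class).
#' @return list with `canonical`, `control`, `other` subsets and the counts
#'   `n_canonical`, `n_control`, `n_other`.
#' @export
filter_canonical <- function(junctions) {
  j <- data.table::as.data.table(junctions)
  canonical <- j[dinuc_class %in% c("GT-AG", "GC-AG")]
  control <- j[dinuc_class == "control"]
  other <- j[!dinuc_class %in% c("GT-AG", "GC-AG", "control")]
  list(canonical = canonical, control = control, other = other,
       n_canonical = nrow(canonical), n_control = nrow(control),
       n_other = nrow(other))
}

#' Control-dinucleotide false discovery rate of junction calls
#'
#' Assuming every control-dinucleotide junction is a false positive, and
#' that false junctions hit the control pair as often as the canonical pair
#' (2 of 16 dinucleotide pairs each, given a GT/GC start), the FDR of the
#' canonical set is the ratio of control to canonical junction counts.
#'
#' @param n_canonical number of canonical (GT-AG / GC-AG) junctions.
#' @param n_control number of control (GT-TC / GC-TC) junctions.
#' @return the estimated FDR (a fraction).
#' @export
estimate_fdr <- function(n_canonical, n_control) {
  if (n_canonical <= 0) stop("FDR undefined: no canonical junctions")
  n_control / n_canonical
}

#' Unique splice-site table of a junction set
#'
#' Explodes a junction table into its donor and acceptor sites, keyed by
#' (chrom, strand, type, boundary): the donor boundary is the intron start
#' on "+" and the intron end on "-".
#'
#' @param junctions aggregated junction table.
#' @return data.table with `chrom`, `strand`, `type`, `boundary`.
#' @export
junction_site_table <- function(junctions) {
  j <- data.table::as.data.table(junctions)
  s <- junction_sites(j)
  unique(data.table::data.table(
    chrom = rep(j$chrom, 2L), strand = rep(j$strand, 2L),
    type = rep(c("donor", "acceptor"), each = nrow(j)),
    boundary = c(s$donor, s$acceptor)))
}

# Annotated splice-site tables (donor and acceptor boundaries) from an
# annotation list (exons/introns/cds, as from read_annotation() or
# annotation_from_truth()).
annotated_sites <- function(annotation) {
  intr <- annotation$introns
  sites <- junction_sites(intr)
  unique(data.table::data.table(
    chrom = rep(intr$chrom, 2L), strand = rep(intr$strand, 2L),
    type = rep(c("donor", "acceptor"), each = nrow(intr)),
    boundary = c(sites$donor, sites$acceptor)))
}

#' Annotation in the catalog's internal form, from a truth set
#'
#' @param truth a `truth_set`.
#' @return list of data.tables `exons`, `introns`, `cds` (0-based
#'   half-open).
#' @export
annotation_from_truth <- function(truth) {
  list(exons = truth$exons[, .(gene, chrom, strand, start, end)],
       introns = truth$introns[, .(gene, chrom, strand, start, end)],
       cds = truth$cds)
}

#' Classify junctions against annotation (five-way)
#'
#' Classes: `known_junction` (the intron is annotated), `both_known_new_pairing`
#' (both splice sites annotated but never spliced together),
#' `new_3ss` (5' site annotated, 3' not), `new_5ss` (3' annotated, 5' not),
#' `both_new` (neither). Per-end distances to the nearest annotated site of
#' the same type are reported, with `near` flags at the given threshold.
#'
#' @param junctions aggregated junction table.
#' @param annotation annotation list (union of gene-model inputs).
#' @param near_bp distance defining "near a known site" (default 50).
#' @return the junction table with `annotation_class`, per-end annotated
#'   flags, distances and near flags, plus a `summary` attribute with the
#'   unannotated junction and read fractions.
#' @export
classify_junctions <- function(junctions, annotation, near_bp = 50L) {
  j <- data.table::copy(data.table::as.data.table(junctions))
  if (nrow(annotation$introns) == 0L) {
    warning("empty annotation: all junctions classified both_new")
    j[, annotation_class := "both_new"]
    return(j[])
  }
  ann_sites <- annotated_sites(annotation)
  intr <- annotation$introns
  sites <- junction_sites(j)
  j[, `:=`(donor_boundary = sites$donor, acceptor_boundary = sites$acceptor)]
  j[, junction_known := !is.na(
    intr[j, on = c("chrom", "strand", "start", "end"), which = TRUE,
         mult = "first"])]
  for (ty in c("donor", "acceptor")) {
    ann <- ann_sites[type == ty]
    bcol <- paste0(ty, "_boundary")
    known <- !is.na(ann[j, on = c("chrom", "strand",
                                  paste0("boundary==", bcol)),
                        which = TRUE, mult = "first"])
    # distance to nearest annotated site of this type
    dist <- rep(NA_real_, nrow(j))
    for (key in unique(paste(j$chrom, j$strand))) {
      parts <- strsplit(key, " ")[[1]]
      sel <- j$chrom == parts[1] & j$strand == parts[2]
      av <- sort(ann[chrom == parts[1] & strand == parts[2], boundary])
      if (length(av) == 0L) next
      b <- j[[bcol]][sel]
      idx <- findInterval(b, av)
      lo <- av[pmax(idx, 1L)]
      hi <- av[pmin(idx + 1L, length(av))]
      dist[sel] <- pmin(abs(b - lo), abs(b - hi))
    }
    j[, paste0(ty, "_annotated") := known]
    j[, paste0(ty, "_dist") := dist]
    j[, paste0(ty, "_near") := !is.na(dist) & dist <= near_bp]
  }
  j[, annotation_class := data.table::fcase(
    junction_known, "known_junction",
    donor_annotated & acceptor_annotated, "both_known_new_pairing",
    donor_annotated & !acceptor_annotated, "new_3ss",
    !donor_annotated & acceptor_annotated, "new_5ss",
    default = "both_new")]
  unann <- j$annotation_class != "known_junction"
  attr(j, "summary") <- list(
    n = nrow(j),
    fraction_unannotated = mean(unann),
    fraction_reads_unannotated = sum(j$reads[unann]) / sum(j$reads))
  j[]
}

#' Per-splice-site usage: partner counts and major-form fractions
#'
#' For every splice site covered by at least `min_coverage` reads, counts
#' the number of distinct partner sites it is spliced to and the fraction of
#' its reads on the most-used ("major") partner, optionally stratified by
#' CDS/UTR/unannotated region of the exonic side.
#'
#' @param junctions aggregated junction table.
#' @param min_coverage minimum total reads per site (default 50).
#' @param annotation optional annotation list for region stratification.
#' @return list with `sites` table and `summary` (mean partner count, mean
#'   major fraction, by site type and region).
#' @export
splice_site_usage <- function(junctions, min_coverage = 50L,
                              annotation = NULL) {
  j <- data.table::as.data.table(junctions)
  sites <- junction_sites(j)
  long <- data.table::data.table(
    chrom = rep(j$chrom, 2L), strand = rep(j$strand, 2L),
    type = rep(c("donor", "acceptor"), each = nrow(j)),
    boundary = c(sites$donor, sites$acceptor),
    partner = c(sites$acceptor, sites$donor),
    reads = rep(j$reads, 2L))
  per_site <- long[, .(total = sum(reads), partners = .N,
                       major_fraction = max(reads) / sum(reads)),
                   by = .(chrom, strand, type, boundary)]
  per_site <- per_site[total >= min_coverage]
  if (nrow(per_site) == 0L) {
    warning("no splice site reaches the coverage threshold")
    return(list(sites = per_site, summary = NULL))
  }
  if (!is.null(annotation)) {
    per_site[, region := site_region(per_site, annotation)]
  }
  byv <- c("type", if ("region" %in% names(per_site)) "region")
  summary <- per_site[, .(n_sites = .N, mean_partners = mean(partners),
                          mean_major_fraction = mean(major_fraction)),
                      by = byv]
  list(sites = per_site[], summary = summary[],
       mean_partners = mean(per_site$partners),
       mean_major_fraction = mean(per_site$major_fraction))
}

# Region (CDS / UTR / unannotated) of the exonic-side base of each site.
site_region <- function(sites, annotation) {
  exonic_pos <- ifelse(sites$type == "donor",
                       ifelse(sites$strand == "+", sites$boundary - 1L,
                              sites$boundary),
                       ifelse(sites$strand == "+", sites$boundary,
                              sites$boundary - 1L))
  in_tab <- function(tab, chrom, pos) {
    if (nrow(tab) == 0L) return(rep(FALSE, length(pos)))
    q <- data.table::data.table(chrom = chrom, start = pos,
                                end = pos + 1L)
    t2 <- data.table::copy(tab)[, .(chrom, start, end)]
    data.table::setkey(t2, chrom, start, end)
    hits <- data.table::foverlaps(q, t2, type = "within", which = TRUE,
                                  mult = "first")
    !is.na(hits)
  }
  in_cds <- in_tab(annotation$cds, sites$chrom, exonic_pos)
  in_exon <- in_tab(annotation$exons, sites$chrom, exonic_pos)
  data.table::fcase(in_cds, "CDS", in_exon, "UTR", default = "unannotated")
}

#' Junction discovery saturation curve
#'
#' Subsamples junction-spanning reads without replacement at each depth and
#' counts the distinct (unannotated) junctions discovered, averaged over
#' replicates. The curve is monotone non-decreasing in expectation
#' (a species-accumulation curve over a finite junction pool).
#'
#' @param read_junctions data.table mapping each junction-spanning read to
#'   its junction (columns `read_id`, `chrom`, `start`, `end`, `strand`, and
#'   optionally `annotated`).
#' @param depth_grid read depths to evaluate.
#' @param n_reps subsample replicates per depth.
#' @param seed integer seed.
#' @param unannotated_only count only unannotated junctions (requires an
#'   `annotated` column).
#' @return data.table with `depth`, `mean_junctions`, `sd_junctions`.
#' @export
saturation_curve <- function(read_junctions, depth_grid, n_reps = 3L,
                             seed = 1L, unannotated_only = FALSE) {
  set.seed(seed)
  rj <- data.table::as.data.table(read_junctions)
  if (unannotated_only) {
    if (!"annotated" %in% names(rj))
      stop("unannotated_only requires an 'annotated' column")
    rj <- rj[annotated == FALSE]
  }
  rj <- unique(rj, by = c("read_id", "chrom", "start", "end", "strand"))
  reads <- unique(rj$read_id)
  n <- length(reads)
  if (max(depth_grid) > n)
    warning("depth grid truncated to the number of available reads")
  depth_grid <- sort(unique(pmin(depth_grid, n)))
  rj[, jkey := paste(chrom, start, end, strand)]
  out <- lapply(depth_grid, function(d) {
    counts <- vapply(seq_len(n_reps), function(r) {
      sub <- sample(reads, d)
      rj[read_id %in% sub, data.table::uniqueN(jkey)]
    }, numeric(1))
    data.table::data.table(depth = d, mean_junctions = mean(counts),
                           sd_junctions = stats::sd(counts))
  })
  data.table::rbindlist(out)
}
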