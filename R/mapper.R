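#' Build a k-mer seed index over a genome
#'
#' Indexes every forward-strand k-mer of the genome (k-mers containing N are
#' skipped) in a hash map for O(1) expected lookup. Reads are later matched
#' on both strands by also querying their reverse complement.
#'
#' @param genome named character vector of chromosome sequences.
#' @param k seed length (default 20, the split-end length).
#' @return a `seed_index` object.
#' @export
build_index <- function(genome, k = 20L) {
  if (k < 12L) stop("seed length k must be >= 12")
  xp <- si_build(names(genome), unname(genome), as.integer(k))
  st <- si_stats(xp)
  if (st$n_positions == 0) warning("genome contains no indexable k-mers")
  structure(list(ptr = xp, k = as.integer(k), chroms = names(genome),
                 genome = genome,
                 n_kmers = st$n_kmers, n_positions = st$n_positions),
            class = "seed_index")
}

#' Query a seed index for the occurrences of one k-mer
#'
#' @param index a `seed_index`.
#' @param kmer a string of length `k`.
#' @return data.table of `chrom`, `pos` (0-based forward-strand starts);
#'   empty if absent.
#' @export
query_index <- function(index, kmer) {
  hits <- data.table::as.data.table(si_query(index$ptr, kmer))
  if (nrow(hits) > 0L) hits[, chrom := index$chroms[chrom]]
  hits[]
}

# Default mapper parameters; thresholds mirror the discovery procedure:
# <=2 mismatches for a verified full-read placement, >=10 bases on each
# side of a junction breakpoint, intron length in (50, 20000].
mapper_params <- function(max_mismatch = 2L, min_overhang = 10L,
                          min_intron = 51L, max_intron = 20000L,
                          discard_short_both = TRUE) {
  list(max_mismatch = as.integer(max_mismatch),
       min_overhang = as.integer(min_overhang),
       min_intron = as.integer(min_intron),
       max_intron = as.integer(max_intron),
       discard_short_both = isTRUE(discard_short_both))
}

#' Contiguous (full-length) read mapping
#'
#' Places each read on either strand by exact seed lookup of its first and
#' last k bases and full-length mismatch verification. A read is uniquely
#' mapped when exactly one locus attains the minimum mismatch count and no
#' second locus lies within one additional mismatch; reads that map
#' contiguously (uniquely or not) are excluded from junction discovery.
#'
#' @param reads character vector of read sequences.
#' @param index a `seed_index`.
#' @param max_mismatch maximum mismatches for a valid placement.
#' @return data.table with `status` (`"unique"`, `"multi"`, `"unmapped"`),
#'   `chrom`, `pos` (0-based), `strand`, `mm`.
#' @export
map_contiguous <- function(reads, index, max_mismatch = 2L) {
  out <- data.table::as.data.table(
    cpp_map_contiguous(index$ptr, reads, as.integer(max_mismatch)))
  out[, status := c("unique", "multi", "unmapped")[status + 1L]]
  out[, chrom := ifelse(is.na(chrom), NA_character_, index$chroms[chrom])]
  out[]
}

#' Map the two ends of a read independently
#'
#' Takes the first `k` and last `k` bases of the read (overlapping for reads
#' shorter than `2k`) and looks each up in the seed index, in both read
#' orientations. An end is uniquely mapped when its k-mer occurs exactly
#' once in the genome.
#'
#' @param reads character vector of read sequences (length >= k).
#' @param index a `seed_index`.
#' @return data.table with one row per read and orientation: hit counts and
#'   the unique position of each end (NA unless unique).
#' @export
split_map <- function(reads, index) {
  out <- data.table::as.data.table(cpp_split_map(index$ptr, reads))
  out[, first_chrom := ifelse(first_nhits == 1L, index$chroms[first_chrom],
                              NA_character_)]
  out[, last_chrom := ifelse(last_nhits == 1L, index$chroms[last_chrom],
                             NA_character_)]
  out[first_nhits != 1L, first_pos := NA_real_]
  out[last_nhits != 1L, last_pos := NA_real_]
  out[]
}

#' Enumerate splice junctions consistent with two mapped read ends
#'
#' For every breakpoint offset `b` with at least `min_overhang` bases on
#' each side, the read is reconstructed as the concatenation of two genomic
#' segments anchored at the two end alignments; the candidates with the
#' minimum total mismatch count are returned, each with its coordinate-shift
#' equivalence class and canonical placement.
#'
#' @param read one read sequence (already in the orientation in which its
#'   ends mapped).
#' @param first,last lists/rows with `chrom` and `pos` (0-based) of the
#'   uniquely mapped first and last ends.
#' @param index a `seed_index`.
#' @param params a [mapper_params()] list.
#' @return data.table of junction candidates (possibly empty): canonical
#'   intron interval, breakpoint, mismatches, placement count, dinucleotide
#'   class and strand.
#' @export
enumerate_junctions <- function(read, first, last, index,
                                params = mapper_params()) {
  ci <- match(first$chrom, index$chroms)
  cl <- match(last$chrom, index$chroms)
  out <- data.table::as.data.table(cpp_enumerate_junctions(
    index$ptr, read, ci, as.double(first$pos), cl, as.double(last$pos),
    params$min_overhang, params$max_mismatch, params$min_intron,
    params$max_intron))
  if (nrow(out) > 0L) {
    out[, chrom := index$chroms[chrom]]
    out[, dinuc_class := class_label(class_code)]
  }
  out[]
}

#' Extend-and-search junction recovery from a single mapped end
#'
#' Extends the unique end alignment base by base without allowing a
#' mismatch, then searches the intron-length window (downstream of a mapped
#' first end, upstream of a mapped last end) for a perfect match to the
#' remainder of the read. A candidate is returned only when the remainder is
#' at least `min_overhang` bases long and matches at exactly one position.
#'
#' @param read one read sequence (oriented as mapped).
#' @param end list/row with `which` (`"first"` or `"last"`), `chrom`, `pos`.
#' @param index a `seed_index`.
#' @param params a [mapper_params()] list.
#' @return one-row data.table (a junction candidate) or an empty one.
#' @export
extend_and_search <- function(read, end, index, params = mapper_params()) {
  ci <- match(end$chrom, index$chroms)
  we <- if (identical(end$which, "last")) 1L else 0L
  out <- data.table::as.data.table(cpp_extend_search(
    index$ptr, read, we, ci, as.double(end$pos), params$min_overhang,
    params$min_intron, params$max_intron))
  if (nrow(out) > 0L) {
    out[, chrom := index$chroms[chrom]]
    out[, dinuc_class := class_label(class_code)]
  }
  out[]
}

class_label <- function(code) {
  c("GT-AG", "GC-AG", "control", "other")[code + 1L]
}

#' Coordinate-shift equivalence class of a junction placement
#'
#' Enumerates every shift `s` of both intron boundaries for which the
#' reconstructed read sequence is unchanged (repeated sequence at the
#' boundaries), and selects the canonical placement: a shift whose intron
#' begins GT (preferred) or GC and ends AG if one exists (on either strand
#' reading), else the control dinucleotides, else the placement as found;
#' ties are broken leftmost.
#'
#' @param candidate list/row with `chrom`, `istart`, `iend`, `breakpoint`.
#' @param index a `seed_index` (carries the genome).
#' @param read_length length of the supporting read.
#' @return list with `shifts`, per-shift `dinucleotides`, canonical
#'   coordinates, class and strand.
#' @export
shift_equivalence <- function(candidate, index, read_length) {
  ci <- match(candidate$chrom, index$chroms)
  out <- cpp_shift_equivalence(index$ptr, ci, as.double(candidate$istart),
                               as.double(candidate$iend),
                               as.integer(candidate$breakpoint),
                               as.integer(read_length))
  out$dinuc_class <- class_label(out$class_code)
  out
}

#' Aggregate junction candidates into a junction table
#'
#' Candidates are keyed by their canonical placement; the supporting read
#' count is the number of distinct reads. Reads consistent with several
#' unrelated junctions at the same minimum mismatch count are counted for
#' each and flagged via `n_ambiguous`.
#'
#' @param candidates data.table of per-read candidates (from
#'   [discover_junctions()] internals or the per-read operations), with
#'   columns `read`, `chrom`, `istart`, `iend`, `strand`, `class_code`,
#'   `n_placements`, `mm`.
#' @return junction table: `chrom`, `start`, `end`, `strand`, `reads`,
#'   `dinuc_class`, `n_placements`, `n_ambiguous`, `mean_mm`.
#' @export
aggregate_junctions <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(data.table::data.table(
      chrom = character(0), start = double(0), end = double(0),
      strand = character(0), reads = integer(0), dinuc_class = character(0),
      n_placements = integer(0), n_ambiguous = integer(0),
      mean_mm = double(0)))
  }
  cand <- data.table::as.data.table(candidates)
  cand[, n_junc_for_read := .N, by = read]
  out <- cand[, .(reads = data.table::uniqueN(read),
                  class_code = min(class_code),
                  n_placements = max(n_placements),
                  n_ambiguous = sum(n_junc_for_read > 1L),
                  mean_mm = mean(mm)),
              by = .(chrom, start = istart, end = iend, strand)]
  out[, dinuc_class := class_label(class_code)]
  out[, class_code := NULL]
  data.table::setorder(out, chrom, start, end)
  out[]
}

#' De novo splice junction discovery
#'
#' Runs the full discovery procedure over a read set: contiguous mapping
#' (contiguously mapping reads are set aside), split-end mapping of the
#' remainder in both orientations, junction enumeration between uniquely
#' mapped end pairs, extend-and-search when only one end maps, shift
#' equivalence and canonical placement, and aggregation into a junction
#' table.
#'
#' @param reads a `read_set` (data.table with `read_id`, `seq`) or character
#'   vector of sequences.
#' @param index a `seed_index` from [build_index()], or a genome (named
#'   character vector) from which one is built.
#' @param params a [mapper_params()] list.
#' @return list with `junctions` (aggregated table), `candidates` (per-read
#'   candidates), `contiguous` (unique contiguous alignments), and `status`
#'   (per-read outcome counts).
#' @export
discover_junctions <- function(reads, index, params = mapper_params()) {
  if (!inherits(index, "seed_index")) index <- build_index(index)
  seqs <- if (is.character(reads)) reads else reads$seq
  ids <- if (is.character(reads)) as.character(seq_along(reads)) else
    reads$read_id
  res <- cpp_discover(index$ptr, seqs, params$max_mismatch,
                      params$min_overhang, params$min_intron,
                      params$max_intron, params$discard_short_both)
  cand <- data.table::as.data.table(res$candidates)
  contig <- data.table::as.data.table(res$contiguous)
  if (nrow(cand) > 0L) {
    cand[, chrom := index$chroms[chrom]]
    cand[, read_id := ids[read]]
  }
  if (nrow(contig) > 0L) {
    contig[, chrom := index$chroms[chrom]]
    contig[, read_id := ids[read]]
  }
  status <- factor(res$status, levels = 0:4,
                   labels = c("contiguous_unique", "contiguous_multi",
                              "short_both_ends_discarded", "junction",
                              "unmapped"))
  list(junctions = aggregate_junctions(cand),
       candidates = cand, contiguous = contig,
       status = table(status))
}

#' Breakpoint offsets recoverable by the discovery procedure
#'
#' For a read of length `L` with seed length `k` and minimum overhang `o`,
#' the both-ends path requires the first and last `k` bases to avoid the
#' junction (`b >= k` and `b <= L - k`) and applies only to reads of length
#' >= 40; the one-end path requires one clean seed and a remainder of at
#' least `o` bases. The union of offsets is returned; the count differs from
#' the plain two-sided overhang bound when seeds straddle the junction.
#'
#' @param read_length read length L.
#' @param k seed length.
#' @param min_overhang minimum bases on each side of the breakpoint.
#' @return list with `offsets` (recoverable breakpoints), `overhang_bound`
#'   (offsets allowed by the two-sided overhang rule alone).
#' @export
allowable_breakpoints <- function(read_length, k = 20L, min_overhang = 10L) {
  L <- read_length
  bound <- seq(min_overhang, L - min_overhang)
  if (L >= 40L) {
    both <- bound[bound >= k & bound <= L - k]
    one_first <- bound[bound >= k]        # first seed clean, remainder >= o
    one_last <- bound[bound <= L - k]     # last seed clean, prefix >= o
    offs <- sort(unique(c(both, one_first, one_last)))
  } else {
    offs <- sort(unique(c(bound[bound >= k], bound[bound <= L - k])))
  }
  list(offsets = offs, overhang_bound = bound)
}
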