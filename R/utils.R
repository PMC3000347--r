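# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of character vectors
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors as the working currency of the simulator and mapper.
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast random DNA of total length n (single string).
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Extract genome subsequence [start, end) in 0-based half-open coordinates.
gseq <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1L, end)
}

# Derive a stage-specific seed from a master seed so pipeline stages are
# individually reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stages <- c(genome = 101L, conservation = 211L, variants = 307L,
              transcripts = 401L, reads = 503L, analysis = 601L,
              saturation = 701L)
  off <- stages[[stage]]
  as.integer((as.double(seed) * 1009 + off) %% 2147483647)
}

#' Intron-boundary dinucleotides in transcript orientation
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open intron coordinates (forward strand).
#' @param strand `"+"` or `"-"`.
#' @return named character vector `c(donor =, acceptor =)`.
#' @export
intron_dinucs <- function(genome, chrom, start, end, strand) {
  d5 <- gseq(genome, chrom, start, start + 2L)
  d3 <- gseq(genome, chrom, end - 2L, end)
  if (identical(strand, "-")) {
    tmp <- revcomp_chr(d3)
    d3 <- revcomp_chr(d5)
    d5 <- tmp
  }
  c(donor = d5, acceptor = d3)
}

# Canonical two intronic bases of a splice site, as 0-based genomic positions.
# type "donor": first two intron bases; "acceptor": last two intron bases.
# boundary: the intron boundary coordinate used as the site key (see
# site_key()): donor on "+" and acceptor on "-" use the intron start, the
# other two use the (exclusive) intron end.
site_canonical_positions <- function(type, strand, boundary) {
  if (type == "donor") {
    if (strand == "+") c(boundary, boundary + 1L) else c(boundary - 1L, boundary - 2L)
  } else {
    if (strand == "+") c(boundary - 2L, boundary - 1L) else c(boundary, boundary + 1L)
  }
}

# Unique string key for a splice site.
site_key <- function(chrom, strand, type, boundary) {
  paste(chrom, strand, type, boundary, sep = ":")
}

# Per-junction site boundaries: donor boundary is the intron start on "+"
# and the intron end on "-"; acceptor is the other one.
junction_sites <- function(dt) {
  stopifnot(all(c("chrom", "strand", "start", "end") %in% names(dt)))
  donor_boundary <- ifelse(dt$strand == "+", dt$start, dt$end)
  acceptor_boundary <- ifelse(dt$strand == "+", dt$end, dt$start)
  list(donor = donor_boundary, acceptor = acceptor_boundary)
}
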