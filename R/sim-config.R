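#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-data generator:
#' a miniature multi-chromosome genome of non-overlapping multi-exon genes,
#' a per-base conservation track, a variant set, an error-bearing transcript
#' pool and short single-end reads.
#'
#' The generator encodes the statistical structure the downstream analyses
#' assume: log-normal intron lengths, power-law gene expression, a per-intron
#' cryptic-splicing probability (optionally a function of intron length), a
#' geometric proposal kernel for cryptic splice sites concentrated near the
#' true site, an NMD proxy that thins frame-disrupting error isoforms, high
#' conservation at true splice sites and exons against a near-zero
#' background, and uniform read starts with a flat per-base sequencing error
#' rate.
#'
#' @param n_genes number of genes.
#' @param n_chroms number of chromosomes genes are distributed over.
#' @param mean_exons mean exon count per gene; exon counts are drawn as
#'   `2 + rgeom(p)` with `p = 1/(mean_exons - 1)` so every gene has at least
#'   one intron and the mean matches the typical four-exon gene.
#' @param exon_length integer range (min, max) of exon lengths in bp.
#' @param utr_padding integer range (min, max) of extra untranslated bases
#'   added to each terminal exon, so that read windows around first and last
#'   junctions are never truncated at transcript ends.
#' @param intron_meanlog,intron_sdlog log-normal intron length parameters.
#' @param intron_range intron length support (bp); lengths are clamped here
#'   so every true junction is discoverable under the mapper's constraints.
#' @param expression_alpha Pareto tail index of the power-law expression
#'   distribution (weights `runif(n)^(-1/alpha)`).
#' @param expression_length_coupling exponent coupling expression to mean
#'   intron length: expression is multiplied by
#'   `(mean intron length / median)^(-coupling)`, so positive values make
#'   highly expressed genes short-introned (the confounding structure seen
#'   in real genomes); 0 leaves expression independent of length.
#' @param per_intron_error_rate probability that one splicing reaction on one
#'   transcript copy uses a cryptic site instead of the true one; either a
#'   single number in (0, 1) or a `function(length)` of intron length.
#' @param error_kernel_decay geometric decay rate of the cryptic-site
#'   proposal kernel with distance from the true site.
#' @param exon_flank cryptic sites may fall up to this many bases into the
#'   flanking exon.
#' @param min_cryptic_offset proposals closer than this to the true site are
#'   excluded, mirroring the -2..+2 ambiguity exclusion used downstream.
#' @param gc_fraction fraction of introns whose donor dinucleotide is GC
#'   rather than GT (GC-AG minor class); AT-AC introns are never generated.
#' @param double_error_fraction fraction of error events that place both a
#'   cryptic donor and a cryptic acceptor inside the intron, creating a
#'   junction with no annotated end.
#' @param frame_bias survival multiplier for frame-disrupting error isoforms
#'   relative to frame-preserving ones (NMD proxy); 1 disables thinning.
#' @param read_length read length in bp (35 or 46 are typical).
#' @param sequencing_error_rate per-base substitution probability.
#' @param depth target mean junction-spanning reads per true junction.
#' @param variant_density per-base probability of a polymorphic site.
#' @param cons_high_mean,cons_high_sd conservation score distribution at true
#'   splice sites and exonic bases.
#' @param cons_bg_mean,cons_bg_sd background (intronic / intergenic / cryptic
#'   site) conservation score distribution.
#' @param intergenic integer range of intergenic spacer lengths.
#' @param seed default master seed used by [run_pipeline()].
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_genome()], [simulate_transcripts()], [simulate_reads()]
#' @export
sim_config <- function(n_genes = 20L,
                       n_chroms = 2L,
                       mean_exons = 4,
                       exon_length = c(50L, 300L),
                       utr_padding = c(100L, 250L),
                       intron_meanlog = log(300),
                       intron_sdlog = 0.9,
                       intron_range = c(60L, 20000L),
                       expression_alpha = 1.5,
                       expression_length_coupling = 0,
                       per_intron_error_rate = 0.007,
                       error_kernel_decay = 0.02,
                       exon_flank = 30L,
                       min_cryptic_offset = 3L,
                       gc_fraction = 0.03,
                       double_error_fraction = 0,
                       frame_bias = 1,
                       read_length = 46L,
                       sequencing_error_rate = 0.001,
                       depth = 20,
                       variant_density = 0.005,
                       cons_high_mean = 2,
                       cons_high_sd = 0.3,
                       cons_bg_mean = 0,
                       cons_bg_sd = 0.2,
                       intergenic = c(200L, 500L),
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_chroms >= 1,
            cfg$mean_exons > 2,
            length(cfg$exon_length) == 2, cfg$exon_length[1] >= 20,
            cfg$exon_length[1] <= cfg$exon_length[2])
  if (cfg$intron_range[1] < 60 || cfg$intron_range[2] > 20000)
    stop("intron_range must lie within [60, 20000] so every true junction ",
         "is discoverable by the mapper")
  probs <- c(gc_fraction = cfg$gc_fraction,
             double_error_fraction = cfg$double_error_fraction,
             sequencing_error_rate = cfg$sequencing_error_rate,
             variant_density = cfg$variant_density)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities outside [0,1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  if (is.numeric(cfg$per_intron_error_rate)) {
    if (cfg$per_intron_error_rate < 0 || cfg$per_intron_error_rate > 1)
      stop("per_intron_error_rate must be in [0,1]")
  } else if (!is.function(cfg$per_intron_error_rate)) {
    stop("per_intron_error_rate must be a probability or a function of ",
         "intron length")
  }
  if (cfg$frame_bias < 0 || cfg$frame_bias > 1)
    stop("frame_bias must be in [0,1]")
  if (!cfg$read_length %in% 20:200) stop("read_length out of range")
  invisible(TRUE)
}

# Per-intron error probabilities from the config (scalar or function).
intron_error_probs <- function(cfg, lengths) {
  eps <- cfg$per_intron_error_rate
  if (is.function(eps)) {
    out <- eps(lengths)
  } else {
    out <- rep(eps, length(lengths))
  }
  pmin(pmax(out, 0), 1)
}
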