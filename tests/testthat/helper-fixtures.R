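# Shared fixtures, built once per test run. The tiny fixture has zero
# sequencing error so mapper output is exactly reconstructable.

library(data.table)

tiny_env <- new.env()

tiny_fixture <- function() {
  if (is.null(tiny_env$fx)) {
    fx <- make_fixture("tiny", seed = 42)
    sim <- generate_genome(fx$config, seed = 42)
    pool <- simulate_transcripts(sim$genome, sim$truth, fx$config, seed = 43,
                                 n_transcripts = fx$n_transcripts)
    reads <- simulate_reads(sim$truth, pool, fx$config, seed = 44)
    index <- build_index(sim$genome)
    disc <- discover_junctions(reads, index)
    track <- generate_conservation_track(sim$genome, sim$truth, fx$config,
                                         seed = 45)
    tiny_env$fx <- list(config = fx$config, genome = sim$genome,
                        truth = sim$truth, pool = pool, reads = reads,
                        index = index, disc = disc, track = track)
  }
  tiny_env$fx
}

default_env <- new.env()

default_fixture <- function() {
  if (is.null(default_env$fx)) {
    fx <- make_fixture("default", seed = 7)
    sim <- generate_genome(fx$config, seed = 7)
    pool <- simulate_transcripts(sim$genome, sim$truth, fx$config, seed = 8,
                                 n_transcripts = fx$n_transcripts)
    track <- generate_conservation_track(sim$genome, sim$truth, fx$config,
                                         seed = 9)
    junc <- junctions_from_truth(sim$genome, sim$truth, pool,
                                 reads_per_copy = 0.5, seed = 10)
    default_env$fx <- list(config = fx$config, genome = sim$genome,
                           truth = sim$truth, pool = pool, track = track,
                           junctions = junc)
  }
  default_env$fx
}

# A small flat-value conservation track covering given chromosomes.
flat_track <- function(genome, value) {
  out <- lapply(genome, function(s) rep(value, nchar(s)))
  class(out) <- "conservation_track"
  out
}

# Hand-built junction table row(s).
jtab <- function(chrom, start, end, strand, reads,
                 dinuc_class = "GT-AG") {
  data.table(chrom = chrom, start = start, end = end, strand = strand,
             reads = reads, dinuc_class = dinuc_class, n_placements = 1L,
             n_ambiguous = 0L, mean_mm = 0)
}
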