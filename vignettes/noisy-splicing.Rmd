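---
title: "Quantifying noisy splicing from short-read RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying noisy splicing from short-read RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisySplice)
library(data.table)
```

## The problem

Deep RNA sequencing of human cells reveals far more splice junctions than
any gene catalog contains, most of them supported by a handful of reads.
Two explanations compete: pervasive regulated alternative splicing, or
stochastic errors of the spliceosome ("noisy splicing"). The two can be
separated with signals that do not depend on annotation quality: whether
putative junctions carry the canonical intronic dinucleotides (GT..AG, with
the minor GC..AG class), whether rarely used splice sites show evolutionary
conservation, whether alternative sites near coding junctions preferentially
preserve reading frame (because frame-disrupting products are degraded by
nonsense-mediated decay, NMD), and whether the sequence context of
unconserved sites is enriched for the same exon-definition motifs that mark
real exons.

`noisySplice` implements this entire analysis chain as testable components:
a split-read junction discovery procedure, a control-dinucleotide false
discovery rate (FDR) for junction calls, conservation-stratified
per-intron splicing error rates with their covariate structure, frame
periodicity of minor splice sites, and hexamer enrichment near unconserved
sites versus matched decoys — together with a synthetic-data generator that
produces genomes, transcript pools with controlled splicing errors, and
reads, so that every estimator can be validated against a known truth.

## Junction discovery

Reads are first mapped contiguously against a k-mer seed index (seed length
20, the same length as the split ends). A read is uniquely placed when
exactly one locus attains the minimum mismatch count (at most 2) and no
second locus lies within one additional mismatch; any read that maps
contiguously is excluded from junction search. For the remainder, the first
and last 20 bases are looked up independently (for reads shorter than 40
bases these ends overlap; if both ends of such a short read map uniquely
the read is discarded, with a configuration switch for the alternative
rule of discarding only placements consistent with a contiguous
alignment). When both ends of a longer read map uniquely to the same
chromosome, in order, and between 51 and 20,000 bases apart, every
breakpoint offset leaving at least 10 bases on each side is evaluated by
reconstructing the read from the two genomic segments; all placements at
the minimum mismatch count are reported. When exactly one end maps, the
alignment is extended base by base without mismatches and the remainder
(at least 10 bases) is searched within the intron-length window for a
perfect match, accepted only if unique.

Because splice-site context is partially repeated at intron boundaries, a
junction-spanning read is often consistent with several coordinate-shifted
intron placements. The shift-equivalence class of a candidate is the set of
shifts of both boundaries that reconstruct the identical read sequence; the
canonical placement is the shift whose intron begins GT (preferred) or GC
and ends AG on either strand reading, then the control pairs, then the
placement as found, ties broken leftmost. Junctions found on the reverse
complement (CT..AC on the forward strand) are reported on the minus strand
in forward-strand coordinates, the standard junction-caller convention.
The mapper core is compiled (C++ via Rcpp), as is usual for read-mapping
code; per-operation R entry points (`build_index()`, `map_contiguous()`,
`split_map()`, `enumerate_junctions()`, `extend_and_search()`,
`shift_equivalence()`, `aggregate_junctions()`) expose every step, and the
test suite checks the whole path against an independent brute-force oracle
written over `Biostrings::matchPattern()`.

A consequence of exact 20-base end seeds worth stating explicitly: for
46-base reads the recoverable breakpoint offsets are 10–36 (27 offsets; the
two-ends path covers 20–26 and the one-end path the rest), while for
35-base reads they are 10–15 and 20–25 (12 offsets), because breakpoints at
16–19 straddle both seeds. `allowable_breakpoints()` reports both the
plain two-sided overhang bound and this seed-aware set; sensitivity
analyses should use the latter.

## Junction classes, FDR, and site usage

A junction is *canonical* if any placement in its equivalence class is
GT-AG or GC-AG, *control* if some placement matches GT-TC or GC-TC (the
acceptor consensus replaced by its complement) and none is canonical, and
*other* otherwise; canonical takes precedence. Under the model that a false
junction's boundary dinucleotides are random, a false call is as likely to
show the control pair as the canonical pair (2 of 16 dinucleotide pairs
each, conditional on the GT/GC start), so the FDR of the canonical set is
estimated by the ratio of control to canonical counts
(`estimate_fdr()`). The canonical worked example for human
lymphoblastoid-scale data is 4,230 control against 306,606 canonical
junctions, an FDR of about 1.4% overall, and 2,985 against 154,927 ≈ 1.9%
for the unannotated subset; secondary summaries of the same counts are
sometimes rounded to 1.5%, so the function always returns the exact
ratio.

Junctions are classified five ways against the union of any number of gene
model inputs (GTF or BED12): annotated junction; both sites annotated but
not as partners; 5' annotated only; 3' annotated only; neither.
"Annotated site" means the exact boundary coordinate occurs in some input;
"near" a known site defaults to 50 bp. Site-level usage
(`splice_site_usage()`) counts, for each site covered by at least 50 reads,
its distinct partners and the share of its most-used ("major") partner,
optionally stratified by the CDS/UTR position of the exonic side (majority
rule across transcripts when inputs conflict).

## Conservation labels and splicing error rates

Each splice site is labeled by the mean conservation score over its two
canonical intronic bases: conserved when the mean is at least `t_hi`
(default 1.5 on a phyloP-like scale — the threshold is a package default,
exposed in every result), unconserved when at most 0.5, intermediate
otherwise. For every junction whose two sites are conserved (a *reference
intron*), the error rate is the fraction of reads involving either of its
sites that splice to an unconserved partner. A read of the reference
junction itself touches both sites but is counted once in the denominator;
each partner-junction read is counted once. Reads to intermediate-label
partners are excluded from numerator and denominator, making the estimate
a conservative lower bound; a variant including them in the denominator is
also reported since either convention is defensible. The global rate is
read-weighted (matching a "fraction of reads" statement), with the
unweighted per-intron mean reported alongside. Under this counting the
estimator is unbiased for the generator's per-intron error probability,
which the acceptance suite verifies to within three binomial standard
errors at two million junction-spanning reads.

Covariate structure is summarized by splitting reference introns into 100
equal-count bins of intron length (or expression), plotting the mean rate
against the mean log10 covariate, with a Spearman correlation of the bin
means as the monotone trend statistic and a cubic smoothing spline
(generalized cross-validation) as the overlay — the trend statistic is a
package choice: a spline alone shows the shape but gives no single
monotonicity number to test against. Confounding is
handled by `residual_correction()`: regress the rate on log10 of one
covariate, re-bin the residuals against the other. Expression is computed
as reads per exonic base per sample, maximized over samples.

## Frame periodicity

Anchor sites are covered by at least 20 reads, spliced to at least two
partners, have a major partner holding at least 90% of reads (the share
threshold is a package default with no community-standard value), and
are annotated protein-coding along with their major partner. Minor-site
offsets from the major site are tallied against the number of AG (or GT)
dinucleotides that could create a site at each offset, excluding offsets
−2..+2 where mapping ambiguity makes assignment unreliable; the ratio is
the periodicity profile, which is invariant to uniform read-depth scaling.
The in-frame fraction of minor sites is tested against 1/3 with a
one-sided exact binomial test. The NMD proxy in the generator (survival of
frame-disrupting error isoforms multiplied by `frame_bias`) creates
exactly this signal; with `frame_bias = 1` the test's type-I error is
checked over 200 replicate simulations.

## Motif enrichment near noise sites

Noise sites are unannotated, unconserved (score ≤ 0.5) junction ends whose
partner is annotated, at least 50 bp from any annotated site. Each is
matched with a decoy: the nearest unused GT (or AG, matching the site
type) between the noise site and its nearest annotated site — never
observed spliced — chosen closest to the noise site for the best local
composition match. 100 bases around each site are read as 50 exonic + 50
intronic (the split is a package convention, exposed in configuration),
with exclusion zones of 5+5 bases for donors and 20 intronic / 2 exonic
for acceptors. Overlapping hexamers are counted per region
(`Biostrings::oligonucleotideFrequency()`), and each of the 4,096 hexamers
is tested in a 2×2 table (this hexamer versus all others, noise versus
decoy) by a 1-df chi-square without continuity correction, falling back to
Fisher's exact test when an expected cell is below 5 (flagged). The log2
enrichment uses a pseudocount of 1 on all four cells — for the ratio only,
never the test — so zero cells stay finite, and swapping the noise and
decoy inputs negates every log2 ratio while preserving every statistic.
Significance is Bonferroni-corrected over the 4,096 hexamers at α = 0.05.
Overlap with a reference list of exonic splicing enhancers and positional
profiles of significant hexamers around constitutive exons (both flanking
sites single-partnered) complete the module.

## The synthetic-data generator

The generator is the package's ground truth, not a fixture. Its defaults
encode the study conditions the analyses assume:

* **Gene structure** — exon counts `2 + Geometric(1/(mean_exons − 1))`
  with mean 4 (the median human gene has four exons; the lower bound keeps
  every gene spliced), exon lengths uniform on 50–300 bp, terminal exons
  padded with 100–250 bp of UTR (real terminal exons carry untranslated
  sequence; the padding also ensures read windows around first and last
  junctions are never clipped by transcript ends, which would otherwise
  bias junction read counts at terminal introns), intron lengths
  log-normal (meanlog log 300, sdlog 0.9) clamped to 60–20,000 bp so every
  true junction is discoverable under the mapper's constraints.
* **Splice sites** — every intron starts GT (GC with probability 0.03,
  the genome-wide minor-class share implied by the printed canonical
  counts) and ends AG; AT-AC introns are never generated.
* **Expression** — power-law weights `runif(n)^(-1/1.5)`. The
  `expression_length_coupling` parameter multiplies expression by
  `(mean intron length / median)^(-c)`, reproducing the observed
  anti-correlation between expression and intron length when a preset
  requires confounding; it defaults to 0.
* **Errors** — each splicing reaction independently uses a cryptic site
  with probability 0.007 per intron (scalar or function of intron
  length). Proposals are the GT (donor side) or AG (acceptor side)
  dinucleotides within the intron plus 30 bp of flanking exon, weighted by
  a geometric kernel in distance from the true site (decay 0.02): the
  distribution of real cryptic offsets is unknown beyond their
  concentration near true sites, so the kernel shape is a stand-in and
  only qualitative profile shapes should be read from it. Offsets −2..+2
  are excluded (mirroring the downstream ambiguity exclusion), and
  proposals whose intron would leave the mapper's 51–20,000 bp window are
  not generated. Introns with no available dinucleotide fall back to
  flagged intron retention. With probability `double_error_fraction` an
  error event instead splices an internal segment between a cryptic GT
  and a cryptic AG inside the retained intron, producing a junction with
  no annotated end; the default is 0 because such junctions touch neither
  end of a reference intron and are invisible to the read-fraction
  estimator — presets enable them for the classification tests.
* **NMD proxy** — frame-disrupting error isoforms survive with
  probability `frame_bias` relative to frame-preserving ones; abundance
  thinning, not mechanistic PTC modeling, is sufficient to induce the
  periodicity signal under test. The default is 1 (off): the
  parameter-recovery condition compares the estimator to the generator's
  per-intron rate, and the two are equal only without NMD thinning;
  the frame-biased preset turns it on for the periodicity analyses.
* **Conservation** — exonic bases and true splice-site dinucleotides are
  drawn from N(2, 0.3), background from N(0, 0.2), and the dinucleotides
  of every cryptic proposal candidate from the background distribution
  (computed before transcripts are drawn, so the track never depends on
  which errors were realized).
* **Reads** — uniform start positions weighted by isoform abundance,
  flat per-base substitution rate 0.001, read length 46 (or 35). The
  `junction_spanning_only` mode restricts starts to windows from which a
  read covers a junction: every junction-level analysis sees exactly the
  same reads, at a thirtieth of the simulation cost, and the
  parameter-recovery run uses it to reach two million junction-spanning
  reads.

What the generator does **not** emulate: realistic human sequence
composition (uniform base frequencies make 20-mers essentially unique, so
mapping ambiguity from repeats is underrepresented), paired-end reads,
position-dependent quality or error profiles, transcript degradation
kinetics, and alternative *annotated* splicing (each gene has one true
isoform). Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to repeat
content or annotation complexity in real genomes.

## Numerical and design choices

* Coordinates are 0-based half-open throughout; a junction is keyed by its
  intron interval on the forward strand plus a strand flag (BED-ready).
* "Unique with mapping quality" semantics are operationalized as: one
  locus at minimum mismatches and no second locus within +1 mismatch.
  End seeds are exact matches; only full-candidate verification allows
  mismatches (at toy-genome scale 20-mers are effectively unique and the
  brute-force oracle stays tractable).
* Reported breakpoint counts: the package documents 27 allowable
  breakpoints for 46-base reads and 12 seed-recoverable offsets for
  35-base reads, as derived above; other conventions in circulation
  (e.g. counts of 26 or 10) are not recoverable from their stated
  constraints, so the package exposes its own arithmetic.
* Tie-breaks: all minimum-mismatch breakpoints are reported and
  multi-junction reads are flagged at aggregation; covariate bin edges
  break ties in table order, deterministically.
* The statistical machinery reuses the standard stack: `binom.test`,
  `chisq.test`/`fisher.test`, `cor(method = "spearman")`, `lm`,
  `smooth.spline` (GCV), `p.adjust`-style Bonferroni by direct
  multiplication; file formats go through Biostrings and rtracklayer.
* A single master seed fans out to fixed per-stage seeds
  (`derive_seed()`), so each stage is individually reproducible and
  identical (config, seed) pairs give byte-identical outputs.

## Problem sizes used by the checks

The package's own validation runs at desk scale: the parameter-recovery
condition uses 200 genes (~580 introns), two million transcript copies and
two million junction-spanning 46-bp reads, recovering the generator rate
within three binomial standard errors; oracle equivalence uses a ~10 kb,
6-gene fixture with zero sequencing error where brute force is exact;
calibration and power checks use 200 replicate transcript pools over 20
independent 30-gene genomes (periodicity), 20 replicates of a 150-gene
confounded design (trend and correction), and 100 replicates of 600-site
window sets (motif spike-in). Corpus-scale figures from billion-read
datasets (hundreds of thousands of junctions) are structurally out of
reach at these sizes and are represented by the property checks, not by
target numbers.

## A small worked run

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 12L, per_intron_error_rate = 0.02,
                  depth = 25, seed = 55)
report <- run_pipeline(cfg, seed = 55, n_transcripts = 8000L,
                       usage_min_coverage = 10L)
report
```

The report echoes every threshold it used (conservation cutoffs, coverage
minima, intron bounds, seed), and each headline number traces to a stage
output: junction counts by class, the control-dinucleotide FDR, mean
partner counts and major-form share, the global error rate with both
weighting conventions, the in-frame minor-site fraction with its exact
binomial p-value, and the per-gene mis-splicing implied by three splicing
reactions.
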