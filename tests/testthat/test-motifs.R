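test_that("hexamer counting matches a sliding-window tally", {
  expect_equal(unname(hexamer_counts("AAAAAAA")[["AAAAAA"]]), 2L)
  empty <- hexamer_counts(character(0))
  expect_equal(length(empty), 4096L)
  expect_true(all(empty == 0L))
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 10000L, replace = TRUE),
             collapse = "")
  counts <- hexamer_counts(s)
  brute <- table(substring(s, 1:(10000 - 5), 6:10000))
  expect_equal(sum(counts), 10000L - 5L)
  for (h in sample(names(brute), 50L))
    expect_equal(unname(counts[[h]]), unname(as.integer(brute[[h]])))
  # windows containing N contribute no counts
  sn <- c("ACGTACGTNACGTACGT")  # two 8-mer N-free stretches -> 2*(8-5)
  expect_equal(sum(hexamer_counts(sn)), 6L)
})

test_that("chi-square enrichment matches the 2x2 oracle and is symmetric", {
  hex <- names(hexamer_counts(character(0)))
  cn <- stats::setNames(rep(10L, 4096L), hex)
  cd <- cn
  same <- enrichment_test(cn, cd)
  expect_true(all(same$chi2 == 0))
  expect_true(all(same$log2_enrichment == 0))
  expect_true(all(!same$significant))
  # hand-computed 2x2 chi-square for counts 30/10000 vs 10/10000
  cn2 <- cd2 <- stats::setNames(rep(0L, 4096L), hex)
  cn2[["AAAAAA"]] <- 30L; cn2[["TTTTTT"]] <- 9970L
  cd2[["AAAAAA"]] <- 10L; cd2[["TTTTTT"]] <- 9990L
  et <- enrichment_test(cn2, cd2)
  a <- 30; b <- 9970; cc <- 10; d <- 9990; n <- 20000
  chi_oracle <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  row <- et[hexamer == "AAAAAA"]
  expect_equal(row$chi2, chi_oracle)
  expect_equal(row$log2_enrichment,
               log2(((a + 1) / (10000 + 2)) / ((cc + 1) / (10000 + 2))))
  # chi-square agrees with stats::chisq.test without continuity correction
  ct <- suppressWarnings(chisq.test(matrix(c(a, b, cc, d), 2L,
                                           byrow = TRUE), correct = FALSE))
  expect_equal(chi_oracle, unname(ct$statistic))
  # swap symmetry
  sw <- enrichment_test(cd2, cn2)
  expect_equal(sw$chi2, et$chi2)
  expect_equal(sw$log2_enrichment, -et$log2_enrichment)
  expect_equal(sw$p, et$p)
})

test_that("a spiked motif is recovered with Bonferroni significance", {
  set.seed(31)
  motif <- "GAAGAA"
  mk_windows <- function(n, present_frac) {
    base <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 90L, replace = TRUE),
            collapse = ""), character(1))
    put <- runif(n) < present_frac
    pos <- sample.int(84L, n, replace = TRUE)
    base[put] <- paste0(substr(base[put], 1L, pos[put] - 1L), motif,
                        substr(base[put], pos[put] + 6L, 90L))
    base
  }
  noise <- mk_windows(800L, 0.30)
  decoy <- mk_windows(800L, 0.10)
  et <- enrichment_test(hexamer_counts(noise), hexamer_counts(decoy))
  row <- et[hexamer == motif]
  expect_true(row$significant)
  expect_gt(row$log2_enrichment, 1)
})

test_that("ESE overlap fractions behave at the extremes", {
  hex <- names(hexamer_counts(character(0)))
  mk <- function(pos_set) {
    data.table(hexamer = hex,
               log2_enrichment = ifelse(hex %in% pos_set, 1, -1))
  }
  pos <- hex[1:100]
  ov <- ese_overlap(mk(pos), mk(pos), ese_list = pos[1:50])
  expect_equal(ov$fraction, 1.0)
  ov0 <- ese_overlap(mk(pos), mk(pos), ese_list = hex[200:240])
  expect_equal(ov0$fraction, 0)
  expect_error(ese_overlap(mk(pos), mk(pos), "NOTHEX"), "malformed")
})

test_that("flank extraction honors window splits, exclusions and strand", {
  g <- c(chr1 = paste(rep(c("A", "C", "G", "T"), 250), collapse = ""))
  donor <- data.table(chrom = "chr1", strand = "+", type = "donor",
                      boundary = 500L)
  fl <- extract_flanks(donor, g)
  expect_equal(nchar(fl$exonic), 45L)    # 50 - 5 exonic exclusion
  expect_equal(nchar(fl$intronic), 45L)  # 50 - 5 intronic exclusion
  acceptor <- data.table(chrom = "chr1", strand = "+", type = "acceptor",
                         boundary = 500L)
  fa <- extract_flanks(acceptor, g)
  expect_equal(nchar(fa$exonic), 48L)    # 50 - 2
  expect_equal(nchar(fa$intronic), 30L)  # 50 - 20
  # minus-strand donor window equals the reverse complement of the
  # mirrored plus-strand extraction
  dminus <- data.table(chrom = "chr1", strand = "-", type = "donor",
                       boundary = 500L)
  fm <- extract_flanks(dminus, g)
  # exonic side of a '-' donor lies at genomic [500+5, 500+50)
  expect_equal(fm$exonic,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(g[[1]], 506L, 550L)))))
  # truncation at the contig edge is flagged
  edge <- data.table(chrom = "chr1", strand = "+", type = "donor",
                     boundary = 10L)
  expect_true(extract_flanks(edge, g)$truncated)
})

test_that("noise/decoy selection respects truth, distance and usage rules", {
  fx <- default_fixture()
  labs <- label_conservation(junction_site_table(fx$junctions), fx$track)
  nd <- select_noise_and_decoy(fx$junctions, labs,
                               annotation_from_truth(fx$truth), fx$genome)
  expect_gt(nrow(nd), 0L)
  # selected noise sites are generator cryptic sites
  cr <- fx$truth$cryptic
  cr_bound <- ifelse(cr$side == "donor",
                     ifelse(cr$strand == "+", cr$g_start, cr$g_end),
                     ifelse(cr$strand == "+", cr$g_end, cr$g_start))
  cr_keys <- paste(cr$chrom, cr$strand, cr$side, cr_bound)
  nd_keys <- paste(nd$chrom, nd$strand, nd$type, nd$boundary)
  expect_true(all(nd_keys %in% cr_keys))
  # decoys never appear as used splice sites
  used <- junction_site_table(fx$junctions)
  used_keys <- paste(used$chrom, used$strand, used$type, used$boundary)
  decoy_keys <- paste(nd$chrom, nd$strand, nd$type, nd$decoy_boundary)
  expect_equal(length(intersect(decoy_keys, used_keys)), 0L)
  # decoy dinucleotides match the site type
  dn <- site_dinuc(fx$genome, nd$chrom, nd$strand, nd$type,
                   nd$decoy_boundary)
  expect_true(all(dn == ifelse(nd$type == "donor", "GT", "AG")))
  # all selected sites are > 50 bp from any annotated site
  ann_sites <- junction_site_table(
    fx$truth$introns[, .(chrom, strand, start, end)])
  for (i in seq_len(min(nrow(nd), 40L))) {
    dists <- abs(ann_sites[chrom == nd$chrom[i] & strand == nd$strand[i],
                           boundary] - nd$boundary[i])
    expect_gt(min(dists), 50)
  }
})

test_that("positional profile endpoints behave as set membership dictates", {
  fx <- tiny_fixture()
  ex <- fx$truth$exons[, .(gene, chrom, strand, start, end)]
  all_hex <- names(hexamer_counts(character(0)))
  p_all <- positional_profile(all_hex, ex, fx$genome, window = 20L)
  expect_true(all(p_all$fraction == 1))
  p_none <- positional_profile(character(0), ex, fx$genome, window = 20L)
  expect_true(all(p_none$fraction == 0))
  # constitutive exon selection: single-partner flanks only
  j <- rbind(jtab("chr1", 100, 200, "+", 30L),
             jtab("chr1", 300, 400, "+", 30L),
             jtab("chr1", 300, 450, "+", 10L))
  ann <- list(exons = data.table(gene = "g1", chrom = "chr1", strand = "+",
                                 start = c(0L, 200L, 400L),
                                 end = c(100L, 300L, 500L)),
              cds = data.table())
  ann$introns <- data.table(gene = "g1", chrom = "chr1", strand = "+",
                            start = c(100L, 300L), end = c(200L, 400L))
  ce <- constitutive_exons(j, ann)
  expect_equal(nrow(ce), 0L)  # the donor at 300 has two partners
  j2 <- j[1:2]
  ce2 <- constitutive_exons(j2, ann)
  expect_equal(ce2$start, 200L)
  expect_equal(ce2$end, 300L)
})
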