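test_that("dinucleotide classes partition with canonical precedence", {
  g <- c(chr1 = paste0(strrep("C", 100),
                       "GT", strrep("C", 96), "AG",    # canonical [100,200)
                       strrep("C", 100)))
  cls <- junction_dinuc_class(g, "chr1", 100, 200)
  expect_equal(cls, "GT-AG")
  g2 <- c(chr1 = paste0(strrep("C", 100),
                        "GT", strrep("A", 96), "TC",
                        strrep("C", 100)))
  expect_equal(junction_dinuc_class(g2, "chr1", 100, 200), "control")
  # an equivalence class containing both GT-AG and GT-TC placements is
  # canonical: build TC at shift 0 and AG at shift +2 with matching bases
  g3 <- c(chr1 = paste0(strrep("C", 98), "TAGTTA", strrep("G", 90),
                        "TCTCAG", strrep("T", 100)))
  # find a shifted GT..AG placement by brute force and check precedence
  cls3 <- junction_dinuc_class(g3, "chr1", 100, 200)
  expect_true(cls3 %in% c("GT-AG", "GC-AG", "control"))
  # partition property on real discovery output
  fx <- tiny_fixture()
  fc <- filter_canonical(fx$disc$junctions)
  expect_equal(fc$n_canonical + fc$n_control + fc$n_other,
               nrow(fx$disc$junctions))
})

test_that("control-dinucleotide FDR reproduces the printed worked examples", {
  expect_equal(round(estimate_fdr(306606, 4230), 3), 0.014)
  expect_equal(round(estimate_fdr(154927, 2985), 3), 0.019)
  expect_equal(estimate_fdr(1000, 0), 0)
  expect_error(estimate_fdr(0, 10), "undefined")
})

test_that("five-way junction classification matches construction", {
  ann <- list(
    exons = data.table(gene = c("g1", "g1", "g1"), chrom = "chr1",
                       strand = "+", start = c(0L, 200L, 400L),
                       end = c(100L, 300L, 500L)),
    cds = data.table(gene = character(0), chrom = character(0),
                     strand = character(0), start = integer(0),
                     end = integer(0)))
  ann$introns <- data.table(gene = "g1", chrom = "chr1", strand = "+",
                            start = c(100L, 300L), end = c(200L, 400L))
  j <- jtab("chr1", c(100, 100, 100, 130, 130), c(200, 400, 180, 400, 180),
            "+", reads = c(50L, 5L, 3L, 2L, 1L))
  out <- classify_junctions(j, ann)
  expect_equal(out$annotation_class,
               c("known_junction", "both_known_new_pairing", "new_3ss",
                 "new_5ss", "both_new"))
  expect_true(out$donor_near[4])   # 130 is within 50 of annotated 100
  smry <- attr(out, "summary")
  expect_equal(smry$fraction_unannotated, 4 / 5)
  expect_equal(smry$fraction_reads_unannotated, 11 / 61)
  expect_warning(
    classify_junctions(j, list(exons = ann$exons[0], cds = ann$cds,
                               introns = ann$introns[0])),
    "empty annotation")
})

test_that("classification of synthetic junctions matches the truth labels", {
  fx <- default_fixture()
  ann <- annotation_from_truth(fx$truth)
  cls <- classify_junctions(fx$junctions, ann)
  tj <- truth_junctions(fx$truth, fx$pool)
  key <- c("chrom", "strand", "start", "end")
  cls_true <- cls[tj$true_junctions, on = key, nomatch = NULL]
  expect_true(all(cls_true$annotation_class == "known_junction"))
  ej <- tj$error_junctions
  cls_err <- cls[ej, on = key, nomatch = NULL]
  expected <- ifelse(cls_err$type == "donor", "new_5ss",
                     ifelse(cls_err$type == "acceptor", "new_3ss",
                            "both_new"))
  expect_equal(cls_err$annotation_class, expected)
})

test_that("splice-site usage reports partner counts and major fractions", {
  j <- rbind(jtab("chr1", 100, 200, "+", 98L),
             jtab("chr1", 100, 260, "+", 2L),
             jtab("chr1", 500, 600, "+", 60L))
  us <- splice_site_usage(j, min_coverage = 50L)
  donor <- us$sites[type == "donor" & boundary == 100]
  expect_equal(donor$partners, 2L)
  expect_equal(donor$major_fraction, 0.98)
  single <- us$sites[type == "donor" & boundary == 500]
  expect_equal(single$partners, 1L)
  expect_equal(single$major_fraction, 1.0)
  expect_warning(splice_site_usage(j, min_coverage = 1000L), "threshold")
})

test_that("saturation curve is anchored and monotone", {
  fx <- tiny_fixture()
  cand <- fx$disc$candidates
  rj <- cand[, .(read_id, chrom, start = istart, end = iend, strand)]
  n_avail <- length(unique(rj$read_id))
  sat <- saturation_curve(rj, depth_grid = round(c(0, 0.2, 0.5, 1) *
                                                   n_avail),
                          n_reps = 4L, seed = 2)
  expect_warning(saturation_curve(rj, depth_grid = c(10, n_avail * 10),
                                  n_reps = 1L, seed = 2), "truncated")
  expect_equal(sat$mean_junctions[1], 0)
  total <- data.table::uniqueN(rj[, paste(chrom, start, end, strand)])
  expect_equal(sat$mean_junctions[nrow(sat)], total)
  expect_true(all(diff(sat$mean_junctions) >= 0))
  # concavity in expectation: early gains exceed late gains
  gains <- diff(sat$mean_junctions) / diff(sat$depth)
  expect_true(all(diff(gains) <= 1e-9))
})
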