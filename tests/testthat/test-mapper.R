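make_toy_genome <- function(seed = 5, n = 3000L) {
  set.seed(seed)
  g <- c(chrA = paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                      collapse = ""))
  g
}

test_that("seed index has L-k+1 forward entries and exact query semantics", {
  set.seed(1)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                      collapse = ""))
  idx <- build_index(g, k = 20L)
  expect_equal(idx$n_positions, 81)
  expect_equal(nrow(query_index(idx, strrep("A", 20L))), 0L)
  # query equals brute-force scan for random k-mers of a larger genome
  g2 <- make_toy_genome(9, 10000L)
  idx2 <- build_index(g2, k = 20L)
  set.seed(2)
  for (i in 1:50) {
    p <- sample.int(nchar(g2) - 19L, 1L)
    km <- substr(g2[[1]], p, p + 19L)
    hits <- query_index(idx2, km)
    brute <- gregexpr(km, g2[[1]], fixed = TRUE)[[1]]
    expect_equal(sort(hits$pos), sort(as.integer(brute) - 1L))
  }
})

test_that("contiguous mapping agrees with a brute-force Hamming oracle", {
  g <- make_toy_genome(11)
  idx <- build_index(g)
  set.seed(3)
  # reads copied from the genome, some with planted mismatches
  n_reads <- 120L
  pos <- sample.int(nchar(g) - 45L, n_reads)
  reads <- substring(g[[1]], pos, pos + 45L)
  flip <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
  reads[flip] <- vapply(reads[flip], function(r) {
    i <- sample.int(46L, 1L)
    b <- setdiff(c("A", "C", "G", "T"), substr(r, i, i))[1]
    paste0(substr(r, 1, i - 1), b, substr(r, i + 1, 46L))
  }, character(1))
  res <- map_contiguous(reads, idx)
  for (i in seq_len(n_reads)) {
    orc <- oracle_hits(g, reads[i], 2L)
    orc_rc <- oracle_hits(g, oracle_revcomp(reads[i]), 2L)
    all_mm <- c(orc$mm, orc_rc$mm)
    if (length(all_mm) == 0) {
      expect_equal(res$status[i], "unmapped")
    } else {
      best <- min(all_mm)
      uniq <- sum(all_mm == best) == 1 && sum(all_mm <= best + 1) == 1
      expect_equal(res$status[i] == "unique", uniq)
      if (uniq) {
        expect_equal(res$mm[i], best)
        expect_equal(res$pos[i], c(orc$pos, orc_rc$pos)[which.min(all_mm)])
      }
    }
  }
  # a read from a duplicated sequence is not uniquely mapped
  g_dup <- c(chrD = paste0(g[[1]], substr(g[[1]], 101, 400)))
  idx_dup <- build_index(g_dup)
  dup_read <- substr(g[[1]], 151, 196)
  expect_equal(map_contiguous(dup_read, idx_dup)$status, "multi")
})

test_that("split ends map uniquely and in order across a junction", {
  g <- make_toy_genome(13)
  idx <- build_index(g)
  # synthetic junction read: 23 bases from one locus + 23 from 500 bp away
  left <- substr(g[[1]], 301, 323)
  right <- substr(g[[1]], 901, 923)
  read <- paste0(left, right)
  sm <- split_map(read, idx)
  fwd <- sm[orient == "+"]
  expect_equal(fwd$first_nhits, 1L)
  expect_equal(fwd$last_nhits, 1L)
  expect_equal(fwd$first_pos, 300)
  expect_equal(fwd$last_pos, 900 + 3)  # last 20 of the read
  expect_lt(fwd$first_pos, fwd$last_pos)
  nn <- split_map(strrep("N", 46L), idx)
  expect_true(all(nn$first_nhits == 0L & nn$last_nhits == 0L))
})

test_that("junction enumeration finds the planted junction and obeys bounds", {
  g <- make_toy_genome(17)
  # plant canonical dinucleotides: exon1 [201,240), intron [240,440), exon2
  s <- g[[1]]
  substr(s, 241, 242) <- "GT"
  substr(s, 439, 440) <- "AG"
  g <- c(chrA = s)
  idx <- build_index(g)
  read <- paste0(substr(s, 218, 240), substr(s, 441, 463))  # breakpoint 23
  sm <- split_map(read, idx)[orient == "+"]
  cand <- enumerate_junctions(read, list(chrom = "chrA", pos = sm$first_pos),
                              list(chrom = "chrA", pos = sm$last_pos), idx)
  expect_gt(nrow(cand), 0L)
  expect_true(all(cand$mm == 0L))
  expect_true(any(cand$can_istart == 240 & cand$can_iend == 440))
  expect_equal(cand$dinuc_class[cand$can_istart == 240][1], "GT-AG")
  # a 46 bp read allows at most 27 breakpoints
  expect_lte(nrow(cand), 27L)
  # intron length bounds are never violated anywhere in discovery
  fx <- tiny_fixture()
  jl <- fx$disc$junctions[, end - start]
  expect_true(all(jl > 50 & jl <= 20000))
})

test_that("extend-and-search recovers one-end-mapped junctions", {
  g <- make_toy_genome(19)
  s <- g[[1]]
  substr(s, 501, 502) <- "GT"
  substr(s, 799, 800) <- "AG"
  g <- c(chrA = s)
  idx <- build_index(g)
  # 35 bp read, breakpoint at offset 22: first 20 map, last 20 span
  read <- paste0(substr(s, 479, 500), substr(s, 801, 813))
  expect_equal(nchar(read), 35L)
  res <- extend_and_search(read, list(which = "first", chrom = "chrA",
                                      pos = 478), idx)
  expect_equal(nrow(res), 1L)
  expect_equal(res$can_istart, 500)
  expect_equal(res$can_iend, 800)
  # remainder of length 9 is rejected
  read9 <- paste0(substr(s, 479, 504), substr(s, 801, 809))
  expect_equal(nchar(read9), 35L)
  res9 <- extend_and_search(read9, list(which = "first", chrom = "chrA",
                                        pos = 478), idx)
  expect_equal(nrow(res9), 0L)
  # duplicated remainder in the window is rejected
  s2 <- s
  substr(s2, 1001, 1013) <- substr(s, 801, 813)
  g2 <- c(chrA = s2)
  idx2 <- build_index(g2)
  read_dup <- paste0(substr(s2, 479, 500), substr(s2, 801, 813))
  res_dup <- extend_and_search(read_dup, list(which = "first", chrom = "chrA",
                                              pos = 478), idx2)
  expect_equal(nrow(res_dup), 0L)
})

test_that("shift equivalence reproduces the consensus-site ambiguity", {
  # exon ...AG | GTAAGT ... intron ... TTTCAG | G... exon: the junction is
  # also consistent with shifting one base left (exonic G matches the
  # intron-final G)
  set.seed(23)
  core <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  s <- paste0(
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    "CCTACAG",      # exon1 end: ...AG
    "GTAAGT", core, "TTTCAG",  # intron with consensus ends
    "GTCCA",        # exon2 start: G...
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""))
  g <- c(chrT = s)
  idx <- build_index(g)
  a <- 67L                      # 0-based intron start (the G of GTAAGT)
  e <- a + 6L + 400L + 6L       # 0-based intron end (after TTTCAG)
  sh <- shift_equivalence(list(chrom = "chrT", istart = a, iend = e,
                               breakpoint = 23L), idx, read_length = 46L)
  expect_true(all(c(-1L, 0L) %in% sh$shifts))
  expect_equal(sh$can_istart, a)          # canonical stays at GT-AG
  expect_equal(sh$dinuc_class, "GT-AG")
  # non-repetitive boundaries give a singleton class
  g2 <- make_toy_genome(29)
  s2 <- g2[[1]]
  substr(s2, 101, 102) <- "GT"; substr(s2, 99, 100) <- "CC"
  substr(s2, 399, 400) <- "AG"; substr(s2, 401, 402) <- "TT"
  # ensure no accidental boundary repeats
  if (substr(s2, 98, 98) == substr(s2, 398, 398))
    substr(s2, 98, 98) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s2, 398, 398))[1]
  if (substr(s2, 103, 103) == substr(s2, 403, 403))
    substr(s2, 103, 103) <- setdiff(c("A", "C", "G", "T"),
                                    substr(s2, 403, 403))[1]
  idx2 <- build_index(c(chrA = s2))
  sh2 <- shift_equivalence(list(chrom = "chrA", istart = 100, iend = 400,
                                breakpoint = 23L), idx2, read_length = 46L)
  expect_equal(sh2$shifts, 0L)
  expect_equal(sh2$n_placements, 1L)
  # homopolymer boundaries: class size equals the brute-force shift count
  s3 <- s2
  substr(s3, 97, 104) <- "AAAAGTAA"
  substr(s3, 397, 404) <- "AAAAAGAA"
  idx3 <- build_index(c(chrA = s3))
  sh3 <- shift_equivalence(list(chrom = "chrA", istart = 100, iend = 400,
                                breakpoint = 23L), idx3, read_length = 46L)
  brute <- sum(vapply(-9:9, function(sft) {
    all(vapply(seq_len(abs(sft)), function(t) {
      o <- if (sft > 0) t - 1L else -t
      substr(s3, 101 + o, 101 + o) == substr(s3, 401 + o, 401 + o)
    }, logical(1)))
  }, logical(1)))
  expect_equal(sh3$n_placements, brute)
})

test_that("candidate placements reconstruct the read with the reported mismatches", {
  fx <- tiny_fixture()
  cand <- fx$disc$candidates
  reads <- fx$reads
  take <- cand[seq_len(min(nrow(cand), 200L))]
  L <- fx$config$read_length
  for (i in seq_len(nrow(take))) {
    r <- reads$seq[match(take$read_id[i], reads$read_id)]
    b <- take$breakpoint[i]
    g <- fx$genome[[take$chrom[i]]]
    # reconstruct at the canonical placement: shift breakpoint accordingly
    recon_mm <- function(a, e, bp) {
      if (a - bp < 0L || e + (L - bp) > nchar(g)) return(Inf)
      left <- substr(g, a - bp + 1L, a)
      right <- substr(g, e + 1L, e + (L - bp))
      rec <- paste0(left, right)
      min(sum(utf8ToInt(rec) != utf8ToInt(r)),
          sum(utf8ToInt(rec) != utf8ToInt(oracle_revcomp(r))))
    }
    # the reported placement is the canonical one; try every breakpoint
    # consistent with it and require the minimum to equal the reported mm
    mins <- vapply(1:(L - 1), function(bp)
      recon_mm(take$istart[i], take$iend[i], bp), numeric(1))
    expect_equal(min(mins), as.numeric(take$mm[i]))
  }
})
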