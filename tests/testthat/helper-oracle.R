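# Brute-force oracle for junction discovery, written in R over
# Biostrings::matchPattern, independently of the package's seed-index /
# C++ path. It follows the same documented decision rules (exact 20-base
# end seeds, <=2-mismatch verification, >=10-base overhangs, intron length
# in (50, 20000], one-end extend-and-search with perfect remainder match,
# canonical placement by GT-AG > GC-AG > control > other, leftmost).

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

oracle_mm <- function(chromseq, pos0, frag) {
  n <- nchar(frag)
  if (pos0 < 0 || pos0 + n > nchar(chromseq)) return(Inf)
  s <- substr(chromseq, pos0 + 1L, pos0 + n)
  sum(utf8ToInt(s) != utf8ToInt(frag))
}

# all placements of pattern with <= max_mm mismatches, per chromosome
oracle_hits <- function(genome, pattern, max_mm) {
  out <- list()
  for (ch in names(genome)) {
    m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(genome[[ch]]),
                                  max.mismatch = max_mm)
    if (length(m) == 0) next
    pos <- BiocGenerics::start(m) - 1L
    mm <- vapply(pos, function(p) oracle_mm(genome[[ch]], p, pattern),
                 numeric(1))
    out[[ch]] <- data.table(chrom = ch, pos = pos, mm = mm)
  }
  if (length(out) == 0)
    return(data.table(chrom = character(0), pos = integer(0), mm = numeric(0)))
  rbindlist(out)
}

oracle_canonical <- function(chromseq, a, e, bp, L, max_shift_cap = 1000L) {
  cls1 <- function(d5, d3) {
    if (d5 == "GT" && d3 == "AG") 0L
    else if (d5 == "GC" && d3 == "AG") 1L
    else if (d5 == "GT" && d3 == "TC") 2L
    else if (d5 == "GC" && d3 == "TC") 2L
    else 3L
  }
  vcap <- min((L - 1L) - bp, max_shift_cap)
  ucap <- min(bp - 1L, max_shift_cap)
  v <- 0L
  while (v < vcap && e + v < nchar(chromseq) &&
         substr(chromseq, a + v + 1L, a + v + 1L) ==
         substr(chromseq, e + v + 1L, e + v + 1L)) v <- v + 1L
  u <- 0L
  while (u < ucap && a - u - 1L >= 0L &&
         substr(chromseq, a - u, a - u) ==
         substr(chromseq, e - u, e - u)) u <- u + 1L
  best <- 99L; bs <- 0L; bstrand <- "+"
  for (s in (-u):v) {
    d5 <- substr(chromseq, a + s + 1L, a + s + 2L)
    d3 <- substr(chromseq, e + s - 1L, e + s)
    fwd <- cls1(d5, d3)
    rev <- cls1(oracle_revcomp(d3), oracle_revcomp(d5))
    cl <- min(fwd, rev)
    st <- if (fwd <= rev) "+" else "-"
    if (cl < best) { best <- cl; bs <- s; bstrand <- st }
  }
  list(start = a + bs, end = e + bs, cls = best, strand = bstrand,
       nplace = u + v + 1L)
}

# Full discovery decision for one read; returns list(status, junctions)
# where junctions is a data.table of canonical min-mismatch placements.
oracle_discover_read <- function(genome, read, k = 20L, max_mm = 2L,
                                 min_ov = 10L, min_intron = 51L,
                                 max_intron = 20000L) {
  L <- nchar(read)
  # contiguous mapping on both strands
  h_f <- oracle_hits(genome, read, max_mm)
  h_r <- oracle_hits(genome, oracle_revcomp(read), max_mm)
  if (nrow(h_f) > 0L) h_f[, strand := "+"]
  if (nrow(h_r) > 0L) h_r[, strand := "-"]
  hits <- rbindlist(list(h_f[mm <= max_mm], h_r[mm <= max_mm]),
                    fill = TRUE)
  if (nrow(hits) > 0) {
    best <- min(hits$mm)
    n_best <- sum(hits$mm == best)
    n_near <- sum(hits$mm <= best + 1)
    status <- if (n_best == 1 && n_near == 1) "contiguous_unique" else
      "contiguous_multi"
    return(list(status = status, junctions = NULL))
  }
  cands <- list()
  short_discard <- FALSE
  for (ori in c("+", "-")) {
    r <- if (ori == "+") read else oracle_revcomp(read)
    f <- oracle_hits(genome, substr(r, 1L, k), 0L)
    l <- oracle_hits(genome, substr(r, L - k + 1L, L), 0L)
    if (nrow(f) == 1L && nrow(l) == 1L) {
      if (L < 40L) { short_discard <- TRUE; next }
      if (f$chrom != l$chrom) next
      ilen <- (l$pos - f$pos) - (L - k)
      if (ilen < min_intron || ilen > max_intron) next
      g <- genome[[f$chrom]]
      res <- list(); bestmm <- max_mm + 1
      for (b in min_ov:(L - min_ov)) {
        rs <- (l$pos + k) - (L - b)
        mm <- oracle_mm(g, f$pos, substr(r, 1L, b)) +
          oracle_mm(g, rs, substr(r, b + 1L, L))
        if (mm > max_mm) next
        if (mm < bestmm) { bestmm <- mm; res <- list() }
        if (mm == bestmm) res[[length(res) + 1L]] <- c(b = b, mm = mm)
      }
      for (x in res) {
        a <- f$pos + x[["b"]]
        e <- a + ilen
        cn <- oracle_canonical(genome[[f$chrom]], a, e, x[["b"]], L)
        cands[[length(cands) + 1L]] <- data.table(
          chrom = f$chrom, start = cn$start, end = cn$end,
          strand = cn$strand, mm = x[["mm"]], cls = cn$cls)
      }
    } else if (xor(nrow(f) == 1L, nrow(l) == 1L)) {
      if (nrow(f) == 1L) {
        g <- genome[[f$chrom]]
        m <- k
        while (m < L && f$pos + m < nchar(g) &&
               substr(g, f$pos + m + 1L, f$pos + m + 1L) ==
               substr(r, m + 1L, m + 1L)) m <- m + 1L
        rem <- L - m
        if (rem < min_ov) next
        a <- f$pos + m
        remfrag <- substr(r, m + 1L, L)
        win_hits <- oracle_hits(genome[f$chrom], remfrag, 0L)
        win_hits <- win_hits[pos >= a + min_intron & pos <= a + max_intron]
        if (nrow(win_hits) != 1L) next
        cn <- oracle_canonical(g, a, win_hits$pos, m, L)
        cands[[length(cands) + 1L]] <- data.table(
          chrom = f$chrom, start = cn$start, end = cn$end,
          strand = cn$strand, mm = 0, cls = cn$cls)
      } else {
        g <- genome[[l$chrom]]
        m <- k
        while (m < L && l$pos + k - m - 1L >= 1L &&
               substr(g, l$pos + k - m, l$pos + k - m) ==
               substr(r, L - m, L - m)) m <- m + 1L
        rem <- L - m
        if (rem < min_ov) next
        e <- l$pos + k - m
        prefrag <- substr(r, 1L, rem)
        win_hits <- oracle_hits(genome[l$chrom], prefrag, 0L)
        win_hits <- win_hits[pos + rem <= e - min_intron &
                               pos + rem >= e - max_intron]
        if (nrow(win_hits) != 1L) next
        cn <- oracle_canonical(g, win_hits$pos + rem, e, rem, L)
        cands[[length(cands) + 1L]] <- data.table(
          chrom = l$chrom, start = cn$start, end = cn$end,
          strand = cn$strand, mm = 0, cls = cn$cls)
      }
    }
  }
  if (length(cands) == 0L)
    return(list(status = if (short_discard) "short_both_ends_discarded" else
      "unmapped", junctions = NULL))
  cd <- unique(rbindlist(cands))
  cd <- cd[mm == min(mm)]
  cd <- unique(cd, by = c("chrom", "start", "end"))
  list(status = "junction", junctions = cd)
}
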