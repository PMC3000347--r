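test_that("periodicity frame classes, ratios and the exact binomial oracle", {
  # frame class is offset mod 3
  expect_true(6 %% 3 == 0)
  # exact binomial tail computed by summation, frozen against binom.test
  p_oracle <- sum(dbinom(126:300, 300, 1 / 3))
  expect_equal(binom.test(126, 300, 1 / 3,
                          alternative = "greater")$p.value, p_oracle)
  expect_equal(round(126 / 300, 2), 0.42)
})

test_that("periodicity profile detects minor sites at the planted offsets", {
  fx <- default_fixture()
  ann <- annotation_from_truth(fx$truth)
  per <- periodicity_profile(fx$junctions, ann, fx$genome, side = "3",
                             window = 60L)
  expect_true(all(per$profile$offset %in% setdiff(-60:60, -2:2)))
  expect_true(all(per$profile$in_frame == (per$profile$offset %% 3 == 0)))
  # ratios are 0 where opportunities exist but no minor site was seen
  zero_rows <- per$profile[opportunities > 0 & minor_count == 0]
  expect_true(all(zero_rows$ratio == 0))
  if (per$n_minor > 0) {
    expect_true(per$in_frame_fraction >= 0 && per$in_frame_fraction <= 1)
    expect_equal(per$p_value,
                 sum(dbinom(per$n_in_frame:per$n_minor, per$n_minor, 1 / 3)))
  }
  # the 5' side (minor donors around coding acceptors) runs symmetrically
  per5 <- periodicity_profile(fx$junctions, ann, fx$genome, side = "5",
                              window = 60L)
  expect_true(all(per5$profile$offset %in% setdiff(-60:60, -2:2)))
  expect_true(all(per5$profile$in_frame ==
                    (per5$profile$offset %% 3 == 0)))
})

test_that("per-intron error rates follow the read arithmetic", {
  g <- c(chr1 = strrep("A", 2000L))
  tr <- flat_track(g, 0)
  # conserved reference junction [100,200); unconserved partner junction
  # [100,300); score the reference sites high, partner acceptor low
  tr$chr1[c(101, 102, 199, 200)] <- 2        # donor +1,+2 / acceptor -2,-1
  tr$chr1[c(299, 300)] <- 0.1
  j <- rbind(jtab("chr1", 100, 200, "+", 995L),
             jtab("chr1", 100, 300, "+", 5L))
  labs <- label_conservation(junction_site_table(j), tr)
  err <- intron_error_rate(j, labs)
  expect_equal(nrow(err$introns), 1L)
  expect_equal(err$introns$error_rate, 5 / 1000)
  expect_equal(err$global_rate, 0.005)
  # no unconserved partner: rate 0
  j0 <- jtab("chr1", 100, 200, "+", 995L)
  err0 <- intron_error_rate(j0, label_conservation(junction_site_table(j0),
                                                   tr))
  expect_equal(err0$global_rate, 0)
  # an intermediate partner is excluded from both numerator and denominator
  tr$chr1[c(399, 400)] <- 1.0
  j2 <- rbind(j, jtab("chr1", 100, 400, "+", 50L))
  labs2 <- label_conservation(junction_site_table(j2), tr)
  err2 <- intron_error_rate(j2, labs2)
  expect_equal(err2$global_rate, 5 / 1000)
  expect_equal(err2$global_rate_incl_intermediate, 5 / 1050)
})

test_that("estimator recovers the generator error rate from truth-level junctions", {
  fx <- default_fixture()
  labs <- label_conservation(junction_site_table(fx$junctions), fx$track)
  err <- intron_error_rate(fx$junctions, labs)
  eps <- fx$config$per_intron_error_rate
  se <- sqrt(eps * (1 - eps) / sum(err$introns$denom))
  expect_lt(abs(err$global_rate - eps), 4 * se + 0.1 * eps)
})

test_that("binning preserves counts and flags trends correctly", {
  set.seed(9)
  n <- 600L
  tab <- data.table(intron_id = sprintf("i%04d", 1:n),
                    length = round(10^runif(n, 1.9, 4.2)))
  tab[, error_rate := 0.001 + 0.004 * (log10(length) - 2) +
        rnorm(n, 0, 0.0008)]
  bt <- bin_and_trend(tab, "length", n_bins = 50L)
  expect_equal(sum(bt$bins$n), n)
  expect_gt(bt$spearman, 0.8)
  # slope recovery from the binned means
  fit <- lm(mean_rate ~ mean_log10_cov, data = bt$bins)
  expect_lt(abs(coef(fit)[2] - 0.004), 0.001)
  # constant response has zero trend
  tab[, error_rate := 0.002]
  expect_equal(bin_and_trend(tab, "length", n_bins = 50L)$spearman, 0)
  expect_error(bin_and_trend(tab[1:10], "length", n_bins = 50L),
               "at least")
})

test_that("expression level is reads per exonic base, maximized over samples", {
  ann <- list(exons = data.table(gene = "g1", chrom = "chr1", strand = "+",
                                 start = 0L, end = 2000L),
              introns = data.table(), cds = data.table())
  al1 <- data.table(chrom = rep("chr1", 1000L), pos = rep(100L, 1000L))
  ex1 <- expression_level(ann, al1)
  expect_equal(ex1$expression, 0.5)
  al2 <- data.table(chrom = rep("chr1", 4000L), pos = rep(5L, 4000L))
  ex12 <- expression_level(ann, list(al1, al2))
  expect_equal(ex12$expression, 2.0)
  expect_error(expression_level(
    list(exons = data.table(gene = "g1", chrom = "chr1", strand = "+",
                            start = 0L, end = 0L)), al1), "zero-length")
})

test_that("estimated expression tracks generator expression", {
  fx <- tiny_fixture()
  ann <- annotation_from_truth(fx$truth)
  contig <- fx$disc$contiguous
  ex <- expression_level(ann, contig[, .(chrom, pos)])
  truthx <- fx$truth$genes[, .(gene, true_expr = expression)]
  m <- merge(ex, truthx, by = "gene")
  expect_gt(cor(m$expression, m$true_expr, method = "spearman"), 0.7)
})

test_that("residual correction removes a confounded association", {
  set.seed(21)
  n <- 500L
  len <- 10^runif(n, 2, 4)
  expr <- 10^(3 - 0.8 * log10(len) + rnorm(n, 0, 0.15))  # anti-correlated
  rate <- 0.001 + 0.004 * (log10(len) - 2) + rnorm(n, 0, 5e-4)
  tab <- data.table(intron_id = as.character(1:n), length = len,
                    expression = expr, error_rate = rate)
  rc <- residual_correction(tab, "length", "expression", n_bins = 25L)
  expect_lt(rc$raw$spearman, -0.5)          # confounded negative trend
  expect_lt(abs(rc$corrected$spearman), 0.35)
  expect_lt(abs(sum(residuals(rc$model))), 1e-8)
  # independent covariates: correction changes little
  expr2 <- 10^rnorm(n, 1, 0.5)
  tab2 <- data.table(intron_id = as.character(1:n), length = len,
                     expression = expr2,
                     error_rate = 0.002 + rnorm(n, 0, 5e-4))
  rc2 <- residual_correction(tab2, "length", "expression", n_bins = 25L)
  expect_lt(abs(rc2$raw$spearman - rc2$corrected$spearman), 0.25)
  expect_error(residual_correction(tab[, length := 100], "length",
                                   "expression"), "degenerate")
})

test_that("per-gene mis-splicing closed form", {
  expect_equal(per_gene_missplice(0.007, 3), 1 - (1 - 0.007)^3)
  expect_equal(round(per_gene_missplice(0.007, 3), 3), 0.021)
  expect_equal(per_gene_missplice(0, 5), 0)
  expect_equal(per_gene_missplice(0.3, 1), 0.3)
  expect_error(per_gene_missplice(1.4, 2))
})
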