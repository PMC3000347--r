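test_that("zero error rate yields zero error isoforms", {
  cfg <- sim_config(n_genes = 5L, per_intron_error_rate = 0)
  sim <- generate_genome(cfg, seed = 1)
  pool <- simulate_transcripts(sim$genome, sim$truth, cfg, seed = 2,
                               n_transcripts = 5000L)
  expect_equal(sum(pool$isoforms$is_error), 0L)
  tj <- truth_junctions(sim$truth, pool)
  expect_equal(nrow(tj$error_junctions), 0L)
})

test_that("per-copy error fraction matches the closed form 1-(1-eps)^n", {
  cfg <- sim_config(n_genes = 10L, per_intron_error_rate = 0.007,
                    frame_bias = 1)
  sim <- generate_genome(cfg, seed = 3)
  n_tx <- 200000L
  pool <- simulate_transcripts(sim$genome, sim$truth, cfg, seed = 4,
                               n_transcripts = n_tx)
  iso <- pool$isoforms
  gene_tot <- iso[, .(total = sum(count)), by = gene]
  gene_err <- iso[is_error == TRUE, .(err = sum(count)), by = gene]
  tab <- merge(gene_tot, gene_err, by = "gene", all.x = TRUE)
  tab[is.na(err), err := 0L]
  n_intr <- sim$truth$genes[, .(gene, n = n_exons - 1L)]
  tab <- merge(tab, n_intr, by = "gene")
  expected <- per_gene_missplice(0.007, tab$n)
  # aggregate: total error copies vs expectation, within 3 SE
  exp_tot <- sum(expected * tab$total)
  se <- sqrt(sum(expected * (1 - expected) * tab$total))
  expect_lt(abs(sum(tab$err) - exp_tot), 3 * se + 1)
  # the three-intron closed form itself
  expect_equal(per_gene_missplice(0.007, 3), 1 - 0.993^3)
  expect_equal(round(100 * per_gene_missplice(0.007, 3)), 2)
})

test_that("realized per-intron error fraction converges to epsilon", {
  cfg <- sim_config(n_genes = 4L, per_intron_error_rate = 0.02)
  sim <- generate_genome(cfg, seed = 5)
  n_tx <- 100000L
  pool <- simulate_transcripts(sim$genome, sim$truth, cfg, seed = 6,
                               n_transcripts = n_tx)
  ev <- merge(pool$events, pool$isoforms[, .(iso_id, count)], by = "iso_id")
  per_intron <- ev[, .(err = sum(count)), by = intron_id]
  copies <- pool$isoforms[, .(copies = sum(count)), by = gene]
  tab <- merge(sim$truth$introns[, .(intron_id, gene, epsilon)],
               per_intron, by = "intron_id", all.x = TRUE)
  tab[is.na(err), err := 0L]
  tab <- merge(tab, copies, by = "gene")
  tab[, se := sqrt(epsilon * (1 - epsilon) / copies)]
  frac_ok <- tab[, abs(err / copies - epsilon) <= 3 * se + 1e-9]
  # allow a single 3-SE excursion across all introns
  expect_gte(mean(frac_ok), 1 - 2 / nrow(tab))
})

test_that("NMD proxy thins frame-disrupting error isoforms", {
  cfg1 <- sim_config(n_genes = 10L, per_intron_error_rate = 0.05,
                     frame_bias = 1)
  sim <- generate_genome(cfg1, seed = 7)
  p1 <- simulate_transcripts(sim$genome, sim$truth, cfg1, seed = 8,
                             n_transcripts = 100000L)
  cfg2 <- sim_config(n_genes = 10L, per_intron_error_rate = 0.05,
                     frame_bias = 0.4)
  p2 <- simulate_transcripts(sim$genome, sim$truth, cfg2, seed = 8,
                             n_transcripts = 100000L)
  frac_if <- function(p) {
    e <- p$isoforms[is_error == TRUE]
    sum(e$count[e$frame_preserving]) / sum(e$count)
  }
  f1 <- frac_if(p1)
  f2 <- frac_if(p2)
  # expected boost: f / (f + bias * (1 - f))
  expect_gt(f2, f1)
  expect_lt(abs(f2 - f1 / (f1 + 0.4 * (1 - f1))), 0.03)
  expect_gt(f2, 1 / 3)
})

test_that("true and error junction sets are disjoint and share boundaries", {
  fx <- tiny_fixture()
  tj <- truth_junctions(fx$truth, fx$pool)
  merged <- merge(tj$true_junctions, tj$error_junctions,
                  by = c("chrom", "strand", "start", "end"))
  expect_equal(nrow(merged), 0L)
  # every single-boundary error junction shares exactly one boundary with
  # its generating intron
  ej <- tj$error_junctions[type %in% c("donor", "acceptor")]
  ti <- fx$truth$introns
  shared <- ej[ti, on = "intron_id",
               .(ok = (start == i.start) + (end == i.end)), nomatch = NULL]
  expect_true(all(shared$ok == 1L))
})

test_that("an intron without cryptic candidates falls back to retention", {
  fx <- tiny_fixture()
  truth2 <- fx$truth
  truth2$cryptic <- truth2$cryptic[0L]
  pool <- simulate_transcripts(fx$genome, truth2, fx$config, seed = 99,
                               n_transcripts = 5000L)
  ev <- pool$events
  expect_gt(nrow(ev), 0L)
  expect_true(all(ev$type == "retention"))
})

test_that("internal (both-new) error junctions are generable", {
  cfg <- sim_config(n_genes = 10L, per_intron_error_rate = 0.05,
                    double_error_fraction = 1, intron_meanlog = log(800))
  sim <- generate_genome(cfg, seed = 11)
  pool <- simulate_transcripts(sim$genome, sim$truth, cfg, seed = 12,
                               n_transcripts = 20000L)
  tj <- truth_junctions(sim$truth, pool)
  internal <- tj$error_junctions[type == "internal"]
  expect_gt(nrow(internal), 0L)
  # internal junctions lie fully inside their generating intron
  ti <- sim$truth$introns
  chk <- internal[ti, on = "intron_id",
                  .(inside = start >= i.start & end <= i.end),
                  nomatch = NULL]
  expect_true(all(chk$inside))
})
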