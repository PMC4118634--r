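test_that("identical configurations give identical simulated output", {
  cfg <- small_config(seed = 5L)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(as.character(p1$genome), as.character(p2$genome))
  expect_identical(p1$truth, p2$truth)
  for (ln in names(p1$reads))
    expect_identical(start(p1$reads[[ln]]), start(p2$reads[[ln]]))
  ## a different seed changes the genome
  p3 <- generate_genome(small_config(seed = 6L))
  expect_false(identical(as.character(p1$genome), as.character(p3)))
})

test_that("genome generation honours GC limits and degenerate inputs", {
  g0 <- generate_genome(small_config(seed = 2L, gc = 0))
  expect_equal(sum(Biostrings::letterFrequency(g0, "GC")), 0)
  g5 <- generate_genome(small_config(seed = 2L, gc = 0.5))
  gc_obs <- sum(Biostrings::letterFrequency(g5, "GC")) / sum(width(g5))
  expect_gt(gc_obs, 0.48)
  expect_lt(gc_obs, 0.52)
  expect_error(generate_genome(simulation_config(chrom_length = 400L)),
               "10 read lengths")
})

test_that("generated annotations satisfy their structural contract", {
  cfg <- small_config(seed = 7L)
  genome <- generate_genome(cfg)
  ann <- generate_annotation(cfg, genome)
  genes <- ann$genes
  expect_length(genes, cfg$n_genes)
  ## pairwise disjoint genes
  expect_equal(sum(width(reduce(genes, ignore.strand = TRUE))),
               sum(width(genes)))
  ## every gene has at least one CDS; both strands represented
  cds_genes <- unique(mcols(ann$parts)$gene_id[
    mcols(ann$parts)$part == "CDS"])
  expect_setequal(cds_genes, mcols(genes)$gene_id)
  expect_true(all(c("+", "-") %in% as.character(strand(genes))))
  expect_true(all(mcols(ann$repeats)$class %in% REPEAT_CLASSES))
  ## n_genes = 0 still yields CGIs and repeats
  cfg0 <- small_config(seed = 7L, n_genes = 0L,
                       n_diff_genes = c(hyper = 0L, hypo = 0L))
  ann0 <- generate_annotation(cfg0, genome)
  expect_length(ann0$genes, 0L)
  expect_length(ann0$cgi, cfg0$n_cgi)
  expect_length(ann0$repeats, cfg0$n_repeats)
})

test_that("hybrid methylome rules are exact at tile level", {
  cfg <- small_config(seed = 9L)
  genome <- generate_genome(cfg)
  ann <- generate_annotation(cfg, genome)
  m <- generate_methylomes(cfg, ann)
  p1 <- m[[1L]]; p2 <- m[[2L]]
  expect_gt(mean(p1$m), mean(p2$m))
  mpv <- (p1$m + p2$m) / 2
  ## delta = 0 additive: every tile equals the mid-parent value exactly
  add <- make_hybrid_methylome(p1, p2, "HA", rule = "additive")
  expect_identical(add$m, mpv)
  ## non_additive_up shifts the mean by delta up to clipping
  up <- make_hybrid_methylome(p1, p2, "HU", rule = "non_additive_up",
                              delta = 0.05)
  clip_correction <- mean(pmin(1, mpv + 0.05) - (mpv + 0.05))
  expect_equal(mean(up$m) - mean(mpv), 0.05 + clip_correction,
               tolerance = 1e-12)
  expect_equal(up$n_clipped, sum(mpv + 0.05 > 1))
  ## below_both sits strictly under both parents wherever it can
  lo <- make_hybrid_methylome(p1, p2, "LO", rule = "below_both",
                              margin = 0.1)
  expect_true(all(lo$m < pmin(p1$m, p2$m) | pmin(p1$m, p2$m) == 0))
  expect_true(all(lo$m >= 0 & lo$m <= 1))
})

test_that("read sampling follows the enrichment model", {
  cfg <- small_config(seed = 13L)
  genome <- generate_genome(cfg)
  ann <- generate_annotation(cfg, genome)
  tiles <- methylome_tiles(ann$seqinfo, cfg$tile)
  ## beta = 0 with a single methylated tile forces all reads there
  m <- rep(0, length(tiles))
  m[200L] <- 1
  meth <- new_meth <- structure(
    list(line_id = "X", tiles = tiles, m = m, rule = "parent",
         n_clipped = 0L), class = "MethylomeTruth")
  cfg0 <- small_config(seed = 13L, beta = 0, n_reads = 2000L)
  rd <- simulate_medip_reads(meth, cfg0)
  expect_length(rd, 2000L)
  expect_true(all(overlapsAny(
    resize(rd, 1L, fix = "start", ignore.strand = TRUE), tiles[200L])))
  ## n_reads = 0 gives empty output without error
  expect_length(simulate_medip_reads(meth, cfg0, n_reads = 0L), 0L)
  ## enrichment monotonicity: tile counts track m (rank correlation)
  cfgP <- simulation_config(seed = 14L, n_reads = 400000L,
                            n_diff_genes = c(hyper = 0L, hypo = 0L))
  genomeP <- generate_genome(cfgP)
  annP <- generate_annotation(cfgP, genomeP)
  methsP <- generate_methylomes(cfgP, annP)
  rdP <- simulate_medip_reads(methsP$P1, cfgP)
  cnt <- countOverlaps(methsP$P1$tiles,
                       resize(rdP, 1L, fix = "start",
                              ignore.strand = TRUE),
                       ignore.strand = TRUE)
  expect_gt(cor(methsP$P1$m, cnt, method = "spearman"), 0.9)
})

test_that("lambda = 0 reads are uniform (Poisson window dispersion)", {
  cfg <- small_config(seed = 21L, lambda = 0, n_reads = 40000L)
  genome <- generate_genome(cfg)
  ann <- generate_annotation(cfg, genome)
  meths <- generate_methylomes(cfg, ann)
  rd <- simulate_medip_reads(meths$P1, cfg)
  wp <- window_profile(rd, ann$seqinfo, window = 10000L,
                       unique_only = FALSE)
  raw <- mcols(wp)$raw
  ## index of dispersion ~ chisq(n-1)/(n-1) under Poisson
  disp <- (length(raw) - 1L) * var(raw) / mean(raw)
  lo <- qchisq(5e-4, length(raw) - 1L)
  hi <- qchisq(1 - 5e-4, length(raw) - 1L)
  expect_gt(disp, lo)
  expect_lt(disp, hi)
})

test_that("trait simulation recovers its generating means", {
  tt <- simulate_trait_table(seed = 8L)
  sm <- trait_summary(tt)
  means <- attr(tt, "line_means")
  at5 <- sm[sm$age == 5L, ]
  for (i in seq_len(nrow(at5))) {
    mu <- means[[at5$trait[i]]][[at5$line_id[i]]]
    expect_lt(abs(at5$mean[i] - mu), 3 * at5$se[i] + 0.05 * mu)
  }
})
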