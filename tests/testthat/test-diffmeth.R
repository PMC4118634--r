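test_that("peak merging coalesces overlapping and book-ended intervals", {
  a <- GRanges("chr1", IRanges(1, 10))
  b <- GRanges("chr1", IRanges(21, 30))
  m <- merge_peak_sets(a, b)
  expect_length(m, 2L)
  b2 <- GRanges("chr1", IRanges(6, 30))
  m2 <- merge_peak_sets(a, b2)
  expect_equal(ranges(m2), IRanges(1, 30))
  ## book-ended (gap 0) intervals join
  m3 <- merge_peak_sets(GRanges("chr1", IRanges(1, 10)),
                        GRanges("chr1", IRanges(11, 20)))
  expect_equal(ranges(m3), IRanges(1, 20))
  ## 100 random intervals equal the boolean-mask union
  set.seed(33)
  s <- sample(1:5000, 100, replace = TRUE)
  e <- s + sample(1:400, 100, replace = TRUE)
  half <- sample(100, 50)
  g1 <- GRanges("chr1", IRanges(s[half], e[half]))
  g2 <- GRanges("chr1", IRanges(s[-half], e[-half]))
  got <- merge_peak_sets(g1, g2)
  want <- oracle_union_mask(s, e, 6000L)
  expect_equal(start(got), want$start)
  expect_equal(end(got), want$end)
  expect_true(all(start(got)[-1L] > end(got)[-length(got)] + 1L))
})

test_that("the region chi-square matches hand and reference computations", {
  ## identical proportions: statistic 0, p 1
  t0 <- chisq_region_test(10, 10, 1e6, 1e6)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  ## hand-derived closed form for 30 vs 10 out of 1e6 each
  t1 <- chisq_region_test(30, 10, 1e6, 1e6)
  expect_equal(t1$statistic, 10.0002000, tolerance = 1e-8)
  expect_equal(t1$p_value, 1.5652323e-3, tolerance = 1e-7)
  ## no-coverage flagging
  t2 <- chisq_region_test(c(0, 5), c(0, 0), 1000, 2000)
  expect_true(t2$no_coverage[1L])
  expect_true(is.na(t2$p_value[1L]))
  expect_false(t2$no_coverage[2L])
  ## oracle equivalence over random tables
  set.seed(55)
  for (i in 1:300) {
    n1 <- sample(1e4:1e6, 1)
    n2 <- sample(1e4:1e6, 1)
    a <- rpois(1, 40)
    b <- rpois(1, 40)
    if (a == 0 && b == 0) next
    got <- chisq_region_test(a, b, n1, n2)
    want <- oracle_chisq(a, b, n1, n2)
    expect_equal(got$statistic, want$stat, tolerance = 1e-9)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
  expect_error(chisq_region_test(5, 1, 0, 10), "n1 > 0")
})

test_that("gene calling enforces direction, fold and coverage rules", {
  si <- tiny_seqinfo(c(chrA = 20000L))
  genes <- GRanges("chrA", IRanges(8001, 10000), strand = "+",
                   gene_id = "g1", seqinfo = si)
  parts <- GRanges("chrA", IRanges(c(6001, 8001), c(8000, 10000)),
                   strand = "+", seqinfo = si,
                   gene_id = c("g1", "g1"),
                   part = c("promoter", "CDS"))
  ann <- feature_annotation(genes, parts, seqinfo = si)
  region <- GRanges("chrA", IRanges(8001, 9000), seqinfo = si)
  r1 <- make_reads("chrA", seq(8001, 8951, by = 190), 49L, si)   # 6 reads
  r2 <- make_reads("chrA", seq(8001, 8996, by = 16), 49L, si)    # 63 reads
  rg <- diff_regions(region, r1, r2, unique_total1 = 1e5,
                     unique_total2 = 1e5)
  calls <- call_differential_genes(rg, ann, r1, r2)
  expect_equal(unique(calls$gene_id), "g1")
  expect_equal(unique(calls$direction), "hyper")  # sample 2 is higher
  expect_true(all(calls$feature == "CDS"))
  ## swapping samples flips the direction (antisymmetry)
  rg_sw <- diff_regions(region, r2, r1, unique_total1 = 1e5,
                        unique_total2 = 1e5)
  calls_sw <- call_differential_genes(rg_sw, ann, r2, r1)
  expect_equal(unique(calls_sw$direction), "hypo")
  expect_equal(calls_sw$p_value, calls$p_value)
  ## sub-threshold fold yields no call even at tiny p
  mcols(rg)$norm1 <- 100; mcols(rg)$norm2 <- 150
  mcols(rg)$p_value <- 1e-6
  expect_equal(nrow(call_differential_genes(rg, ann, r1, r2)), 0L)
  ## both samples must have reads in the overlapped feature
  r_none <- make_reads("chrA", integer(0), 49L, si)
  rg2 <- diff_regions(region, r1, r_none, unique_total1 = 1e5,
                      unique_total2 = 1e5)
  expect_equal(nrow(call_differential_genes(rg2, ann, r1, r_none)), 0L)
})

test_that("panel contrasts are antisymmetric and self-null", {
  cfg <- small_config(seed = 37L)
  panel <- simulate_panel(cfg)
  lines <- list(
    P1 = list(reads = panel$reads$P1, peaks = panel$peaks$P1),
    P2 = list(reads = panel$reads$P2, peaks = panel$peaks$P2))
  tab <- compare_panel(lines, panel$annotation,
                       data.frame(s1 = c("P1", "P2", "P1"),
                                  s2 = c("P2", "P1", "P1")))
  ## swapped contrast exchanges hyper and hypo counts
  expect_equal(tab$n_hyper[1L], tab$n_hypo[2L])
  expect_equal(tab$n_hypo[1L], tab$n_hyper[2L])
  ## a line against itself calls nothing
  expect_equal(tab$n_hyper[3L], 0L)
  expect_equal(tab$n_hypo[3L], 0L)
  expect_error(compare_panel(lines, panel$annotation,
                             data.frame(s1 = "P1", s2 = "NOPE")),
               "NOPE")
})

test_that("thresholds are monotone and truth genes are recovered", {
  cfg <- small_config(seed = 39L, n_reads = 30000L)
  panel <- simulate_panel(cfg)
  res <- diffmeth_contrast(panel$reads$P1, panel$reads$P2,
                           panel$peaks$P1, panel$peaks$P2,
                           panel$annotation)
  strict_p <- diffmeth_contrast(panel$reads$P1, panel$reads$P2,
                                panel$peaks$P1, panel$peaks$P2,
                                panel$annotation, alpha = 1e-4)
  strict_f <- diffmeth_contrast(panel$reads$P1, panel$reads$P2,
                                panel$peaks$P1, panel$peaks$P2,
                                panel$annotation, fold = 4)
  key <- function(x) paste(x$calls$gene_id, x$calls$feature,
                           x$calls$region)
  expect_true(all(key(strict_p) %in% key(res)))
  expect_true(all(key(strict_f) %in% key(res)))
  ## planted genes come back with the right direction
  called <- unique(res$calls[, c("gene_id", "direction")])
  hit <- merge(panel$truth, called, by = "gene_id",
               suffixes = c("_truth", "_called"))
  recall <- length(unique(hit$gene_id)) / nrow(panel$truth)
  expect_gte(recall, 0.8)
  expect_true(all(hit$direction_truth == hit$direction_called))
})
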