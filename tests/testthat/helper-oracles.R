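## Independent brute-force oracles and small fixture builders shared by
## the tests. Oracles deliberately re-derive results from first
## principles (enumeration, closed forms, base-R reference functions)
## rather than reusing package code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## Pearson chi-square on the 2x2 layout via stats::chisq.test
oracle_chisq <- function(a, b, n1, n2) {
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(stat = unname(ct$statistic), p = unname(ct$p.value))
}

## exact upper-tail hypergeometric P(X >= k) by log-binomial summation
oracle_hyper_p <- function(k, K, N, n) {
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## brute-force two-strand cytosine-context scanner (per-position loop)
oracle_context_counts <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cnt <- c(CG = 0L, CHG = 0L, CHH = 0L)
  dropped <- c(incomplete = 0L, ambiguous = 0L)
  classify <- function(d1, d2) {
    if (d1 == "G") return("CG")
    if (d1 %in% c("A", "T", "C")) {
      if (d2 == "G") return("CHG")
      if (d2 %in% c("A", "T", "C")) return("CHH")
    }
    NA_character_
  }
  for (i in seq_len(n)) {
    if (ch[i] == "C") {
      if (i + 2L > n) {
        dropped[["incomplete"]] <- dropped[["incomplete"]] + 1L
      } else {
        ctx <- classify(ch[i + 1L], ch[i + 2L])
        if (is.na(ctx)) dropped[["ambiguous"]] <- dropped[["ambiguous"]] + 1L
        else cnt[[ctx]] <- cnt[[ctx]] + 1L
      }
    }
    if (ch[i] == "G") {
      if (i - 2L < 1L) {
        dropped[["incomplete"]] <- dropped[["incomplete"]] + 1L
      } else {
        ctx <- classify(unname(comp[ch[i - 1L]]), unname(comp[ch[i - 2L]]))
        if (is.na(ctx)) dropped[["ambiguous"]] <- dropped[["ambiguous"]] + 1L
        else cnt[[ctx]] <- cnt[[ctx]] + 1L
      }
    }
  }
  list(counts = cnt, dropped = dropped)
}

## boolean-mask union of intervals on one sequence of given length
oracle_union_mask <- function(starts, ends, len) {
  mask <- logical(len)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  r <- rle(mask)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  data.frame(start = begins[r$values], end = stops[r$values])
}

## scaled-down simulation for fast module tests (dots override defaults)
small_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_chrom = 2L, chrom_length = 200000L,
               n_genes = 40L, n_cgi = 20L, n_repeats = 30L,
               n_reads = 20000L,
               n_diff_genes = c(hyper = 8L, hypo = 8L))
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

tiny_seqinfo <- function(lens = c(chrA = 10000L, chrB = 8000L)) {
  GenomeInfoDb::Seqinfo(seqnames = names(lens),
                        seqlengths = unname(lens))
}

## reads GRanges from coordinate vectors
make_reads <- function(chrom, start, width = 49L, seqinfo,
                       is_unique = TRUE, strand = "+") {
  start <- as.integer(start)
  gr <- GRanges(rep_len(chrom, length(start)),
                IRanges(start, width = width),
                strand = rep_len(strand, length(start)),
                seqinfo = seqinfo)
  mcols(gr)$is_unique <- rep_len(is_unique, length(gr))
  mcols(gr)$line_id <- rep_len("test", length(gr))
  gr
}
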