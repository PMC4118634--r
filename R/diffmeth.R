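## Differential methylation between two samples: merge the two peak
## sets, count normalized reads per merged region, filter with a
## Pearson chi-square test, and classify overlapping genes as hyper- or
## hypomethylated.

#' Merge two samples' peak sets into disjoint regions
#'
#' The union of both peak sets with overlapping or book-ended intervals
#' coalesced; the result is sorted and pairwise disjoint. These merged
#' regions (not the 1-bp summits) are the units on which the two
#' samples' read counts are compared — regions must have width to hold
#' reads.
#'
#' @param peaks1,peaks2 `GRanges` of peaks.
#' @return Sorted, disjoint `GRanges`.
#' @export
merge_peak_sets <- function(peaks1, peaks2) {
  reduce(sort(c(granges(peaks1), granges(peaks2))))
}

#' Pearson chi-square test on two samples' region counts
#'
#' Tests homogeneity of a region's read count against the library sizes
#' via the 2x2 table `[[a, N1 - a], [b, N2 - b]]`: Pearson chi-square
#' with 1 degree of freedom, no continuity correction (MeDIP peak counts
#' are large). Regions with `a = b = 0` are undefined and flagged
#' `no_coverage` (statistic and p set to `NA`); they are excluded from
#' differential calls.
#'
#' @param a,b Raw read counts of samples 1 and 2 in the region
#'   (vectorized).
#' @param n1,n2 Library totals (uniquely mapped reads) of the two
#'   samples.
#' @return Data frame `(statistic, p_value, no_coverage)`.
#' @examples
#' chisq_region_test(30, 10, 1e6, 1e6)  # stat ~ 10.0002
#' @export
chisq_region_test <- function(a, b, n1, n2) {
  stopifnot(all(n1 > 0), all(n2 > 0), all(a >= 0), all(b >= 0),
            all(a <= n1), all(b <= n2))
  m <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), m)
  b <- rep_len(as.numeric(b), m)
  n1 <- rep_len(as.numeric(n1), m)
  n2 <- rep_len(as.numeric(n2), m)
  x11 <- a; x12 <- n1 - a
  x21 <- b; x22 <- n2 - b
  N <- n1 + n2
  stat <- N * (x11 * x22 - x12 * x21)^2 /
    ((x11 + x12) * (x21 + x22) * (x11 + x21) * (x12 + x22))
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  none <- a == 0 & b == 0
  stat[none] <- NA_real_
  p[none] <- NA_real_
  data.frame(statistic = stat, p_value = p, no_coverage = none)
}

#' Merged regions with per-sample counts and chi-square statistics
#'
#' Counts each sample's reads over every merged region (full-span
#' overlap), normalizes to per-million of the sample's uniquely mapped
#' total, and attaches the [chisq_region_test()] results.
#'
#' @param regions Merged regions from [merge_peak_sets()].
#' @param reads1,reads2 Alignment `GRanges` of the two samples.
#' @param unique_total1,unique_total2 Per-million denominators
#'   (defaults: unique read counts of each sample).
#' @param unique_only Count only uniquely mapped reads (default `TRUE`).
#' @return `regions` with metadata columns `raw1`, `raw2`, `norm1`,
#'   `norm2`, `statistic`, `p_value`, `no_coverage`.
#' @export
diff_regions <- function(regions, reads1, reads2,
                         unique_total1 = NULL, unique_total2 = NULL,
                         unique_only = TRUE) {
  pick <- function(r) {
    if (unique_only && !is.null(mcols(r)$is_unique))
      r[mcols(r)$is_unique] else r
  }
  r1 <- pick(reads1)
  r2 <- pick(reads2)
  if (is.null(unique_total1)) unique_total1 <- length(r1)
  if (is.null(unique_total2)) unique_total2 <- length(r2)
  raw1 <- countOverlaps(regions, r1, ignore.strand = TRUE)
  raw2 <- countOverlaps(regions, r2, ignore.strand = TRUE)
  ts <- chisq_region_test(raw1, raw2, unique_total1, unique_total2)
  mcols(regions)$raw1 <- raw1
  mcols(regions)$raw2 <- raw2
  mcols(regions)$norm1 <- raw1 * 1e6 / unique_total1
  mcols(regions)$norm2 <- raw2 * 1e6 / unique_total2
  mcols(regions)$statistic <- ts$statistic
  mcols(regions)$p_value <- ts$p_value
  mcols(regions)$no_coverage <- ts$no_coverage
  regions
}

#' Call hyper-/hypomethylated genes from tested merged regions
#'
#' For every gene feature overlapping a merged region, a call is emitted
#' when all of: `p < alpha`; the normalized-count ratio exceeds `fold`
#' (strictly; a zero-count side gives an infinite ratio, which passes
#' when p does); and both samples have at least one read in the
#' region/feature overlap. Direction follows the sample-2 comparison: in
#' a sample1-versus-sample2 contrast the gene is `hyper`methylated when
#' sample 2's normalized count is higher, `hypo` when sample 1's is. One
#' gene may be called in several feature classes (and, via different
#' regions, in both directions: gene-level totals then count it once per
#' direction).
#'
#' @param regions Output of [diff_regions()].
#' @param annotation A `FeatureAnnotation`.
#' @param reads1,reads2 The same (filtered) reads used for counting;
#'   needed for the per-feature coverage check.
#' @param alpha P-value threshold (default 0.01).
#' @param fold Fold-change threshold (default 2; strict).
#' @return Data frame with one row per gene x feature x region call:
#'   `gene_id`, `feature`, `direction`, `fold`, `p_value`, `region`.
#' @export
call_differential_genes <- function(regions, annotation, reads1, reads2,
                                    alpha = 0.01, fold = 2) {
  stopifnot(is(annotation, "FeatureAnnotation"))
  mc <- mcols(regions)
  ratio <- pmax(mc$norm1, mc$norm2) / pmin(mc$norm1, mc$norm2)
  pass <- !mc$no_coverage & !is.na(mc$p_value) & mc$p_value < alpha &
    ratio > fold
  empty <- data.frame(gene_id = character(0), feature = character(0),
                      direction = character(0), fold = numeric(0),
                      p_value = numeric(0), region = character(0),
                      stringsAsFactors = FALSE)
  if (!any(pass)) return(empty)
  cand <- regions[pass]
  parts <- annotation$parts
  hits <- findOverlaps(cand, parts, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  inter <- pintersect(granges(cand)[queryHits(hits)],
                      granges(parts)[subjectHits(hits)],
                      ignore.strand = TRUE)
  cov1 <- countOverlaps(inter, reads1, ignore.strand = TRUE) > 0L
  cov2 <- countOverlaps(inter, reads2, ignore.strand = TRUE) > 0L
  keep <- cov1 & cov2
  if (!any(keep)) return(empty)
  q <- queryHits(hits)[keep]
  s <- subjectHits(hits)[keep]
  mcq <- mcols(cand)[q, ]
  out <- data.frame(
    gene_id = mcols(parts)$gene_id[s],
    feature = mcols(parts)$part[s],
    direction = ifelse(mcq$norm2 > mcq$norm1, "hyper", "hypo"),
    fold = pmax(mcq$norm1, mcq$norm2) / pmin(mcq$norm1, mcq$norm2),
    p_value = mcq$p_value,
    region = as.character(granges(cand))[q],
    stringsAsFactors = FALSE)
  unique(out)
}

#' Gene-level differential counts
#'
#' Deduplicates feature-level calls to one record per gene and
#' direction; a gene called in conflicting directions by different
#' regions counts once per direction.
#'
#' @param calls Output of [call_differential_genes()].
#' @return Named integer vector `c(hyper = , hypo = )`.
#' @export
differential_gene_counts <- function(calls) {
  u <- unique(calls[, c("gene_id", "direction")])
  c(hyper = sum(u$direction == "hyper"),
    hypo = sum(u$direction == "hypo"))
}

#' Run one differential-methylation contrast end to end
#'
#' Merges the two samples' peaks, counts and tests regions, and calls
#' genes.
#'
#' @param reads1,reads2,peaks1,peaks2 Per-sample alignments and peaks.
#' @param annotation A `FeatureAnnotation`.
#' @inheritParams call_differential_genes
#' @inheritParams diff_regions
#' @return `list(regions = , calls = , counts = )`.
#' @export
diffmeth_contrast <- function(reads1, reads2, peaks1, peaks2, annotation,
                              alpha = 0.01, fold = 2, unique_only = TRUE) {
  regions <- merge_peak_sets(peaks1, peaks2)
  pick <- function(r) {
    if (unique_only && !is.null(mcols(r)$is_unique))
      r[mcols(r)$is_unique] else r
  }
  r1 <- pick(reads1)
  r2 <- pick(reads2)
  regions <- diff_regions(regions, r1, r2, unique_only = FALSE)
  calls <- call_differential_genes(regions, annotation, r1, r2,
                                   alpha = alpha, fold = fold)
  list(regions = regions, calls = calls,
       counts = differential_gene_counts(calls))
}

#' Hyper/hypo gene counts for a panel of contrasts
#'
#' @param lines Named list; each element is `list(reads = , peaks = )`
#'   for one line.
#' @param annotation A `FeatureAnnotation`.
#' @param contrasts Data frame (or 2-column matrix) with columns
#'   `s1`, `s2` naming the lines of each contrast.
#' @inheritParams diffmeth_contrast
#' @return Data frame `(s1, s2, n_hyper, n_hypo)`, one row per
#'   contrast.
#' @export
compare_panel <- function(lines, annotation, contrasts, alpha = 0.01,
                          fold = 2, unique_only = TRUE) {
  contrasts <- as.data.frame(contrasts, stringsAsFactors = FALSE)
  names(contrasts)[1:2] <- c("s1", "s2")
  unknown <- setdiff(unique(c(contrasts$s1, contrasts$s2)), names(lines))
  if (length(unknown) > 0L)
    stop("unknown line id(s) in contrasts: ",
         paste(unknown, collapse = ", "))
  res <- lapply(seq_len(nrow(contrasts)), function(i) {
    a <- lines[[contrasts$s1[i]]]
    b <- lines[[contrasts$s2[i]]]
    cnt <- diffmeth_contrast(a$reads, b$reads, a$peaks, b$peaks,
                             annotation, alpha = alpha, fold = fold,
                             unique_only = unique_only)$counts
    data.frame(s1 = contrasts$s1[i], s2 = contrasts$s2[i],
               n_hyper = cnt[["hyper"]], n_hypo = cnt[["hypo"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
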