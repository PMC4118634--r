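## Read/peak assignment to genomic features and binned metaprofiles.

#' Fractions of reads or peaks overlapping each feature class
#'
#' An item (read or peak) is counted for every class it overlaps by at
#' least 1 bp, so an item spanning two classes counts in both and the
#' per-class fractions need not sum to 1. The denominator is the total
#' number of items supplied (all mapped reads, or all peaks of the
#' line), recorded in the output.
#'
#' @param items `GRanges` of reads or peaks.
#' @param annotation A `FeatureAnnotation`.
#' @param classes Feature classes to report; defaults to the five gene
#'   parts, `CGI`, and every repeat class present.
#' @param denominator Total used for fractions (defaults to
#'   `length(items)`).
#' @return Data frame `(class, n, fraction, denominator)`.
#' @export
feature_fractions <- function(items, annotation, classes = NULL,
                              denominator = length(items)) {
  stopifnot(is(annotation, "FeatureAnnotation"))
  rep_classes <- unique(mcols(annotation$repeats)$class)
  if (is.null(classes))
    classes <- c(FEATURE_PARTS, "CGI", rep_classes)
  empty <- length(annotation$parts) == 0L &&
    length(annotation$cgi) == 0L && length(annotation$repeats) == 0L
  if (empty) warning("empty annotation: all fractions are zero")
  n <- vapply(classes, function(cl) {
    target <- if (cl %in% FEATURE_PARTS) {
      annotation$parts[mcols(annotation$parts)$part == cl]
    } else if (cl == "CGI") {
      annotation$cgi
    } else {
      annotation$repeats[mcols(annotation$repeats)$class == cl]
    }
    if (length(target) == 0L) return(0L)
    sum(overlapsAny(items, target, ignore.strand = TRUE))
  }, integer(1))
  data.frame(class = classes, n = unname(n),
             fraction = if (denominator > 0) unname(n) / denominator
                        else rep(0, length(classes)),
             denominator = denominator,
             stringsAsFactors = FALSE, row.names = NULL)
}

## mean of a per-base step function over n equal-width bins, with
## proportional attribution of bases split by fractional boundaries
bin_means <- function(x, n) {
  L <- length(x)
  cum <- c(0, cumsum(x))
  interp <- function(t) {
    i <- floor(t)
    frac <- t - i
    cum[i + 1L] + ifelse(frac > 0, frac * x[pmin(i + 1L, L)], 0)
  }
  b <- L * (0:n) / n
  (interp(b[-1L]) - interp(b[-(n + 1L)])) / diff(b)
}

#' Binned metaprofile of coverage depth around intervals
#'
#' The classic 20/40/20 layout: fixed-width flank bins over `flank` bp
#' upstream and downstream, and `n_body` bins each covering an equal
#' fraction of the interval (so body bins are variable bp wide;
#' fractional boundaries attribute bases proportionally). Depth is
#' averaged within each bin, scaled to per-million of uniquely mapped
#' reads, then averaged across intervals per bin index. Stranded
#' intervals are oriented 5' to 3'; unstranded ones left to right in
#' genome coordinates. Flanks running off a chromosome end contribute
#' zero depth.
#'
#' @param intervals `GRanges` (e.g. CpG islands or gene bodies).
#'   Intervals shorter than `n_body` bp are skipped with a message.
#' @param reads Alignment `GRanges`.
#' @param unique_total Per-million denominator; defaults to the unique
#'   reads in `reads`.
#' @param n_up,n_body,n_down Bin counts (default 20/40/20).
#' @param flank Flank span in bp (default 2000).
#' @return Data frame with `bin` (1-based across the 80 bins), `segment`
#'   (`upstream`/`body`/`downstream`) and `depth`;
#'   `attr(x, "n_intervals")` gives the number profiled.
#' @export
metaprofile <- function(intervals, reads, unique_total = NULL,
                        n_up = 20L, n_body = 40L, n_down = 20L,
                        flank = 2000L) {
  if (length(intervals) == 0L) stop("no intervals to profile")
  if (is.null(unique_total)) {
    unique_total <- if (!is.null(mcols(reads)$is_unique))
      sum(mcols(reads)$is_unique) else length(reads)
  }
  short <- width(intervals) < n_body
  if (any(short)) {
    message(sum(short), " interval(s) shorter than ", n_body,
            " bp skipped")
    intervals <- intervals[!short]
  }
  if (length(intervals) == 0L) stop("no intervals left to profile")
  cov <- coverage(reads)
  lens <- seqlengths(seqinfo(reads))
  nbins <- n_up + n_body + n_down
  acc <- matrix(0, nrow = length(intervals), ncol = nbins)
  chrom_depth <- list()
  for (k in seq_along(intervals)) {
    chrom <- as.character(seqnames(intervals))[k]
    if (is.null(chrom_depth[[chrom]])) {
      chrom_depth[[chrom]] <- if (chrom %in% names(cov))
        as.numeric(cov[[chrom]]) else numeric(lens[[chrom]])
    }
    depth <- chrom_depth[[chrom]]
    L <- length(depth)
    s <- start(intervals)[k]
    e <- end(intervals)[k]
    slice <- function(a, b) {
      out <- numeric(b - a + 1L)
      lo <- max(a, 1L)
      hi <- min(b, L)
      if (lo <= hi) out[(lo - a + 1L):(hi - a + 1L)] <- depth[lo:hi]
      out
    }
    up <- bin_means(slice(s - flank, s - 1L), n_up)
    body <- bin_means(slice(s, e), n_body)
    down <- bin_means(slice(e + 1L, e + flank), n_down)
    prof <- c(up, body, down)
    if (as.character(strand(intervals))[k] == "-") prof <- rev(prof)
    acc[k, ] <- prof
  }
  depth_mean <- colMeans(acc) * 1e6 / unique_total
  out <- data.frame(
    bin = seq_len(nbins),
    segment = rep(c("upstream", "body", "downstream"),
                  c(n_up, n_body, n_down)),
    depth = depth_mean,
    stringsAsFactors = FALSE)
  attr(out, "n_intervals") <- length(intervals)
  out
}
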