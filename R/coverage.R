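## Mapping summaries, per-million 100-kb window tracks, genome coverage,
## and CG/CHG/CHH cytosine-context coverage statistics.

#' Per-line mapping summary
#'
#' Mapped and uniquely-mapped rates as percentages of the original read
#' count: `rate = 100 * count / total_reads`. Rates are kept at full
#' precision; round only at presentation.
#'
#' @param total_reads,mapped_reads,unique_reads Read counts (vectorized
#'   over lines).
#' @param line_id Optional line labels.
#' @param mapped_bases,unique_bases Optional base counts carried through.
#' @return A data frame with one row per line: counts, `mapped_rate` and
#'   `unique_rate` (percent).
#' @examples
#' mapping_summary(97959184, 81729006, 65078019, "P1")
#' @export
mapping_summary <- function(total_reads, mapped_reads, unique_reads,
                            line_id = NULL, mapped_bases = NA,
                            unique_bases = NA) {
  if (any(total_reads == 0)) stop("total_reads must be positive")
  if (any(mapped_reads > total_reads))
    stop("mapped_reads cannot exceed total_reads")
  if (any(unique_reads > mapped_reads))
    stop("unique_reads cannot exceed mapped_reads")
  if (is.null(line_id)) line_id <- paste0("line", seq_along(total_reads))
  data.frame(line_id = line_id,
             total_reads = total_reads,
             mapped_reads = mapped_reads,
             unique_reads = unique_reads,
             mapped_rate = 100 * mapped_reads / total_reads,
             unique_rate = 100 * unique_reads / total_reads,
             mapped_bases = mapped_bases,
             unique_bases = unique_bases,
             stringsAsFactors = FALSE)
}

#' @describeIn mapping_summary Build the summary from an alignment
#'   `GRanges` (with `is_unique`) plus the original sequencing depth.
#' @param reads `GRanges` from [read_alignments()] or the simulator.
#' @export
mapping_summary_from_reads <- function(reads, total_reads,
                                       line_id = NA_character_) {
  mapping_summary(total_reads, length(reads),
                  sum(mcols(reads)$is_unique), line_id,
                  mapped_bases = sum(width(reads)),
                  unique_bases = sum(width(reads)[mcols(reads)$is_unique]))
}

#' Normalized window coverage track
#'
#' Chromosomes are tiled with fixed windows (the last window of each
#' chromosome may be short); each read is assigned to the window
#' containing its start coordinate, and window counts are normalized to
#' reads-per-million of uniquely mapped reads:
#' `normalized = raw * 1e6 / unique_total`.
#'
#' @param reads Alignment `GRanges`.
#' @param seqinfo `Seqinfo` for the genome (defaults to the reads').
#' @param window Window width in bp (default 100 kb).
#' @param unique_only Count only uniquely mapped reads (default `TRUE`,
#'   consistent with the per-million denominator).
#' @param unique_total Denominator for the per-million scaling; defaults
#'   to the number of unique reads in `reads`.
#' @return `GRanges` of windows with metadata columns `raw` and `norm`;
#'   raw counts over all windows sum to the number of counted reads.
#' @export
window_profile <- function(reads, seqinfo = NULL, window = 100000L,
                           unique_only = TRUE, unique_total = NULL) {
  if (window <= 0L) stop("window must be positive")
  if (is.null(seqinfo)) seqinfo <- seqinfo(reads)
  if (anyNA(seqlengths(seqinfo)))
    stop("window_profile needs complete seqlengths")
  if (is.null(unique_total)) {
    unique_total <- if (!is.null(mcols(reads)$is_unique))
      sum(mcols(reads)$is_unique) else length(reads)
  }
  counted <- if (unique_only && !is.null(mcols(reads)$is_unique))
    reads[mcols(reads)$is_unique] else reads
  wins <- tileGenome(seqlengths(seqinfo), tilewidth = window,
                     cut.last.tile.in.chrom = TRUE)
  ## assign by start coordinate: reduce each read to its first base
  starts <- resize(counted, width = 1L, fix = "start", ignore.strand = TRUE)
  raw <- countOverlaps(wins, starts, ignore.strand = TRUE)
  mcols(wins)$raw <- raw
  mcols(wins)$norm <- if (unique_total > 0) raw * 1e6 / unique_total
                      else rep(NA_real_, length(wins))
  wins
}

#' Fraction of the genome covered by at least one read
#'
#' @param reads Alignment `GRanges`.
#' @param seqinfo `Seqinfo` (defaults to the reads').
#' @return Proportion of genome bases overlapped by one or more reads.
#' @export
genome_coverage <- function(reads, seqinfo = NULL) {
  if (is.null(seqinfo)) seqinfo <- seqinfo(reads)
  if (anyNA(seqlengths(seqinfo)))
    stop("genome_coverage needs complete seqlengths")
  if (length(reads) == 0L) return(0)
  sum(width(reduce(reads, ignore.strand = TRUE))) /
    sum(as.numeric(seqlengths(seqinfo)))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Index every cytosine by its CG/CHG/CHH context
#'
#' Scans both strands: a plus-strand cytosine at position `i` is
#' classified by bases `i+1, i+2`; a minus-strand cytosine (a `G` on the
#' plus strand) by the complements of bases `i-1, i-2`. `H` is A, T or
#' C. Cytosines whose two downstream bases run off the chromosome end
#' are dropped and counted, as are those with an `N` in the window.
#'
#' @param genome A `DNAStringSet`.
#' @return An object of class `ContextSites`: a list with `sites` (data
#'   frame `chrom`, `pos`, `strand`, `context`), per-context `totals`,
#'   and `dropped` diagnostics (`incomplete`, `ambiguous`).
#' @export
context_sites <- function(genome) {
  all_sites <- vector("list", length(genome))
  dropped <- c(incomplete = 0L, ambiguous = 0L)
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    chars <- strsplit(as.character(genome[[ci]]), "", fixed = TRUE)[[1L]]
    n <- length(chars)
    out <- list()
    for (str in c("+", "-")) {
      if (str == "+") {
        idx <- which(chars == "C")
        complete <- idx <= n - 2L
        dropped[["incomplete"]] <- dropped[["incomplete"]] +
          sum(!complete)
        idx <- idx[complete]
        d1 <- chars[idx + 1L]
        d2 <- chars[idx + 2L]
      } else {
        idx <- which(chars == "G")
        complete <- idx >= 3L
        dropped[["incomplete"]] <- dropped[["incomplete"]] +
          sum(!complete)
        idx <- idx[complete]
        d1 <- unname(COMPLEMENT[chars[idx - 1L]])
        d2 <- unname(COMPLEMENT[chars[idx - 2L]])
      }
      ctx <- rep(NA_character_, length(idx))
      is_h1 <- d1 %in% c("A", "T", "C")
      ctx[d1 == "G"] <- "CG"
      ctx[is_h1 & d2 == "G"] <- "CHG"
      ctx[is_h1 & d2 %in% c("A", "T", "C")] <- "CHH"
      amb <- is.na(ctx)
      dropped[["ambiguous"]] <- dropped[["ambiguous"]] + sum(amb)
      if (any(!amb))
        out[[str]] <- data.frame(chrom = chrom, pos = idx[!amb],
                                 strand = str, context = ctx[!amb],
                                 stringsAsFactors = FALSE)
    }
    all_sites[[ci]] <- do.call(rbind, out)
  }
  sites <- do.call(rbind, all_sites)
  if (is.null(sites))
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), context = character(0))
  rownames(sites) <- NULL
  totals <- table(factor(sites$context, levels = c("CG", "CHG", "CHH")))
  structure(list(sites = sites, totals = totals, dropped = dropped),
            class = "ContextSites")
}

#' @export
print.ContextSites <- function(x, ...) {
  cat("ContextSites:", paste(names(x$totals), as.integer(x$totals),
                             sep = "=", collapse = ", "),
      "| dropped:", paste(names(x$dropped), x$dropped, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Context coverage statistics
#'
#' The proportion of CG/CHG/CHH sites whose cytosine position is covered
#' by at least `d` reads, the regional methylation-coverage statistic of
#' MeDIP analyses (1x depth by default).
#'
#' @param sites A [context_sites()] index.
#' @param reads Alignment `GRanges`.
#' @param d Depth threshold (>= 1).
#' @param unique_only Restrict depth to uniquely mapped reads (default
#'   `FALSE`: all mapped reads contribute depth).
#' @return Data frame with one row per context: `covered_sites`,
#'   `total_sites`, `proportion` (in `[0, 1]`).
#' @export
context_coverage <- function(sites, reads, d = 1L, unique_only = FALSE) {
  if (d < 1L) stop("depth threshold d must be >= 1")
  stopifnot(is(sites, "ContextSites"))
  if (unique_only && !is.null(mcols(reads)$is_unique))
    reads <- reads[mcols(reads)$is_unique]
  cov <- coverage(reads)
  df <- sites$sites
  covered <- logical(nrow(df))
  for (chrom in unique(df$chrom)) {
    sel <- df$chrom == chrom
    if (chrom %in% names(cov)) {
      depth <- as.integer(cov[[chrom]][df$pos[sel]])
      covered[sel] <- depth >= d
    }
  }
  ctx <- factor(df$context, levels = c("CG", "CHG", "CHH"))
  total <- as.integer(table(ctx))
  hit <- as.integer(tapply(covered, ctx, sum, default = 0L))
  data.frame(context = c("CG", "CHG", "CHH"),
             depth_threshold = d,
             covered_sites = hit,
             total_sites = total,
             proportion = ifelse(total > 0, hit / total, NA_real_),
             stringsAsFactors = FALSE)
}
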