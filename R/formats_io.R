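## Readers and writers for the external formats the pipeline touches.
## Internally everything is a GRanges (1-based closed); BED (0-based
## half-open) and MACS peak tables (1-based) are converted at this
## boundary only.

#' Read aligned MeDIP-Seq reads from SAM or BED
#'
#' Parses single-end alignment records into a `GRanges` with one range per
#' mapped read. Unmapped records (SAM flag 0x4) are skipped and counted;
#' the count is available as `metadata(x)$n_skipped`.
#'
#' Dialects for the per-read uniqueness flag (multi-mappers cannot be
#' re-derived downstream, so the aligner must supply it):
#' * SAM: a read is unique when `MAPQ > 0` and it is not flagged secondary
#'   (0x100).
#' * BED6: the score column carries the flag, `1` = uniquely mapped,
#'   `0` = ambiguous.
#'
#' @param path Path to the alignment file.
#' @param format `"sam"` or `"bed"`.
#' @param seqinfo Optional [GenomeInfoDb::Seqinfo] declaring the valid
#'   chromosomes. Required for BED input; for SAM it defaults to the
#'   `@SQ` header lines.
#' @param line_id Sample label stored in the `line_id` metadata column.
#' @return `GRanges` with metadata columns `is_unique` (logical) and
#'   `line_id`; `metadata(x)$n_skipped` gives the number of unmapped
#'   records that were dropped.
#' @examples
#' cfg <- simulation_config(seed = 1, n_reads = 200)
#' sim <- simulate_panel(cfg)
#' f <- tempfile(fileext = ".sam")
#' write_sam(sim$reads$P1, f)
#' rd <- read_alignments(f, "sam", line_id = "P1")
#' length(rd)
#' @export
read_alignments <- function(path, format = c("sam", "bed"), seqinfo = NULL,
                            line_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  gr <- switch(format,
    sam = read_sam_alignments(path, seqinfo),
    bed = read_bed_alignments(path, seqinfo)
  )
  mcols(gr)$line_id <- rep_len(line_id, length(gr))
  gr
}

read_sam_alignments <- function(path, seqinfo = NULL) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  if (is.null(seqinfo)) {
    sq <- lines[startsWith(lines, "@SQ")]
    if (length(sq) == 0L && any(!is_header))
      stop("SAM file has no @SQ header lines and no seqinfo was supplied")
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    seqinfo <- Seqinfo(seqnames = sn, seqlengths = ln)
  }
  body_idx <- which(!is_header & nzchar(lines))
  n_skipped <- 0L
  if (length(body_idx) == 0L) {
    gr <- GRanges(seqinfo = seqinfo)
    mcols(gr)$is_unique <- logical(0)
    metadata(gr)$n_skipped <- 0L
    return(gr)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM record at line ", body_idx[which(nf < 11L)[1L]],
         ": fewer than 11 fields")
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(flag))
    stop("malformed SAM record at line ", body_idx[which(is.na(flag))[1L]],
         ": FLAG is not an integer")
  mapped <- bitwAnd(flag, 4L) == 0L
  n_skipped <- sum(!mapped)
  fields <- fields[mapped]
  body_idx <- body_idx[mapped]
  flag <- flag[mapped]
  if (length(fields) == 0L) {
    gr <- GRanges(seqinfo = seqinfo)
    mcols(gr)$is_unique <- logical(0)
    metadata(gr)$n_skipped <- n_skipped
    return(gr)
  }
  chrom <- vapply(fields, `[[`, "", 3L)
  bad_chrom <- setdiff(unique(chrom), seqlevels(seqinfo))
  if (length(bad_chrom) > 0L)
    stop("unknown chromosome(s) in SAM records: ",
         paste(bad_chrom, collapse = ", "))
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  if (anyNA(pos) || any(pos < 1L))
    stop("malformed SAM record at line ",
         body_idx[which(is.na(pos) | pos < 1L)[1L]], ": bad POS")
  mapq <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  seq <- vapply(fields, `[[`, "", 10L)
  width <- nchar(seq)
  if (any(seq == "*")) {
    ## fall back on CIGAR reference span when SEQ is omitted
    cig <- vapply(fields, `[[`, "", 6L)[seq == "*"]
    width[seq == "*"] <- cigar_ref_width(cig)
  }
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  is_unique <- !is.na(mapq) & mapq > 0L & bitwAnd(flag, 256L) == 0L
  gr <- GRanges(chrom, IRanges(start = pos, width = width), strand = strand,
                seqinfo = seqinfo)
  over <- end(gr) > seqlengths(seqinfo)[as.character(seqnames(gr))]
  if (any(over))
    stop("malformed SAM record at line ", body_idx[which(over)[1L]],
         ": alignment extends past the end of its chromosome")
  mcols(gr)$is_unique <- is_unique
  metadata(gr)$n_skipped <- n_skipped
  gr
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

read_bed_alignments <- function(path, seqinfo) {
  if (is.null(seqinfo))
    stop("seqinfo must be supplied for BED alignment input")
  bed <- read_bed(path)
  bad_chrom <- setdiff(unique(as.character(seqnames(bed))),
                       seqlevels(seqinfo))
  if (length(bad_chrom) > 0L)
    stop("unknown chromosome(s) in BED records: ",
         paste(bad_chrom, collapse = ", "))
  if (is.null(bed$score))
    stop("BED alignment dialect requires a score column (1 = unique)")
  gr <- GRanges(seqnames(bed), ranges(bed), strand = strand(bed),
                seqinfo = seqinfo)
  mcols(gr)$is_unique <- bed$score > 0
  metadata(gr)$n_skipped <- 0L
  gr
}

#' Read peak intervals from a MACS-style table or BED
#'
#' @param path Path to the peak file. Lines starting with `#` and blank
#'   lines are ignored; a `chr<TAB>start...` header row is detected and
#'   skipped for the MACS dialect.
#' @param format `"macs_xls"` (1-based tab-delimited, as written by MACS
#'   1.4) or `"bed"` (0-based half-open).
#' @return `GRanges` in input order, one range per peak.
#' @export
read_peaks <- function(path, format = c("macs_xls", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) > 0L && grepl("^chr(om)?\t", lines[1L])) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (length(lines) == 0L) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed peak record at line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed peak record at line ",
         lineno[which(is.na(start) | is.na(end))[1L]],
         ": non-numeric coordinates")
  bad <- end <= start
  if (any(bad))
    stop("invalid peak interval (end <= start) at line ",
         lineno[which(bad)[1L]])
  if (format == "bed") start <- start + 1  # 0-based half-open -> 1-based
  GRanges(chrom, IRanges(start = as.integer(start), end = as.integer(end)))
}

#' Read and write canonical BED
#'
#' `read_bed()` parses BED3/BED6 into a `GRanges`; `write_bed()` writes a
#' `GRanges` back out. A `write_bed(read_bed(f))` round trip is
#' byte-identical for canonical tab-separated BED6 (and BED3 when neither
#' `name`, `score` nor strand is set).
#'
#' @param path File path.
#' @param gr `GRanges`, optionally with `name` and `score` metadata
#'   columns.
#' @return `read_bed()`: a `GRanges`; `write_bed()`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED record at line ", lineno[which(nf < 3L)[1L]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end) || any(end <= start))
    stop("malformed BED record at line ",
         lineno[which(is.na(start) | is.na(end) | end <= start)[1L]])
  strand <- rep("*", length(lines))
  name <- NULL
  score <- NULL
  if (all(nf >= 4L)) name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L))
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(nf >= 6L)) strand <- vapply(fields, `[[`, "", 6L)
  gr <- GRanges(chrom, IRanges(start = as.integer(start) + 1L,
                               end = as.integer(end)),
                strand = ifelse(strand %in% c("+", "-"), strand, "*"))
  if (!is.null(name)) mcols(gr)$name <- name
  if (!is.null(score)) mcols(gr)$score <- score
  gr
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  cols <- list(as.character(seqnames(gr)),
               format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
               format(end(gr), scientific = FALSE, trim = TRUE))
  has_name <- !is.null(mcols(gr)$name)
  has_score <- !is.null(mcols(gr)$score)
  has_strand <- any(as.character(strand(gr)) != "*")
  if (has_name || has_score || has_strand) {
    cols <- c(cols, list(if (has_name) mcols(gr)$name else rep(".", n)))
    if (has_score || has_strand) {
      sc <- if (has_score) mcols(gr)$score else rep(0, n)
      cols <- c(cols, list(format(sc, scientific = FALSE, trim = TRUE)))
    }
    if (has_strand) {
      st <- as.character(strand(gr))
      cols <- c(cols, list(ifelse(st == "*", ".", st)))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Write aligned reads as SAM
#'
#' Emits a minimal single-end SAM file (`@HD`/`@SQ` header, flag, MAPQ
#' encoding the uniqueness dialect read back by [read_alignments()]).
#' Sequence and quality strings are written as runs of `N` / `I` of the
#' read length: MeDIP coverage analysis never inspects base calls.
#'
#' @param reads `GRanges` with `is_unique` metadata column and a complete
#'   `seqinfo`.
#' @param path Output path.
#' @param unmapped Optional integer: number of additional unmapped
#'   placeholder records (flag 4) to append, useful for exercising
#'   skip-counting in readers.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, unmapped = 0L) {
  si <- seqinfo(reads)
  if (anyNA(seqlengths(si)))
    stop("write_sam needs complete seqlengths on the reads' seqinfo")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", seqnames(si), "\tLN:", seqlengths(si)))
  n <- length(reads)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (n > 0L) {
    flag <- ifelse(as.character(strand(reads)) == "-", 16L, 0L)
    mapq <- ifelse(mcols(reads)$is_unique, 60L, 0L)
    w <- width(reads)
    recs <- paste(paste0("read", seq_len(n)), flag,
                  as.character(seqnames(reads)), start(reads), mapq,
                  paste0(w, "M"), "*", 0L, 0L,
                  strrep("N", w), strrep("I", w), sep = "\t")
    writeLines(recs, con)
  }
  if (unmapped > 0L) {
    recs <- paste(paste0("unmapped", seq_len(unmapped)), 4L, "*", 0L, 0L,
                  "*", "*", 0L, 0L, strrep("N", 49L), strrep("I", 49L),
                  sep = "\t")
    writeLines(recs, con)
  }
  invisible(path)
}
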