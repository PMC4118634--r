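## FeatureAnnotation: strand-aware gene models decomposed into
## promoter / 5'UTR / CDS / intron / 3'UTR, plus CpG-island and
## repeat-class intervals. The container every read- and peak-assignment
## step works against.

#' Gene-part vocabulary used throughout the package
#' @keywords internal
FEATURE_PARTS <- c("promoter", "five_prime_UTR", "CDS", "intron",
                   "three_prime_UTR")

#' Repeat-class vocabulary for simulated annotations
#'
#' The transposable-element and repeat families profiled in poplar MeDIP
#' studies (RepeatMasker nomenclature).
#' @keywords internal
REPEAT_CLASSES <- c("LTR-Gypsy", "LTR-Copia", "DNA/En-Spm",
                    "Low_complexity", "Simple-repeat", "rRNA")

#' Construct a FeatureAnnotation
#'
#' Bundles gene models (decomposed into parts), CpG islands, and repeat
#' intervals behind one object. Gene parts of a single gene must not
#' overlap each other (promoters excepted: a promoter may run into a
#' neighbouring gene).
#'
#' @param genes `GRanges` of gene spans with a `gene_id` metadata column
#'   and `+`/`-` strand.
#' @param parts `GRanges` with `gene_id` and `part` metadata columns,
#'   `part` drawn from `promoter`, `five_prime_UTR`, `CDS`, `intron`,
#'   `three_prime_UTR`.
#' @param cgi `GRanges` of CpG islands (unstranded).
#' @param repeats `GRanges` with a `class` metadata column drawn from the
#'   RepeatMasker-style vocabulary.
#' @param seqinfo `Seqinfo` for the genome.
#' @return An object of class `FeatureAnnotation`.
#' @export
feature_annotation <- function(genes, parts, cgi = GRanges(),
                               repeats = GRanges(), seqinfo = NULL) {
  stopifnot(is(genes, "GRanges"), is(parts, "GRanges"))
  if (is.null(mcols(genes)$gene_id)) stop("genes need a gene_id column")
  if (anyDuplicated(mcols(genes)$gene_id))
    stop("gene_id values must be unique")
  if (is.null(mcols(parts)$part) || is.null(mcols(parts)$gene_id))
    stop("parts need gene_id and part columns")
  bad <- setdiff(unique(mcols(parts)$part), FEATURE_PARTS)
  if (length(bad) > 0L)
    stop("unknown feature part(s): ", paste(bad, collapse = ", "))
  if (length(repeats) > 0L && is.null(mcols(repeats)$class))
    stop("repeats need a class column")
  if (!is.null(seqinfo)) {
    for (nm in c("genes", "parts", "cgi", "repeats")) {
      gr <- get(nm)
      seqlevels(gr) <- seqlevels(seqinfo)
      seqinfo(gr) <- seqinfo
      assign(nm, gr)
    }
  }
  ## within one gene, non-promoter parts must be pairwise disjoint
  body <- parts[mcols(parts)$part != "promoter"]
  if (length(body) > 1L) {
    by_gene <- split(body, mcols(body)$gene_id)
    ov <- vapply(by_gene, function(p)
      sum(width(reduce(p, ignore.strand = TRUE))) != sum(width(p)),
      logical(1))
    if (any(ov))
      stop("overlapping parts within gene(s): ",
           paste(names(by_gene)[ov], collapse = ", "))
  }
  structure(list(genes = genes, parts = parts, cgi = cgi,
                 repeats = repeats, seqinfo = seqinfo),
            class = "FeatureAnnotation")
}

#' @export
print.FeatureAnnotation <- function(x, ...) {
  cat("FeatureAnnotation:", length(x$genes), "genes,",
      length(x$cgi), "CGIs,", length(x$repeats), "repeats\n")
  tab <- table(mcols(x$parts)$part)
  cat("  parts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Promoter intervals upstream of transcription start sites
#'
#' Promoters are the fixed-span region immediately upstream of the
#' annotated TSS, strand-aware: a `+` gene spanning `[s, e]` has promoter
#' `[s - span, s - 1]`, a `-` gene has `[e + 1, e + span]`. Promoters are
#' clipped at chromosome boundaries when sequence lengths are known; a
#' message reports how many were clipped.
#'
#' @param genes `GRanges` of gene spans with strand.
#' @param span Promoter span in bp (default 2000).
#' @return `GRanges` of promoters, parallel to `genes`.
#' @examples
#' g <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(5001, 8000), strand = "+")
#' build_promoters(g)  # 3001-5000
#' @export
build_promoters <- function(genes, span = 2000L) {
  prom <- suppressWarnings(promoters(genes, upstream = span,
                                     downstream = 0L))
  ## clip at chromosome ends (start < 1 always clippable; end needs
  ## lengths)
  clipped <- start(prom) < 1L
  if (!anyNA(seqlengths(prom))) {
    lens <- seqlengths(prom)[as.character(seqnames(prom))]
    clipped <- clipped | end(prom) > lens
  }
  prom <- trim(prom)
  if (any(clipped))
    message(sum(clipped), " promoter(s) clipped at chromosome boundaries")
  prom
}

#' Read gene models from GFF3 into a FeatureAnnotation
#'
#' Expects canonical nested rows (`gene` > `mRNA` > `exon`/`CDS`/
#' `five_prime_UTR`/`three_prime_UTR`). Introns are derived as the gaps
#' between the exons of each mRNA; promoters are constructed with
#' [build_promoters()].
#'
#' @param path GFF3 file (1-based inclusive coordinates, as per the
#'   format).
#' @param promoter_span Promoter span in bp.
#' @param cgi,repeats Optional `GRanges` of CpG islands / repeats to
#'   attach (e.g. from [read_bed()]; repeat class taken from the BED
#'   `name` column).
#' @param seqinfo Optional `Seqinfo`; enables promoter clipping at
#'   chromosome ends.
#' @return A [feature_annotation()] object.
#' @export
read_gff3 <- function(path, promoter_span = 2000L, cgi = GRanges(),
                      repeats = GRanges(), seqinfo = NULL) {
  imp <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(imp$type)
  genes <- imp[typ == "gene"]
  gene_ids <- genes$ID
  if (anyNA(gene_ids)) stop("gene rows must carry an ID attribute")
  mrna <- imp[typ == "mRNA"]
  mrna_parent <- as.character(unlist(mrna$Parent))
  if (length(mrna_parent) != length(mrna) ||
      !all(mrna_parent %in% gene_ids))
    stop("mRNA row(s) whose Parent is not a declared gene: ",
         paste(setdiff(mrna_parent, gene_ids), collapse = ", "))
  mrna_gene <- setNames(mrna_parent, mrna$ID)

  child_types <- c(exon = "exon", CDS = "CDS",
                   five_prime_UTR = "five_prime_UTR",
                   three_prime_UTR = "three_prime_UTR")
  children <- imp[typ %in% child_types]
  ch_parent <- as.character(unlist(children$Parent))
  if (length(ch_parent) != length(children) ||
      !all(ch_parent %in% names(mrna_gene)))
    stop("feature row(s) whose Parent is not a declared mRNA: ",
         paste(setdiff(ch_parent, names(mrna_gene)), collapse = ", "))
  ch_gene <- mrna_gene[ch_parent]
  ch_type <- as.character(children$type)

  ## CDS within one mRNA must not overlap
  cds <- children[ch_type == "CDS"]
  if (length(cds) > 0L) {
    by_tx <- split(ranges(cds), ch_parent[ch_type == "CDS"])
    bad <- vapply(by_tx, function(r)
      sum(width(reduce(r))) != sum(width(r)), logical(1))
    if (any(bad))
      stop("overlapping CDS within mRNA(s): ",
           paste(names(by_tx)[bad], collapse = ", "))
  }

  ## introns: gaps between exons of the same mRNA (fall back on the
  ## union of CDS and UTRs when no exon rows are present)
  intron_list <- list()
  for (tx in names(mrna_gene)) {
    sel <- ch_parent == tx
    ex <- children[sel & ch_type == "exon"]
    if (length(ex) == 0L) ex <- children[sel]
    if (length(ex) == 0L) next
    exr <- reduce(ranges(ex))
    gaps <- setdiff(IRanges(min(start(exr)), max(end(exr))), exr)
    if (length(gaps) > 0L)
      intron_list[[tx]] <- GRanges(
        seqnames(ex)[1L], gaps, strand = strand(ex)[1L],
        gene_id = unname(mrna_gene[tx]), part = "intron")
  }
  introns <- if (length(intron_list) > 0L)
    suppressWarnings(do.call(c, unname(intron_list))) else GRanges()

  part_rows <- children[ch_type != "exon"]
  parts <- GRanges(seqnames(part_rows), ranges(part_rows),
                   strand = strand(part_rows),
                   gene_id = unname(ch_gene[ch_type != "exon"]),
                   part = ch_type[ch_type != "exon"])
  gene_gr <- GRanges(seqnames(genes), ranges(genes), strand = strand(genes),
                     gene_id = gene_ids)
  if (!is.null(seqinfo)) {
    seqlevels(gene_gr) <- seqlevels(seqinfo)
    seqinfo(gene_gr) <- seqinfo
  }
  prom <- build_promoters(gene_gr, promoter_span)
  mcols(prom) <- NULL
  mcols(prom)$gene_id <- gene_ids
  mcols(prom)$part <- "promoter"
  parts <- suppressWarnings(c(parts, introns, prom))
  if (length(repeats) > 0L && is.null(mcols(repeats)$class) &&
      !is.null(mcols(repeats)$name))
    mcols(repeats)$class <- mcols(repeats)$name
  feature_annotation(gene_gr, sort(parts), cgi, repeats, seqinfo)
}

#' Write a FeatureAnnotation's gene models as GFF3
#'
#' One mRNA per gene; exon rows are the per-gene union of CDS and UTR
#' parts. Reading the file back with [read_gff3()] recovers the original
#' 1-based coordinates.
#'
#' @param ann A `FeatureAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(is(ann, "FeatureAnnotation"))
  genes <- ann$genes
  parts <- ann$parts
  rows <- character(0)
  fmt <- function(gr, type, attrs) {
    paste(as.character(seqnames(gr)), "medipr", type, start(gr), end(gr),
          ".", as.character(strand(gr)), ".", attrs, sep = "\t")
  }
  for (i in seq_along(genes)) {
    gid <- mcols(genes)$gene_id[i]
    tid <- paste0(gid, ".1")
    g <- genes[i]
    p <- parts[mcols(parts)$gene_id == gid & mcols(parts)$part != "promoter"]
    exonic <- reduce(p[mcols(p)$part != "intron"], ignore.strand = TRUE)
    strand(exonic) <- strand(g)
    rows <- c(rows,
              fmt(g, "gene", paste0("ID=", gid)),
              fmt(g, "mRNA", paste0("ID=", tid, ";Parent=", gid)),
              if (length(exonic) > 0L)
                fmt(exonic, "exon", paste0("Parent=", tid)),
              vapply(which(mcols(p)$part != "intron"), function(j)
                fmt(p[j], mcols(p)$part[j], paste0("Parent=", tid)),
                character(1)))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
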