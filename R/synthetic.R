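## Ground-truth MeDIP-Seq simulator: toy genome, annotation, per-line
## tile methylomes (two parents plus hybrids under additive or
## non-additive rules), and enrichment-weighted 49-bp single-end reads.
## Methylation is modelled at tile (fragment) resolution, not
## per-cytosine: MeDIP read density is a regional signal.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with the study
#' defaults: a 3-Mb two-chromosome genome at 34% GC, 250 genes, 80 CpG
#' islands, 200 repeats, 500-bp methylation tiles, 49-bp single-end
#' reads, 1e5 reads per line, enrichment weight `beta + lambda * m` per
#' tile (`lambda = 10`, `beta = 0.05`), 90% uniquely mapped reads, and a
#' panel of two parents (mean methylation 0.60 vs 0.30) with one
#' non-additive better-parent hybrid (`delta = 0.05`) and one
#' below-both-parents hybrid (`margin = 0.1`).
#'
#' Per-line methylomes share a uniform random field `u` over tiles and
#' set `m = u^gamma` with `gamma = 1/level - 1`, so a higher-level line
#' is tile-wise above a lower-level one and line quantiles are nested —
#' mirroring parents of similar genetic background whose methylomes
#' differ in overall level, not in which regions are methylable.
#'
#' @param seed Integer seed; identical configurations give identical
#'   outputs.
#' @param n_chrom,chrom_length Genome shape.
#' @param gc Genome GC fraction.
#' @param n_genes,gene_length Number of genes and min/max span (bp).
#' @param n_cgi,cgi_length CpG islands: count and min/max span.
#' @param n_repeats,repeat_length,repeat_classes,repeat_weights Repeat
#'   intervals: count, span range, class vocabulary, sampling weights.
#' @param tile Methylome tile size (bp).
#' @param read_length,n_reads,unique_frac Read geometry, reads per line,
#'   fraction flagged uniquely mapped.
#' @param lambda,beta MeDIP enrichment strength and unmethylated
#'   background rate: a read start falls in a tile with weight
#'   `beta + lambda * m(tile)`.
#' @param parent_levels Named vector of the two parental mean methylation
#'   levels (P1 first).
#' @param hybrids Named list of hybrid rules; each element is
#'   `list(rule = , delta = / margin = )` with rule one of `additive`,
#'   `non_additive_up`, `non_additive_down`, `below_both`.
#' @param peak_quantile Tiles with `m` at or above this methylome
#'   quantile form the truth peaks.
#' @param n_diff_genes Named vector `c(hyper = , hypo = )` of
#'   differential genes planted between the two parents by
#'   [simulate_panel()].
#' @param diff_high,diff_low Tile methylation levels used for planted
#'   differential genes.
#' @param cgi_boost Additive methylation boost inside CpG islands
#'   (default 0; used to emulate CGI-methylated genomes).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chrom = 2L, chrom_length = 1500000L,
                              gc = 0.34,
                              n_genes = 250L, gene_length = c(1000L, 3000L),
                              n_cgi = 80L, cgi_length = c(300L, 800L),
                              n_repeats = 200L,
                              repeat_length = c(200L, 2000L),
                              repeat_classes = REPEAT_CLASSES,
                              repeat_weights = c(0.3, 0.2, 0.1, 0.15,
                                                 0.15, 0.1),
                              tile = 500L,
                              read_length = 49L, n_reads = 100000L,
                              unique_frac = 0.9,
                              lambda = 10, beta = 0.05,
                              parent_levels = c(P1 = 0.6, P2 = 0.3),
                              hybrids = list(
                                H1 = list(rule = "non_additive_up",
                                          delta = 0.05),
                                L1 = list(rule = "below_both",
                                          margin = 0.1)),
                              peak_quantile = 0.9,
                              n_diff_genes = c(hyper = 50L, hypo = 50L),
                              diff_high = 0.95, diff_low = 0.05,
                              cgi_boost = 0) {
  cfg <- as.list(environment())
  stopifnot(n_chrom >= 1L, chrom_length >= 1L, gc >= 0, gc <= 1,
            n_genes >= 0L, n_cgi >= 0L, n_repeats >= 0L,
            tile >= 1L, read_length >= 1L, n_reads >= 0L,
            unique_frac >= 0, unique_frac <= 1,
            lambda >= 0, beta >= 0,
            length(parent_levels) == 2L,
            all(parent_levels > 0 & parent_levels < 1),
            peak_quantile > 0, peak_quantile < 1,
            diff_high > diff_low, diff_high <= 1, diff_low >= 0)
  if (length(repeat_weights) != length(repeat_classes))
    stop("repeat_weights must match repeat_classes")
  for (h in cfg$hybrids)
    if (!h$rule %in% c("additive", "non_additive_up",
                       "non_additive_down", "below_both"))
      stop("unknown hybrid rule: ", h$rule)
  structure(cfg, class = "simulation_config")
}

## run code under a seed derived from the config without disturbing the
## caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

derive_seed <- function(seed, offset) (as.integer(seed) %% 900000000L) + offset

#' Generate a random toy genome
#'
#' I.i.d. bases at the requested GC fraction; chromosomes are named
#' `chr1 ... chrN`.
#'
#' @param config A [simulation_config()].
#' @return A [Biostrings::DNAStringSet] with names and widths set.
#' @export
generate_genome <- function(config) {
  stopifnot(is(config, "simulation_config"))
  if (config$chrom_length < 10L * config$read_length)
    stop("chrom_length must be at least 10 read lengths")
  gc <- config$gc
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(derive_seed(config$seed, 1L), {
    seqs <- vapply(seq_len(config$n_chrom), function(i)
      paste(sample(names(prob), config$chrom_length, replace = TRUE,
                   prob = prob), collapse = ""),
      character(1))
  })
  genome <- DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_chrom))
  genome
}

genome_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome), seqlengths = width(genome))
}

place_intervals <- function(n, len_range, seqinfo, max_tries = 200L,
                            what = "interval") {
  chroms <- seqlevels(seqinfo)
  lens <- seqlengths(seqinfo)
  p_chr <- character(n)
  p_start <- integer(n)
  p_end <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      w <- sample(len_range[1L]:len_range[2L], 1L)
      chr <- sample(chroms, 1L)
      if (lens[chr] <= w) next
      s <- sample.int(lens[chr] - w, 1L)
      e <- s + w - 1L
      prev <- which(p_chr[seq_len(i - 1L)] == chr)
      if (!any(p_start[prev] <= e & p_end[prev] >= s)) {
        p_chr[i] <- chr
        p_start[i] <- s
        p_end[i] <- e
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place ", n, " non-overlapping ", what,
           "s after ", max_tries, " tries each")
  }
  if (n == 0L) return(GRanges(seqinfo = seqinfo))
  GRanges(p_chr, IRanges(p_start, p_end), seqinfo = seqinfo)
}

#' Generate a random gene / CGI / repeat annotation
#'
#' Genes are pairwise non-overlapping, on both strands, and every gene
#' has at least one CDS; multi-exon genes get derived introns. CpG
#' islands are mutually disjoint; repeats carry classes drawn from the
#' RepeatMasker-style vocabulary and may overlap anything (as in real
#' genomes).
#'
#' @param config A [simulation_config()].
#' @param genome The [generate_genome()] output.
#' @return A [feature_annotation()] object.
#' @export
generate_annotation <- function(config, genome) {
  stopifnot(is(config, "simulation_config"))
  si <- genome_seqinfo(genome)
  with_seed(derive_seed(config$seed, 2L), {
    genes <- sort(place_intervals(config$n_genes, config$gene_length, si,
                                  what = "gene"))
    parts <- GRanges(seqinfo = si)
    if (config$n_genes > 0L) {
      strand(genes) <- sample(c("+", "-"), config$n_genes, replace = TRUE)
      mcols(genes)$gene_id <- sprintf("g%03d", seq_len(config$n_genes))
      part_df <- do.call(rbind, lapply(seq_len(config$n_genes), function(i)
        decompose_gene(as.character(seqnames(genes))[i], start(genes)[i],
                       end(genes)[i], as.character(strand(genes))[i],
                       mcols(genes)$gene_id[i])))
      parts <- GRanges(part_df$chrom,
                       IRanges(part_df$start, part_df$end),
                       strand = part_df$strand, seqinfo = si,
                       gene_id = part_df$gene_id, part = part_df$part)
      prom <- suppressMessages(build_promoters(genes))
      mcols(prom) <- NULL
      mcols(prom)$gene_id <- mcols(genes)$gene_id
      mcols(prom)$part <- "promoter"
      parts <- c(parts, prom)
    } else {
      mcols(genes)$gene_id <- character(0)
      mcols(parts)$gene_id <- character(0)
      mcols(parts)$part <- character(0)
    }
    cgi <- place_intervals(config$n_cgi, config$cgi_length, si,
                           what = "CGI")
    repeats <- GRanges(seqinfo = si)
    if (config$n_repeats > 0L) {
      rep_list <- lapply(seq_len(config$n_repeats), function(i) {
        w <- sample(config$repeat_length[1L]:config$repeat_length[2L], 1L)
        chr <- sample(seqlevels(si), 1L)
        s <- sample.int(seqlengths(si)[chr] - w, 1L)
        GRanges(chr, IRanges(s, width = w), seqinfo = si)
      })
      repeats <- do.call(c, rep_list)
      mcols(repeats)$class <- sample(config$repeat_classes,
                                     config$n_repeats, replace = TRUE,
                                     prob = config$repeat_weights)
    } else {
      mcols(repeats)$class <- character(0)
    }
  })
  feature_annotation(genes, sort(parts), cgi, repeats, si)
}

## split one gene span into UTR/CDS/intron parts (strand-aware);
## returns a plain data frame so the caller can build one GRanges
decompose_gene <- function(chrom, s, e, strand, gene_id) {
  L <- e - s + 1L
  minus <- strand == "-"
  n_ex <- sample(1:3, 1L)
  minseg <- 60L
  n_seg <- 2L * n_ex - 1L
  if (L < n_seg * minseg) {
    n_ex <- 1L
    n_seg <- 1L
  }
  props <- runif(n_seg)
  lens <- minseg + floor(props / sum(props) * (L - n_seg * minseg))
  lens[n_seg] <- L - sum(lens[-n_seg])
  seg_start <- s + cumsum(c(0L, lens[-n_seg]))
  seg_end <- seg_start + lens - 1L
  is_exon <- seq_len(n_seg) %% 2L == 1L
  ex_s <- seg_start[is_exon]
  ex_e <- seg_end[is_exon]
  ## UTRs: clipped off the 5'-most and 3'-most exon ends
  first_ex <- if (minus) length(ex_s) else 1L
  last_ex <- if (minus) 1L else length(ex_s)
  u5 <- min(sample(30:120, 1L), (ex_e[first_ex] - ex_s[first_ex] + 1L) %/% 3L)
  u3 <- min(sample(30:120, 1L), (ex_e[last_ex] - ex_s[last_ex] + 1L) %/% 3L)
  rows <- list()
  add <- function(st, en, part)
    data.frame(chrom = chrom, start = st, end = en, strand = strand,
               part = part, gene_id = gene_id, stringsAsFactors = FALSE)
  cds_s <- ex_s
  cds_e <- ex_e
  if (u5 > 0L) {
    if (minus) {
      rows[[length(rows) + 1L]] <-
        add(ex_e[first_ex] - u5 + 1L, ex_e[first_ex], "five_prime_UTR")
      cds_e[first_ex] <- ex_e[first_ex] - u5
    } else {
      rows[[length(rows) + 1L]] <-
        add(ex_s[first_ex], ex_s[first_ex] + u5 - 1L, "five_prime_UTR")
      cds_s[first_ex] <- ex_s[first_ex] + u5
    }
  }
  if (u3 > 0L) {
    if (minus) {
      rows[[length(rows) + 1L]] <-
        add(ex_s[last_ex], ex_s[last_ex] + u3 - 1L, "three_prime_UTR")
      cds_s[last_ex] <- ex_s[last_ex] + u3
    } else {
      rows[[length(rows) + 1L]] <-
        add(ex_e[last_ex] - u3 + 1L, ex_e[last_ex], "three_prime_UTR")
      cds_e[last_ex] <- ex_e[last_ex] - u3
    }
  }
  keep <- cds_e >= cds_s
  if (any(keep))
    rows[[length(rows) + 1L]] <- add(cds_s[keep], cds_e[keep], "CDS")
  if (n_seg > 1L)
    rows[[length(rows) + 1L]] <-
      add(seg_start[!is_exon], seg_end[!is_exon], "intron")
  do.call(rbind, rows)
}

#' Tile a genome for methylome modelling
#'
#' @param seqinfo A `Seqinfo`.
#' @param tile Tile width in bp; the last tile of each chromosome may be
#'   short.
#' @return `GRanges` of tiles in genomic order.
#' @export
methylome_tiles <- function(seqinfo, tile = 500L) {
  tileGenome(seqlengths(seqinfo), tilewidth = tile,
             cut.last.tile.in.chrom = TRUE)
}

#' Construct a MethylomeTruth object
#'
#' Per-line ground truth: a methylation level `m` in `[0, 1]` for every
#' genome tile. Used by the read simulator and by recovery tests (e.g. a
#' constant-`m` methylome gives the null for chi-square calibration).
#'
#' @param line_id Line label.
#' @param tiles `GRanges` tiling of the genome (see [methylome_tiles()]).
#' @param m Numeric vector of tile methylation levels, parallel to
#'   `tiles`.
#' @param rule Provenance tag (`"parent"` or a hybrid rule name).
#' @param n_clipped Number of tiles clipped into `[0, 1]` during
#'   construction.
#' @return An object of class `MethylomeTruth`.
#' @export
methylome_truth <- function(line_id, tiles, m, rule = "parent",
                            n_clipped = 0L) {
  stopifnot(length(tiles) == length(m), all(m >= 0), all(m <= 1))
  structure(list(line_id = line_id, tiles = tiles, m = as.numeric(m),
                 rule = rule, n_clipped = n_clipped),
            class = "MethylomeTruth")
}

new_methylome <- methylome_truth

#' @export
print.MethylomeTruth <- function(x, ...) {
  cat("MethylomeTruth", x$line_id, "(", x$rule, "):",
      length(x$tiles), "tiles, mean m =", round(mean(x$m), 3), "\n")
  invisible(x)
}

#' Combine two parental methylomes under a hybrid rule
#'
#' Rules, applied tile-wise with MPV the mid-parent value
#' `(m_P1 + m_P2)/2`:
#' * `additive` — `m = MPV` exactly;
#' * `non_additive_up` — `m = min(1, MPV + delta)`;
#' * `non_additive_down` — `m = max(0, MPV - delta)`;
#' * `below_both` — `m = max(0, min(m_P1, m_P2) - margin)`, emulating a
#'   hybrid whose methylation falls below both parents.
#'
#' Values pushed outside `[0, 1]` are clipped; the number of clipped
#' tiles is recorded in the result's `n_clipped`.
#'
#' @param p1,p2 Parental `MethylomeTruth` objects on identical tiles.
#' @param line_id Label for the hybrid line.
#' @param rule,delta,margin See above.
#' @return A `MethylomeTruth`.
#' @export
make_hybrid_methylome <- function(p1, p2, line_id,
                                  rule = c("additive", "non_additive_up",
                                           "non_additive_down",
                                           "below_both"),
                                  delta = 0.05, margin = 0.1) {
  rule <- match.arg(rule)
  stopifnot(length(p1$m) == length(p2$m))
  mpv <- (p1$m + p2$m) / 2
  raw <- switch(rule,
    additive = mpv,
    non_additive_up = mpv + delta,
    non_additive_down = mpv - delta,
    below_both = pmin(p1$m, p2$m) - margin)
  m <- pmin(1, pmax(0, raw))
  new_methylome(line_id, p1$tiles, m, rule,
                n_clipped = sum(raw != m))
}

#' Generate the per-line methylome panel
#'
#' Two parents from the shared uniform field (`m = u^gamma`,
#' `gamma = 1/level - 1`, optionally CGI-boosted) and the configured
#' hybrids via [make_hybrid_methylome()].
#'
#' @param config A [simulation_config()].
#' @param annotation A `FeatureAnnotation` (provides `Seqinfo` and the
#'   CGIs for `cgi_boost`).
#' @return Named list of `MethylomeTruth`, parents first.
#' @export
generate_methylomes <- function(config, annotation) {
  stopifnot(is(config, "simulation_config"),
            is(annotation, "FeatureAnnotation"))
  si <- annotation$seqinfo
  tiles <- methylome_tiles(si, config$tile)
  levels <- config$parent_levels
  with_seed(derive_seed(config$seed, 3L), {
    u <- runif(length(tiles))
  })
  meths <- list()
  for (i in seq_along(levels)) {
    gamma <- 1 / levels[[i]] - 1
    m <- u^gamma
    if (config$cgi_boost > 0 && length(annotation$cgi) > 0L) {
      hit <- overlapsAny(tiles, annotation$cgi)
      m[hit] <- pmin(1, m[hit] + config$cgi_boost)
    }
    meths[[names(levels)[i]]] <- new_methylome(names(levels)[i], tiles, m)
  }
  for (h in names(config$hybrids)) {
    spec <- config$hybrids[[h]]
    meths[[h]] <- make_hybrid_methylome(
      meths[[1L]], meths[[2L]], h, rule = spec$rule,
      delta = if (!is.null(spec$delta)) spec$delta else 0.05,
      margin = if (!is.null(spec$margin)) spec$margin else 0.1)
  }
  meths
}

#' Plant truth-differential genes between two lines
#'
#' Overwrites the tile methylation over each chosen gene span so the two
#' lines differ strongly there: `hyper` genes are high in `line2` and low
#' in `line1` (hypermethylated in a line1-vs-line2 contrast), `hypo`
#' genes the reverse.
#'
#' @param methylomes Named list of `MethylomeTruth`.
#' @param annotation `FeatureAnnotation` supplying gene spans.
#' @param line1,line2 Names of the two lines to separate.
#' @param n_hyper,n_hypo Number of genes per direction.
#' @param high,low Tile methylation levels written into the planted
#'   spans.
#' @param pad Minimum bp separation enforced between planted footprints
#'   (default 1000, two default tiles), so neighbouring planted genes of
#'   opposite direction cannot book-end into a single merged peak
#'   region.
#' @param seed RNG seed for the gene draw.
#' @return `list(methylomes = , truth = )` where `truth` is a data frame
#'   with `gene_id` and `direction`.
#' @export
plant_differential_genes <- function(methylomes, annotation, line1, line2,
                                     n_hyper = 50L, n_hypo = 50L,
                                     high = 0.95, low = 0.05,
                                     pad = 1000L, seed = 1L) {
  stopifnot(line1 %in% names(methylomes), line2 %in% names(methylomes))
  ids <- mcols(annotation$genes)$gene_id
  if (n_hyper + n_hypo > length(ids))
    stop("not enough genes to plant ", n_hyper + n_hypo,
         " differential genes")
  ## candidate footprints (span of gene plus promoter and all parts);
  ## planted genes are chosen with pairwise disjoint footprints so no
  ## tile carries two conflicting planted directions
  all_gr <- c(granges(annotation$genes), granges(annotation$parts))
  all_gid <- c(ids, mcols(annotation$parts)$gene_id)
  spans <- unlist(range(split(all_gr, all_gid), ignore.strand = TRUE))
  spans <- spans[ids]
  f_chr <- as.character(seqnames(spans))
  f_s <- start(spans)
  f_e <- end(spans)
  with_seed(derive_seed(seed, 4L), {
    order_idx <- sample(seq_along(ids))
  })
  chosen_idx <- integer(0)
  for (i in order_idx) {
    if (length(chosen_idx) == n_hyper + n_hypo) break
    prev <- chosen_idx[f_chr[chosen_idx] == f_chr[i]]
    if (!any(f_s[prev] <= f_e[i] + pad & f_e[prev] >= f_s[i] - pad))
      chosen_idx <- c(chosen_idx, i)
  }
  if (length(chosen_idx) < n_hyper + n_hypo)
    stop("could not find ", n_hyper + n_hypo,
         " genes with disjoint footprints")
  chosen <- ids[chosen_idx]
  truth <- data.frame(
    gene_id = chosen,
    direction = rep(c("hyper", "hypo"), c(n_hyper, n_hypo)),
    stringsAsFactors = FALSE)
  tiles <- methylomes[[line1]]$tiles
  ## the planted span is each gene's whole annotated footprint
  ## (promoter included) so every feature-level call reflects the
  ## planted difference
  hits <- findOverlaps(tiles, spans[chosen], ignore.strand = TRUE)
  tile_idx <- queryHits(hits)
  dir_of <- setNames(truth$direction, truth$gene_id)
  tile_dir <- unname(dir_of[chosen[subjectHits(hits)]])
  for (ln in c(line1, line2)) {
    hi_dir <- if (ln == line2) "hyper" else "hypo"
    methylomes[[ln]]$m[tile_idx] <- ifelse(tile_dir == hi_dir, high, low)
  }
  list(methylomes = methylomes, truth = truth)
}

#' Truth peaks of a methylome
#'
#' Tiles with methylation at or above the stated methylome quantile,
#' coalesced into maximal runs — the simulator's stand-in for an external
#' peak caller's output.
#'
#' @param methylome A `MethylomeTruth`.
#' @param quantile Quantile threshold (default 0.9).
#' @return `GRanges` of peak regions.
#' @export
truth_peaks <- function(methylome, quantile = 0.9) {
  thr <- stats::quantile(methylome$m, quantile, names = FALSE)
  reduce(methylome$tiles[methylome$m >= thr])
}

#' Simulate MeDIP-enriched single-end reads for one line
#'
#' Each read picks a tile with probability proportional to
#' `beta + lambda * m(tile)`, then a uniform start within the tile
#' (constrained so the full read fits the chromosome). Strands are
#' assigned uniformly and a configurable fraction of reads is flagged
#' uniquely mapped.
#'
#' @param methylome A `MethylomeTruth`.
#' @param config A [simulation_config()].
#' @param line_seed Seed for this line's read draw (derive different
#'   values for independent replicate draws).
#' @param n_reads Number of reads (defaults to `config$n_reads`).
#' @return Sorted `GRanges` of reads with `is_unique` and `line_id`
#'   metadata columns.
#' @export
simulate_medip_reads <- function(methylome, config,
                                 line_seed = config$seed,
                                 n_reads = config$n_reads) {
  stopifnot(is(config, "simulation_config"))
  tiles <- methylome$tiles
  si <- seqinfo(tiles)
  if (n_reads == 0L) {
    gr <- GRanges(seqinfo = si)
    mcols(gr)$is_unique <- logical(0)
    mcols(gr)$line_id <- character(0)
    return(gr)
  }
  w <- config$beta + config$lambda * methylome$m
  if (all(w == 0)) stop("all tile weights are zero; nothing to sample")
  L <- config$read_length
  lens <- seqlengths(si)
  ## valid start range per tile: read must fit its chromosome
  lo <- start(tiles)
  hi <- pmin(end(tiles), lens[as.character(seqnames(tiles))] - L + 1L)
  ok <- hi >= lo
  w[!ok] <- 0
  with_seed(derive_seed(line_seed, 7L), {
    idx <- sample.int(length(tiles), n_reads, replace = TRUE, prob = w)
    offs <- floor(runif(n_reads) * (hi[idx] - lo[idx] + 1L))
    starts <- lo[idx] + as.integer(offs)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    uniq <- runif(n_reads) < config$unique_frac
  })
  gr <- GRanges(seqnames(tiles)[idx], IRanges(starts, width = L),
                strand = strands, seqinfo = si)
  mcols(gr)$is_unique <- uniq
  mcols(gr)$line_id <- methylome$line_id
  sort(gr)
}

#' Simulate the full parent-hybrid panel
#'
#' Runs the generator end to end: genome, annotation, methylome panel,
#' planted truth-differential genes between the two parents (per
#' `config$n_diff_genes`), per-line reads and truth peaks.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `genome`, `seqinfo`, `annotation`,
#'   `methylomes`, `reads` (named list of `GRanges`), `peaks` (named list
#'   of `GRanges`), `truth` (planted differential-gene table, possibly
#'   empty), and `config`.
#' @export
simulate_panel <- function(config = simulation_config()) {
  genome <- generate_genome(config)
  ann <- generate_annotation(config, genome)
  meths <- generate_methylomes(config, ann)
  truth <- data.frame(gene_id = character(0), direction = character(0))
  nd <- config$n_diff_genes
  if (sum(nd) > 0L && length(ann$genes) > 0L) {
    parents <- names(config$parent_levels)
    planted <- plant_differential_genes(
      meths, ann, parents[1L], parents[2L],
      n_hyper = nd[["hyper"]], n_hypo = nd[["hypo"]],
      high = config$diff_high, low = config$diff_low,
      seed = config$seed)
    meths <- planted$methylomes
    truth <- planted$truth
  }
  reads <- list()
  peaks <- list()
  for (i in seq_along(meths)) {
    nm <- names(meths)[i]
    reads[[nm]] <- simulate_medip_reads(
      meths[[nm]], config, line_seed = derive_seed(config$seed, 100L + i))
    peaks[[nm]] <- truth_peaks(meths[[nm]], config$peak_quantile)
  }
  list(genome = genome, seqinfo = genome_seqinfo(genome),
       annotation = ann, methylomes = meths, reads = reads,
       peaks = peaks, truth = truth, config = config)
}

#' Simulate a growth-trait table for a parent-hybrid field trial
#'
#' Tree height (m) and DBH (diameter at breast height, cm) for a
#' randomized-block trial: per-line true five-year means, a common
#' age-growth curve, small block effects and multiplicative measurement
#' noise. Defaults emulate a poplar panel where better-parent hybrids
#' exceed and lower-parent hybrids fall short of the higher parent.
#'
#' @param seed RNG seed.
#' @param line_means Named list with per-trait named vectors of true
#'   five-year line means.
#' @param ages Integer ages (years) measured.
#' @param n_blocks,trees_per_block Trial layout.
#' @param cv Coefficient of variation of the tree-level noise.
#' @return A data frame `(line_id, block, tree, age, trait, value)`;
#'   `attr(x, "line_means")` records the generating means.
#' @export
simulate_trait_table <- function(seed = 1L,
                                 line_means = list(
                                   height = c(P1 = 10.0, P2 = 9.0,
                                              H1 = 10.781, H2 = 11.255,
                                              H3 = 11.109, L1 = 9.423,
                                              L2 = 9.241),
                                   dbh = c(P1 = 13.5, P2 = 14.2,
                                           H1 = 14.379, H2 = 14.412,
                                           H3 = 14.302, L1 = 11.229,
                                           L2 = 11.102)),
                                 ages = 1:5, n_blocks = 4L,
                                 trees_per_block = 8L, cv = 0.015) {
  age_factor <- (ages / max(ages))^0.8
  rows <- list()
  with_seed(derive_seed(seed, 5L), {
    for (trait in names(line_means)) {
      means <- line_means[[trait]]
      for (line in names(means)) {
        block_eff <- rnorm(n_blocks, 0, cv / 3)
        for (b in seq_len(n_blocks)) {
          for (a in seq_along(ages)) {
            mu <- means[[line]] * age_factor[a] * (1 + block_eff[b])
            vals <- mu * (1 + rnorm(trees_per_block, 0, cv))
            rows[[length(rows) + 1L]] <- data.frame(
              line_id = line, block = b,
              tree = seq_len(trees_per_block), age = ages[a],
              trait = trait, value = pmax(vals, 0.01),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "line_means") <- line_means
  out
}
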