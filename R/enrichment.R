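## Hypergeometric term enrichment for differentially methylated gene
## lists, against a whole-genome population, with Benjamini-Hochberg
## adjustment.

#' Read a gene-to-term annotation map
#'
#' Two-column TSV (`gene_id`, `term_id`); an optional second file maps
#' `term_id` to a human-readable name.
#'
#' @param path Gene/term TSV (no header required; a `gene` or `gene_id`
#'   header row is detected and skipped).
#' @param term_names Optional TSV `(term_id, name)`.
#' @return A list of class `AnnotationMap`: `gene2term` (named list of
#'   character vectors), `term2gene`, and `term_names`.
#' @export
read_annotation_map <- function(path, term_names = NULL) {
  tab <- fread(path, header = FALSE, sep = "\t",
               col.names = c("gene_id", "term_id"), data.table = FALSE)
  if (nrow(tab) > 0L && tab$gene_id[1L] %in% c("gene", "gene_id"))
    tab <- tab[-1L, , drop = FALSE]
  nm <- NULL
  if (!is.null(term_names)) {
    nm_tab <- fread(term_names, header = FALSE, sep = "\t",
                    data.table = FALSE)
    nm <- setNames(nm_tab[[2L]], nm_tab[[1L]])
  }
  annotation_map(tab, term_names = nm)
}

#' Build an annotation map from a gene/term table
#'
#' @param gene_terms Data frame with `gene_id` and `term_id` columns.
#' @param term_names Optional named character vector of term names.
#' @return An `AnnotationMap`.
#' @export
annotation_map <- function(gene_terms, term_names = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(gene_terms)))
  gene_terms <- unique(gene_terms[, c("gene_id", "term_id")])
  structure(list(
    gene2term = split(gene_terms$term_id, gene_terms$gene_id),
    term2gene = split(gene_terms$gene_id, gene_terms$term_id),
    term_names = term_names), class = "AnnotationMap")
}

#' @export
print.AnnotationMap <- function(x, ...) {
  cat("AnnotationMap:", length(x$gene2term), "genes,",
      length(x$term2gene), "terms\n")
  invisible(x)
}

#' Hypergeometric term enrichment with BH adjustment
#'
#' For each term with at least one population gene: upper-tail
#' hypergeometric probability of drawing `k` or more annotated genes in
#' a study set of size `n` from a population of `N` genes of which `K`
#' carry the term, i.e. `P(X >= k)`. P-values are Benjamini-Hochberg
#' adjusted across all tested terms and results are sorted by adjusted
#' p.
#'
#' @param study Character vector of study gene ids (e.g. one contrast's
#'   differentially methylated genes). Must be a subset of the
#'   population.
#' @param annotation An `AnnotationMap`.
#' @param population Population gene ids; defaults to every gene in the
#'   annotation map (the whole annotated genome).
#' @return Data frame `(term_id, name, k, n, K, N, p_value, p_adjusted)`
#'   sorted by `p_adjusted`, ties by `p_value`.
#' @export
hypergeometric_enrichment <- function(study, annotation,
                                      population = NULL) {
  stopifnot(is(annotation, "AnnotationMap"))
  if (is.null(population)) population <- names(annotation$gene2term)
  population <- unique(population)
  study <- unique(study)
  missing <- setdiff(study, population)
  if (length(missing) > 0L)
    stop("study gene(s) absent from the population: ",
         paste(missing, collapse = ", "))
  if (length(population) < 2L) stop("population must have >= 2 genes")
  N <- length(population)
  n <- length(study)
  terms <- names(annotation$term2gene)
  K <- vapply(annotation$term2gene,
              function(g) length(intersect(g, population)), integer(1))
  keep <- K > 0L
  terms <- terms[keep]
  K <- K[keep]
  k <- vapply(annotation$term2gene[keep],
              function(g) length(intersect(g, study)), integer(1))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  nm <- if (!is.null(annotation$term_names))
    unname(annotation$term_names[terms]) else NA_character_
  out <- data.frame(term_id = terms, name = nm, k = unname(k), n = n,
                    K = unname(K), N = N, p_value = unname(p),
                    p_adjusted = unname(padj),
                    stringsAsFactors = FALSE)
  out[order(out$p_adjusted, out$p_value, out$term_id), , drop = FALSE]
}

#' Per-term rollup of differential-gene calls
#'
#' Counts hyper- and hypomethylated genes per annotation term, per
#' contrast; useful for the functional-category summaries of
#' parent-hybrid panels.
#'
#' @param calls Data frame of gene calls with `gene_id` and `direction`
#'   columns, plus a `contrast` column when several contrasts are
#'   stacked.
#' @param annotation An `AnnotationMap`.
#' @return Data frame `(contrast, term_id, direction, n_genes)`; empty
#'   input gives an empty rollup.
#' @export
category_rollup <- function(calls, annotation) {
  stopifnot(is(annotation, "AnnotationMap"))
  empty <- data.frame(contrast = character(0), term_id = character(0),
                      direction = character(0), n_genes = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  if (is.null(calls$contrast)) calls$contrast <- "contrast1"
  u <- unique(calls[, c("contrast", "gene_id", "direction")])
  terms <- annotation$gene2term[u$gene_id]
  nterm <- lengths(terms)
  if (sum(nterm) == 0L) return(empty)
  expanded <- data.frame(
    contrast = rep(u$contrast, nterm),
    term_id = unlist(terms, use.names = FALSE),
    direction = rep(u$direction, nterm),
    stringsAsFactors = FALSE)
  agg <- aggregate(list(n_genes = rep(1L, nrow(expanded))),
                   expanded, FUN = sum)
  agg[order(agg$contrast, agg$term_id, agg$direction), , drop = FALSE]
}

#' Genes called in every contrast
#'
#' The intersection across contrasts of genes with a given direction —
#' e.g. genes hypermethylated in all better-parent hybrid-versus-parent
#' comparisons.
#'
#' @param calls Stacked call data frame with `contrast`, `gene_id`,
#'   `direction`.
#' @param direction `"hyper"` or `"hypo"`.
#' @return Character vector of gene ids.
#' @export
intersect_calls <- function(calls, direction = "hyper") {
  if (nrow(calls) == 0L) return(character(0))
  sel <- calls[calls$direction == direction, c("contrast", "gene_id")]
  sets <- split(sel$gene_id, sel$contrast)
  if (length(sets) == 0L) return(character(0))
  Reduce(intersect, lapply(sets, unique))
}
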