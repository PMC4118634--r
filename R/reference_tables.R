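## Bundled published summary tables (desk-scale reference data) from a
## poplar parent-hybrid MeDIP-Seq leaf-methylome panel: per-line mapping
## statistics, peak summaries, peak-feature counts, and printed
## cytosine-context coverages. Used to exercise the package's summary
## arithmetic on real printed numbers.

#' Bundled reference summary tables
#'
#' Loads the published per-line summary tables shipped with the package
#' (see the comment headers of the TSV files under `inst/extdata/` for
#' provenance notes, including one corrected digit-grouping typo).
#'
#' @return A list of data frames: `mapping` (per-line read counts and
#'   printed rates), `peaks` (per-line MACS peak summaries),
#'   `peak_features` (peak counts per genome feature), and
#'   `context_coverage` (printed CG/CHG/CHH coverages, percent).
#' @examples
#' ref <- medip_reference_tables()
#' with(ref$mapping[1, ],
#'      mapping_summary(total_reads, mapped_reads, unique_reads, line_id))
#' @export
medip_reference_tables <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "medipr"),
    sep = "\t", header = TRUE, comment.char = "#",
    stringsAsFactors = FALSE, check.names = FALSE)
  list(mapping = rd("medip_mapping_stats.tsv"),
       peaks = rd("medip_peak_stats.tsv"),
       peak_features = rd("medip_peak_features.tsv"),
       context_coverage = rd("medip_context_coverage.tsv"))
}
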