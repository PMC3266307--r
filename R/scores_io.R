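#' Write probe-set scores to CSV
#'
#' One row per probe set, sorted by probe-set id, with scores in fixed
#' 4-decimal notation and the per-gene selection flag in a `best`
#' column. (Two-decimal display, as used in published summary tables, is
#' a presentation choice left to reports.)
#'
#' @param scores a `probeset_scores` data.frame.
#' @param path output path.
#' @param mapping the `gene_mapping` defining the `best` flag; computed
#'   from `scores` by default.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path,
                         mapping = best_probeset_per_gene(scores)) {
  sc <- scores[order(scores$probeset_id), , drop = FALSE]
  fmt4 <- function(x) sprintf("%.4f", x)
  df <- data.frame(
    probeset_id = sc$probeset_id,
    targeted_gene = ifelse(is.na(sc$targeted_gene), "", sc$targeted_gene),
    n_probes = sc$n_probes,
    specificity = fmt4(sc$specificity),
    coverage = fmt4(sc$coverage),
    proc_requirement = ifelse(is.na(sc$proc_requirement), "",
                              sprintf("%.1f", sc$proc_requirement)),
    robustness = fmt4(sc$robustness),
    overall = fmt4(sc$overall),
    best = sc$probeset_id %in% mapping$probeset_id,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read probe-set scores written by [write_scores()]
#' @param path path to the CSV file.
#' @return A `probeset_scores` data.frame with an extra `best` column.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(probeset_id = "character",
                                       targeted_gene = "character"))
  df$targeted_gene[df$targeted_gene == ""] <- NA_character_
  df$proc_requirement <- suppressWarnings(as.numeric(df$proc_requirement))
  class(df) <- c("probeset_scores", "data.frame")
  df
}

#' Write a gene -> probe-set mapping to TSV
#'
#' Columns `gene_id`, `probeset_id`, `overall_score` (4 decimals),
#' `tie_broken` (lowercase true/false), sorted by gene id.
#'
#' @param mapping a `gene_mapping` from [best_probeset_per_gene()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  mp <- mapping[order(mapping$gene_id), , drop = FALSE]
  df <- data.frame(gene_id = mp$gene_id, probeset_id = mp$probeset_id,
                   overall_score = sprintf("%.4f", mp$overall_score),
                   tie_broken = tolower(as.character(mp$tie_broken)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene -> probe-set mapping written by [write_mapping()]
#' @param path path to the TSV file.
#' @return A `gene_mapping` data.frame.
#' @export
read_mapping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         probeset_id = "character"))
  df$tie_broken <- df$tie_broken == "true"
  class(df) <- c("gene_mapping", "data.frame")
  df
}
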