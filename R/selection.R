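#' Select the best probe set for each gene
#'
#' For each gene targeted by at least one probe set, selects the probe
#' set with the highest overall score to represent the gene. Ties on the
#' overall score are broken by higher robustness, then higher
#' specificity, then lexicographically smallest probe-set id, and the
#' chosen row is flagged `tie_broken`. Robustness is the secondary key
#' because it is the component that most often separates otherwise
#' comparable probe sets. Genes whose best overall score is 0 are still
#' mapped (score cutoffs are deliberately left to the user); genes never
#' targeted are absent.
#'
#' @param scores a `probeset_scores` data.frame from [score_probesets()].
#' @return A data.frame of class `gene_mapping` with columns `gene_id`,
#'   `probeset_id`, `overall_score`, `tie_broken`, one row per gene,
#'   sorted by `gene_id`. Each probe set can represent at most its own
#'   targeted gene, so the mapping is one-to-one.
#' @export
best_probeset_per_gene <- function(scores) {
  sc <- scores[!is.na(scores$targeted_gene), , drop = FALSE]
  rows <- lapply(split(sc, sc$targeted_gene), function(g) {
    ord <- order(-g$overall, -g$robustness, -g$specificity, g$probeset_id)
    g <- g[ord, , drop = FALSE]
    data.frame(gene_id = g$targeted_gene[1],
               probeset_id = g$probeset_id[1],
               overall_score = g$overall[1],
               tie_broken = sum(g$overall == g$overall[1]) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), probeset_id = character(0),
                      overall_score = numeric(0), tie_broken = logical(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_mapping", "data.frame")
  out
}

#' Look up the probe set representing a gene
#'
#' @param mapping a `gene_mapping` from [best_probeset_per_gene()].
#' @param gene_id gene identifier(s).
#' @return Probe-set id(s); `NA` for unmapped genes.
#' @export
lookup <- function(mapping, gene_id) {
  mapping$probeset_id[match(gene_id, mapping$gene_id)]
}
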