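#' Score a platform and map genes to their best probe sets
#'
#' End-to-end pipeline: read probes and transcriptome, align probes
#' internally (or ingest precomputed BLAST tabular hits), score every
#' probe set, select the best probe set per gene, and optionally write
#' the score CSV and mapping TSV. Identical inputs and options always
#' produce byte-identical outputs.
#'
#' @param probes_path path to the probe file.
#' @param probes_format "probe_tab" or "fasta".
#' @param transcripts_path cDNA FASTA path.
#' @param gene_map_path transcript -> gene table path.
#' @param hits_path optional BLAST tabular (-outfmt 6) path; when given,
#'   the internal aligner is skipped and hits are ingested instead.
#' @param p per-base interruption probability (see [platform_p()]).
#' @param out_scores,out_mapping optional output paths.
#' @param params a [scoring_params()] object.
#' @return Invisibly, a list with `scores`, `mapping` and `hits`.
#' @export
run_scoring <- function(probes_path, probes_format = c("probe_tab", "fasta"),
                        transcripts_path, gene_map_path,
                        hits_path = NULL, p = 1 / 600,
                        out_scores = NULL, out_mapping = NULL,
                        params = scoring_params()) {
  probes_format <- match.arg(probes_format)
  probes <- if (probes_format == "probe_tab") read_probe_tab(probes_path)
            else read_probe_fasta(probes_path)
  db <- read_transcriptome(transcripts_path, gene_map_path)
  message(length(unique(probes$probeset_id)), " probe sets, ",
          length(db$seq), " transcripts, ",
          length(unique(db$gene)), " genes")
  hits <- if (is.null(hits_path)) search_all(probes, db, params)
          else read_blast_tabular(hits_path, db = db, params = params)
  scores <- score_probesets(probes, hits, db, p = p)
  mapping <- best_probeset_per_gene(scores)
  message(sum(is.na(scores$targeted_gene)), " probe set(s) without a ",
          "targeted gene; ", sum(scores$ambiguous_target),
          " ambiguous target(s); ",
          length(setdiff(unique(db$gene), mapping$gene_id)),
          " gene(s) not represented by any probe set")
  if (!is.null(out_scores)) write_scores(scores, out_scores, mapping)
  if (!is.null(out_mapping)) write_mapping(mapping, out_mapping)
  invisible(list(scores = scores, mapping = mapping, hits = hits))
}
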