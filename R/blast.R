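#' Read precomputed alignment hits in BLAST tabular format
#'
#' Ingests a 12-column BLAST tabular file (`-outfmt 6`) produced by an
#' external BLASTN run of probe queries against a transcript database, as
#' an alternative to the internal aligner. Query ids must follow the
#' `<probeset_id>:<probe>` convention; subject ids are transcript
#' accessions. Per (probe, transcript) pair only the maximum-bit-score
#' row is kept, mirroring the use of the maximum bit score as the
#' hybridization-affinity proxy. Subject coordinates are normalized to
#' ascending `t_start <= t_end`, with `strand = "minus"` when the file
#' reports them descending. Tiers are assigned from the file's bit score
#' via [classify_bits()]; raw scores are not present in the tabular
#' format and are reported as `NA`.
#'
#' @param path path to the tabular file.
#' @param db optional [transcript_db()]; if supplied, rows whose subject
#'   is not in the database are skipped with a warning.
#' @param params a [scoring_params()] object (tier thresholds).
#' @return An `alignment_hits` data.frame (see [best_local_alignment()]).
#' @export
read_blast_tabular <- function(path, db = NULL, params = scoring_params()) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 12L) {
    stop("expected 12 tab-separated columns (BLAST -outfmt 6), got ",
         ncol(df), call. = FALSE)
  }
  bit <- suppressWarnings(as.numeric(df[[12]]))
  if (anyNA(bit)) {
    stop("non-numeric bit score at row ", which(is.na(bit))[1], ": '",
         df[[12]][which(is.na(bit))[1]], "'", call. = FALSE)
  }
  qid <- df[[1]]
  sep <- regexpr(":", qid, fixed = TRUE)
  probeset <- ifelse(sep > 0, substring(qid, 1L, sep - 1L), qid)
  sstart <- as.integer(df[[9]]); send <- as.integer(df[[10]])
  minus <- sstart > send
  hits <- data.frame(probeset_id = probeset, probe_id = qid,
                     transcript_id = df[[2]], raw_score = NA_integer_,
                     bit_score = bit,
                     t_start = ifelse(minus, send, sstart),
                     t_end = ifelse(minus, sstart, send),
                     strand = ifelse(minus, "minus", "plus"),
                     tier = classify_bits(bit, params),
                     stringsAsFactors = FALSE)
  if (!is.null(db)) {
    unknown <- !hits$transcript_id %in% names(db$seq)
    if (any(unknown)) {
      warning(sum(unknown), " hit(s) to unknown transcript(s) skipped: ",
              paste(unique(hits$transcript_id[unknown]), collapse = ", "),
              call. = FALSE)
      hits <- hits[!unknown, , drop = FALSE]
    }
  }
  # keep only the best row per (probe, transcript); ties keep the first row
  ord <- order(hits$probe_id, hits$transcript_id, -hits$bit_score)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("probe_id", "transcript_id")]), ,
               drop = FALSE]
  hits <- hits[order(hits$probeset_id, hits$probe_id, hits$transcript_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}
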