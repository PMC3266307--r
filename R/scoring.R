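#' Platform interruption probability
#'
#' Per-base probability that in vitro transcription of the labeled target
#' is interrupted (by transcript degradation or loss of enzyme
#' processivity). The defaults follow the manufacturer's probe placement
#' design criteria: probes within 600 bases of the 3' end on U95/U133
#' class arrays, within 300 bases on the X3P array.
#'
#' @param platform one of "u95", "u133", "u133plus2", "x3p".
#' @return The per-base interruption probability `p`.
#' @export
platform_p <- function(platform = c("u133", "u133plus2", "u95", "x3p")) {
  platform <- match.arg(tolower(platform),
                        c("u133", "u133plus2", "u95", "x3p"))
  if (platform == "x3p") 1 / 300 else 1 / 600
}

hit_genes <- function(hits, db) unname(db$gene[hits$transcript_id])

#' Genes specifically detected by one probe
#'
#' A probe specifically detects a gene if it has a strong alignment to at
#' least one transcript of that gene and no strong or moderate alignment
#' to a transcript of any other gene. By construction the result has at
#' most one element: two genes with strong hits disqualify each other.
#' Moderate alignments to other transcripts of the same gene do not
#' disqualify it.
#'
#' @param hits `alignment_hits` rows restricted to this probe.
#' @param db a [transcript_db()].
#' @return Character vector of length 0 or 1.
#' @export
specific_genes_of_probe <- function(hits, db) {
  sm <- hits[hits$tier %in% c("strong", "moderate"), , drop = FALSE]
  if (nrow(sm) == 0) return(character(0))
  g <- hit_genes(sm, db)
  u <- unique(g)
  if (length(u) != 1L) return(character(0))
  if (any(sm$tier == "strong")) u else character(0)
}

#' Targeted gene of a probe set
#'
#' The gene specifically detected by the largest number of the probe
#' set's probes. A tie between genes is broken to the lexicographically
#' smallest gene id and flagged ambiguous; if no probe specifically
#' detects any gene the targeted gene is `NA`.
#'
#' @param probe_ids the probe set's probe identifiers.
#' @param hits `alignment_hits` for (at least) these probes.
#' @param db a [transcript_db()].
#' @return List with elements `gene` (gene id or `NA`) and `ambiguous`
#'   (logical).
#' @export
targeted_gene <- function(probe_ids, hits, db) {
  specifics <- unlist(lapply(probe_ids, function(p)
    specific_genes_of_probe(hits[hits$probe_id == p, , drop = FALSE], db)))
  if (length(specifics) == 0) return(list(gene = NA_character_, ambiguous = FALSE))
  tab <- table(specifics)
  winners <- sort(names(tab)[tab == max(tab)])
  list(gene = winners[1], ambiguous = length(winners) > 1L)
}

#' Specificity score of a probe set
#'
#' The fraction of the probe set's probes that specifically detect its
#' targeted gene; 0 when there is no targeted gene.
#'
#' @param probe_ids the probe set's probe identifiers.
#' @param hits `alignment_hits` for these probes.
#' @param db a [transcript_db()].
#' @param gene the targeted gene; resolved via [targeted_gene()] when
#'   `NULL`.
#' @return A fraction in `[0, 1]`.
#' @export
specificity_score <- function(probe_ids, hits, db, gene = NULL) {
  if (is.null(gene)) gene <- targeted_gene(probe_ids, hits, db)$gene
  if (is.na(gene)) return(0)
  n_specific <- sum(vapply(probe_ids, function(p)
    identical(specific_genes_of_probe(hits[hits$probe_id == p, , drop = FALSE],
                                      db), gene),
    logical(1)))
  n_specific / length(probe_ids)
}

#' Transcripts of a gene detected by a probe set
#'
#' A transcript is detected if a strict majority of the probe set's
#' probes (> n/2) have a strong alignment to it.
#'
#' @param probe_ids the probe set's probe identifiers.
#' @param gene the targeted gene.
#' @param hits `alignment_hits` for these probes.
#' @param db a [transcript_db()].
#' @return Character vector of detected transcript accessions.
#' @export
detected_transcripts <- function(probe_ids, gene, hits, db) {
  tx <- transcripts_of(db, gene)
  strong <- hits[hits$tier == "strong" & hits$probe_id %in% probe_ids &
                   hits$transcript_id %in% tx, , drop = FALSE]
  counts <- vapply(tx, function(t)
    length(unique(strong$probe_id[strong$transcript_id == t])), 0L)
  tx[counts > length(probe_ids) / 2]
}

#' Coverage score of a probe set
#'
#' The fraction of the targeted gene's transcripts (splice isoforms)
#' detected by the probe set, computed without regard to isoform
#' abundance; 0 when there is no targeted gene.
#'
#' @inheritParams detected_transcripts
#' @return A fraction in `[0, 1]`.
#' @export
coverage_score <- function(probe_ids, gene, hits, db) {
  if (is.na(gene)) return(0)
  tx <- transcripts_of(db, gene)
  length(detected_transcripts(probe_ids, gene, hits, db)) / length(tx)
}

#' Processivity requirement of alignment hits
#'
#' The number of bases from the 5'-most aligned transcript position
#' through the transcript's 3' terminus, inclusive: `L - t_start + 1` for
#' transcript length `L`. This is the length of labeled target that in
#' vitro transcription, primed at the poly-A (3') end, must synthesize
#' without interruption to reach the probe's site.
#'
#' @param hits `alignment_hits` rows (normally strong-tier).
#' @param db a [transcript_db()].
#' @return Numeric vector of base counts, one per hit row.
#' @export
processivity_requirement <- function(hits, db) {
  unname(transcript_lengths(db, hits$transcript_id)) - hits$t_start + 1
}

#' Robustness from a processivity requirement
#'
#' The survival probability of `N` independent per-base synthesis steps,
#' \eqn{(1 - p)^N}: the probability that in vitro transcription reaches
#' a probe site `N` bases from the 3' end without interruption. Equals 1
#' at `N = 0` and is strictly decreasing in both `N` and `p`.
#'
#' @param N processivity requirement(s) in bases (>= 0, may be
#'   half-integral).
#' @param p per-base interruption probability.
#' @return Probability vector, same length as `N`.
#' @export
robustness_from_requirement <- function(N, p = 1 / 600) {
  stopifnot(p > 0, p < 1, all(N >= 0))
  (1 - p)^N
}

#' Robustness score of a probe set
#'
#' The overall processivity requirement `N` is the median of the
#' per-alignment requirements over all strong alignments between the
#' probe set's probes and transcripts of the targeted gene (standard
#' median: mean of the central pair for an even count, used as a
#' real-valued exponent). The robustness score is the probability that
#' target synthesis proceeds `N` bases without interruption at per-base
#' interruption probability `p`:
#' \deqn{S_r = (1 - p)^N}
#'
#' @inheritParams detected_transcripts
#' @param p per-base interruption probability, see [platform_p()].
#' @return List with elements `N` (bases, possibly half-integral, or
#'   `NA` when there is no strong hit) and `S_r` (probability; 0 when
#'   `N` is `NA`).
#' @export
robustness_score <- function(probe_ids, gene, hits, db, p = 1 / 600) {
  stopifnot(p > 0, p < 1)
  if (is.na(gene)) return(list(N = NA_real_, S_r = 0))
  tx <- transcripts_of(db, gene)
  strong <- hits[hits$tier == "strong" & hits$probe_id %in% probe_ids &
                   hits$transcript_id %in% tx, , drop = FALSE]
  if (nrow(strong) == 0) return(list(N = NA_real_, S_r = 0))
  N <- stats::median(processivity_requirement(strong, db))
  list(N = N, S_r = robustness_from_requirement(N, p))
}

#' Overall probe-set score
#'
#' The product of the specificity, coverage and robustness scores,
#' \eqn{S_o = S_s S_c S_r}; each factor lies in `[0, 1]`, so
#' \eqn{S_o \le \min(S_s, S_c, S_r)}.
#'
#' @param specificity,coverage,robustness component scores in `[0, 1]`
#'   (vectorized).
#' @return The overall score(s).
#' @export
overall_score <- function(specificity, coverage, robustness) {
  stopifnot(all(specificity >= 0 & specificity <= 1),
            all(coverage >= 0 & coverage <= 1),
            all(robustness >= 0 & robustness <= 1))
  specificity * coverage * robustness
}

#' Score one probe set
#'
#' @param probeset one probe set as a [probe_table()] subset (all rows
#'   sharing one `probeset_id`).
#' @param hits `alignment_hits` from [search_all()] or
#'   [read_blast_tabular()] (may cover other probe sets; filtered by
#'   probe id).
#' @param db a [transcript_db()].
#' @param p per-base interruption probability.
#' @return One-row data.frame with columns `probeset_id`,
#'   `targeted_gene`, `n_probes`, `specificity`, `coverage`,
#'   `proc_requirement`, `robustness`, `overall`, `ambiguous_target`.
#' @export
score_probeset <- function(probeset, hits, db, p = 1 / 600) {
  stopifnot(length(unique(probeset$probeset_id)) == 1L)
  probe_ids <- probeset$probe_id
  h <- hits[hits$probe_id %in% probe_ids, , drop = FALSE]
  tg <- targeted_gene(probe_ids, h, db)
  S_s <- specificity_score(probe_ids, h, db, gene = tg$gene)
  S_c <- coverage_score(probe_ids, tg$gene, h, db)
  rob <- robustness_score(probe_ids, tg$gene, h, db, p = p)
  data.frame(probeset_id = probeset$probeset_id[1],
             targeted_gene = tg$gene,
             n_probes = length(probe_ids),
             specificity = S_s, coverage = S_c,
             proc_requirement = rob$N, robustness = rob$S_r,
             overall = overall_score(S_s, S_c, rob$S_r),
             ambiguous_target = tg$ambiguous,
             stringsAsFactors = FALSE)
}

#' Score every probe set on a platform
#'
#' @param probes a [probe_table()] (all probe sets).
#' @inheritParams score_probeset
#' @return A data.frame of class `probeset_scores`, one row per probe
#'   set in order of first appearance; see [score_probeset()] for
#'   columns.
#' @export
score_probesets <- function(probes, hits, db, p = 1 / 600) {
  out <- do.call(rbind, lapply(probe_sets(probes), score_probeset,
                               hits = hits, db = db, p = p))
  rownames(out) <- NULL
  class(out) <- c("probeset_scores", "data.frame")
  out
}
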