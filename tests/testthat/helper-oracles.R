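# Independent oracles and small constructors shared across tests.

rc <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                ""))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Literal brute force: maximum score over every ungapped offset and every
# contiguous sub-block, one strand. Independent of the package's scan.
brute_ungapped <- function(probe, transcript, match = 1, mismatch = -3) {
  p <- strsplit(probe, "")[[1]]
  t <- strsplit(transcript, "")[[1]]
  m <- length(p); n <- length(t)
  best <- 0
  for (off in (1 - m):(n - 1)) {
    i1 <- max(1L, 1L - off); i2 <- min(m, n - off)
    if (i1 > i2) next
    s <- ifelse(p[i1:i2] == t[(i1:i2) + off], match, mismatch)
    cs <- c(0, cumsum(s))
    for (a in seq_along(s)) {
      for (b in a:length(s)) best <- max(best, cs[b + 1] - cs[a])
    }
  }
  best
}

# Smith-Waterman with prohibitive gap penalties = best ungapped local
# block, via Biostrings (independent reference implementation).
sw_ungapped <- function(probe, transcript) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(probe, transcript, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 1e5, gapExtension = 1e5,
                                scoreOnly = TRUE)
}

has_seed <- function(probe, transcript, k = 8) {
  n <- nchar(probe)
  kmers <- unique(substring(probe, 1:(n - k + 1), k:n))
  for (km in kmers) if (grepl(km, transcript, fixed = TRUE)) return(TRUE)
  FALSE
}

# Strand-aware seeded oracle score: NA when neither strand is seeded.
oracle_score <- function(probe, transcript, scorer = sw_ungapped) {
  cand <- numeric(0)
  if (has_seed(probe, transcript)) cand <- c(cand, scorer(probe, transcript))
  p2 <- rc(probe)
  if (has_seed(p2, transcript)) cand <- c(cand, scorer(p2, transcript))
  if (length(cand) == 0) NA_real_ else max(cand)
}

# Hand-built alignment hit rows for scoring tests (bit score is set to a
# tier-consistent representative value; scoring reads only the tier).
mk_hit <- function(probe_id, transcript_id, tier, t_start = 1L,
                   probeset_id = sub(":.*$", "", probe_id)) {
  bit <- c(strong = 50.05, moderate = 40, weak = 20)[[tier]]
  data.frame(probeset_id = probeset_id, probe_id = probe_id,
             transcript_id = transcript_id, raw_score = NA_integer_,
             bit_score = bit, t_start = as.integer(t_start),
             t_end = as.integer(t_start + 24L), strand = "plus", tier = tier,
             stringsAsFactors = FALSE)
}

mk_hits <- function(...) {
  h <- do.call(rbind, list(...))
  class(h) <- c("alignment_hits", "data.frame")
  h
}

# Tiny database: geneA with two transcripts (lengths 1000/800), geneB and
# geneC with one each. Sequence content never inspected by the scoring
# functions, only lengths and gene assignment.
mk_db <- function(lengths = c(T1 = 1000L, T2 = 800L, T3 = 900L, T4 = 700L),
                  genes = c(T1 = "geneA", T2 = "geneA", T3 = "geneB",
                            T4 = "geneC")) {
  transcript_db(vapply(lengths, function(L) strrep("A", L), ""), genes)
}

mk_scores <- function(...) {
  df <- do.call(rbind, list(...))
  class(df) <- c("probeset_scores", "data.frame")
  df
}

score_row <- function(probeset_id, gene, S_s, S_c, N, S_r,
                      n_probes = 11L, ambiguous = FALSE) {
  data.frame(probeset_id = probeset_id, targeted_gene = gene,
             n_probes = n_probes, specificity = S_s, coverage = S_c,
             proc_requirement = N, robustness = S_r, overall = S_s * S_c * S_r,
             ambiguous_target = ambiguous, stringsAsFactors = FALSE)
}
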