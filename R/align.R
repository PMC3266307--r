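#' Alignment scoring parameters
#'
#' Parameters of the seeded ungapped local aligner and its Karlin-Altschul
#' bit-score normalization. The defaults emulate an ungapped BLASTN search
#' with match +1, mismatch -3 and word size 8, and calibrate the bit score
#' so that a perfect 24-base match falls exactly at the "strong" tier
#' threshold (48 bits) and a perfect 16-base match at the "moderate"
#' threshold (32 bits). lambda is given to three decimals deliberately:
#' truncating to 1.37 would place a 24-base exact match at 47.9 bits,
#' below the strong threshold.
#'
#' @param match match reward (raw score units per identical base).
#' @param mismatch mismatch penalty (negative).
#' @param lambda Karlin-Altschul lambda, in nats per raw score unit.
#' @param K Karlin-Altschul K.
#' @param word_size seed length: an alignment is only reported if the
#'   probe and transcript share `word_size` consecutive identical bases
#'   on the strand of the alignment.
#' @param strong_min_bits,moderate_min_bits tier thresholds in bits.
#' @return An object of class `scoring_params`.
#' @examples
#' p <- scoring_params()
#' bits(24, p)  # ~48.07, just above the strong threshold
#' @export
scoring_params <- function(match = 1L, mismatch = -3L,
                           lambda = 1.374, K = 0.711,
                           word_size = 8L,
                           strong_min_bits = 48, moderate_min_bits = 32) {
  stopifnot(match > 0, mismatch < 0, lambda > 0, K > 0,
            word_size >= 1, strong_min_bits > moderate_min_bits)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 lambda = lambda, K = K, word_size = as.integer(word_size),
                 strong_min_bits = strong_min_bits,
                 moderate_min_bits = moderate_min_bits),
            class = "scoring_params")
}

#' Convert a raw ungapped alignment score to bits
#'
#' Standard Karlin-Altschul normalization
#' \deqn{B = (\lambda R - \ln K) / \ln 2}
#' for raw score \eqn{R}; strictly increasing in the raw score.
#'
#' @param raw_score non-negative raw score(s) (+1 per match, -3 per
#'   mismatch under the defaults).
#' @param params a [scoring_params()] object.
#' @return Bit score(s), same length as `raw_score`.
#' @export
bits <- function(raw_score, params = scoring_params()) {
  stopifnot(all(raw_score >= 0))
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Classify a bit score into an alignment tier
#'
#' Tiers follow the BLASTN-derived convention for 25-mer probes:
#' `strong` (>= 48 bits; at least 24 identical bases under the default
#' calibration, the probe almost certainly detects the target),
#' `moderate` (32-48 bits; 16-23 identical bases, the probe may respond),
#' `weak` (< 32 bits; unlikely to respond). The descriptive upper bounds
#' (51 and 47 bits for perfect 25-mers) are not enforced.
#'
#' @param bit_score numeric vector of bit scores.
#' @param params a [scoring_params()] object.
#' @return Character vector in `c("strong", "moderate", "weak")`.
#' @export
classify_bits <- function(bit_score, params = scoring_params()) {
  stopifnot(all(is.finite(bit_score)))
  ifelse(bit_score >= params$strong_min_bits, "strong",
         ifelse(bit_score >= params$moderate_min_bits, "moderate", "weak"))
}

# -- internal sequence helpers -------------------------------------------

BASES <- c("A", "C", "G", "T")

encode_dna <- function(x) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1]], BASES)
  if (anyNA(v)) stop("sequence contains non-ACGT characters: ", x)
  v
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), ""))
}

# Per-transcript score vectors: element [[b]][j] is the score of probe
# base b against transcript position j. Computed once per transcript and
# shared by both strands and all probes in search_all.
score_vectors <- function(t_int, params) {
  lapply(1:4, function(b) {
    v <- rep(params$mismatch, length(t_int))
    v[t_int == b] <- params$match
    as.numeric(v)
  })
}

# Best ungapped local block of integer-encoded probe p against a
# transcript, via a vectorized Kadane scan: run[j] is the best score of a
# block ending at probe row i, transcript position j, updated row by row
# with a one-position shift (blocks are diagonal). Tracks the probe row
# where each running block started (for transcript coordinates) and the
# longest run of consecutive matches (for seeding). Returns NULL when no
# positive-scoring block exists or no diagonal carries word_size
# consecutive matches; score ties resolve to the smallest t_start.
ungapped_best_block <- function(p, sc_by_base, params) {
  m <- length(p); n <- length(sc_by_base[[1]])
  NEG <- -1e9
  run <- rep(NEG, n)
  runstart <- integer(n)
  mrun <- integer(n)
  best <- 0
  cand_ts <- integer(0)
  cand_te <- integer(0)
  seeded <- FALSE
  ws <- params$word_size
  for (i in seq_len(m)) {
    sc <- sc_by_base[[p[i]]]
    ext <- c(NEG, run[-n]) + sc
    fresh <- sc > ext
    run <- pmax(ext, sc)
    runstart <- c(0L, runstart[-n])
    runstart[fresh] <- i
    mrun <- (c(0L, mrun[-n]) + 1L) * (sc > 0)
    if (!seeded && any(mrun >= ws)) seeded <- TRUE
    rmax <- max(run)
    if (rmax > 0 && rmax >= best) {
      js <- which(run == rmax)
      ts <- js - (i - runstart[js])
      if (rmax > best) {
        best <- rmax
        cand_ts <- ts
        cand_te <- js
      } else {
        cand_ts <- c(cand_ts, ts)
        cand_te <- c(cand_te, js)
      }
    }
  }
  if (!seeded || best <= 0) return(NULL)
  k <- which.min(cand_ts)
  list(raw = best, t_start = cand_ts[k], t_end = cand_te[k])
}

#' Best ungapped local alignment of a probe against a transcript
#'
#' Finds the maximum-raw-score ungapped local alignment between a probe
#' and a transcript, searching both the probe as given and its reverse
#' complement. An alignment is reported only if the searched strand shares
#' at least `word_size` consecutive identical bases with the transcript
#' (BLAST-like exact seeding; at word size 8 this loses no alignment of
#' moderate tier or better, which requires a raw score of at least 16).
#' Equal-scoring alignments resolve to the smallest transcript start
#' coordinate, then to the plus strand.
#'
#' @param probe probe sequence (A/C/G/T string, nominally 25 bases).
#' @param transcript transcript cDNA sequence (A/C/G/T string, 5'->3').
#' @param params a [scoring_params()] object.
#' @param probe_id,probeset_id,transcript_id optional identifiers copied
#'   into the result.
#' @return A one-row data.frame with columns `probeset_id`, `probe_id`,
#'   `transcript_id`, `raw_score`, `bit_score`, `t_start`, `t_end`
#'   (1-based inclusive transcript coordinates, `t_start <= t_end`),
#'   `strand` ("plus"/"minus") and `tier`; or `NULL` if no seeded
#'   alignment exists on either strand.
#' @export
best_local_alignment <- function(probe, transcript, params = scoring_params(),
                                 probe_id = NA_character_,
                                 probeset_id = NA_character_,
                                 transcript_id = NA_character_) {
  sc <- score_vectors(encode_dna(transcript), params)
  align_encoded(encode_dna(probe), encode_dna(revcomp(probe)), sc, params,
                probe_id, probeset_id, transcript_id)
}

# Shared core so search_all can precompute transcript score vectors once.
align_encoded <- function(p_plus, p_minus, sc_t, params,
                          probe_id, probeset_id, transcript_id) {
  hp <- ungapped_best_block(p_plus, sc_t, params)
  hm <- ungapped_best_block(p_minus, sc_t, params)
  if (is.null(hp) && is.null(hm)) return(NULL)
  if (is.null(hm)) {
    h <- hp; strand <- "plus"
  } else if (is.null(hp)) {
    h <- hm; strand <- "minus"
  } else if (hp$raw > hm$raw ||
             (hp$raw == hm$raw && hp$t_start <= hm$t_start)) {
    h <- hp; strand <- "plus"
  } else {
    h <- hm; strand <- "minus"
  }
  b <- bits(h$raw, params)
  data.frame(probeset_id = probeset_id, probe_id = probe_id,
             transcript_id = transcript_id,
             raw_score = as.integer(h$raw), bit_score = b,
             t_start = as.integer(h$t_start), t_end = as.integer(h$t_end),
             strand = strand, tier = classify_bits(b, params),
             stringsAsFactors = FALSE)
}

seed_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Align every probe against every seeded transcript
#'
#' Runs [best_local_alignment()] for each (probe, transcript) pair that
#' shares at least one exact `word_size`-mer on either strand (found via a
#' k-mer index of the transcriptome, so unrelated pairs are never scanned).
#' Hits of every tier, including weak, are retained; downstream scoring
#' filters by tier.
#'
#' @param probes a [probe_table()].
#' @param db a [transcript_db()].
#' @param params a [scoring_params()] object.
#' @return An `alignment_hits` data.frame (one row per retained pair; see
#'   [best_local_alignment()] for columns), ordered by probeset_id,
#'   probe_id, transcript_id — invariant to transcript input order.
#' @export
search_all <- function(probes, db, params = scoring_params()) {
  stopifnot(inherits(probes, "probe_table"), inherits(db, "transcript_db"),
            nrow(probes) > 0, length(db$seq) > 0)
  k <- params$word_size
  tid <- names(db$seq)
  index <- new.env(parent = emptyenv(), size = 4L * sum(nchar(db$seq)))
  for (i in seq_along(db$seq)) {
    for (km in seed_kmers(db$seq[[i]], k)) {
      index[[km]] <- c(index[[km]], i)
    }
  }
  t_sc <- lapply(db$seq, function(s) score_vectors(encode_dna(s), params))
  out <- vector("list", nrow(probes))
  for (r in seq_len(nrow(probes))) {
    pr <- probes$sequence[r]
    prc <- revcomp(pr)
    kms <- unique(c(seed_kmers(pr, k), seed_kmers(prc, k)))
    cand <- sort(unique(unlist(lapply(kms, function(km)
      if (!is.null(index[[km]])) index[[km]] else integer(0)))))
    if (length(cand) == 0) next
    pp <- encode_dna(pr); pm <- encode_dna(prc)
    hits <- lapply(cand, function(i)
      align_encoded(pp, pm, t_sc[[i]], params,
                    probes$probe_id[r], probes$probeset_id[r], tid[i]))
    out[[r]] <- do.call(rbind, hits)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(probeset_id = character(0), probe_id = character(0),
                      transcript_id = character(0), raw_score = integer(0),
                      bit_score = numeric(0), t_start = integer(0),
                      t_end = integer(0), strand = character(0),
                      tier = character(0), stringsAsFactors = FALSE)
  } else {
    res <- res[order(res$probeset_id, res$probe_id, res$transcript_id), ,
               drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("alignment_hits", "data.frame")
  res
}
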