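#' Specify a synthetic probe-set fixture
#'
#' Describes a toy transcriptome plus planted probe sets whose
#' specificity, coverage and robustness scores are known analytically
#' from the construction, so the whole pipeline can be tested without
#' any external sequence download. Five archetypes are available:
#' \describe{
#'   \item{specific_3prime}{probes tiled near the 3' end of a block
#'     shared by all of a gene's isoforms: fully specific, full
#'     coverage, high robustness.}
#'   \item{cross_hybridizer}{as above, but a sub-block of the probe
#'     region is copied into another gene, giving moderate cross-hits
#'     that cost specificity for the overlapping probes.}
#'   \item{isoform_partial}{probes placed on a region unique to one of
#'     two isoforms: specific, but coverage 1/2.}
#'   \item{five_prime_shifted}{probes placed thousands of bases from the
#'     3' end: robustness collapses.}
#'   \item{orphan}{probes drawn from random sequence absent from the
#'     transcriptome: no targeted gene, all scores 0.}
#' }
#'
#' @param seed integer seed; fully determines the fixture.
#' @param archetypes list of descriptors, each a list with elements
#'   `archetype` (one of the five names above), `n_probes`,
#'   `distance_from_3prime` (bases between the 3'-most probe end and the
#'   transcript 3' terminus) and, for cross_hybridizer,
#'   `shared_block_len` (16-23 bases, so the planted cross-hit is
#'   moderate, never strong). Defaults build one probe set of each
#'   archetype with 11 probes tiled at 7-base steps.
#' @param n_background_genes untargeted decoy genes.
#' @param isoforms_per_gene range (lo, hi) of isoform counts.
#' @param transcript_length range (lo, hi) of transcript lengths, bases.
#' @param probe_step tiling step between consecutive probe starts.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         archetypes = default_archetypes(),
                         n_background_genes = 2L,
                         isoforms_per_gene = c(2L, 2L),
                         transcript_length = c(1200L, 2000L),
                         probe_step = 7L) {
  stopifnot(length(isoforms_per_gene) == 2, length(transcript_length) == 2,
            probe_step >= 1, n_background_genes >= 1)
  for (a in archetypes) {
    stopifnot(a$archetype %in% c("specific_3prime", "cross_hybridizer",
                                 "isoform_partial", "five_prime_shifted",
                                 "orphan"),
              a$n_probes >= 1)
    if (a$archetype == "cross_hybridizer") {
      stopifnot(a$shared_block_len >= 16, a$shared_block_len <= 23)
    }
  }
  structure(list(seed = as.integer(seed), archetypes = archetypes,
                 n_background_genes = as.integer(n_background_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 transcript_length = as.integer(transcript_length),
                 probe_step = as.integer(probe_step)),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
default_archetypes <- function() {
  list(
    list(archetype = "specific_3prime", n_probes = 11L,
         distance_from_3prime = 30L),
    list(archetype = "cross_hybridizer", n_probes = 11L,
         distance_from_3prime = 30L, shared_block_len = 20L),
    list(archetype = "isoform_partial", n_probes = 11L),
    list(archetype = "five_prime_shifted", n_probes = 11L,
         distance_from_3prime = 3000L),
    list(archetype = "orphan", n_probes = 11L)
  )
}

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

kmers_both <- function(seqs, k) {
  unique(unlist(lapply(c(seqs, revcomp(seqs)), seed_kmers, k = k)))
}

any_kmer_in <- function(kmers, text) {
  for (km in kmers) if (grepl(km, text, fixed = TRUE)) return(TRUE)
  FALSE
}

# Probe start/end offsets, tiling `n` probes at `step` so the last probe
# ends at `last_end` (1-based, within the containing sequence).
tile_probes <- function(last_end, n, step) {
  ends <- last_end - step * (n - seq_len(n))
  list(start = ends - 24L, end = ends)
}

#' Generate a synthetic fixture with analytically known scores
#'
#' Builds random uniform-composition transcripts (isoforms of a gene
#' share a 3' block), plants probes as exact 25-mer substrings according
#' to each archetype, and computes the expected scores directly from the
#' construction geometry — never by running the aligner or the scoring
#' code. Planted probes are rejection-sampled so that none of their
#' 16-mers (either strand) occurs in another gene's transcripts, which
#' rules out accidental strong or moderate cross-hits and keeps the
#' analytic expectations exact. The copied cross-hybridization block is
#' flanked in the recipient transcript by deliberately mismatching guard
#' bases, so its alignment score equals the planted overlap exactly and
#' can never extend into the strong tier.
#'
#' @param spec a [fixture_spec()].
#' @param p per-base interruption probability used for the expected
#'   robustness scores.
#' @return A list of class `probe_fixture` with elements `probes` (a
#'   [probe_table()]), `db` (a [transcript_db()]) and `expected` (a
#'   `probeset_scores` data.frame of ground-truth scores).
#' @export
generate_fixture <- function(spec, p = 1 / 600) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  step <- spec$probe_step
  arcs <- spec$archetypes
  ids <- make.unique(vapply(arcs, `[[`, "", "archetype"), sep = "_")

  for (attempt in seq_len(100L)) {
    genes <- list()   # gene_id -> named character vector of isoform seqs
    built <- vector("list", length(arcs))
    for (ai in seq_along(arcs)) {
      a <- arcs[[ai]]
      b <- switch(a$archetype,
        specific_3prime = build_3prime(a, spec, n_iso = sample_range(spec$isoforms_per_gene)),
        cross_hybridizer = build_3prime(a, spec, n_iso = 1L,
                                        block_len = a$shared_block_len),
        five_prime_shifted = build_3prime(a, spec, n_iso = 1L),
        isoform_partial = build_isopartial(a, spec),
        orphan = build_orphan(a))
      b$probeset_id <- paste0("fx_", ids[ai])
      b$gene_id <- if (a$archetype == "orphan") NA_character_ else
        paste0("G", toupper(substr(ids[ai], 1, 4)), ai)
      if (!is.na(b$gene_id)) {
        iso <- b$isoforms
        names(iso) <- paste0(b$gene_id, ".", seq_along(iso))
        genes[[b$gene_id]] <- iso
      }
      built[[ai]] <- b
    }
    for (bg in seq_len(spec$n_background_genes)) {
      gid <- sprintf("BG%02d", bg)
      k <- sample_range(spec$isoforms_per_gene)
      B <- sample(300:600, 1L)
      shared <- rand_seq(B)
      iso <- vapply(seq_len(k), function(i) {
        L <- sample_range(spec$transcript_length)
        paste0(rand_seq(max(L - B, 50L)), shared)
      }, "")
      names(iso) <- paste0(gid, ".", seq_len(k))
      genes[[gid]] <- iso
    }
    # rejection: no planted probe 16-mer (either strand) may occur in
    # another gene's transcripts (for orphans: in any transcript)
    all_tx <- unlist(genes)
    clean <- TRUE
    for (b in built) {
      other <- if (is.na(b$gene_id)) all_tx else
        all_tx[!grepl(paste0("^", b$gene_id, "\\."), names(all_tx))]
      if (any_kmer_in(kmers_both(b$probes, 16L),
                      paste(other, collapse = "#"))) {
        clean <- FALSE
        break
      }
    }
    if (clean) break
    if (attempt == 100L) stop("fixture rejection sampling did not converge")
  }

  # Plant cross-hybridization blocks into the first background gene.
  # Eight guard bases on each flank are forced to mismatch the source
  # diagonal, so no ungapped block can score above the planted overlap:
  # crossing the guards costs 24 while at most 25 - overlap - 8 <= 16
  # random bases lie beyond them.
  cross_gene <- "BG01"
  n_guard <- 8L
  for (b in built) {
    if (is.null(b$cross_block)) next
    tx1 <- names(genes[[cross_gene]])[1]
    s <- genes[[cross_gene]][[tx1]]
    bl <- nchar(b$cross_block$seq)
    q <- sample(40:(nchar(s) - bl - 40L), 1L)
    mismatching <- function(base) sample(setdiff(BASES, base), 1L)
    substr(s, q, q + bl - 1L) <- b$cross_block$seq
    ls <- strsplit(b$cross_block$left_src, "")[[1]]
    rs <- strsplit(b$cross_block$right_src, "")[[1]]
    for (i in seq_len(n_guard)) {
      pos <- q - n_guard - 1L + i
      substr(s, pos, pos) <- mismatching(ls[i])
      pos <- q + bl - 1L + i
      substr(s, pos, pos) <- mismatching(rs[i])
    }
    genes[[cross_gene]][[tx1]] <- s
  }

  seqs <- unlist(unname(lapply(genes, identity)))
  gene_of <- structure(rep(names(genes), times = lengths(genes)),
                       names = names(seqs))
  db <- transcript_db(seqs, gene_of)

  probes <- do.call(rbind, lapply(built, function(b)
    data.frame(probeset_id = b$probeset_id,
               probe_id = paste0(b$probeset_id, ":", seq_along(b$probes)),
               sequence = b$probes, stringsAsFactors = FALSE)))
  probes <- validate_probe_table(probes)

  expected <- do.call(rbind, lapply(built, function(b) {
    N <- if (length(b$reqs) == 0) NA_real_ else stats::median(b$reqs)
    S_r <- if (is.na(N)) 0 else (1 - p)^N
    data.frame(probeset_id = b$probeset_id, targeted_gene = b$gene_id,
               n_probes = length(b$probes),
               specificity = b$S_s, coverage = b$S_c,
               proc_requirement = N, robustness = S_r,
               overall = b$S_s * b$S_c * S_r,
               ambiguous_target = FALSE, stringsAsFactors = FALSE)
  }))
  class(expected) <- c("probeset_scores", "data.frame")

  structure(list(probes = probes, db = db, expected = expected),
            class = "probe_fixture")
}

# Probes tiled inside a 3' block shared by all isoforms, the 3'-most
# probe ending `distance_from_3prime` bases from the transcript end.
# Optionally records a sub-block (for cross-hybridization planting).
build_3prime <- function(a, spec, n_iso, block_len = NULL) {
  n <- a$n_probes; step <- spec$probe_step; d <- a$distance_from_3prime
  span <- 25L + step * (n - 1L)
  B <- d + span + 30L
  shared <- rand_seq(B)
  iso <- vapply(seq_len(n_iso), function(i) {
    L <- sample_range(spec$transcript_length)
    paste0(rand_seq(max(L - B, 50L)), shared)
  }, "")
  at <- tile_probes(B - d, n, step)
  probes <- substring(shared, at$start, at$end)
  reqs <- rep(B - at$start + 1, times = n_iso)
  S_s <- 1
  cross <- NULL
  if (!is.null(block_len)) {
    b_o <- at$start[ceiling(n / 2)] + 2L
    overlap <- pmax(0L, pmin(at$end, b_o + block_len - 1L) -
                      pmax(at$start, b_o) + 1L)
    S_s <- mean(overlap < 16L)
    cross <- list(seq = substring(shared, b_o, b_o + block_len - 1L),
                  left_src = substring(shared, b_o - 8L, b_o - 1L),
                  right_src = substring(shared, b_o + block_len,
                                        b_o + block_len + 7L))
  }
  list(isoforms = iso, probes = probes, reqs = reqs, S_s = S_s, S_c = 1,
       cross_block = cross)
}

# Two isoforms sharing a 3' block; probes on the 5' region unique to
# isoform 1, so only that isoform is detected.
build_isopartial <- function(a, spec) {
  n <- a$n_probes; step <- spec$probe_step
  span <- 25L + step * (n - 1L)
  U1 <- span + 65L
  B <- sample(300:600, 1L)
  u1 <- rand_seq(U1)
  iso <- c(paste0(u1, rand_seq(B)),
           paste0(rand_seq(sample(150:400, 1L)), rand_seq(B)))
  # the two isoforms share no sequence here; sharing is irrelevant to
  # the planted expectations and independent blocks keep them exact
  at <- tile_probes(U1 - 30L, n, step)
  probes <- substring(u1, at$start, at$end)
  L1 <- nchar(iso[1])
  list(isoforms = iso, probes = probes, reqs = L1 - at$start + 1,
       S_s = 1, S_c = 0.5, cross_block = NULL)
}

build_orphan <- function(a) {
  list(isoforms = NULL, probes = vapply(seq_len(a$n_probes),
                                        function(i) rand_seq(25L), ""),
       reqs = numeric(0), S_s = 0, S_c = 0, cross_block = NULL)
}

#' Write a fixture bundle to disk
#'
#' Writes the fixture's probes (probe-tab and FASTA), transcriptome
#' (FASTA plus gene map) and expected scores (CSV) into a directory.
#' The same seed always produces byte-identical files.
#'
#' @param spec a [fixture_spec()] (or an already generated
#'   `probe_fixture`).
#' @param dir output directory, created if needed.
#' @param p per-base interruption probability for the expected scores.
#' @return Named list of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(spec, dir, p = 1 / 600) {
  fx <- if (inherits(spec, "probe_fixture")) spec else
    generate_fixture(spec, p = p)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    probe_tab = file.path(dir, "probes.probe_tab"),
    probe_fasta = file.path(dir, "probes.fasta"),
    transcripts = file.path(dir, "transcripts.fasta"),
    gene_map = file.path(dir, "gene_map.tsv"),
    expected = file.path(dir, "expected_scores.csv"))
  write_probe_tab(fx$probes, paths$probe_tab)
  write_probe_fasta(fx$probes, paths$probe_fasta)
  write_transcriptome(fx$db, paths$transcripts, paths$gene_map)
  write_scores(fx$expected, paths$expected)
  invisible(paths)
}
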