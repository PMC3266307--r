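test_that("bit scores follow the Karlin-Altschul closed form", {
  p <- scoring_params()
  # frozen from (1.374 * raw - ln 0.711) / ln 2
  expect_equal(bits(24, p), 48.0663902, tolerance = 1e-6)
  expect_equal(bits(16, p), 32.2082863, tolerance = 1e-6)
  expect_equal(bits(0, p), 0.4920785, tolerance = 1e-6)
  expect_true(all(diff(bits(0:30, p)) > 0))
})

test_that("calibration reproduces the tier/length correspondence exactly", {
  p <- scoring_params()
  expect_gte(bits(24, p), p$strong_min_bits)
  expect_lt(bits(23, p), p$strong_min_bits)
  expect_gte(bits(16, p), p$moderate_min_bits)
  expect_lt(bits(15, p), p$moderate_min_bits)
  # three-decimal lambda matters: lambda = 1.37 would break the strong
  # boundary at 24 identical bases
  expect_lt(bits(24, scoring_params(lambda = 1.37)), 48)
})

test_that("bit scores classify into strong/moderate/weak tiers", {
  p <- scoring_params()
  expect_identical(classify_bits(bits(25, p), p), "strong")   # ~50.05
  expect_identical(classify_bits(bits(16, p), p), "moderate") # ~32.21
  expect_identical(classify_bits(bits(15, p), p), "weak")     # ~30.23
  expect_identical(classify_bits(c(48, 47.99, 32, 31.99)),
                   c("strong", "moderate", "moderate", "weak"))
})

test_that("a planted exact 25-mer is found with exact coordinates", {
  set.seed(101)
  tr <- rand_dna(500)
  pr <- substring(tr, 101, 125)
  h <- best_local_alignment(pr, tr)
  expect_equal(h$raw_score, 25L)
  expect_equal(h$t_start, 101L)
  expect_equal(h$t_end, 125L)
  expect_identical(h$strand, "plus")
  expect_identical(h$tier, "strong")
  expect_equal(h$bit_score, bits(25), tolerance = 1e-12)
})

test_that("one central mismatch leaves a full-length moderate block", {
  set.seed(102)
  tr <- rand_dna(400)
  pr <- substring(tr, 201, 225)
  mid <- strsplit(pr, "")[[1]]
  mid[13] <- setdiff(c("A", "C", "G", "T"), mid[13])[1]
  pr <- paste(mid, collapse = "")
  h <- best_local_alignment(pr, tr)
  # 24 matches - one mismatch beats either 12-match flank: raw 21
  expect_equal(h$raw_score, 21L)
  expect_identical(h$tier, "moderate")
  expect_equal(h$raw_score, brute_ungapped(pr, tr))
})

test_that("reverse-complemented probes score identically on the minus strand", {
  set.seed(103)
  for (i in 1:5) {
    tr <- rand_dna(300)
    pr <- substring(tr, 51, 75)
    hp <- best_local_alignment(pr, tr)
    hm <- best_local_alignment(rc(pr), tr)
    expect_equal(hm$raw_score, hp$raw_score)
    expect_equal(hm$t_start, hp$t_start)
    expect_equal(hm$t_end, hp$t_end)
    expect_identical(hm$strand, "minus")
  }
})

test_that("aligner equals the literal offset/sub-block oracle at small n", {
  set.seed(104)
  for (i in 1:40) {
    n <- sample(60:300, 1)
    tr <- rand_dna(n)
    pr <- if (i %% 2 == 0) {
      rand_dna(25)
    } else {
      # plant a mutated copy so seeds and nontrivial blocks exist
      pos <- sample(n - 24, 1)
      x <- strsplit(substring(tr, pos, pos + 24), "")[[1]]
      k <- sample(0:6, 1)
      if (k > 0) {
        at <- sample(25, k)
        x[at] <- vapply(x[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      }
      s <- paste(x, collapse = "")
      if (runif(1) < 0.5) rc(s) else s
    }
    h <- best_local_alignment(pr, tr)
    ora <- oracle_score(pr, tr, scorer = brute_ungapped)
    if (is.null(h)) {
      expect_true(is.na(ora))
    } else {
      expect_equal(h$raw_score, as.integer(ora))
    }
  }
})

test_that("no alignment is reported without a word-size exact seed", {
  # 7 identical bases sprinkled with mismatches: no 8-mer seed
  tr <- paste0(strrep("A", 50), "CCCCCCC", strrep("A", 50))
  pr <- paste0("GGGGGGGGG", "CCCCCCC", "GGGGGGGGG")
  expect_null(best_local_alignment(pr, tr))
  # extend the shared block to 8: now reported
  tr2 <- paste0(strrep("A", 50), "CCCCCCCC", strrep("A", 50))
  pr2 <- paste0("GGGGGGGG", "CCCCCCCC", "GGGGGGGGG")
  h <- best_local_alignment(pr2, tr2)
  expect_equal(h$raw_score, 8L)
})

test_that("equal-scoring hits resolve to the smallest transcript start", {
  set.seed(105)
  core <- rand_dna(25)
  filler <- function() rand_dna(40)
  tr <- paste0(filler(), core, filler(), core, filler())
  h <- best_local_alignment(core, tr)
  expect_equal(h$t_start, 41L)
})

test_that("search_all finds planted hits and ignores unrelated genes", {
  fx <- generate_fixture(fixture_spec(seed = 11))
  hits <- search_all(fx$probes, fx$db)
  spec_hits <- hits[hits$probeset_id == "fx_specific_3prime", ]
  strong <- spec_hits[spec_hits$tier == "strong", ]
  own <- transcripts_of(fx$db, "GSPEC1")
  expect_true(all(strong$transcript_id %in% own))
  expect_equal(nrow(strong), 11L * length(own))
  # orphan probes never reach strong or moderate anywhere
  orphan <- hits[hits$probeset_id == "fx_orphan", ]
  expect_false(any(orphan$tier %in% c("strong", "moderate")))
  # cross-hybridizer: planted moderate hits into the decoy gene
  cross <- hits[hits$probeset_id == "fx_cross_hybridizer" &
                  hits$tier == "moderate", ]
  expect_true(any(fx$db$gene[cross$transcript_id] == "BG01"))
})

test_that("search_all results are invariant to transcript input order", {
  fx <- generate_fixture(fixture_spec(seed = 12))
  hits1 <- search_all(fx$probes, fx$db)
  perm <- sample(length(fx$db$seq))
  db2 <- transcript_db(fx$db$seq[perm], fx$db$gene[perm])
  hits2 <- search_all(fx$probes, db2)
  expect_equal(hits1, hits2)
})

test_that("any alignment with a word-size run of matches is seeded and found", {
  set.seed(106)
  for (i in 1:20) {
    tr <- rand_dna(400)
    seed8 <- substring(tr, 200, 207)
    pr <- paste0(rand_dna(9), seed8, rand_dna(8))
    h <- best_local_alignment(pr, tr)
    expect_false(is.null(h))
    expect_gte(h$raw_score, 8L)
  }
})
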