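test_that("probe-level specificity follows the strong/moderate exclusion rule", {
  db <- mk_db()
  # strong to geneA only
  expect_identical(specific_genes_of_probe(mk_hits(mk_hit("p:1", "T1", "strong")),
                                           db), "geneA")
  # a moderate hit to any other gene disqualifies
  expect_identical(specific_genes_of_probe(
    mk_hits(mk_hit("p:1", "T1", "strong"), mk_hit("p:1", "T3", "moderate")),
    db), character(0))
  # strong hits to two genes disqualify each other
  expect_identical(specific_genes_of_probe(
    mk_hits(mk_hit("p:1", "T1", "strong"), mk_hit("p:1", "T3", "strong")),
    db), character(0))
  # moderate hits to another transcript of the same gene are harmless
  expect_identical(specific_genes_of_probe(
    mk_hits(mk_hit("p:1", "T1", "strong"), mk_hit("p:1", "T2", "moderate")),
    db), "geneA")
  # weak hits elsewhere are ignored entirely
  expect_identical(specific_genes_of_probe(
    mk_hits(mk_hit("p:1", "T1", "strong"), mk_hit("p:1", "T3", "weak")),
    db), "geneA")
})

test_that("targeted gene is the specific-probe plurality with flagged ties", {
  db <- mk_db()
  ids <- paste0("ps:", 1:11)
  hits <- mk_hits(do.call(rbind, lapply(ids[1:10], mk_hit,
                                        transcript_id = "T1",
                                        tier = "strong")))
  tg <- targeted_gene(ids, hits, db)
  expect_identical(tg$gene, "geneA")
  expect_false(tg$ambiguous)
  # 5 probes specific to geneA vs 5 to geneB: lexicographic winner, flagged
  hits2 <- mk_hits(
    do.call(rbind, lapply(ids[1:5], mk_hit, transcript_id = "T1",
                          tier = "strong")),
    do.call(rbind, lapply(ids[6:10], mk_hit, transcript_id = "T3",
                          tier = "strong")))
  tg2 <- targeted_gene(ids, hits2, db)
  expect_identical(tg2$gene, "geneA")
  expect_true(tg2$ambiguous)
  # nothing specific anywhere
  hits3 <- mk_hits(mk_hit("ps:1", "T1", "strong"),
                   mk_hit("ps:1", "T3", "strong"))
  tg3 <- targeted_gene(ids, hits3, db)
  expect_true(is.na(tg3$gene))
  expect_false(tg3$ambiguous)
})

test_that("specificity score is the specific-probe fraction", {
  db <- mk_db()
  ids <- paste0("ps:", 1:11)
  mk_n_specific <- function(k) mk_hits(
    do.call(rbind, lapply(ids[seq_len(k)], mk_hit, transcript_id = "T1",
                          tier = "strong")),
    if (k < 11) do.call(rbind, lapply(ids[(k + 1):11], function(p)
      rbind(mk_hit(p, "T1", "strong"), mk_hit(p, "T3", "moderate")))))
  expect_equal(specificity_score(ids, mk_n_specific(10), db), 10 / 11)
  expect_equal(specificity_score(ids, mk_n_specific(3), db), 3 / 11)
  expect_equal(specificity_score(ids, mk_hits(mk_hit("ps:1", "T1", "weak")),
                                 db), 0)
})

test_that("transcript detection needs a strict majority of strong probes", {
  db <- mk_db()
  ids <- paste0("ps:", 1:11)
  strong_to <- function(tx, k) do.call(rbind, lapply(ids[seq_len(k)], mk_hit,
                                                     transcript_id = tx,
                                                     tier = "strong"))
  hits <- mk_hits(strong_to("T1", 6), strong_to("T2", 5))
  expect_identical(detected_transcripts(ids, "geneA", hits, db), "T1")
  expect_equal(coverage_score(ids, "geneA", hits, db), 0.5)
  hits11 <- mk_hits(strong_to("T1", 11), strong_to("T2", 11))
  expect_equal(coverage_score(ids, "geneA", hits11, db), 1)
  expect_equal(coverage_score(ids, NA_character_, hits11, db), 0)
})

test_that("processivity requirement counts 5' alignment start to 3' end", {
  db <- mk_db(lengths = c(T1 = 1000L, TS = 25L),
              genes = c(T1 = "geneA", TS = "geneS"))
  h <- mk_hits(mk_hit("p:1", "T1", "strong", t_start = 976),
               mk_hit("p:2", "T1", "strong", t_start = 101),
               mk_hit("p:3", "TS", "strong", t_start = 1))
  expect_equal(processivity_requirement(h, db), c(25, 900, 25))
})

test_that("robustness is the survival probability of the median requirement", {
  db <- mk_db(lengths = c(T1 = 1000L), genes = c(T1 = "geneA"))
  ids <- paste0("p:", 1:4)
  # requirements 100, 200, 300, 400 -> even-count median 250
  h <- mk_hits(do.call(rbind, Map(function(p, st) mk_hit(p, "T1", "strong",
                                                         t_start = st),
                                  ids, c(901, 801, 701, 601))))
  r <- robustness_score(ids, "geneA", h, db, p = 1 / 600)
  expect_equal(r$N, 250)
  expect_equal(r$S_r, (1 - 1 / 600)^250, tolerance = 1e-12)
  # moderate hits contribute nothing
  r2 <- robustness_score(ids, "geneA", mk_hits(mk_hit("p:1", "T1", "moderate")),
                         db)
  expect_true(is.na(r2$N))
  expect_equal(r2$S_r, 0)
  # closed form sanity
  expect_equal(robustness_from_requirement(0), 1)
  expect_equal(robustness_from_requirement(268, 1 / 600), 0.6395188,
               tolerance = 1e-6)
})

test_that("overall score is the plain product of the three components", {
  expect_equal(overall_score(10 / 11, 1, 0.64), 0.5818, tolerance = 1e-4)
  expect_equal(round(overall_score(10 / 11, 1, 0.64), 2), 0.58)
  expect_equal(overall_score(0.9, 0, 0.5), 0)
  expect_equal(overall_score(1, 1, 1), 1)
  expect_error(overall_score(1.2, 1, 1))
})

test_that("score_probeset composes the components and holds its invariants", {
  fx <- generate_fixture(fixture_spec(seed = 3))
  hits <- search_all(fx$probes, fx$db)
  sc <- score_probesets(fx$probes, hits, fx$db)
  expect_equal(sc$overall, sc$specificity * sc$coverage * sc$robustness)
  expect_true(all(sc$overall <= pmin(sc$specificity, sc$coverage,
                                     sc$robustness) + 1e-12))
  none <- sc[is.na(sc$targeted_gene), ]
  expect_true(all(none[c("specificity", "coverage", "robustness",
                         "overall")] == 0))
  expect_true(all(sc[c("specificity", "coverage", "robustness",
                       "overall")] >= 0 &
                    sc[c("specificity", "coverage", "robustness",
                         "overall")] <= 1))
})

test_that("a probe set with no hits at all scores zero with no target", {
  db <- mk_db()
  pt <- suppressWarnings(probe_table("PS9", paste0("PS9:", 1:3),
                                     replicate(3, rand_dna(25))))
  empty <- search_all(pt, db)[0, ]
  class(empty) <- c("alignment_hits", "data.frame")
  row <- score_probeset(pt, empty, db)
  expect_true(is.na(row$targeted_gene))
  expect_equal(row[["overall"]], 0)
  expect_true(is.na(row$proc_requirement))
})

test_that("scores are invariant to probe and transcript permutations", {
  fx <- generate_fixture(fixture_spec(seed = 4))
  hits <- search_all(fx$probes, fx$db)
  base <- score_probesets(fx$probes, hits, fx$db)
  set.seed(99)
  perm_probes <- do.call(rbind, lapply(probe_sets(fx$probes), function(g)
    g[sample(nrow(g)), ]))
  perm_probes <- probe_table(perm_probes$probeset_id, perm_probes$probe_id,
                             perm_probes$sequence)
  perm_tx <- sample(length(fx$db$seq))
  db2 <- transcript_db(fx$db$seq[perm_tx], fx$db$gene[perm_tx])
  sc2 <- score_probesets(perm_probes, search_all(perm_probes, db2), db2)
  sc2 <- sc2[match(base$probeset_id, sc2$probeset_id), ]
  rownames(sc2) <- NULL
  expect_equal(sc2, base)
})

test_that("robustness falls monotonically with distance and with p", {
  N <- c(0, 25, 268, 1000, 3012)
  s600 <- robustness_from_requirement(N, 1 / 600)
  s300 <- robustness_from_requirement(N, 1 / 300)
  expect_true(all(diff(s600) < 0))
  expect_true(all(s300[-1] < s600[-1]))
  expect_equal(s600[1], 1)
  # ~3000 bases from the 3' end robustness collapses to ~0.007
  expect_lt(robustness_from_requirement(3012, 1 / 600), 0.01)
})
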