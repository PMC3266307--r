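---
title: "Scoring and selecting microarray probe sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and selecting microarray probe sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probemap)
```

## The problem

On Affymetrix-style expression arrays a gene is often interrogated by
several probe sets, and their measurements can disagree or even
contradict each other. Analyses that need *the* expression level of a
named gene — a receptor status marker, the members of a published
signature — therefore need a defensible rule for choosing one probe set
per gene. probemap scores every probe set on three biologically
motivated axes and selects, for each gene, the probe set with the best
combined score, producing a one-to-one gene → probe-set mapping.

## The model

All scoring starts from ungapped local alignments of each 25-base probe
against a transcriptome of cDNA sequences with known gene assignments.

**Alignment tiers.** Alignments are scored +1 per matching base and −3
per mismatch, without gaps, and converted to bits with the standard
Karlin–Altschul normalization $B = (\lambda R - \ln K)/\ln 2$ using
$\lambda = 1.374$, $K = 0.711$ (the ungapped +1/−3 parameters for
uniform base composition). An alignment is *strong* at ≥ 48 bits, which
under this calibration means at least 24 identical bases of a 25-mer —
the probe almost certainly detects the target. It is *moderate* in
[32, 48) bits (an uninterrupted match of 16–23 bases; the probe may or
may not respond) and *weak* below 32 bits. $\lambda$ must carry three
decimals: at 1.37 a perfect 24-base match scores 47.9 bits and the
strong boundary no longer corresponds to 24 identical bases.

**Specificity $S_s$.** A probe *specifically detects* a gene if it has
a strong alignment to at least one of the gene's transcripts and no
strong or moderate alignment to a transcript of any other gene
(moderate self-hits to other isoforms of the same gene are harmless).
The *targeted gene* of a probe set is the gene specifically detected by
the most probes, and $S_s$ is the fraction of the set's probes specific
to it.

**Coverage $S_c$.** A transcript is *detected* by a probe set if a
strict majority of the probes align strongly to it; $S_c$ is the
fraction of the targeted gene's transcripts (splice isoforms) detected,
deliberately ignoring isoform abundance.

**Robustness $S_r$.** Labeled target is synthesized from the poly-A
(3') end, so a probe whose site lies $N$ bases from the 3' terminus
requires $N$ uninterrupted synthesis steps. With a per-base
interruption probability $p$,
$$S_r = (1 - p)^N,$$
where $N$ is the median, over all strong alignments between the set's
probes and the targeted gene's transcripts, of the per-alignment
requirement (transcript length − alignment start + 1). The default
$p = 1/600$ matches the manufacturer's design criterion of placing
probes within 600 bases of the 3' end; X3P-like designs use $1/300$
(`platform_p()`). In degraded clinical material $p$ is larger, which is
why $S_r$ matters: at $p = 1/600$, a probe set 3000 bases from the 3'
end keeps only $S_r \approx 0.007$.

**Overall score and selection.** $S_o = S_s \, S_c \, S_r$, and each
gene is represented by its highest-$S_o$ probe set. No absolute cutoff
is applied: a gene whose best probe set scores 0 is still mapped, with
the score exposed so users can filter.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| match / mismatch | +1 / −3 | raw score | ungapped alignment scoring |
| $\lambda$, $K$ | 1.374, 0.711 | nats per raw unit, — | bit-score calibration |
| word size | 8 | bases | exact-seed length; guarantees every alignment with ≥ 8 consecutive matches is examined, so no moderate-or-better hit (raw ≥ 16) can be missed |
| strong / moderate thresholds | 48 / 32 | bits | tier boundaries (≙ 24 and 16 identical bases) |
| $p$ | 1/600 (1/300 X3P) | per base | interruption probability in $S_r$ |

## Numerical and design choices

* **Both strands are searched.** Probe files differ in whether probes
  are given in sense or antisense orientation relative to the cDNA;
  accepting either strand (and recording it) makes the tool robust to
  both conventions.
* **Seed gating.** A strand contributes a hit only if probe and
  transcript share an exact 8-mer on that strand; the reported hit is
  then the global maximum-score ungapped block. With no seed on either
  strand no hit is reported.
* **Tie-breaks are deterministic everywhere.** Equal-scoring alignments
  resolve to the smallest transcript coordinate, then the plus strand.
  A targeted-gene tie resolves to the lexicographically smallest gene
  id and is flagged `ambiguous_target`. A selection tie on $S_o$ falls
  through higher $S_r$, higher $S_s$, then smallest probe-set id, and
  is flagged `tie_broken`. Identical inputs always give byte-identical
  outputs.
* **"Majority" is strict** (> n/2): an 11-probe set needs ≥ 6 strong
  probes to detect a transcript.
* **The median for $N$ is taken over alignments** (probe × transcript
  pairs), not over per-probe summaries, and an even count yields the
  usual half-integral median, used as-is as a real exponent — an
  arbitrary rounding rule would change $S_r$ by less at stake than it
  introduces.
* **The 3' distance is inclusive** of the aligned block
  ($N = L - t_{start} + 1$): it equals the length of labeled target
  that must be synthesized to cover the probe site. The inclusive
  versus exclusive reading changes $S_r$ by under 0.2%.
* **Transcripts without a gene assignment are dropped** at load time
  (with a count). Treating them as an anonymous "other gene" would
  silently destroy specificity scores for every probe that happens to
  hit an unannotated accession.
* **Precomputed hits.** Users who already ran BLASTN can ingest
  12-column tabular output instead of running the internal aligner;
  only the maximum bit score per probe–transcript pair is kept, and
  tiers come from the file's bit scores. Raw scores are unavailable in
  that format and are reported as `NA`.

## The synthetic fixture generator

`generate_fixture()` emulates the input universe — RefSeq-style cDNA
with isoforms sharing a 3' block, Affymetrix-style 11-probe sets tiled
at 7-base steps — with five planted archetypes (fully specific 3'
probe sets, cross-hybridizers, isoform-partial sets, 5'-shifted sets,
and orphans), and returns expected scores computed *analytically from
the construction geometry*, never by running the scoring code:

```{r example}
fx <- generate_fixture(fixture_spec(seed = 7))
fx$expected[, c("probeset_id", "specificity", "coverage", "robustness")]
```

Two constructions keep the expectations exact rather than approximate.
First, planted probes are rejection-sampled so none of their 16-mers
(either strand) occurs in another gene's transcripts; since a moderate
alignment needs a raw score of 16 within a 25-base window, accidental
cross-gene hits of moderate or strong tier are essentially impossible.
Second, the block copied into another gene to create deliberate
cross-hybridization is flanked by eight guard bases forced to mismatch
its source diagonal, so its alignment score equals the planted overlap
exactly — chance extension can never promote a planted moderate hit
into the strong tier.

What the generator does *not* emulate: realistic base composition and
repeat structure, hybridization thermodynamics (tiers stand in for
affinity), isoform abundance, sequencing or annotation error, and the
scale of a real platform (tens of probe sets versus tens of thousands).
Passing the planted-truth tests therefore demonstrates that the scoring
machinery implements its definitions exactly; it does not validate the
biological accuracy of any particular score on real arrays.

## Verification strategy and problem sizes

The test suite checks the aligner against two independent oracles: a
literal exhaustive scan over every ungapped offset and every contiguous
sub-block (40 instances up to 300 bases), and Smith–Waterman local
alignment with prohibitive gap penalties via Biostrings (1000 random
instances up to 2 kb), both in exact agreement. The calibration
invariants (24 ↔ strong, 16 ↔ moderate) are asserted directly, the
planted-fixture expectations are required to match pipeline output to
1e−9 across the five archetypes for 20 seeds, and every reader/writer
pair round-trips byte-identically. These sizes make the whole suite run
in about two minutes on one core while still exercising every boundary
the method defines.

## Limitations

* Scores describe probe placement against a supplied transcriptome;
  they are only as current as that transcriptome and the
  transcript → gene table.
* $p$ is a single platform-wide constant, though real specimens vary;
  the robustness ranking between probe sets is unaffected, but absolute
  $S_r$ values should not be over-interpreted.
* Gapped alignments and composition-adjusted statistics are out of
  scope; at 25-mer scale and these thresholds a gapped block cannot
  outscore the ungapped optimum by enough to change a tier.
* The selection never applies a quality cutoff; downstream users should
  inspect `overall_score` (and the `ambiguous_target` / `tie_broken`
  flags) before trusting a mapping for a critical gene.
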