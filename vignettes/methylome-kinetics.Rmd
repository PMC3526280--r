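---
title: "Determining bacterial methylomes from sequencing kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining bacterial methylomes from sequencing kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacterial genomes carry N6-methyladenine (m6A) and N4-methylcytosine (m4C)
marks laid down by the methyltransferases (MTases) of restriction-modification
(RM) systems. During single-molecule real-time sequencing, the polymerase
hesitates opposite a modified template base, lengthening the interpulse
duration (IPD). Summarising the IPDs aligned to each genomic position and
strand therefore exposes the methylome: which positions are modified, what
degenerate recognition sequences the active MTases target, how completely
each recognition site is methylated genome-wide, and — from the structure of
the sites — what type of RM system is responsible.

`methylmotif` implements that entire analysis: a Phred-scaled t-test kinetic
score per position and strand, discovery of contiguous, degenerate and
bipartite IUPAC motifs from the top-scoring hits, threshold selection by the
unassigned-hit-fraction rule, per-motif extent-of-methylation summaries,
complementary-strand motif pairing and RM-type classification. Because real
kinetics data are large and instrument-bound, the package also ships a
seeded generator of synthetic genomes and kinetics that emulates the
methylome complements of six well-characterized bacteria, so every stage is
testable at desk scale.

## The kinetic score

For each position and strand we observe the per-position summaries
$(n, \bar{x}, s)$ — read count, mean and SD of log-IPD. Against a
sequence-context reference mean $\mu_c$ (below), the score is a one-sided
one-sample t statistic

$$ t = \frac{\bar{x} - \mu_c}{s / \sqrt{n}},\qquad
   p = P(T_{n-1} > t), \qquad \mathrm{score} = -10\log_{10} p , $$

capped at 1000 because $p$ underflows double precision at strong m6A
signals. Reference uncertainty is ignored: $\mu_c$ is estimated from
thousands of positions per context, so its standard error is negligible
against $s/\sqrt{n}$. Scores are computed only at A and C positions by
default — the chemistries of interest modify those bases — and a position
needs `min_coverage` (default 10) reads on its strand. The score floor of
20 (p = 0.01) is deliberately permissive; the reporting threshold is chosen
later from the data.

The context reference ("in-silico kinetic reference") is trained by
`build_context_model()` on kinetics of unmethylated DNA: the mean log-IPD
per centered k-mer on the read strand, k = 3 by default. A 3-mer is small
enough to estimate well from a 200 kb control and captures the simulator's
context structure exactly; unseen contexts fall back to the global mean.
With real data, a whole-genome-amplified control or a vendor context table
plays this role.

## Motif discovery

The top 1000 hits (by score) are converted to 41-mer windows read 5'→3' on
the called strand, so the methylated base is always the center character.
Discovery then iterates:

1. **Seed enumeration.** Every contiguous 4–8-mer covering the center, at
   every offset, plus every spaced dyad — half-sites of 2–5 nt separated by
   a 4–9 nt nonspecific spacer, center inside a half-site — that actually
   occurs in the windows. The dyad spacer range is a superset of the 5–8 nt
   typical of Type I sites so that a 2 nt half-site adjacent to the spacer
   remains reachable.
2. **Seed scoring.** Each seed's window count is scored by the upper-tail
   binomial probability under a null where non-center columns follow the
   genome's mononucleotide composition and the center column follows the
   empirical center-base distribution of the windows (windows are centered
   on called A/C by construction; an unconditional background would inflate
   every center-covering seed about four-fold). Seeds must explain at least
   `min_support = 20` windows, be at least `enrich_floor = 10`-fold
   enriched, and pass p < 0.01 Bonferroni-corrected over all enumerated
   seeds.
3. **Refinement.** The best seed is refined by three moves, tried in
   priority order until none applies:
   - *extension*: absorb a flanking column whose composition among
     supporting windows is covered ≥ 90% by a 1–2-base IUPAC code, or —
     when the column is a mixture — a single base that is both ≥ 40%
     frequent and at least twice its background frequency. The latter
     "split" move is what separates the two strand-specific motifs of an
     asymmetric double-strand site (GG**A**TC / G**A**TCC share their
     GATC core);
   - *tighten*: specialize an informative interior spacer column of a dyad
     (a coarse dyad seed can win with part of a half-site hidden in its
     N-run); 3-base codes require 97% coverage because a random spacer
     column can reach 90% by sampling noise but a genuine 3-base column
     excludes its fourth base almost entirely;
   - *generalization*: widen one position by one base, accepted while it
     explains ≥ 5% new windows, keeps 10-fold enrichment, and the added
     base is at least ~background-frequent in that column once the
     position is freed — the evidence gate that recovers R/Y/H/K/D codes
     while refusing moves that would merely fuse unrelated window families
     sharing a core.
4. **Mask and repeat.** The refined candidate is emitted with the center
   position as its methylated offset (A → m6A, C → m4C), its windows are
   removed, and the search restarts until no seed passes.

Extension precedes generalization deliberately: families sharing a short
core (RA**A**TTY, GKA**A**YG and TA**A**Y-type sites all contain AA at the
center) must be specialized into full-length motifs before any widening
could merge them. Ties between equally scoring seeds break
lexicographically. Both strand motifs of an asymmetric double-strand
specificity are emitted separately — kinetic signals are strand-resolved —
and collapsed only by `pair_motifs()`.

m5C is *not* called genome-wide: its kinetic signal is weak and diffuse,
and the pipeline mirrors that reality — the simulator's m5C specificities
exist purely as a nuisance term to exercise robustness.

## Threshold, extent, and RM types

`assign_hits()` maps every detected position to the first motif whose
pattern matches there with its methylated offset. `select_threshold()` then
picks the minimal score cut — the largest retained hit set — whose
unassigned fraction is ≤ 1% (read as an inequality: exact equality is
unattainable on discrete scores). For m4C-dominated methylomes the target
is 5%, because the weaker m4C population sits closer to the noise floor; in
the pipeline this is keyed to the `bce` fixture by default and settable per
run. An unattainable target yields an `Inf` sentinel and a warning rather
than an abort.

`methylation_extent()` reports, per motif, detected/total genomic
positions. Denominators are per-strand methylatable positions (both strands
of a palindromic site count as two), which matches strand-resolved calling;
duplex placement counts are also emitted since published totals do not
always state their convention.

`pair_motifs()` groups two motifs when one's pattern is the reverse
complement of the other's — they then describe the same duplex placements,
each methylating its own strand — and marks self-reverse-complementary
patterns (RG**A**TCY) as double-strand on their own. `classify_rm_type()`
applies the structural heuristics: bipartite + double-strand → Type I;
contiguous + double-strand → Type II; contiguous + single-strand →
Type III or IIG; bipartite + single-strand is flagged unclassified. These
are heuristics: a Type IIG enzyme that methylates both strands of a spaced
site (the GAGN5GT case) is labelled Type I by structure. The residual
check — rerunning discovery on the unassigned, above-threshold windows —
closes the loop; a clean run returns nothing.

## The synthetic-data generator

`simulate_kinetics()` draws, per position and strand, a Poisson read count
(mean 60 per strand, enough for near-complete genome-wide detection) and
the exact sufficient statistics of n log-IPDs from
$\mathcal{N}(\mu_c + \delta, \sigma)$: the sample mean as
$\mathcal{N}(\mu_c+\delta, \sigma/\sqrt{n})$ and the sample SD from the
scaled chi-square law, so no per-read data is ever materialized. Log-IPDs
are modelled normally in log space (IPDs are heavy-tailed and positive),
which also makes the t-test well calibrated on the null — a property the
test suite checks directly at p = 0.01 and 0.001.

Signal shifts are $\delta_{m6A} = \ln 4$, $\delta_{m4C} = \ln 2$,
$\delta_{m5C} = \ln 1.2$ with $\sigma = 0.6$, reproducing the qualitative
ordering of the three marks (strong m6A, weaker m4C, weak m5C); m5C
additionally leaks half its shift into the two neighbouring positions
(diffuse signal). No quantitative effect sizes are published for these
shifts; they are configuration, not constants. The per-context baseline
$\mu_c$ (3-mer, SD 0.3 around zero) is drawn from a dedicated
`context_seed` that is a property of the *configuration*, not the run: a
sample and its unmethylated control share the same chemistry.

Fixtures (`make_fixture()`) plant the motif complements of the six emulated
organisms on a 200 kb random genome. Two generator decisions deserve
explanation:

- **Both strands of asymmetric double-strand sites are planted
  explicitly** (e.g. CCACN6CTC *and* GAGN6GTGG), since Type I MTases
  methylate one adenine per strand; hemimethylating specificities (Type
  III-like TCC**A**GG, the Type IIG sites) are planted on their single
  strand only.
- **Site-count spiking.** A 200 kb i.i.d. genome contains only ~10–25
  chance occurrences of a long bipartite site, an order of magnitude fewer
  per genome than the multi-Mb organisms being emulated. Each planted
  duplex family is therefore topped up to at least 150 occurrences by
  writing concrete instances (degenerate and spacer positions drawn
  uniformly) into random non-overlapping slots before the truth set is
  scanned. This keeps discovery support well above `min_support` at desk
  scale while leaving flanks and spacers random.

What the simulation does *not* emulate: per-read IPD traces and alignment
artifacts, polymerase pausing and DNA damage, context-dependent SD,
phosphorothioate backbone signals, and real genomic sequence composition
(the background is i.i.d.; the discovery background model is order-0 for
the same reason, and configurable in principle). Passing tests on fixtures
therefore demonstrate the statistical machinery, not performance on real
instrument data, where context models are richer and noise is not i.i.d.

The C. salexigens-like fixture plants RG**A**TCY at fraction 0.9 —
methylation of that site is known to be incomplete in vivo — and the
B. cereus-like fixture carries its two m5C specificities at full fraction
but with the weak m5C shift, where they surface only as unassigned noise
near the threshold, which is exactly why that methylome uses the 5% target.

## Numerical and interface choices

- Coordinates are 1-based on both strands everywhere in R structures and
  text outputs (the R/Bioconductor idiom); only BED output is 0-based
  half-open. A site's strand is the strand of the methylated base; patterns
  are always written 5'→3' on that strand. Motif offsets are 1-based
  indices into the pattern.
- All overlapping motif occurrences are reported; circular contigs wrap
  across the origin (fixtures are linear).
- Every stochastic stage consumes a child seed derived from the single
  user-facing seed, and runs never touch the caller's RNG state; identical
  configuration and seed reproduce artifacts byte-for-byte, which the
  manifest-replay test asserts literally.
- Binomial tail probabilities are computed in log space throughout;
  p-underflow is handled by the score cap, not by clamping inputs.
- Ties: equally scoring detection records order by (contig, position,
  strand); equally scoring seeds break lexicographically by pattern.

Problem sizes used by the test suite and the acceptance script — 200 kb
fixture genomes at 60× per-strand coverage, 1000-hit discovery input,
20 null-discovery trials of 300 windows, calibration on ~60 k null
positions — were chosen so the full analysis of one fixture completes in
about a minute while keeping every planted family's discovery support
comfortably above threshold.

## Known limitations

- Discovery assumes exactly one methylated position per window center;
  specificities methylating multiple offsets of one site would be reported
  as separate motifs.
- Near-nonspecific rules (one- or two-base "motifs" of promiscuous
  MTases) are below the support/enrichment design envelope on purpose.
- The RM-type caller is structural only; it cannot distinguish Type III
  from single-strand Type IIG, and mislabels double-strand bipartite
  Type IIG systems as Type I.
- Interior spacer tightening trusts supporter composition; after several
  mask-and-repeat rounds that composition can in principle be biased by
  earlier masking. The stricter 3-base-code bar mitigates, but does not
  eliminate, this.
- The order-0 background is right for the i.i.d. simulator but too simple
  for real genomes with strong composition bias; a higher-order background
  would be the first change for real-data use.
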