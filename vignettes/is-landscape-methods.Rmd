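---
title: "Methods: insertion-sequence landscape analysis with iscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insertion-sequence landscape analysis with iscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscape)
```

`iscape` implements a complete desk-scale pipeline for studying the
landscape of insertion sequences (ISs) in prokaryotic genomes: where ISs
sit, how they are oriented relative to their gene neighbors, where they
pile up, and which IS–gene adjacencies are conserved across taxa. This
vignette documents the model and its assumptions, every tunable parameter,
what the synthetic corpus generator does and does not emulate, and the
numerical choices made where the method left room for interpretation.

## Coordinate model and data containers

All intervals are 0-based half-open `[start, end)` internally; GFF3
(1-based inclusive) and BED (0-based half-open) are converted at the I/O
boundary only. Annotations live in a `genome_set`: a `replicons` table
(assembly, replicon, chromosome/plasmid, length) and a `genes` table. A
"genome" is the set of replicons sharing an assembly identifier; per-genome
statistics aggregate over replicons. Taxonomy is a seven-rank lineage per
assembly; because proteobacterial classes are as deep and populous as
typical phyla, classes under the phylum Proteobacteria are promoted to
phylum rank at load time (switchable via `promote_proteobacteria`).

## IS occurrence calling

Detection consumes normalized alignment hits (BLAST outfmt 6; nucleotide
and translated hits are pooled before filtering, and minus-orientation
subject coordinates are flipped at read time). Three steps, each a pure
function:

1. **80:80 filter** (`filter_hits`): keep hits with alignment length
   ≥ `min_len` (80 bp) and identity ≥ `min_identity` (80%). Both
   boundaries are inclusive — the conventional reading of the 80:80 rule —
   and both are parameters, so a strict `> 80 bp` variant is one argument
   away.
2. **Best-hit selection** (`resolve_overlaps`): several library members
   typically align over the same genomic region; "same region" is made
   precise as the transitive closure of pairwise ≥ 1 bp overlap, and within
   each overlap-connected component only the smallest-E-value hit survives.
   E-value ties are broken by longer alignment, then higher identity, then
   lexicographic member name — an arbitrary but deterministic order that
   makes reruns byte-identical.
3. **Merging** (`merge_occurrences`): adjacent surviving hits of the same
   family separated by a gap strictly below `merge_gap` (80 bp) are unioned
   into one occurrence, modelling fragmented or interrupted elements; a gap
   of exactly 80 bp stays split. Merging only joins hits that are
   consecutive in genomic order, so a merged interval can never swallow an
   interleaved occurrence of another family, preserving the per-replicon
   non-overlap invariant. Gap between `[a,b)` and `[c,d)` with `b ≤ c` is
   `c − b`.

Occurrences shorter than `min_size` (80 bp) are dropped. Subfamily labels
are ignored and occurrence strand is not modelled: the downstream
orientation analysis uses only gene strands.

## IG couples, shapes and function statistics

Each IS is paired with the nearest coding gene entirely to its left (−1),
entirely to its right (+1), and any overlapping gene (0, distance 0);
non-coding features are ignored throughout. Distance is the gap between the
nearest interval boundaries — the method never defined it more precisely,
and this is the natural reading of an IS–gene distance. The shape of an IS
is determined solely by the strands of its −1/+1 genes read left to right:
`SPS` (+,+), `SNS` (−,−), `OC` (+,−), `OD` (−,+). The overlapped gene never
contributes to shape, and an IS that overlaps a gene is still counted once
in shape statistics.

Shape counts per family are compared to the uniform 25% expectation with a
3-df χ² test; at p < `alpha` (0.01) a shape is called over- or
under-represented only if it also departs ≥ 10% from expectation (`margin`)
— the 10% rule guards against statistically significant but negligible
biases at large n. Units with fewer than `min_is` (10) shaped ISs are
`not_tested`; the ≥ 10 gate is stated at genome level by the method and is
applied here to any tested unit, since χ² expectations below ~2.5 per cell
are unreliable.

Gene-function (IGF) statistics normalize product strings (uppercase,
collapsed whitespace; a strict byte-identical mode exists via
`strict_names`) and gate functions at `gate_frac` (0.01%) of all coding
genes — recomputed from the corpus at hand rather than hard-coding the
count that 0.01% happens to be in any particular corpus. For family *f*
and function *g*, the expected couple count is the family's gated couple
total times the corpus frequency of *g* among gated functions, so expected
counts sum to observed totals per family; each cell gets a 1-df χ² with the
same α and 10% rule. Raw p-values are used, matching the method's choice of
no multiple-testing correction, but a Benjamini–Hochberg column is emitted
for users who want one. "Hypothetical protein" is reported by default and
excludable by flag.

## Hotspots

A hotspot is a maximal run of ≥ `min_run` (3) consecutive ISs — any family
mix — where each adjacent gap is smaller than the summed lengths of its two
flanking ISs and no coding gene overlaps the gap. Genes overlapping the ISs
themselves do not break a chain; replicons are treated as linear (no
wrap-around), a simplification that can only split a hotspot spanning the
origin.

Hotspot reporting is screened per replicon by a Wilcoxon–Mann–Whitney test
(`require_nonuniform`, default on): observed adjacent spacings versus
spacings pooled from `n_mc` (100) seeded uniform placements of the same IS
count on the same replicon, applied only when the replicon carries ≥ 10
ISs. The construction of this test was left open by the method; two choices
here deserve note. First, the comparison population is Monte-Carlo rather
than analytic, keeping the test exact for any n; a positions-versus-uniform-
quantiles variant is available (`method = "quantile"`). Second, the
alternative is one-sided toward *small* spacings: the non-uniformity that
matters for hotspot screening is clustering, and a two-sided location test
would also flag perfectly even spacing — which is the opposite of
clustered. Detection itself is independent of the screen, so both gated and
ungated hotspot lists are obtainable.

## Syntenic IS–gene sets

The synteny analysis restricts to `OD` (`←IS→`) records — the
configuration in which the IS can serve as a promoter for both neighbors —
though other shapes can be admitted (`shapes`). Two records are presIG
partners iff (i) same IS family, (ii) at least two of the four flanking
genes form homologous cross-genome pairs with each gene used at most once
(so a single promiscuous gene cannot satisfy the rule; pairs may cross
sides unless `strict_sides`), and (iii) the records come from distinct
strains. The method's wording for (iii) — distinct clades or species —
would make same-species links impossible and thereby abolish the
species-level category it also defines; distinct strains is the reading
consistent with that category. Homology is E ≤ `sig_threshold` (1e-50,
boundary-inclusive), consumed from a gene-vs-gene hit table; missing
homology data counts as non-homologous.

sIG sets are connected components of the presIG relation. Category follows
the taxonomic span in priority order: ≥ 2 phyla → `phylum`; else ≥ 2
species → `class_to_genus`; else ≥ 2 strains → `species`; singletons are
`unique` IGs. `threshold_sweep` reclassifies across an E-value grid —
relaxing the threshold only adds edges, so the unique count is monotone
non-increasing, and the crossing region of the phylum/species/unique curves
motivates the 1e-50 operating point.

## Phylum networks and reservoirs

Per family, each phylum sIG set increments the edge weight of every
unordered pair of phyla it spans (a set across k phyla feeds all C(k,2)
edges; a single-increment mode exists for users who prefer set-as-one-link
semantics). Degree counts partner phyla, strength sums incident weights,
and Σ strengths = 2 Σ weights by the handshake identity — asserted on every
generated graph. Reservoir ranking divides each phylum's IS count by its
number of IS-containing genomes, with alphabetical tie-breaks for
stability.

## Motif overlap

Motifs (TFBS, promoter, terminator, riboswitch; experimental or predicted)
count for an IS when the intervals share ≥ 1 bp, strand-agnostically — IS
occurrences carry no strand, and regulatory elements within an element act
in either orientation. A full-containment mode (`contained_only`) and a
strand pre-filter (`strands`) cover the stricter variants. Summaries report
the fraction of ISs with ≥ 1 motif and the mean motifs per motif-containing
IS (undefined and reported as `NA` when no IS contains a motif).

## Family-by-clade distribution

For each family and clade the pipeline tabulates genomes-with-family,
clade size, their ratio (the heatmap fraction), and the count expected if
family-containing genomes were spread uniformly. The flagging test is
specified only as "Student's t"; the construction used here is a per-clade
Welch two-sample t of per-genome presence/absence (clade versus all other
genomes) with Bonferroni correction over clades, flagging the family at
p < 0.01. A one-sample t across clade-level residuals is not viable:
residuals sum to zero by construction, and outlier-driven alternatives
(squared or absolute residuals) lose essentially all power at the 4–30
clades typical of these corpora.

## The synthetic corpus generator

`simulate_corpus()` builds corpora by assembling each replicon left to
right from gene and IS "units", so every planted feature has a known
coordinate, flank configuration, and expected detection outcome. Defaults
define the standard study conditions: 4 phyla × 3 species × 3 strains
(36 genomes), chromosomes of 1–5 Mb (a quarter of genomes also carry a
30–300 kb plasmid with ~3× the per-bp IS density), genes of mean 900 bp
with ~150 bp intergenic gaps and ~3% non-coding features, a function
vocabulary with Zipf-like weights in which "hypothetical protein" takes
~20–25% of genes (mirroring the unannotated fraction of real corpora), an
8-family IS library with member lengths 300–3000 bp and mode near 1.2 kb,
Poisson(12) background ISs per chromosome with equiprobable shapes,
fragmentation of 15% of eligible ISs with gaps of 20–140 bp straddling the
80 bp merge threshold, decoy hits violating 80:80 (short, or 60–79.4%
identity), 30% extra lower-scoring same-family hits to exercise best-hit
resolution, 3 planted hotspots of 3–5 ISs with 90–450 bp gene-free gaps,
3 syntenic blocks each at phylum / class-to-genus / species level with
flank-gene homology at E = 1e-120…1e-60 (well below the 1e-50 threshold,
plus above-threshold noise pairs among ordinary genes), and a 0.4 motif
rate on `OD` ISs with 1–3 motifs of 8–40 bp each.

E-values of generated hits are a deterministic, monotone function of
alignment length × identity, so best-hit resolution is reproducible;
identical seed and configuration yield byte-identical corpora and pipeline
outputs. The ground-truth record carries expected occurrence intervals
(including merge expectations and never-called decoys), shapes, hotspots,
sIG memberships with intended categories, and per-occurrence motif counts.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: sequence-level evolution (hits are emitted directly,
not aligned), annotation errors and coordinate noise, operon structure,
compositional biases in insertion-site preference, incomplete or
contaminated assemblies, and homology detected through anything other than
the planted block relations. Tests against this truth validate the *rules*
of the pipeline exactly; they do not validate an aligner or an annotation
workflow.

## Problem sizes used in tests and the acceptance script

Replicated checks (50-corpus hotspot recovery, module unit tests) run on
reduced corpora — 6–24 genomes with 0.15–0.4 Mb replicons — chosen so that
each corpus still contains every planted feature class while a full
replicate set completes in seconds; single-corpus checks (sIG category
recovery, the worked example) use the default 36-genome, 1–5 Mb
configuration. The Wilcoxon gate calibration uses 100 clustered and 100
uniform placements of 100 ISs on 5 Mb with 100 Monte-Carlo draws each; the
χ² calibration uses 1000 balanced multinomial replicates of n = 1000 and
200 skewed (70/10/10/10) replicates.

## Known limitations

Circular replicons are linearized; hotspots spanning the origin are split.
The clade-distribution t-test construction is one defensible choice among
several the method's description admits. Merging is strictly sequential in
genomic order, so a fragmented element interleaved with another family's
occurrence stays split. Function-name normalization collapses case and
whitespace but not synonyms ("glycosyl transferase" vs
"glycosyltransferase" remain distinct, as in the original analysis).
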