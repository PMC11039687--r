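---
title: "Annotating and comparing epidermal differentiation complex gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and comparing epidermal differentiation complex gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcscan)
```

## The problem

The epidermal differentiation complex (EDC) is a conserved mammalian gene
cluster, flanked by S100A genes, that encodes the protein components of the
cornified envelope. Comparative questions about it — which genes a lineage
has retained, amplified or pseudogenized — reduce to a recurring set of
computations on genome assemblies:

1. locate the cluster between its anchor genes by translated homology
   search with reference proteins as queries;
2. rebuild exon/CDS models for each hit, guided by an intact ortholog;
3. classify gene architecture — single-coding-exon EDC genes (SEDC: one
   non-coding plus one coding exon, e.g. loricrin, SPRRs, LCEs) versus
   S100 fused-type proteins (SFTP: one non-coding plus two coding exons,
   with an N-terminal S100 domain and a long repetitive tail, e.g.
   filaggrin, trichohyalin);
4. call orthology by reciprocal best hits plus shared local synteny;
5. scan each locus for inactivating lesions — premature stop codons,
   frameshifts, splice-site loss, missing exons — against the intact
   template, and classify the gene as intact, truncated or pseudogenized;
6. profile the predicted proteins (composition bias, internal tandem
   repeats, a conserved C-terminal motif, segment architecture);
7. build gene-family trees and test whether a tandem array is
   monophyletic, i.e. the product of lineage-specific amplification.

`edcscan` implements this pipeline as composable functions plus a
synthetic-cluster generator that provides machine-readable ground truth,
so every stage is testable at desk scale without downloading genomes.

## The synthetic test bed

`generate_cluster()` emulates the structures the pipeline must handle:

```{r}
cfg <- cluster_config(seed = 7, n_sedc = 4, n_sftp = 2, lce_array_size = 4,
                      lesion_rate = 0)
cl <- generate_cluster(cfg)
cl
```

A cluster is one scaffold carrying, between two S100-like anchor genes,
generic SEDC-like genes, SFTP-like genes and an LCE-like tandem array,
with random intergenic spacers (geometric lengths, mean
`intergenic_mean`). Specifics worth knowing:

* **Gene architecture.** SEDC-like genes have one non-coding exon, one
  GT..AG intron and one coding exon. SFTP-like genes have a non-coding
  exon and two coding exons; the synthetic 90-residue S100-like domain
  (an invented sequence, see `s100_consensus()`) occupies the first
  coding exon in full. Real SFTPs split the domain across the junction;
  placing it wholly in the first coding segment keeps the architecture
  rule — "two coding exons whose first segment carries the domain" —
  directly testable, which is the generator's purpose.
* **Repetitive tails.** The SFTP tail is a 9–21-codon unit repeated 8–20
  times with 5% per-copy substitution, with exactly 78% of unit positions
  drawn from a two-letter alphabet (R/E for trichohyalin-like genes, G/S
  for hornerin-like ones). The biased-position count is fixed and
  substitutions are composition-preserving, so the realized tail
  composition stays within a few points of the configured bias — the
  property the composition profiler is tested against. An eight-residue
  placeholder motif (`sftp_cterm_motif()`, invented) is appended to every
  intact SFTP protein so motif scanning has ground truth; the pattern is
  always an explicit argument, never hard-wired biology.
* **Tandem arrays.** `amplify_tandem()` grows an array by iterated
  duplication of a uniformly chosen copy (the genealogy expected from
  unequal crossing over) and then applies per-site substitution to each
  copy. Branch lengths count duplication events, so the true genealogy is
  ultrametric and the copies form a clade relative to any outgroups.
* **Lesions.** With `lesion_rate > 0`, each non-anchor gene independently
  receives one lesion: premature stop (35%), 1–2 bp insertion or deletion
  (20% each), splice-site mutation (15%) or coding-exon deletion (10%,
  SFTPs only). Indel coordinates are recorded left-normalized in gene
  sense space — the same canonicalization VCF uses — because the position
  of an indel inside a repeated context is only defined up to that
  context, and the scanner normalizes identically, which is what makes
  "exact coordinate recovery" a well-posed test.
* **Mutation model.** All divergence operations (array copies, the
  sister species from `sister_cluster()`) are substitution-only and
  frame-safe: the initiator and terminator codons are untouched,
  substitutions that would create an in-frame stop are redrawn, and
  splice dinucleotides are preserved. This keeps "intact" genes truly
  intact, so gene status is exclusively the product of
  `implant_lesion()` and the truth table stays exact. The price is
  realism: no real lineage evolves under a guarantee of coding
  integrity, there are no real indels outside implanted lesions, no
  codon-usage or GC heterogeneity, no transposable elements and no
  assembly gaps. Passing tests therefore demonstrate correctness of the
  machinery under clean conditions, not robustness to every artifact of
  real assemblies.

The `true_status` labels follow the same rule the scanner uses (below),
so status recovery is a genuine end-to-end check of detection, not of
label bookkeeping.

## Translated search

`search_translated()` is a tBLASTn-style search: six-frame translation,
exact four-residue word seeding, x-drop ungapped extension along the
diagonal, then gapped local refinement (BLOSUM62, gap open 11, extend 1,
x-drop 20, minimum score 40 — BLAST-like conventions, recorded in
`search_params()`). Two numerical choices matter:

* an ungapped extension covering ≥90% of the query is already the local
  alignment and is emitted directly; dynamic programming is reserved for
  partial hits, and its window pads the ungapped span by only 40
  residues, because an intron breaks the reading frame — wider windows
  would merely let the DP bridge into a neighbouring exon, which is the
  chainer's job;
* every reported HSP keeps its gapped alignment strings, and
  `hsp_score()` recomputes the score from them, so scores are externally
  verifiable.

Low-complexity masking (`mask_low_complexity()`) is Shannon-entropy based
(window 12, threshold 2.2 bits) and lowercases masked residues, which
blocks seeding but not extension. It is applied only on request: EDC
proteins have strongly biased composition, and a masked search
demonstrably misses a poly-QP query that the unmasked search finds — the
reason comparative EDC work runs with the filter off.

No E-value statistics are computed; within an anchored cluster, raw score
and identity thresholds are sufficient and keep every number exactly
reproducible.

## Locus assembly and gene models

`chain_hsps()` groups HSPs by scaffold and strand and chains them
collinearly in transcription order with genomic gaps ≤ `max_intron`
(default 10 kb), by dynamic programming on summed scores. A member must
contribute at least 15 new query residues: the conserved C-terminal motif
and the shared S100 domain otherwise produce tiny cross-paralog HSPs that
attach to chains and inflate locus spans. Query overlaps up to 30
residues are tolerated because ungapped extensions can leak a few
residues across an intron.

`run_pipeline()` assigns loci to queries one-to-one, iteratively: the
globally best remaining chain is claimed, then unassigned queries
re-chain with HSPs inside claimed regions removed. In tandem arrays and
paralogous families a query's single best hit is often another family
member (e.g. an intact copy outscoring the query's own frameshifted
locus); exclusive claiming resolves this the way reciprocal-best
assignment does.

`build_gene_model()` aligns the intact template gene into the locus
region at the DNA level (template fully aligned, BLASTN-like +1/−2 with
gap open 6), carries exon boundaries through the alignment, and refines
intron boundaries to the nearest GT..AG pair within 30 bp under an
equal-shift rule that preserves intron length and reading frame. A locus
whose splice sites cannot be restored, or whose start codon is absent
within 30 bp, is flagged and classified `other` rather than dropped.

Architecture classification needs a formal stand-in for "has an S100
domain": `s100_profile()` builds a log-odds position profile from the
packaged synthetic consensus (pseudocount 0.05), and the first coding
segment qualifies when its best sliding-window score reaches 60% of the
profile self-score. On 10%-diverged domain instances this margin is wide
(≈0.84 vs 0.6) and random sequence scores far below zero.

## Orthology

Orthology follows the two criteria standard in cluster-level comparative
genomics: reciprocal best hits between protein sets (Smith–Waterman
scores, ties fail the test and are flagged ambiguous) and shared local
synteny — the fraction of the up-to-`2k` flanking gene families of the
query locus (k = 3 per side by default) present among the target locus's
flanks, order-insensitive, threshold 0.5. Neither k nor the threshold has
a canonical published value; both are exposed.

Verdicts: `ortholog` needs RBH plus synteny; a failed RBH with conserved
synteny is `ambiguous` only when the forward best hit scores at least
half the query's self-score (a near-identical tandem copy), otherwise
`none` (the true ortholog is absent and a distant paralog surfaced).
One-to-one orthology inside an array is identifiable only when copies are
more diverged from each other than the two species are; the package's own
tests use 8% copy divergence against a 5% species split for that reason.

## Lesion scanning and status

`detect_disruptions()` aligns the intact template gene into the locus
region at the DNA level and reads lesions off the alignment:

* a target triplet on the **template codon grid** equal to TAA/TAG/TGA
  before the final codon is a premature stop, with its template codon
  index. Stops that appear downstream of a frameshift are out of frame
  relative to the grid and are deliberately not called — they are
  consequences, not mutations;
* an indel run inside a coding exon with length ≢ 0 (mod 3) is a
  frameshift at the left-normalized position (balanced insertions and
  deletions cancel and are ignored);
* a non-GT donor or non-AG acceptor at a template intron boundary is a
  splice loss at the mutated base;
* a coding exon with under 20% of its bases aligned, **or** under 70%
  identity across the exon, is a missing exon; the identity criterion
  exists because a deleted exon sometimes cross-aligns to a paralogous
  neighbour at ~50–60% identity, far below any real divergence in play.
  The junction is taken from the last aligned template base upstream and
  left-normalized like an indel;
* a non-ATG triplet at the template start is a start loss.

The protein-level route (align translated exons, back-map to nucleotides)
was considered and rejected as the primary mechanism: exactly where
lesions occur, translations are dominated by stops and frame changes and
carry less information than the DNA itself. DNA-level alignment also
yields exact coordinates at the divergences involved.

`classify_status()` encodes the working definitions: no lesions is
*intact*; premature stop(s) only, with the first stop at ≥20% of the
template CDS and nothing upstream of it, is *truncated* (the locus still
encodes a shortened protein from an intact start — the situation of a
filaggrin gene that has lost its C-terminal half); anything else with
lesions is a *pseudogene*. The 20% bound and the lesion taxonomy are
config-exposed package conventions — the field uses these labels without
formal criteria. Lesions within a few bases of exon boundaries should be
read cautiously in real data, where sequencing and assembly errors are
possible; the synthetic truth has no such errors.

`measure_orf_runway()` supports the classic "recent pseudogene" argument:
a long stop-free runway downstream of a premature stop indicates the
reading frame was intact until recently. On random sequence the expected
runway is 64/3 ≈ 21 codons; thousands of stop-free codons are
vanishingly unlikely by chance.

## Protein features

`aa_composition()` computes exact residue frequencies (X excluded from
the denominator) and the combined fraction of the two most frequent
residues — the summary under statements like "arginine and glutamate
account for ~50% of trichohyalin". `detect_repeats()` scores
self-similarity at each candidate lag, reports maximal high-identity runs
with a column-majority consensus, resolves overlaps by copies × identity,
and collapses a unit to any divisor length within 2 identity points
(parsimony; a 2u call on a u-repeat is otherwise equally good).
`scan_cterminal_motif()` takes the motif as an explicit pattern argument
with wildcards — the conserved SFTP motif itself is configuration, not
package biology — and enforces a C-terminal window (50 residues).
`segment_architecture()` derives the N-terminal / repeat / C-terminal
organization used to compare KPLCE-like proteins, where an empty terminal
segment is itself a finding.

## Phylogenetics

Tree building is distance-based: p-distances with pairwise deletion,
in-package neighbor joining (Saitou–Nei; Q-matrix ties resolved to the
lowest index pair for determinism; negative branch lengths clamped to
zero and flagged), nonparametric bootstrap by column resampling with
supports attached to the full-data tree's bipartitions, and a monophyly
test on the outgroup-rooted tree. NJ on any additive matrix recovers the
generating topology exactly, which the tests verify on random trees with
`ape::nj` as an independent cross-check. Maximum-likelihood inference is
out of scope by design; at the divergences relevant here (2% within an
array versus ~30% to the nearest paralogs) the monophyly conclusion does
not depend on the inference method, and NJ keeps the whole pipeline
deterministic and dependency-light. `progressive_align()` (center-star
over pairwise global alignments) is internal plumbing for unequal-length
inputs; users with a curated alignment should supply it directly.

## Reported study sizes

The package's acceptance checks run at fixed desk-scale sizes, chosen to
exercise every code path with comfortable statistics: a 30-gene
two-species null cluster (5% divergence, no lesions — expecting perfect
architecture agreement and zero lesion calls), a 50-gene cluster at
lesion rate 0.3 for recovery of implanted lesions by exact kind and
coordinate, ten 20-gene clusters for status recovery, 100 random additive
matrices (5–8 leaves) for NJ, an 8-copy 2%-divergence array with three
30%-diverged paralog outgroups and 100 bootstrap replicates for the
monophyly reproduction, and a 10 kb sequence for exhaustive ORF-runway
verification. `scripts/acceptance.R` recomputes all of these from
scratch under a caller-supplied seed.

## Known limitations

* The generator's clean mutation model (above) means false-positive
  rates measured here do not bound false-positive rates on real
  assemblies with sequencing errors and segmental duplications.
* Lesion coordinates are exact under the acceptance conditions
  (template–target divergence 0 at the lesion scale); under substantial
  divergence, indel placement inside repeats becomes genuinely ambiguous
  and only the left-normalized convention keeps comparisons meaningful.
* Orthology within tandem arrays is reported honestly as `ambiguous`
  when copies tie; no attempt is made to date duplications or resolve
  array history beyond the monophyly test.
* The search has no E-value model; score thresholds are calibrated for
  anchored-cluster scale, not genome-wide screening.
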