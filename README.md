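# edcscan

Comparative annotation of epidermal differentiation complex (EDC) gene
clusters in mammalian genome assemblies — and a synthetic cluster
generator that makes the whole pipeline testable at desk scale.

## The problem

The EDC is a conserved gene cluster (human 1q21.3), flanked by S100A
genes, encoding cornified-envelope proteins. Questions about its
evolution — which genes a lineage kept, amplified in tandem arrays, or
inactivated — come down to a pipeline: translated homology search of
reference proteins against an assembly, template-guided gene-model
reconstruction, architecture classification (single-coding-exon EDC
genes, *SEDC*, versus S100 fused-type proteins, *SFTP*: one non-coding
plus two coding exons with an N-terminal S100 domain and a repetitive
tail), orthology by reciprocal best hits (RBH) plus shared local
synteny, detection of inactivating lesions (premature stop codons,
frameshifts, splice-site loss, missing exons) against intact ortholog
templates, protein composition/repeat/motif profiling, and
neighbor-joining gene-family trees with a monophyly test for tandem
arrays.

`edcscan` implements each stage as an exported function and wires them
together in `run_pipeline()`. A seeded generator (`generate_cluster()`,
`sister_cluster()`, `amplify_tandem()`, `implant_lesion()`) builds
EDC-like scaffolds with machine-readable truth tables, so correctness is
measured against known ground truth rather than eyeballed.

Core quantities, in the field's notation:

* HSP score `S = Σ BLOSUM62(qᵢ, tᵢ) − Σ_gaps (11 + L)`, recomputable
  from every reported alignment via `hsp_score()`.
* Shannon window entropy `H = −Σ p_a log₂ p_a` for low-complexity
  masking (window 12, threshold 2.2 bits, with an explicit off switch —
  EDC proteins are composition-biased and masking suppresses real hits).
* p-distance with pairwise deletion, Saitou–Nei neighbor joining,
  bootstrap support as the percentage of column-resampled replicates
  containing a bipartition.
* Gene status: *intact* (no lesions), *truncated* (premature stop(s)
  only, first stop ≥ 20% into the template CDS), *pseudogene*
  (anything else).

## Worked example

Generate a reference cluster, derive a diverged sister species carrying
a premature stop and a frameshift in one gene, and run the pipeline:

```r
library(edcscan)

ref <- generate_cluster(cluster_config(seed = 7, n_sedc = 4, n_sftp = 2,
                                       lce_array_size = 4, lesion_rate = 0))
tgt <- sister_cluster(ref, divergence = 0.05, seed = 8)
tgt <- implant_lesion(tgt, "SFTP1", "premature_stop", position = 40)
tgt <- implant_lesion(tgt, "SFTP1", "frameshift_del", position = 400)

rep <- run_pipeline(ref, tgt, seed = 1)
rep
#> edc_report
#> edc_annotation: 12 genes (anchor=2, LCE-like=4, SEDC=4, SFTP=2)
#> status: intact=11, pseudogene=1
#> lesion scan: intact=11, pseudogene=1

rep$disruptions[["SFTP1"]]
#> disruption_report SFTP1: status pseudogene, 2 lesion(s), ORF fraction 0.12
#>    gene           kind genomic_pos codon_index detail
#> 1 SFTP1 premature_stop        7647          40    TAG
#> 2 SFTP1     frameshift        8250         134   del2

rep$family_matrix
#>     family target
#> 1 LCE-like    4/0
#> 2     SEDC    4/0
#> 3     SFTP    1/1
```

The scan found exactly the two implanted lesions — the stop at codon 40
(so the remaining open reading frame covers only 12% of the template,
hence *pseudogene*, not *truncated*) — and the family matrix counts the
gene in the pseudogene column (`functional/pseudogene` per cell). All
other genes, including every tandem-array copy, are recovered intact
with their exon coordinates and architecture matching the truth tables.

A monophyly test for a tandem amplification:

```r
founder <- ref$templates[["LCE1"]]$cds
ogs <- setNames(vapply(1:3, function(i) ref$templates[[paste0("SEDC", i)]]$cds, ""),
                paste0("og", 1:3))
amp <- amplify_tandem(founder, 8, 0.02, seed = 9, outgroups = ogs)
bs  <- bootstrap_support(progressive_align(c(amp$copies, ogs), type = "dna"),
                         n_replicates = 100, seed = 10)
is_monophyletic(bs$tree, amp$copy_labels, "og1")
#> [1] TRUE
#> ...
clade_support(bs, amp$copy_labels)
#> [1] 100
```

A thin CLI (`inst/exec/edc-scan`) exposes `simulate`, `search`, `tree`
and `report` subcommands over the same functions.

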