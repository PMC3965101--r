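---
title: "Subsystem-driven prokaryotic genome annotation with prokann"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subsystem-driven prokaryotic genome annotation with prokann}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`prokann` annotates prokaryotic, phage and plasmid genome assemblies against
a reference collection of role-annotated proteins. Its central idea is that
protein function can be assigned by *signature amino-acid 8-mers*: short
peptides that occur (nearly) exclusively in proteins sharing one functional
role. A functional role is a canonical free-text description of a gene
product ("Phenylalanyl-tRNA synthetase alpha chain (EC 6.1.1.20)"), and a
*subsystem* is a curated set of roles implementing one biological process,
optionally with named *variants* — organism-specific subsets of those roles.

The pipeline interleaves three sources of evidence:

1. **Signature k-mers** promote ab initio gene candidates to
   protein-encoding genes and assign their functions.
2. **A trainable coding model** (a 3-periodic Markov chain) is retrained on
   the k-mer-validated calls and used to refine gene starts, iteratively.
3. **Exact protein alignment** against the closest reference genomes
   rescues genes the k-mers missed, backfills long gene-free stretches,
   detects sequencing frameshifts, and re-annotates genes whose
   chromosomal neighborhood is conserved.

Finally the annotated genome is projected onto the subsystem collection
(with variant estimation) and functional coupling between chromosomally
close genes is estimated from pairs of close bidirectional best hits
(PCBBHs) against the reference genomes.

## Stage order

For a prokaryotic submission `annotate()` runs:

1. Enumerate all maximal open reading frames (both strands, six frames,
   minimum 90 nt, stop codon included; every in-frame start is recorded).
2. Estimate the closest reference genomes by summed best-hit alignment
   scores of the candidate translations against each genome's universal
   plus "unduplicated" proteins (at most 200 extra per genome); the top 30
   genomes form the neighbor set.
3. Iterate: scan candidate translations against the signature 8-mer index;
   promote candidates with enough evidence; retain promoted candidates that
   do not significantly overlap an earlier call; retrain the coding model
   on the retained set; re-pick starts. The loop stops when an iteration
   promotes nothing new, or after three iterations.
4. Rescue unpromoted candidates similar to a neighbor proteome; then accept
   any remaining candidate that overlaps nothing.
5. Detect frameshift fragment pairs against neighbor template proteins;
   join them only when the user opts in (proposals are always logged).
6. Backfill: translate gene-free stretches longer than 1500 bp in six
   frames and search them against the neighbor proteomes.
7. Assign functions to still-unannotated genes from their best alignment
   hit; replace the function of genes inside conserved bidirectional
   best-hit (BBH) triples with the neighbor's subsystem role; search gaps
   flanked by subsystem BBHs for genes the neighbor carries in between.
8. Final cleanup: evidence-free features that are embedded, significantly
   overlapping, or shorter than 90 nt are removed.
9. Subsystem projection, variant estimation, PCBBH coupling, export
   (GFF3, GenBank, FASTA, TSV).

Submissions whose contigs sum to less than 100 kb take the phage/plasmid
route instead: gene calling runs once and *all* candidates are accepted
(subject only to the overlap rule), after which the pipeline continues from
frameshift detection onward. A user-supplied mode always overrides the
automatic choice. RNA genes are not detected; a pre-computed RNA feature
table (GFF3) can be merged and is treated as immovable.

## Key parameters

All thresholds live in `pk_config()` and can be overridden per call or via
a flat key-value file. The load-bearing ones:

| key | default | meaning |
|---|---|---|
| `mode_threshold` | 100000 bp | phage/plasmid route below this total length (strict) |
| `kmer_k` | 8 | signature peptide length |
| `kmer_dominance` | 0.9 | majority-role fraction required to store a k-mer |
| `kmer_min_occurrences` | 2 | minimum total occurrences to store a k-mer |
| `promote_min_hits` / `promote_margin` | 3 / 2 | promotion rule: top role needs 3 hits and a lead of 2 |
| `min_orf_len` | 90 nt | ORF floor, and the final-cleanup length cutoff |
| `overlap_min_bp` / `overlap_frac` | 90 bp / 0.5 | overlap is "significant" beyond max(90 bp, half the shorter feature) |
| `model_order` | 4 | order of the periodic Markov coding model |
| `min_score`, `min_identity`, `min_coverage` | 50, 0.3, 0.7 | alignment acceptance thresholds (BLOSUM62 raw score, fraction, fraction) |
| `n_neighbors`, `max_extra_proteins` | 30, 200 | neighbor-set size; unduplicated proteins per genome |
| `min_gap` | 1500 bp | stretches strictly longer than this are backfilled |
| `max_join_gap`, `join_coverage` | 300 bp, 0.8 | frameshift fragments: maximum separation; combined template coverage |
| `min_variant_jaccard` | 0.5 | variant activity floor |
| `close_threshold` | 5000 bp | "close" for PCBBH coupling |

The promotion rule, the signature criterion and all alignment thresholds
are this package's own calibration — the approach defines the mechanism,
not the constants — which is why each one is an explicit config key.

## The coding model and start selection

GLIMMER-class interpolated models are replaced by a fixed-order (default 4)
3-periodic Markov chain: for each codon position, the conditional
distribution of the next base given the preceding `order` bases, with
add-pseudocount smoothing, plus a homogeneous background chain of the same
order trained on the non-coding complement of the current calls. An ORF's
score is the summed per-base log-odds; each base's context is read from the
surrounding contig, so scores are exactly additive over concatenated
in-frame blocks and minus-strand scoring equals plus-strand scoring of the
reverse complement by construction.

Start selection needs one caveat that is worth recording. Every in-frame
extension of an ORF is, by definition, free of stop codons, and a coding
model trained on real codons assigns stop-free sequence a systematically
positive log-odds (~0.05 nat/base on synthetic data). A pure
maximum-score rule therefore always prefers the longest start. Without a
ribosome-binding-site model (out of scope), the package anchors starts with
the annotation evidence itself: for a k-mer-promoted candidate the start is
trimmed to the latest recorded option that still precedes the candidate's
first signature hit. Unpromoted candidates keep the model rule — maximum
score plus a fixed small initiator bonus (ATG +0.5, GTG +0.25, TTG +0
nats).

Two further choices in the calling loop: the very first iteration uses raw
maximal ORFs (a clean-room build has no pre-trained model to bootstrap
from), and overlap arbitration within a pass is deterministic — more k-mer
hits win, then higher coding score (length in the single-pass phage route,
which trains no model), then the leftmost start.

## Frameshift repair

Two calls on the same contig and strand whose translations align to
disjoint, collinear segments of one template protein — together covering at
least 80% of it, neither alone reaching 80% — are proposed as a frameshift
join. Fragment pairs are searched within a 300 bp window rather than only
between consecutive calls, because interleaved spurious calls on the other
strand would otherwise hide a pair; and candidates that were promoted but
lost overlap arbitration are still visible as fragments, because the two
fragment ORFs of a frameshifted gene frequently overlap each other. Segment
disjointness on the template carries a 25-residue tolerance: the fragment
ORFs read a stretch of out-of-register ("junk") residues around the shift
point, which lets local alignments overrun the true boundary by roughly
that much. The inferred indel is reported modulo 3 as the single-base
explanation (+1 insertion / -1 deletion).

Joins are applied only on explicit opt-in, and the assembly sequence is
never edited: a joined gene is a two-segment compound location (GFF3 twin
CDS lines sharing an ID; GenBank `join()`), with the inference — fragments,
template, offset, indel — recorded in the annotation log and exported as a
`/note`.

## The synthetic world

`generate_world()` emulates the structure the pipeline consumes: protein
families sharing functional roles (one family per role by default), spread
over several reference genomes, grouped into subsystems with two variants
each, with a held-out set of "novel" families absent from the emitted
reference. `simulate_genome()` composes a genome from family genes
(reverse-complemented with probability 0.5), point-mutated at a set rate,
separated by geometric intergenic spacers, optionally frameshift-injected,
and returns an exact truth table.

Defaults state the study conditions: 40 roles, 6 proteins per family over
6 reference genomes, 90% within-family protein identity, genes of 100-300
codons, 200 genes per simulated genome, 0.5% per-base mutation, 120 bp mean
spacers, 5% frameshift injection where exercised. Two deliberate
simplifications keep the truth table exact: substitutions are uniform (no
substitution matrix), and substitutions that would create an in-frame stop,
or touch the start/stop codon, are redrawn — so every implanted gene
remains a single ORF and "recall" is well-defined. Consequences worth
keeping in mind: synthetic families are random sequences, so signature
8-mers are essentially collision-free between roles — real proteomes share
domains across roles and will yield fewer, noisier signatures; spacers are
uniform random DNA with no regulatory structure; there are no assembly
errors other than the injected indels; and paralogy within a genome is
absent unless families are drawn repeatedly. Passing tests therefore
demonstrate the machinery and its thresholds, not annotation accuracy on
real genomes.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; exporters convert to
  1-based inclusive. Overlap of `[0,300)` and `[300,600)` is zero.
* Translation uses table 11; GTG/TTG initiators render as M; internal stops
  render as `*` and are tolerated in candidates (they are the frameshift
  signal), and a single trailing stop is trimmed.
* k-mers containing `X` (or `*`) are never indexed or counted.
* Ties: k-mer majority ties discard the k-mer; best-hit ties break by
  lexicographic subject id (logged); variant ties prefer fewer roles, then
  the smaller code (logged); overlap arbitration ties break leftmost.
* Inside the pipeline, batch Smith-Waterman is gated by an exact shared
  5-mer prescreen (`seed_filter`), the same seeding idea BLAST uses; the
  public alignment functions default to exhaustive exact mode, and the
  oracle tests compare that exact path against an independent dynamic
  program.
* An empty genome errors; a genome with no ORFs, no k-mer hits, or no
  neighbors flows through and yields valid empty outputs.
* A model trained with `pseudocount > 0` scores any input finitely; unseen
  contexts back off to the uniform 1/4.

## Problem sizes in the test suite

The committed tests run the full pipeline on 200-gene genomes (~140 kb) for
the recovery regressions, 12-60-gene genomes for pipeline-property tests,
500 random proteins for the scan oracle, 200 random pairs for the alignment
oracle, and toy proteomes of at most 20 genes for the BBH oracle; these
sizes exercise every code path while keeping the default suite fast on one
CPU.

## Known limitations

* No RNA gene detection, no selenoprotein/pyrrolysine handling, no RBS
  model, no E-value statistics (raw score + identity + coverage instead),
  no metabolic reconstruction.
* Function transfer is only as good as the reference roles; the package
  never invents role text.
* Start calls for genes without k-mer evidence inherit the longest-start
  bias discussed above.
* The GFF3 reader covers the subset this package writes (plus plain RNA
  feature tables), not arbitrary third-party GFF3 dialects.
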