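---
title: "Methods: the CMS organelle screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CMS organelle screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
parameters matter, what the synthetic data do and do not emulate, and
which conventions were fixed where the field leaves them open.

## The screen

Alloplasmic CMS lines obtained by protoplast fusion carry a mosaic
mitochondrial genome. The screen implemented here takes three assembled
circular genomes — the CMS line, its iso-nuclear maintainer (the
recipient parent), and optionally the donor species — and produces a
ranked candidate report. Stages, in order:

1. **ORF calling** (`find_orfs`). Both strands, all three frames,
   standard genetic code, ATG starts only, one ORF per (stop, frame)
   with nested in-frame starts suppressed. Circularity is handled by
   scanning the doubled sequence and discarding calls that start in the
   second copy; an ORF may therefore wrap the origin. The floor is a
   protein of **101 residues** ("longer than 100 amino acids"), the
   convention of conventional ORF-finder screens.
2. **Specificity** (`call_presence`, `specific_orfs`). Each CMS ORF is
   searched against the maintainer; the verdict is *present* iff the
   best hit covers ≥ 90% of the ORF at ≥ 95% identity. These two
   thresholds are the package's own — published screens state no
   numbers — and are exposed in `cms_params()`. Identity here is
   computed over aligned (non-gap) columns: a shared gene carrying a
   33 bp in-frame insertion is still the same gene, and counting the
   gap columns against identity would misclassify it as CMS-specific.
3. **Transmembrane prediction** (`predict_tm`). Kyte–Doolittle
   hydropathy, window 19, threshold 1.6 — the published canonical
   choice for TM detection — with runs merged across gaps of < 5
   sub-threshold positions (a single polar residue should not split a
   helix) and segments kept at ≥ 19 residues. This is a deliberate,
   reproducible stand-in for HMM topology servers: per-ORF segment
   *counts* from such servers are not a contract the package tries to
   match; the presence/absence of TM structure is.
4. **Chimera detection** (`detect_chimera`). Every annotated CDS of the
   maintainer mitogenome is a potential fusion partner. A local
   alignment of ≥ 100 nt at ≥ 90% identity counts as a chimeric
   fragment; an ORF whose best hit covers ≥ 80% of it at ≥ 95%
   identity is reclassified as a plain core-gene copy and excluded.
   Both published chimera examples this models (a 175 bp *atp8*
   fragment and a 133 bp *cox1* fragment, each at ~98% identity) clear
   these thresholds comfortably.
5. **Context, origin, ranking**. `genomic_context` reports the circular
   intergenic distance to the nearest annotated gene (0 when
   overlapping; ties break toward upstream). `assign_origin` uses exact
   string search on the doubled parental sequences: `donor_identical`
   requires a full-length perfect copy in the donor and none in the
   recipient (this mirrors the absolute "100% identical" claim such
   studies make); a full length reconstructable only as a donor prefix
   plus recipient suffix (or vice versa) is `recombinant`; an ORF found
   verbatim in *both* parents cannot be attributed and is reported
   `recipient_identical` — the conservative call, and one that cannot
   arise for ORFs that passed the specificity filter. The candidate
   tier is exactly: specific ∧ (TM ≥ 1) ∧ (chimera ≠ ∅), ordered by
   fragment identity × length, then TM count.

Around the ORF screen sit the genome-scale comparisons:

* `compare_cds` globally aligns orthologous exon-joined CDS and emits
  one SNP record per mismatch column (codon context from the first
  sequence; multi-hit codons are classified by joint translation;
  `substitution_class` follows the standard purine/pyrimidine rule) and
  one indel record per gap run (`in_frame` iff length ≡ 0 mod 3).
* `summarize_genome_diff` counts substitution columns and gap runs over
  collinearity blocks — the chloroplast-style "60 SNPs and 50 gaps
  (0–5 bp)" comparison.
* `find_repeats` reports maximal exact repeated pairs (direct and
  inverted) by 31-mer seeding and diagonal run merging. Any exact
  repeat ≥ 500 nt contains shared 31-mers, so none can be missed. A
  `"near"` mode chains same-diagonal runs across small gaps for
  diverged copies. `predict_subgenomes` applies the textbook model:
  recombination across a direct repeat on a circle of length L excises
  circles of `d` and `L − d`, which must sum to L — the package asserts
  only this sum property, since published subcircle sizes are derived
  from unstated conventions.
* `anchor_map` + `chain_blocks` compute collinearity: shared 31-mers
  (kept up to 4 occurrences per sequence — *strict* uniqueness would
  mask the long repeat copies organelle genomes carry), merged into
  maximal runs, greedily chained on each strand when query and
  reference gaps are ≤ 2000 nt and the diagonal drifts ≤ 200 nt, with
  inter-anchor gaps closed by global alignment. Coverage is the
  percentage of the *query* inside blocks ≥ 500 nt (the report
  convention "coverage of A to B" is read as the fraction of the named
  genome aligned); identity is length-weighted across blocks.
* `pairwise_distances` (p-distance, gaps count as differences) and
  `neighbor_joining` (Saitou–Nei, lowest-index tie-break, negative
  branch estimates clamped to zero and flagged, 6-decimal newick)
  support homolog-set trees for the candidates.

## Alignment conventions

The default scoring scheme is BLASTN-like: match +2, mismatch −3, gap
open −5, gap extend −2, with a gap run of length L costing
`open + L·extend`. The engines are exact affine-gap dynamic programming
(Smith–Waterman / Needleman–Wunsch); the test suite checks their scores
against an independent exhaustive Gotoh implementation on all short
inputs. Traceback ties are resolved deterministically by the engine;
the package does not promise a particular co-optimal alignment, only
the optimal score and a deterministic result. `percent_identity`
divides matches by *all* alignment columns including gaps — the
denominator had to be fixed somewhere, and this choice makes identity
monotone under added gaps; the one deliberate exception (presence
calls) is documented above.

GC content excludes `N` from numerator and denominator and is rounded
half-up to two decimals, the precision organelle reports print.
Coordinates are 0-based half-open internally; GenBank output is written
1-based inclusive, and `join(...)`/`complement(...)` CDS locations
round-trip exactly. Ambiguity codes beyond `N` are rejected at parse
time so every downstream classifier stays total.

## The synthetic trio

`simulate_trio()` is first-class, tested code, not a fixture. It builds
the three genomes from an ordered list of sequence elements (intergenic
pads, genes, ORF cassettes, repeat copies, recipient-specific
segments), each present or absent per line, so that every planted
feature has exactly known coordinates in every genome:

* **Shared genes.** Twenty named mitochondrial genes (~300–460 codons,
  polar-biased codon usage so no gene can fake a TM helix), one of them
  (*rps3*) split into two exons around a 200 nt intron, two (*atp8*,
  *cob*) on the minus strand, and one (*cox2-2*) present in the
  recipient only and retained by the cybrid.
* **SNP plan.** 26 substitutions over 12 genes: 10 synonymous (5
  transitions / 5 transversions) and 16 non-synonymous (13/3),
  matching the published composition between a rapeseed CMS line and
  its maintainer under the standard transition definition. Sites are
  chosen by rejection sampling (one per codon, never creating a stop),
  which guarantees exact truth labels.
* **Indel plan.** One 33 bp (11-codon) in-frame insertion in the second
  exon of the donor *rps3*.
* **Specific ORFs.** Sixteen donor-only ORFs reproducing a published
  CMS inventory: protein lengths 101–394, per-ORF TM stretch counts
  (0–6; 11 of 16 have ≥ 1), and three chimeras — a 675 bp ORF with a
  175 bp *atp8* fragment and two ORFs (930/1041 bp) with a 133 bp
  *cox1* fragment, each fragment mutated to ~98% identity and inserted
  at a non-codon-aligned offset (the homology is nucleotide-level).
  Each cassette is flanked by a 12 nt guard that contains a stop codon
  in all six frames, so no ORF can leak across cassette boundaries;
  filler codons include sparse Leu/Val/Ile "breakers" whose shifted
  frames are stop-rich, and the generator verifies by construction
  (re-running the ORF caller and TM predictor on every cassette) that
  the planted ORF is the only one and its TM count is exact.
* **Context constraints.** The *orf346* analogue ends 103 bp upstream
  of *nad3*; *ccmB* starts 217 bp downstream of the *orf224* analogue.
* **Repeats.** 9432/7383/2427/1592 nt units, ORF-free by construction.
  In the cybrid the first three are inverted pairs and the last direct;
  the 7383 and 2427 nt repeats also exist as direct pairs in both
  parents. Pad nucleotides flanking the copies are pinned (A by copy a,
  C by copy b) so exact repeats cannot extend past their planted
  boundaries in any genome or orientation.
* **Mosaic.** The cybrid takes the donor version of every slot except
  *cox2-2* and five 2 kb recipient-only segments, yielding a ~93%
  donor fraction — the generator's truth table records the expected
  coverage, and the collinearity stage is tested against it within
  ±2 percentage points (block boundaries cost up to k nt each).

**Scale.** The recipient is ~127 kb and the cybrid ~158 kb — about 60%
of the real molecules this emulates (222/270 kb) — with repeat lengths,
variant counts and the ORF inventory kept at their published values.
This size keeps the full simulate-and-screen cycle under a minute while
every planted count remains exactly recoverable; nothing in the
pipeline depends on the scale. A second generator,
`simulate_diverged_pair()` (60 kb, 60 SNPs, 50 indels of 1–5 bp at
≥ 80 bp spacing), models the chloroplast-style near-identical
comparison.

**What the synthetic data do not emulate:** real codon usage and GC
structure (genes are polar-biased by design), RNA editing, tandem
microsatellites, diverged repeat copies (planted repeats are exact),
sequencing or assembly error, and biologically realistic intergenic
sequence (pads are stop-rich by construction). Passing the recovery
tests therefore demonstrates that the *screen logic* is correct and
exactly invertible on known structure — not that thresholds are tuned
for any particular real genome.

## Numerical and degenerate-input choices

* Half-up rounding for printed percentages (GC to 2 decimals, identity
  to 1) — base R's round-half-to-even would disagree with printed
  report values.
* `find_orfs` requires `nt_length ≤ genome length` (a circular ORF
  cannot lap itself) and names ORFs `orf<protein length>` with
  `a`, `b`, ... suffixes on ties in genome order.
* `hydropathy_profile` on a protein shorter than the window warns and
  returns an empty profile; `predict_tm` then reports zero segments.
* `compare_cds` warns on internal stop codons but still classifies.
* An all-`N` sequence has undefined GC content (error), and empty
  sequences are rejected everywhere at construction.
* Chain/blocks: overlapping blocks on the query are resolved longest
  first; a later block keeps its largest uncovered piece (statistics
  scaled proportionally) or is dropped below the 500 nt floor.
* `neighbor_joining` requires a symmetric zero-diagonal matrix with
  ≥ 3 labelled taxa; Q-matrix ties take the lowest-index pair, making
  the tree deterministic under taxon permutation (topology-invariant,
  as tested).

## Problem sizes used by the tests

The routine suite runs the full default trio once (~158 kb cybrid;
about a minute of CPU) plus the 60 kb diverged pair; oracle-equivalence
suites use strings ≤ 12 nt (alignment), ≤ 5 kb (repeats), ≤ 3 kb
(anchors) and 4–8 taxa (neighbor joining), sizes at which the
exhaustive references are exact and fast. The acceptance script repeats
the trio and pair runs from scratch at the caller's seed.

## Known limitations

* The presence thresholds (0.90 / 95%) implicitly decide how much
  homology disqualifies an ORF from being "specific"; a CMS ORF with an
  88%-similar maintainer homolog is still specific under them, which is
  the behaviour real inventories exhibit, but the cutoffs are
  conventions, not biology.
* TM segment counts from hydropathy differ from HMM-based servers,
  especially for marginal helices; only ≥ 1 vs 0 is treated as
  evidence.
* Coverage/identity figures depend on the aligner convention (HSP
  union vs chained blocks); reproduction of published figures is
  expected only within a couple of percentage points.
* The repeat finder's exact mode reports only perfect copies; the
  `"near"` mode chains across small gaps but is not a full diverged
  repeat aligner.
* Whole-genome comparisons treat the molecules linearly from their
  deposited origin; a block spanning the origin appears as two blocks.
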