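---
title: "Methods: amplified cidA-cidB operon analysis with cidscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplified cidA-cidB operon analysis with cidscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidscope)
```

## The model

Cytoplasmic incompatibility (CI) in *Culex pipiens* is governed by
*Wolbachia* (*w*Pip), and its unusual diversity of crossing types tracks the
*cidA–cidB* operon. Three observations structure everything `cidscope`
computes:

1. **The operon is amplified.** Every *w*Pip genome carries several
   near-identical copies of the operon, while standard reference assemblies
   carry one. Reads from all copies therefore map onto the single reference
   copy, and the ratio of its normalized coverage to that of single-copy
   marker genes estimates the copy number.
2. **Copies differ only in a few polymorphic regions.** Each gene has two
   such regions (cidA: aa 118–152 and 336–401; cidB: aa 242–278 and
   450–481); within a region a small set of alleles circulates (cidA
   upstream: α, β, γ, δ; downstream: 1, 2; cidB upstream: a, b; downstream:
   1, 2, 3). A copy is named by its allele pair, e.g. `cidA_IV(δ/1)`, and
   variants arise as block recombinants of these pools.
3. **Two variants mark incompatibility.** Lines whose males are
   incompatible with all tester females carry both `cidA_IV(δ/·)` and
   `cidB_IV(a/2)`; lines carrying neither are compatible. The association
   is tested on a 2×2 of crossing type × signature with the
   continuity-corrected two-proportion χ² test.

## The synthetic world

`build_world(seed)` constructs a complete, self-consistent instance of this
system as a pure function of the seed: gene scaffolds, allele pools, a
circular reference genome (one operon copy, 14 single-copy marker genes of
600 bp, a single-copy *wsp* locus, 150 bp spacers) and the diagnostic
PCR-RFLP system. Design choices that matter:

* **Alleles are engineered, not just random.** The published alignments
  give amino-acid blocks, not full sequences, so pools are generated from a
  seeded uniform base model with ≥ 5 % pairwise divergence per region
  (disjoint "barcode" substitution sets per allele). On top of that,
  restriction sites are planted so that in-silico PCR-RFLP of each variant
  reproduces the diagnostic fragment patterns: the cidA 778 bp amplicon
  digests to 524/122/57/51/24 bp for δ, with α adding a cut that splits the
  524 band into 471 + 53 and β/γ one that splits it into 441 + 83 (note
  471 + 53 = 441 + 83 = 524 — the printed patterns are internally one
  cut apart, which the construction exploits). The cidB 1267 bp amplicon
  digests to 1028/239 for allele 2, with alleles 1 and 3 splitting the 1028
  band into 892 + 136 and 861 + 167.
* **Indel-free.** All alleles of a region share one length. The real
  cidB amplicon varies 1267–1276 bp across variants (a ~9 bp indel), so the
  world's variant-1 pattern has a 136 bp band where the printed pattern has
  145 bp. The printed multisets are still reproduced exactly by
  `amplicon_from_map()`, which builds one amplicon per published pattern
  (lengths 1276/1267/1267); concordance tests on the world use
  `world_patterns()`, i.e. the world's own digests.
* **The cidB tail artifact is emulated.** The reference carries a second,
  identical copy of the cidB tail (from nt 2461); leftmost-placement maps
  fully-contained tail reads onto the gene, inflating its coverage — which
  is exactly why that interval is excluded from the copy-number estimate.
* **Sample genomes share the reference backbone.** Marker genes, *wsp* and
  inter-locus spacers are identical between reference and sample; only the
  operon cassette (k copies, unique junction spacers) differs. Drawing
  fresh spacers per genome would depress marker-edge coverage under exact
  placement and bias the copy-number ratio upward by ~10–15 %.

What the generator does **not** emulate: sequencing quality scores, indels,
GC bias, mate pairs, multiple-displacement-amplification bias, lytic-phage
copy-number distortion, and between-group scaffold divergence (group labels
are metadata). A green test therefore establishes correctness of the
*estimators and calling logic* under the stated noise model, not robustness
to real-library artifacts.

## Estimators and numerical choices

**Coverage copy number.** Reads are placed by exact (optionally
near-exact, trusted-band) matching, once per read at the leftmost best
locus. Depth is normalized by the genome-wide mean (idempotent; mean-one
within 1e-9). Region means exclude the polymorphic regions *widened by
read_length − 1 on each side*: under exact placement a read overlapping any
divergent base fails entirely, so the coverage trough extends a read length
beyond the region proper. The published analysis excludes "polymorphic
regions" for their coverage variability; the margin is this package's
faithful version of that rule under its own mapper. Marker aggregation is
the arithmetic mean of the 14 per-gene means (a `median` switch exists; the
source does not state the aggregation).

**qPCR.** `Cq = baseline − log_E(copies) + N(0, noise_sd)` with
`baseline = 25` cycles (typical single-copy bacterial locus on a
LightCycler), efficiency `E = 2` by default (none reported), three
replicates. The estimator is `E^(ΔCq)` on replicate means.

**Repertoire typing.** Allele assignment is exact at the nucleotide level —
regions are fixed-length by construction and the relevant polymorphism is
substitutional; near-misses report the Hamming-nearest registered allele.
Clones are typed in open-registry mode so that error-bearing clones become
novel labels (deterministically `n1, n2, ...`) rather than failures; the
`min_support = 2` default then discards singletons as putative
chimera/error clones, reported, not silently dropped. aa→nt interval
conversion is `[s,e] → [3s−2, 3e]`; the internally inconsistent printed
nucleotide coordinates for the cidB downstream region are not used.

**RFLP calling.** Patterns match by one-to-one fragment pairing within a
±5 bp tolerance (gel-resolution analogue; published patterns differ by
≥ 30 bp in their discriminating bands). Small co-migrating bands can be
flagged non-discriminating and become optional in matching — necessary for
the α pattern, whose 53 and 51 bp bands are unresolvable at the tolerance.
Mixed-template mode compares *band sets* (unique lengths) against pairwise
pattern unions, because a line's pooled amplicons co-migrate shared bands.

**Blocks and recombination.** `detect_blocks()` merges polymorphic columns
separated by ≤ `max_gap` columns (default 3 at aa level) — the published
figures color blocks without a formal rule, so the gap is the package's
parameterization of that ambiguity. The four-gamete test binarizes every
allele pair of two blocks and reports recombination if all four haplotypes
occur. Caveat: this is exact for biallelic sites; multi-allelic *merged*
blocks can fire without recombination (ancestral-vs-rest binarization), so
the recombination-free invariant is tested on single-column blocks. Block
analyses default to nucleotide level (the published networks' level is
unstated). P distances use pairwise gap deletion; gaps are not states in
polymorphic-column calls by default.

**Association.** `prop_test_yates()` implements
`χ² = N (max(|ad − bc| − N/2, 0))² / (r₁r₂c₁c₂)` with the upper-tail
chi-square probability (df 1) from the standard incomplete-gamma routine
(`pchisq`), cross-checked in tests against `stats::prop.test` to 1e-10. The
default positivity rule is `any_variant` — the published statistic (χ² = 78)
is reproduced by positives 17/17 vs 16/163, i.e. the complement of "carries
neither" — with `both_variants` available as a switch. Degenerate tables:
a zero column (no positives anywhere) yields χ² = 0 (proportions equal);
a zero row is an error. Undetermined (mixed-outcome) lines are excluded
from the table and counted separately.

## Stated-world parameters

| Parameter | Default | Why |
|---|---|---|
| operon copies `k` | 3 (pipeline) | matches the observed ~3× coverage excess |
| depth | 50× | comfortable for a ~18 kb reference; criterion scale |
| read length | 100 bp | short-read protocol scale |
| clones per line | 48 | the study's cloning depth |
| `min_support` | 2 | singleton clones are the standard artifact class |
| panel | 180 lines, 17/8/8/147 | the published category counts |
| discordance rate | 0 (planted mode) | planted categories already encode the 16 discordant lines |
| qPCR noise | 0.1 cycles | tight replicate agreement typical of a good run |
| RFLP tolerance | ±5 bp | gel resolution; discriminating bands differ by ≥30 bp |
| `max_gap` | 3 columns | block-coloring ambiguity parameter |

Test-budget scale-downs (documented, not hidden): the estimator-recovery
invariant runs at 5 seeds × k ∈ {1,3,5} × 30× depth (the acceptance test
runs the stated 50×); the strand-symmetry property at 300 random sequences.

## Limitations

* The coverage mapper is exact/trusted-band, not an aligner; at realistic
  error rates (> ~1 %) placement loss is uniform but the regional margins
  above are calibrated for error-free reads.
* Group labels (I–V) are input metadata throughout; the pk1 group assay is
  out of scope, as are chromatogram parsing, multiple sequence alignment,
  split-network estimation and any wet-lab modeling.
* The real study's repertoires and SRA-based coverage are not reproducible
  offline; every empirical number in this vignette and the README is
  computed by the package's own tests or acceptance script on synthetic
  data.
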