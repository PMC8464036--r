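---
title: "Methods: homology-driven characterization of de novo transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-driven characterization of de novo transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txannot)
```

`txannot` characterizes assembled transcriptomes by transferring
information from a reference database of proteins clustered into
homologous gene families (GFs). This vignette is the package's own
account of the methods: the models and rules each stage implements, the
parameters that matter and their defaults, what the synthetic fixture
generator does and does not emulate, and the design choices made where
the design was genuinely open.

## Protein-level taxonomic classification

A transcript is classified by the taxon of the reference protein(s) that
share its longest exact amino-acid substring. The query is translated in
all six frames under the standard genetic code, each translation is
split at stop codons, and the resulting stop-free fragments are matched
against the reference proteins. A match shorter than the minimum match
length (default **11 aa**) is ignored; with no qualifying match the
transcript stays unclassified. When several distinct taxa tie at the
maximal match length, the transcript is lifted to their lowest common
ancestor (LCA) in the taxonomy tree; ties among proteins of one taxon
need no lifting. This mirrors the maximal-exact-match (MEM) strategy of
protein-level read classifiers, which can bridge large evolutionary
distances because amino-acid identity decays far more slowly than
nucleotide identity.

Two deliberate contracts shape the implementation:

* **The search structure is not mandated.** `classify_transcript()` uses
  a binary search over shared k-mer lengths; its only contract is exact
  agreement with a brute-force scan over every substring of every
  fragment, which the test suite enforces on hundreds of generated
  queries.
* **Split indexes merge exactly.** Searching the reference in *k* parts
  and merging with `merge_split_results()` (longest match wins; equal
  maximal lengths from different taxa resolve to their LCA) must equal
  the single-index result on every query — exactly, not approximately —
  because the per-split and unified selection criteria are identical.
  The merge is associative and commutative, so split order is
  irrelevant.

The low-complexity filter suppresses a fragment when one residue exceeds
50% of its length or its Shannon entropy falls below 1.5 bits. The
masking algorithm used by the external classifiers this emulates is not
published as a precise rule, so this simple, documented criterion is our
own stand-in; it is configurable off
(`classifier_config(low_complexity_filter = FALSE)`).

Rank summaries (`summarize_rank()`) lift classified transcripts to their
ancestor at a requested rank, keep at most the top 10 clades, and
aggregate both non-top clades and kept clades under 1% of the depicted
transcripts into "Other"; transcripts classified above the rank are
excluded from the depicted set and reported separately, so counts always
reconcile.

## Similarity hits, gene families, and functional transfer

Translated similarity searches (DIAMOND/BLASTX tabular format, 12
columns) are parsed and filtered at a maximum E-value of **1e-5** by
default. For each transcript the *top hit* is selected under a total
order — lowest E-value, then highest bitscore, then subject identifier —
so selection is deterministic and permutation-invariant. The top-hit
subject's gene family (if it has one) is assigned to the transcript;
transcripts without any hit receive no family and no transferred
annotation.

Functional labels (GO, InterPro, KO) transfer from the top-hit subject,
from the assigned family, or from both (the default). Family-level
transfer is a **majority vote**: a label must be carried by at least
50% of the family members, counting all members in the denominator, not
only annotated ones — "half the members" reads as total membership. The
vote threshold is exposed (`gf_vote_threshold`), and transfer provenance
(`hit`, `gf`, `both`) is recorded per label. GO labels are stored as
asserted; ancestor propagation is deferred to enrichment time (off by
default) so that stored annotation stays minimal and auditable.

Non-coding transcripts are recognized from Infernal `cmsearch --tblout`
results against Rfam covariance models (the package parses this output;
it never runs Infernal). Each matched transcript is assigned to its top
family by bitscore (ties: lower E-value, then accession), restricted by
default to the six ubiquitous clans — tRNA, RNase P, SRP RNA, SSU rRNA,
LSU rRNA, 5S rRNA — and annotated with the curated GO terms mapped to
the family. A transcript holding both a gene family and an RNA family
keeps both and lands in the *ambiguous* default subset.

## Frames, frameshifts, ORFs and meta-annotation

Strand and frame derive from the translated-search coordinates: the
query start exceeds the query end exactly when the alignment lies on the
minus strand, and the frame is the alignment start's position within its
codon (`((qstart - 1) mod 3) + 1` on the plus strand,
`((L - qstart) mod 3) + 1` on the minus strand, *L* the query length).
Frame evidence is restricted to the HSPs of the top-hit subject: a
single coherent evidence set, rather than a mixture over all subjects
(the alternative is a documented switch point, not a hidden behavior).
A **putative frameshift** is flagged when two or more distinct frames
occur on the chosen strand — the signature of HSPs split across a small
insertion or deletion. Conflicting strands are recorded as a strand
conflict, not a frameshift.

The ORF is the longest stop-free codon run within the chosen strand and
frame, extended to the sequence edges when no stop bounds it; a start
codon is *not* required, because assembled fragments routinely lack 5'
ends — start/stop presence is bookkept separately and feeds the
meta-annotation instead. Ties between equally long runs go to the
leftmost run; in the de novo case (no hits, not an RNA) the search spans
all six frames, preferring the plus strand and lower frames on ties.
The stop codon is excluded from both the amino-acid sequence and the
nucleotide coordinates, which keeps length semantics unambiguous for the
recovery ratio below. In CDS mode every input is translated on strand
`+1` and the ORF search is skipped.

Any NCBI translation table can drive prediction. Under the ciliate
nuclear code (table 6), TAA and TAG encode glutamine and only TGA
remains a stop, so a fixed frame can only gain coding length relative to
the standard table — a monotonicity the tests assert. The **best-hit
recovery ratio** (predicted ORF length in aa over the best-hit protein
length) is the diagnostic for code misspecification: internal reassigned
stops truncate standard-code predictions and drag the ratio far below 1.
We use the full subject protein length, not the HSP alignment length, as
the denominator, because the ratio should approach 1 exactly when a
complete transcript recovers its full protein; the alignment-length
variant is computable from the same records if wanted.

Meta-annotation compares the predicted ORF length with the protein
lengths of the transcript's family members: with
`rho = length(ORF) / median(member lengths)`, a transcript is
`full_length` when start and stop are present and `rho >= 0.8`,
`quasi_full_length` when only the length test passes, `partial` when
`rho < 0.8`, and `no_information` without a family. The median and the
0.8 threshold are our explicit choices (both configurable): a robust
central statistic plus a knob, where the lineage of tools this follows
defers the details to unpublished internals.

## Core gene-family completeness

For any clade, a family is **core** when represented in at least 90% of
the clade's species in the reference — tolerating annotation errors or
loss in a few species. The comparison is exact integer
cross-multiplication (so 9/10 species at `t = 0.9` is core and 8/10 is
not, with no floating-point boundary surprises). Each core family gets a
weight

\[ w_f = \frac{s_f}{S} \cdot \frac{s_f}{n_f} \]

with `s_f` the represented species, `S` the clade species count and
`n_f` the member count within clade species: broad coverage and low
average copy number raise the weight, and a universal single-copy family
weighs exactly 1. The source this scoring scheme descends from does not
restate its weight formula, so this product of the two named quantities
is our own fixed choice, isolated behind `gf_weight()` so any positive
weight map can be substituted. Members from outside the clade are
excluded from `n_f`, so out-of-clade paralogs cannot dilute weights.

The completeness score is the summed weight of represented core families
over the summed weight of all core families, with represented families
taken from each transcript's top hit (or, with `k > 1`, from the
best-scoring family among the top *k* hits, scored by maximum bitscore).
The score is monotone in the transcript set and equals 1 exactly when
every core family is represented.

## Subset enrichment

Enrichment of a transcript subset uses the upper-tail hypergeometric
distribution with the annotated transcripts of the experiment as the
background: drawing `n` subset transcripts from `N` background
transcripts of which `K` carry a label, the p-value is `P(X >= k)`.
q-values come from Benjamini–Hochberg correction over the tested labels,
and records pass a q-cutoff conventionally between 0.05 and 1e-5. Two
readings of "background" are possible; we count transcripts carrying at
least one label in the tested namespace (switchable to an explicit
background set), since enrichment against never-annotated transcripts
conflates annotation coverage with biology. Only over-representation is
reported by default. Subset comparison reports per-label frequencies and
their ratio (flagging subset-private labels), and the taxonomy-aware
ratio conditions both label and genus assignment, for community samples
where a function must be attributed to a clade.

## The synthetic fixture generator

Every test input is generated in code, deterministically under a seed
(`make_fixture_set()`). The generator emulates exactly the structures
the engine's rules act on:

* a taxonomy with a main clade (10 species paired under genera, by
  default) and a small outgroup;
* random reference proteins of 80–400 aa with a **per-family common
  length**, so the meta-annotation length ratio of a generated
  transcript is known by construction;
* gene families with a controlled species-coverage profile spanning the
  90% core boundary, plus occasional paralogs, so core status and
  weights are known exactly;
* labels planted at member frequencies 1, ~0.5 and ~0.25, exercising
  the majority-vote boundary;
* transcripts built from reference CDS with random strand and frame,
  bounded by an in-frame TGA before the start codon (a stop under both
  shipped tables), with variants: 5'-truncations below and above the
  0.8 length threshold, single-nucleotide insertions splitting the CDS
  into two adjacent-frame HSPs, outgroup-derived contaminants,
  RNA-flagged random sequences with simulated Infernal hits, and
  ciliate-style CDS in which every glutamine is encoded as TAA/TAG
  (chosen so the longest standard-code run stays below 80% of the
  protein);
* hit tables whose coordinates reproduce the placements and whose
  E-values/bitscores are rank-consistent labels arranged so the source
  gene wins top-hit selection, with periodic worse-scoring decoys.

Default per-type counts (40 coding, 8 quasi, 12 partial, 15 frameshift,
8 contaminant, 8 RNA, 4 ambiguous, 5 hit-free; 100 transcripts over 10
species and 10 families) are sized like a small but structurally
complete experiment; the genetic-code comparisons use 50 ciliate-style
plus 50 standard transcripts, and the classifier/oracle comparisons use
200 queries against a 50-protein reference.

What the fixtures do **not** emulate: realistic residue composition
(proteins are uniform over the 20 amino acids), alignment noise
(simulated HSPs are exact), score distributions (E-values are ordering
devices, not probabilities), sequencing error beyond the planted indels,
and expression levels. Passing tests therefore demonstrate that the
rules are implemented exactly as specified and recover planted truth —
not that the external search tools whose outputs are parsed would
produce such clean evidence on real data.

## Numerical and degenerate-input choices

* Exact rational threshold comparisons for the core-family boundary
  (integer cross-multiplication, exact for thresholds with up to six
  decimals).
* Hypergeometric tails via `stats::phyper`, BH via `stats::p.adjust`;
  both cross-checked in tests against exhaustive enumeration and the
  hand-applied step-up rule.
* Tie-breaks are total everywhere: top hits by (E-value, bitscore,
  subject id), Rfam families by (bitscore, E-value, accession), ORF runs
  leftmost-first, enrichment rows by (q, fold, identifier).
* Codons containing N translate to X; `*` in reference proteins is
  stripped with a warning; a transcript shorter than one codon in its
  frame yields no ORF rather than an error; an RNA-flagged transcript
  without homology evidence gets no ORF at all.
* Coordinates are 1-based inclusive on the input orientation throughout;
  minus-strand features report ascending coordinates plus a strand flag.

## Known limitations

The classifier is a reference implementation meant for exactness, not
throughput: it is quadratic-ish in reference size and intended for
small-to-moderate references, while production-scale classification
flows in through `parse_kaiju()`. Frameshifts are detected, not
repaired. The engine never runs DIAMOND, Kaiju or Infernal itself; their
outputs are inputs. eggNOG-style annotation routines and
alignment/phylogeny construction are out of scope.
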