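---
title: "Methods: COG annotation by translated search and cross-database mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COG annotation by translated search and cross-database mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The annotation model

`metacog` treats functional annotation of short community-sequencing reads
as one translated homology search plus one relational lookup. A read is
translated in all six reading frames; each frame's stop-free segments are
aligned locally (Smith–Waterman, affine gaps) against a protein database
in which every sequence carries a COG identifier and one or more of the 25
single-letter functional category codes. The read inherits the COG and
category tags of its best hit whose e-value falls strictly below the
threshold; reads with no such hit stay unassigned. A cross-mapping store
then expands each COG call into KEGG, Pfam, GO and SEED term sets without
further alignment — the "mapping" phase is pure lookup, a property the
package makes observable through `alignment_call_count()` and asserts in
its tests.

The key assumption is that a COG is a good proxy for function across
annotation systems: if the cross-mapping rows are trustworthy, the derived
namespaces can only be as wrong as the COG call itself. The evaluation
harness (`confusion_counts()`, `predictive_values()`) exists to quantify
exactly that, per namespace, against a benchmark produced by direct
search.

### The four workflow options

Options 1 and 2 search the full database in a single pass, with the exact
or the heuristic engine. Options 3 and 4 run the two-stage *directed*
search: stage 1 queries a reduced database of cluster representatives and
fixes a tentative category per read (partitioning the query set into at
most 25 subsets); stage 2 searches only the full-database partition(s) of
that category. The stage-2 space is a strict subset of the full database
whenever the stage-1 winner carries fewer than 25 tags, which is the
source of the directed search's cost reduction — and of its accuracy risk:
if the true source protein lies outside the tentative category, the final
call can be wrong or missing. That trade-off is intrinsic to the strategy,
not an implementation artefact.

Two consequences the test suite pins down:

* *Conditional equivalence*: whenever option 1's best hit shares a
  category with the stage-1 winner, option 3 returns the same COG. This
  holds because the stage-2 subset then contains the global best hit, all
  hits within a stage share the same search-space size `n`, and the
  ranking and tie-breaking rules are identical.
* *Benchmark identity for option 1*: a benchmark defined as "direct search
  of the full database with the same engine and threshold" performs the
  same computation as option 1, so option-1 COG PPV and NPV against it are
  exactly 1 whenever both the assigned and unassigned classes are
  non-empty. The acceptance script reports these values from a fresh run
  rather than asserting them axiomatically: a defect anywhere in the
  search, assignment or evaluation path would break the identity.

## The built-in search engine

The alignment kernel is authored in C++ (Gotoh recurrences, full local
alignment with traceback for the reported hit). Two engine modes exist:

* **exact** — every frame segment against every subject; plays the role of
  the rigorous aligner in options 1/3.
* **heuristic** — subjects must share at least one seed k-peptide
  (default k = 4) with some frame segment before being aligned; plays the
  role of the fast aligner in options 2/4. Because surviving candidates
  are aligned with the same exact kernel and scored with the same
  search-space size, heuristic hits are a subset of exact hits with
  identical scores and e-values: the prefilter can miss, never invent.
  This soundness property is asserted on generated read sets.

Pre-computed hit tables from any external aligner can substitute for the
built-in engine in the single-pass options via `parse_external_hits()`
(12-column tabular dialect, 1-based inclusive coordinates). The directed
options drive two internally coordinated searches, so an external table —
which fixes one search — is rejected there as a usage error.

### Scoring and statistics

* Substitution matrix: BLOSUM62 over the 20 amino acids plus `X`; all
  `X` pairs score ≤ 0 (−1 in BLOSUM62), so ambiguous residues can never
  create a match.
* Gap model: a gap of length *k* scores `gap_open + k·gap_extend`
  (defaults −11, −1, i.e. 12 for a single-residue gap), the NCBI
  existence/extension convention matching the Karlin–Altschul parameters
  below.
* E-values: `E = K·m·n·exp(−λS)` with λ = 0.267 and K = 0.041, the
  standard gapped BLOSUM62-11-1 constants. They are fixed, not fit, so
  e-values are approximate in absolute terms; every comparison the
  package makes is engine-internal, where only ordering matters. `m` is
  the frame peptide length; `n` is the total residue count of the
  database being searched (the reduced database in stage 1, the partition
  union in stage 2, and the full database in heuristic mode too, so that
  both modes agree hit-for-hit).
* Threshold: hits are accepted when `E` is strictly below the configured
  cut-off; the default 1e-5 follows the conventional cut-off for
  translated searches of short reads and is exposed as a flag because the
  right value is dataset-dependent.
* Stop codons segment frames: a local alignment never crosses `*`. The
  alternative — substituting `X` and letting alignments span stops — was
  rejected because it invites spurious extensions through what is, in a
  correct reading frame, a hard biological boundary.
* Codons containing `N` translate to `X` unconditionally (even when the
  ambiguity would resolve, e.g. `GGN`), keeping the no-match guarantee
  simple and uniform.

### Determinism and tie-breaks

Results must not depend on input order or scheduling, so every selection
has a total order: best hit by smallest e-value, then larger raw score,
then lexicographic subject id, then frame order (+1, +2, +3, −1, −2, −3);
co-optimal alignments by smallest query start, then smallest subject
start; cluster visiting by decreasing length, then lexicographic id. The
strand-symmetry property (a read and its reverse complement yield the same
best subject and score, frames swapping sign) follows from the frame
layout and is asserted in the tests.

## Database reduction

The reduced database is built per category: greedy incremental clustering
visits proteins in decreasing length order, joining the first cluster
whose founding representative matches at ≥ `identity_threshold`, and each
cluster contributes its longest member (ties: smallest id), tagged with
the category it was clustered under. Two documented choices:

* **Identity convention.** Identity is CD-HIT style: identical aligned
  residues divided by the length of the *shorter* sequence. Normalising
  by the local alignment length alone would let a 3-residue perfect match
  merge unrelated proteins; normalising by the shorter sequence makes the
  score mean "fraction of the smaller protein actually matched". The
  default threshold 0.6 cleanly separates the simulator's within-COG
  identities (~0.8 for members mutated at 10% per site from a common
  ancestor) from unrelated-pair identities (≲0.2), and is a configuration
  key because real protein families are messier.
* **Multi-category proteins** are clustered once per category, matching
  the per-category pipeline; a protein chosen as representative under
  several categories is emitted once with the union of its tags (emitting
  it twice would duplicate its id and break record uniqueness). Directed
  search already handles multi-tag stage-1 winners by searching the union
  of the matching partitions.

The reduction ratio achieved on real COG data is an emergent property of
that data; the package logs sizes and asserts only the structural
invariants (never larger than the full database; category codes
conserved; provenance partitions each category's proteins).

## The cross-mapping store

Mapping rows arrive in two source classes: `curated_import` (mined
tables) and `homology` (sequence-search-derived). Per (COG, namespace),
agreeing sources merge; differing sources resolve to the homology set
wholesale, with the conflict logged. Three choices were genuinely open:

* The precedence rule is applied uniformly across namespaces, though the
  motivating conflict arises for KEGG; a uniform rule is simpler to audit
  and the conflict log preserves what was discarded.
* Conflicts are resolved at set granularity (any difference → the whole
  homology set wins), the strictest reading of "the sources did not
  match". Term-level merging would silently mix provenances.
* GO terms are derived by composition COG→Pfam→GO through `pfam2go`
  pairs, using the *kept* Pfam set (so a Pfam term that lost a conflict
  contributes no GO terms), merged with any direct GO rows. GO terms are
  not propagated up the ontology; consumers who need ancestor closure
  should apply it downstream, where the ontology version is known.

## The synthetic generator

`generate_toy_cogdb()` draws ancestor proteins i.i.d. uniform over the 20
amino acids and derives each COG's members by per-site substitution
(default 10%), tagging every protein with its category;
`sample_reads()` picks a protein and peptide window uniformly,
reverse-translates with uniformly random synonymous codons, applies
i.i.d. base errors, and reverse-complements with probability 0.5. The
truth cross-mapping is bijective per namespace, so derived-annotation
accuracy against truth equals COG accuracy — deliberately isolating
mapping-phase *correctness* from mapping-content *quality*.

What this emulates: the tag structure, family similarity, frame/strand
geometry and search statistics the pipeline must handle. What it does
not: codon-usage bias, realistic quality profiles, chimeras, abundance
skew, domain shuffling, and families related *across* COGs. Passing tests
therefore demonstrate that the machinery is correct under planted signal,
not that any particular accuracy will be achieved on real communities —
the directed options in particular lose accuracy on real data in ways the
uniform-random toy database cannot reproduce.

With error-free reads of ≥ 90 nt the planted COG is recovered for every
read on the fixed-seed fixture (a verbatim ≥ 30-residue peptide scores
far above any cross-COG alignment here); the suite asserts this after
confirming the same calls with an independently coded exhaustive-search
oracle.

## Problem sizes and verification

The test suite runs entirely on generated data: a 5-category fixture
(30 proteins, 90 nt reads) for per-module tests, a 10-category fixture
(60 proteins, 150 nt reads, 15 random negative controls) for the
self-consistency checks, and a full 25-category database (150 proteins)
for partition-coverage checks; the alignment kernel is compared against a
pure-R full-matrix dynamic-programming oracle on 240 random peptide pairs
up to 50 residues, including mutated and truncated relatives to exercise
gapped paths. The acceptance script scales the same fixtures up (500
planted + 50 random reads; 20 reads per category for the stage-1 subset
count). These sizes were chosen so each property is exercised well past
its edge cases while a full run stays comfortably interactive.

## Known limitations

* E-values use fixed Karlin–Altschul constants; absolute values are
  approximate (edge effects and composition are ignored).
* The greedy clustering is order-deterministic but, like all greedy
  schemes, can split families a globally optimal clustering would join.
* `X` runs in reads (from `N`-rich sequence) shrink the alignable
  segments and can only lose sensitivity.
* The cross-mapping store models no per-row confidence; a homology-derived
  row always beats a curated one regardless of underlying evidence.
* GO evaluation by PPV/NPV is intentionally unsupported in the harness
  defaults: without ancestor closure, exact-term comparison would be
  misleading.
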