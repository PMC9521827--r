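---
title: "Template-based draft reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based draft reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemdraft)
```

## The reconstruction model

`gemdraft` builds a draft genome-scale metabolic model (GEM) for a query
organism by transferring reactions from template GEMs. The underlying
assumption is the standard orthology-transfer one: if the query genome
carries orthologs of the genes that catalyse a template reaction, the
query organism likely carries that reaction too. The draft is an
over-approximation by design — it is meant to be curated and gap-filled
afterwards, not simulated as is — so the pipeline optimises for
faithfulness of the gene evidence, not for flux consistency.

### Orthology: reciprocal best hits

Homologous genes are identified by a bidirectional similarity search
between the query proteome and the pooled template proteins. Hits are
filtered on three axes, all inclusive bounds:

| parameter | default | meaning |
|---|---|---|
| `maxEvalue` | 1e-20 | statistical significance ceiling |
| `minBitscore` | 50 | alignment-quality floor (bits) |
| `minQueryCoverage` | 0.75 | alignment length / query length |

Coverage is defined against the *query* of each direction and applied in
both directions by default (`coverageBothDirections = FALSE` relaxes the
reverse direction, for the reading under which coverage constrains only
the forward search). A pair (t, q) becomes an ortholog pair iff t is q's
best hit forward and q is t's best hit in reverse. "Best" is maximal bit
score, ties broken by smaller e-value and then by lexicographically
smaller subject id, which makes the map reproducible on tie-heavy inputs.
Multiple HSPs per (query, subject) pair are collapsed to the top-scoring
one before ranking, because coverage of a single HSP is well defined
whereas a sum of HSP lengths is not. Best-hit reciprocity is the standard
reading of "reciprocal matches"; an any-reciprocal-hit mode
(`anyReciprocal = TRUE`) is exposed for sensitivity analysis.

The search engine is an injection point. `blastpEngine()` adapts BLAST+
(`makeblastdb`/`blastp`, tabular output extended with the query length
column). `exactMatchEngine` and `kmerMatchEngine(k = 12)` are
deterministic in-R engines used by the test suite; the k-mer engine
indexes subject 12-mers and scores candidate pairs by positional
identity, which is adequate for the mutated-copy proteomes the fixture
generator produces and has essentially zero spurious-match probability on
unrelated random sequences at that k.

### GPR evaluation

A GPR rule is a Boolean tree over gene ids: `and` nodes are enzyme
complexes (all subunits required), `or` nodes isozymes (any one
suffices), and `and` binds tighter than `or`. Evaluation semantics:

* single-gene rule — the ortholog must be present;
* pure OR rule — one present ortholog suffices (a *partial* GPR can be
  assembled);
* pure AND rule — every gene must be mapped (a *complete* conjunction);
* mixed rule — the rule is decomposed by OR into conjunction clauses and
  each clause judged as above.

`decomposeOr()` produces the *minimal* disjunctive normal form: clauses
are deduplicated and absorbed (no clause is a superset of another), which
makes the decomposition canonical and hence directly testable. DNF
expansion is capped at 10,000 intermediate clauses and fails loudly with
the reaction id rather than truncating; real curated-model rules stay far
below this.

`assemblePartialGpr()` rewrites surviving clauses onto query gene ids.
When one template gene maps to several query genes, every combination of
per-gene choices becomes a clause. Under the strict policy (the default,
and the setting used for benchmarking drafts) only fully mapped clauses
survive; a mixed rule with one complete and one incomplete clause is
included on the strength of the complete clause. In non-strict mode a
clause's mapped subset survives as a partial conjunction, and the
reaction is flagged `"partial"` — the flag is reaction-level metadata, not
part of the Boolean tree, so truth-table semantics stay clean. Reactions
with no GPR at all (spontaneous and boundary pseudo-reactions) are
excluded by default and re-admitted by `allowNoGpr = TRUE`.

### Deduplication

Pooled template collections contain duplicated reactions from three
sources: reversibility re-writes, protonation-state variants, and
compartment copies. The canonical key strips protons (metabolite base ids
in `protonIds`, default `"h"`, in any compartment), encodes each side as
a sorted multiset of (base id, compartment, |coefficient|), and puts the
lexicographically smaller side first, so reversed writings and
proton-shifted variants of one transformation collide on one key.
Coefficients are compared through a fixed 15-significant-digit decimal
rendering, exact for the short decimal coefficients curated models use.

Compartments stay in the key by default: collapsing a cytosolic and a
periplasmic copy changes network topology, which is not a safe automatic
decision. `collapseCompartments = TRUE` opts into merging copies that are
identical up to a consistent compartment relabelling.

Merged groups keep one representative (smallest reaction id, then
smallest source model id), OR their assembled GPRs (re-minimized by
absorption), become reversible if any variant was — or if two
irreversible variants ran in opposite directions, since the merged
reaction then has both capabilities — and record every contributing
(template, reaction id) pair in provenance, so the alternative
keep-first-GPR policy remains recoverable from the output.

### Template selection

Organisms are profiled by presence/absence of COG identifiers restricted
to the METABOLISM general functional category (letters C, E, F, G, H, I,
P, Q); annotation tables are consumed as TSV (the annotation tool itself
is out of scope). Profiles are compared by Jaccard distance,
1 − |A∩B| / |A∪B|, computed via `vegan::vegdist`. The distance used for
"metabolically closest" is a genuine design choice — no single metric is
canonical for quantifying presence/absence overlap — so a Hamming
alternative (fraction of differing entries) is exposed by flag and the
choice is surfaced in this vignette rather than buried. Pairs of all-zero
profiles are defined to have distance 0, with a warning. `topKClosest()`
excludes the target and breaks ties lexicographically.

### Assessment

Drafts are scored against a reference by exact reaction-identifier
overlap: TP = shared, FP = draft-only, FN = reference-only, with

$$P = \frac{TP}{TP+FP},\quad R = \frac{TP}{TP+FN},\quad
F1 = \frac{2PR}{P+R}.$$

Exchange, sink and demand pseudo-reactions are excluded, detected by id
prefix (`EX_`/`SK_`/`DM_`) *and* by topology (all metabolites on one side
of the equation), so unprefixed sinks are still caught. Identifier
matching is by exact string because draft and reference draw from the
same namespace; `_copy<digits>` suffix stripping is off by default since
silent normalization can inflate TP. Zero denominators yield 0 with a
`degenerate` flag instead of an error, so an empty draft still produces a
report row. Reports print metrics to three decimals.

## The fixture generator

`generateFixture()` emulates the structure the pipeline exercises — a
small template universe with planted ground truth — not the content
statistics of real curated collections. Defaults define the reference
conditions used throughout the tests: 3 templates × 25 reactions × 18
genes, equal weights over the four GPR shapes (with each shape forced at
least once per template), 3 planted duplicate pairs cycling
reversibility/protonation, 80% ortholog coverage at mutation rate 0,
5 decoy query sequences, 80-residue proteins, and a reference model that
perturbs the expected draft by 5 planted FPs and 5 planted FNs so target
P/R/F1 are known in closed form. Sequences are random over the 20-residue
alphabet and ≥ 60 aa, long enough that the k = 12 k-mer engine has no
spurious matches. Every reaction carries a unique signature metabolite,
which rules out accidental key collisions and makes planted-merge counts
exact.

Ground truth is computed from the generator's own records (the clause
sets, ortholog subset and duplicate pairs it planted) *before* any
pipeline code runs, so pipeline-vs-truth comparisons are genuinely
independent. Same spec + same seed gives byte-identical fixture
directories.

What passing these tests does **not** show about real data: fixture
proteomes have no paralog families, no domain-level partial homology, no
multi-HSP alignments and no compositional bias, so ortholog recovery
rates on fixtures say nothing about BLAST sensitivity on real genomes;
and fixture GPRs are small, so the DNF cap is never approached. The
tests validate the algorithmic contracts, not biological recall.

## Numerical and degenerate-input choices

* Stoichiometric coefficients are R doubles parsed from the source text;
  duplicate detection compares their fixed decimal rendering, which is
  exact for the inputs the formats carry.
* GPR strings are stored verbatim at load time and parsed on demand, so a
  malformed rule fails at evaluation with the reaction id, not at load.
* A reaction that is all protons after stripping raises a degenerate-key
  error rather than silently merging with other empty keys.
* PCA (`pcaProfiles()`) drops zero-variance columns (threshold
  configurable), z-scores the rest, uses `stats::prcomp`, and
  canonicalizes each component's sign so its largest-magnitude loading is
  positive — component signs are otherwise arbitrary and would make
  score-level tests flaky.
* FASTA ids and gene ids are byte-exact and case-sensitive end to end; no
  normalization is applied anywhere, since silent normalization breaks
  provenance.
* Pooled template gene-id collisions: identical-sequence duplicates are
  collapsed, conflicting ones are an error.
* Random template mode samples uniformly without replacement under an
  explicit integer seed, echoed in the draft's `runInfo`, so every random
  draft is reproducible.

## Problem sizes

The test suite and the acceptance script run at deliberately desk-scale
sizes, chosen to exercise every code path with exhaustive or brute-force
oracles: 1,000 random rules over ≤ 6 genes with all 2^n assignments
enumerated; 300-reaction fixtures for selection semantics (≥ 50 reactions
per GPR shape); 100–200-reaction templates for self-recovery; bipartite
homology instances up to 100 × 100 against a quadratic scan; and
10 × 40 block matrices for the PCA separation check. Headline benchmark
numbers against published curated models require the external model
collections and proteomes and are out of scope here.

## Known limitations

* No gap-filling, biomass assembly, media definition or flux simulation:
  drafts are pre-curation artifacts.
* No NOT operator or weighted GPRs; no HMM/profile or nucleotide search.
* SBML support is Level 3 + FBC v2 only (no Level 1/2, no legacy
  notes-field GPRs); JSON support is the COBRA schema.
* Cross-compartment deduplication uses a deterministic relabelling
  heuristic, not full graph isomorphism; exotic multi-compartment
  reactions identical only under a permutation the traversal order does
  not produce will not merge.
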