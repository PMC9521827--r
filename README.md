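# gemdraft

Template-based draft reconstruction of genome-scale metabolic models
(GEMs) in R.

Building a curated GEM from scratch is slow; the fastest route to a first
draft is to transfer reactions from already-curated *template* models. A
reaction is transferred when the query organism has the genes to catalyse
it, which is decided by its gene–protein–reaction (GPR) rule — a Boolean
expression over gene identifiers in which `and` joins the subunits of an
enzyme complex and `or` separates isozymes. `gemdraft` implements this
workflow end to end for bacteria-scale proteomes, together with the
machinery to choose templates and to benchmark the resulting drafts, for
anyone building or evaluating automated GEM reconstructions.

## What it does

1. **Ortholog detection.** A bidirectional similarity search between the
   query proteome and the pooled template proteins, filtered at
   e-value ≤ 1e-20, bit score ≥ 50 and query coverage ≥ 0.75, followed by
   reciprocal best-hit matching: (t, q) is an ortholog pair iff each is
   the other's top-scoring hit. Search engines are pluggable
   (`blastpEngine()` shells out to BLAST+; `exactMatchEngine` and
   `kmerMatchEngine()` are deterministic in-R engines).
2. **GPR evaluation and rewriting.** Each template GPR is parsed
   (`and` binds tighter than `or`), expanded into its minimal disjunctive
   normal form — a set of *isozyme clauses*, each a minimal gene set
   sufficient for the reaction — and rewritten onto query genes. Under the
   strict policy a reaction is kept iff at least one clause is *fully*
   mapped: a single mapped isozyme suffices for an OR rule, a complex
   requires every subunit, and a mixed rule is decomposed by OR and judged
   clause by clause.
3. **Deduplication.** Template collections contain the same
   transformation written several ways: sides swapped (reversibility),
   with or without free protons (protonation state), or duplicated across
   compartments. A canonical reaction key (proton-stripped, orientation-
   normalized sided multiset of metabolites) merges the first two classes;
   compartment copies are kept unless explicitly collapsed. Merged
   variants OR their GPRs and pool their provenance.
4. **Template selection.** Organisms are profiled by presence/absence of
   metabolic COGs (METABOLISM functional categories), compared by Jaccard
   distance, and the k closest organisms supply the templates
   (`"selected"` mode); `"all"` and seeded `"random"` modes are also
   available.
5. **Assessment.** Draft vs reference comparison over all reactions except
   exchange/sink/demand pseudo-reactions, scored with

   P = TP / (TP + FP),  R = TP / (TP + FN),  F1 = 2·P·R / (P + R),

   plus Venn-style overlap-region counts and PCA of model content for
   multi-model comparisons.

Models are read and written as COBRA/BiGG JSON and SBML Level 3 + FBC v2.
A deterministic fixture generator (`generateFixture()`) builds synthetic
template collections with known ground truth, so the whole pipeline is
testable offline.

## Worked example

```r
library(gemdraft)

fx <- generateFixture(fixtureSpec(seed = 1))      # 3 templates, known truth
draft <- buildDraft(fx$templates, fx$queryProteome,
                    engine = exactMatchEngine, draftId = "demo_draft")
draft
#> DraftNetwork demo_draft
#>   reactions:   66
#>   metabolites: 96
#>   genes:       40
#>   GPRs:        66 complete, 0 partial
#>   templates:   tmpl01, tmpl02, tmpl03

assessDraft(draft, fx$reference)
#>   TP FP FN precision    recall        f1
#> 1 61  5  5 0.9242424 0.9242424 0.9242424

head(reactions(draft)[, c("id", "gpr", "gprStatus")], 3)
#>       id                    gpr gprStatus
#> 1 R01001              q_T01G003  complete
#> 2 R01002 q_T01G003 or q_T01G009  complete
#> 3 R01004              q_T01G006  complete
```

The fixture plants 42 ortholog pairs, three duplicate groups and a
reference model that differs from the expected draft by five removed and
five added reactions; the run selects 69 of 78 pooled reactions, merges
the 3 planted duplicates, and the 5/5 planted FP/FN show up exactly in the
confusion counts. Draft GPRs are written in terms of query gene ids
(`q_…`), with the contributing templates recorded per reaction.

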