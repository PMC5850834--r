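---
title: "Orthology-based functional annotation: model, conventions and design choices"
author: "orthomapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthology-based functional annotation: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomapr)
```

## The model

`orthomapr` annotates query proteins by *orthology assignment* rather
than generic homology transfer. The underlying biological assumption is
the ortholog conjecture: genes separated by a speciation event retain
ancestral function more often than genes separated by a duplication, so
a transfer pipeline should identify, per query, the set of genuine
orthologs in a reference database and draw functional labels only from
them.

The pipeline has three stages, each with a small number of conventions
that are worth stating precisely because the literature often leaves
them implicit.

### Stage 1 — seed-ortholog search

The query never enters a gene tree itself; instead its best database
match (the *seed ortholog*) acts as its proxy. The built-in scorer is a
Smith–Waterman local aligner (via `Biostrings::pairwiseAlignment`) with
BLOSUM62 and affine gaps (open 11, extend 1). Raw scores are
transformed with fixed Karlin–Altschul constants $\lambda = 0.267$,
$K = 0.041$ — the standard ungapped-approximation values. These
constants are a *convention*, not a fit: the search engine is a
replaceable component, and parsers for HMMER `domtblout` and
BLAST/DIAMOND tabular format 6 allow externally computed statistics to
be dropped in unchanged.

E-value search spaces: query length × total database residues in
direct mode; query length × the group's residues in the fine phase of
the two-phase mode. The two-phase ("coarse-then-fine") mode scores each
root-level OG by the maximum bit score over its members — a desk-scale
stand-in for a profile-HMM match that preserves the two-phase control
flow; true HMM scoring re-enters through the `domtblout` parser.

Determinism: seed selection uses the total order (bit score desc,
E-value asc, protein id asc), so results are invariant to input order;
there is no worker-count dependence because the implementation is
single-threaded by design (a `--cpu` flag is accepted and validated for
interface compatibility).

Default filters are `max_evalue = 0.001` (the conventional operating
cutoff for this kind of search) and `min_bitscore = 20`.

### Stage 2 — species-overlap orthology

Gene-tree internal nodes are labelled speciation or duplication by
*species overlap*: for an internal node, the overlap score is the
Jaccard index of the species sets of its child subtrees (for
multifurcations, the maximum over child pairs), and the node is a
duplication iff the score strictly exceeds `overlap_threshold`. The
default threshold 0 is the strictest parameter-free reading — one
shared species is enough to imply a duplication. Raising the threshold
can only turn duplications into speciations, never the reverse
(monotonicity, covered by a property test).

A leaf `t` is an ortholog of a seed `s` iff their LCA node is a
speciation. The relation type is read at that LCA: with `m` copies of
the seed's species in the child subtree holding the seed and `n` copies
of `t`'s species in the child holding `t`, the relation is
one2one/one2many/many2one/many2many. Counting uses only the two
relevant species, matching the semantics of ortholog tables.
Same-species leaves whose LCA with the seed is a duplication are
*in-paralogs*; they are reported but never donate annotations.

Rooting convention: a newick string is interpreted as the rooted
topology exactly as written, and the package never re-roots. An earlier
design rejected basal trifurcations as "probably unrooted", but that
heuristic misclassifies legitimate multifurcating roots (which arise
naturally when the species tree has polytomies), so it was dropped;
database builders are responsible for storing rooted trees.

### Stage 3 — scoped transfer

The taxonomic scope restricts donors to the clade where transfer is
most trustworthy. In `auto` mode the scope is the narrowest clade level
that lies on the seed species' lineage **and** hosts an OG containing
the seed, falling back level by level to the root. This is the simplest
mechanism that realises "transfer from the taxonomically closest
orthologs, adjusted per query"; the mechanism itself is our convention.
Orthology is computed on the gene tree of the OG *at the resolved
scope*, so in-paralog exclusion sees exactly the taxa the transfer will
use.

The seed ortholog itself donates annotations (relation `"seed"`)
alongside its selected tree orthologs, all under the same scope and
taxon-exclusion filters. Rationale: the seed is the query's closest
detected ortholog, and excluding it would discard the best donor; the
`status` field still distinguishes `annotated` (at least one tree
ortholog survived selection) from `seed_only`.

GO evidence classes: `experimental` = {EXP, IDA, IPI, IMP, IGI, IEP},
`non_electronic` = everything except IEA, `all`. Transferred terms are
ancestor-propagated through `is_a` and `part_of` edges (the
conventional closure; `regulates` does not propagate). Gene-name
prediction normalises donor names (strip trailing copy-number digits
and separators, upper-case) and takes the majority, breaking ties by
the donor whose species has the deepest LCA with the seed's, then
lexicographically.

## The evaluation framework

Predictions are classified per (protein, term): **TP** if the term lies
in the protein's gold set (experimentally evidenced terms,
ancestor-closed); otherwise **FP** if assigning it to the protein's
taxon violates a taxon constraint (`never_in_taxon` with the query
inside the clade, or `only_in_taxon` with the query outside);
otherwise **uncertain**. Constraints inherit down the term DAG — a
constraint on a parent binds every descendant term — because a child
term logically entails its parent; without inheritance the classifier
would be trivially evadable.

Gold sets are ancestor-closed by default, symmetrically with the
closure applied to predictions, so a method is not penalised as
"uncertain" for predicting a parent entailed by a gold term. The raw
(unclosed) mode is also exposed.

Summaries report the *strict TP-ratio* ΣTP/Σ(TP+FP+uncertain) (any
non-true term counts against the method), the TP/(TP+FP) proportion,
coverage, and per-protein categories (`tp_only`, `mixed`, `no_tp`)
whose proteome fractions sum to the coverage. With zero annotated
proteins the ratios are reported as NA, never as 0.

**F-max** follows the CAFA convention: thresholds 0.01…1.00 in steps of
0.01; per-threshold precision averaged over proteins with at least one
surviving prediction (*partial mode*), recall averaged over all
benchmark proteins with non-empty gold; F-max is the maximal harmonic
mean, reporting the largest threshold attaining it. Unscored
predictions carry score 1 and collapse to a single operating point.
Note that F-max on a fixed grid is invariant to monotone score
rescaling only up to grid resolution; the exact invariance holds when
each run is evaluated at its own operating points, which the test suite
checks that way.

**Functional profiles** map GO terms to abundances by summing gene
abundances over each term's annotated genes (term sets ancestor-closed,
so abundance accrues to parents). Two profiles are compared by
tie-corrected Spearman correlation over the *union* of their term keys
(absent terms count 0 — only terms appearing in either profile enter).
The p-value uses the large-sample t approximation; an exact permutation
option exists for unions of at most 8 terms (8! = 40,320 permutations;
beyond that the enumeration cost is disproportionate for a secondary
diagnostic, and the t approximation is already adequate).

## The synthetic database

`simulateDatabase()` generates the complete study conditions with
recorded ground truth. Defaults (all overridable in `simConfig()`):

| parameter | default | meaning |
|---|---|---|
| `n_species` | 20 | taxonomy leaves; internal nodes up to depth 2 become OG clade levels |
| `branching` | 2–3 | children per taxonomy node |
| `n_families` | 30 | gene families (root-level OGs) |
| `dup_rate` | 0.2 | per-branch, per-lineage duplication probability |
| `loss_rate` | 0.05 | per-branch, per-lineage loss probability |
| `seq_length` | 120 | residues per protein |
| `subst_prob` | 0.03 | per-branch, per-site substitution probability |
| `n_go_terms` | 60 | synthetic GO DAG size (single namespace, 1–2 parents per term) |
| `k_root_terms` / `term_gain_prob` / `term_loss_prob` | 3 / 0.08 / 0.05 | annotation inheritance along the gene tree |
| `model_frac` | 0.3 | fraction of species that are "model organisms" |
| `exp_prob_model` / `exp_prob_other` / `tas_prob` | 0.7 / 0.05 / 0.1 | evidence-code emission (remainder IEA) |

These values were chosen once as a realistic desk-scale caricature of a
curated orthology resource: moderate duplication with rarer loss, ~70%
minimum pairwise sequence identity within families (so seed search is
non-trivial but solvable), a model-organism skew in experimental
evidence, and an IEA-dominated annotation background elsewhere.

What the generator deliberately captures: nested OG levels with induced
subtrees; per-(protein, term) evidence codes; taxon constraints that
the generated annotations satisfy *by construction* (derived from the
realised term usage, `only_in` at the users' LCA clade, `never_in` on
user-free root clades); metagenomic samples with log-normal species
abundances and Poisson read noise, with the gold profile built by the
read-counting construction.

What it does **not** capture — and hence what passing tests do *not*
show about real data: indels and alignment ambiguity (substitutions
only), rate heterogeneity across sites and lineages, horizontal
transfer, gene fusion/fission, annotation errors in the reference
database, incomplete or biased GO curation beyond the simple
model-organism skew, and real GO DAG scale (tens of thousands of terms)
or real taxonomy scale. Loss events are the one adversarial feature
kept on by default: unifurcation collapse after loss is exactly what
makes species-overlap labelling fallible, so the suite asserts exact
recovery only under `loss_rate = 0` and treats recovery under loss as a
measured quantity, not a guarantee.

Determinism: all generation flows from `simConfig()$seed`; identical
configs give byte-identical bundles on disk, which the suite checks by
hashing a full simulate → annotate → benchmark run.

## Numerical and degenerate-input choices

* Hit tie-breaks: bit score desc, E-value asc, target id asc; group
  ties by group id. Gene-name ties: taxonomic proximity, then
  lexicographic.
* Empty inputs: empty query FASTA → header-only output, exit 0; empty
  OG table is a valid database; proteins absent from all OGs are legal;
  an all-extinct family configuration terminates with an informative
  error after a bounded number of redraws.
* `propagate(∅) = ∅`; obsolete terms are dropped from propagation with
  a warning; unknown terms are an error (annotation transfer warns and
  drops instead, since reference annotations may postdate the loaded
  ontology).
* Undefined statistics are NA markers, never silent zeros: TP-ratio
  with no annotations, Spearman rho on constant vectors.
* Validation failures in `loadDatabase()` are collected and reported
  together rather than failing at the first.

## Problem sizes

The test suite and acceptance script run entirely on simulated data at
the sizes chosen for the study conditions: exhaustive tree enumeration
up to 6 leaves (1,069 rooted binary topologies), 200 loss-free families
for recovery, a 20-species / 30-family bundle (~650 proteins) for the
end-to-end transfer checks, 100 random DAGs for closure properties, and
100 random profile pairs for the correlation oracle. These sizes give
exact, enumerable oracles; nothing in the method depends on them.

## Known limitations

* The species-overlap rule with threshold 0 over-calls duplications on
  trees with deep coalescence or contamination; the threshold is
  exposed but there is no adaptive choice.
* Scope resolution requires the root clade level to cover all species;
  a seed species outside every level is a configuration error by
  design.
* The built-in aligner is quadratic per pair and intended for
  desk-scale databases; large-scale use should feed external DIAMOND/
  HMMER results through the parsers.
* KEGG transfer is pathway-level only (no KO/module mapping), and COG
  categories are OG-level by definition.
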