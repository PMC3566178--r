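---
title: "Compiling and analysing protein complex catalogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling and analysing protein complex catalogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexcat)
```

## The problem

Curated collections of human protein complexes (CORUM, HPRD, PINdb and the
like) overlap heavily, both across databases and within a single one: the
same biological assembly is recorded several times with slightly different
member lists. Any analysis that treats complexes as units — deriving
co-complex protein pairs, mapping drugs onto complexes, associating
complexes with diseases, or benchmarking complex-prediction algorithms —
is distorted by this redundancy. `complexcat` compiles a non-redundant
catalogue from such collections and provides the downstream analyses that
a compiled catalogue supports.

## The compilation model

Every complex $C$ receives a **significance score**: the mean semantic
similarity over all unordered member pairs,

$$\mathrm{score}(C) = \frac{1}{\binom{|C|}{2}} \sum_{\{p_i, p_j\} \subseteq C} \mathrm{sim}(p_i, p_j),$$

where $\mathrm{sim}$ is a Gene Ontology biological-process similarity.
Proteins in a genuine complex co-operate in a common process, so a
coherent complex scores high; an arbitrary protein set scores near the
ontology background.

Protein-pair similarity uses the contribution-propagation scheme of Wang
and colleagues. Within the GO DAG, a term's semantics is described by the
**S-values** of its ancestors: the term itself has S-value 1, and an
ancestor's S-value is the maximum over paths toward the term of the
product of edge weights ($w_{is\_a} = 0.8$, $w_{part\_of} = 0.6$, the
measure's canonical constants — the defaults of `go_dag()`). Two terms
are compared through their common ancestors,

$$\mathrm{sim}(a, b) = \frac{\sum_{t \in A_a \cap A_b} S_a(t) + S_b(t)}{SV(a) + SV(b)},$$

and two genes through the best-match average of their term sets: each
term of one gene is matched with its best counterpart in the other, the
two directional means are averaged. Annotations are used as given, without
propagation to ancestors — the propagation is already inside the S-value
machinery. Pairs involving unannotated genes are *excluded* from the
score average rather than scored 0; scoring them 0 would penalize
sparsely annotated complexes for database incompleteness rather than
incoherence. The exclusion count is reported. Singleton complexes and
complexes with no scoreable pair score 0, which ranks them last: they can
be absorbed but never absorb.

Complex overlap is measured by the Jaccard coefficient
$J(A, B) = |A \cap B| / |A \cup B|$. Compilation ranks complexes by
descending score (ties broken by size, then id, so runs are reproducible)
and sweeps the ranking once. For each retained complex, every later
complex with $J$ above the **overlapping threshold** (default 0.5) is
redundant and removed: if $J$ also exceeds the **merge threshold**
(default 0.8) the two are near-identical and the lower-ranked one is
merged in (member union); otherwise the merged set would be arbitrary, so
the lower-scored complex is simply discarded. The growing union is used
for subsequent comparisons (`grow = FALSE` restores comparison against
the original members; both behaviours are defensible and the choice is
exposed).

The two defaults deliberately satisfy
`overlap_thres < merge_thres`: were the assignment reversed, every
redundant pair would exceed the merge threshold and the discard branch
could never fire, so nothing could ever be filtered out.

A single sweep can leave a small residue: a merge enlarges the retained
complex, and the enlarged set can newly exceed the threshold against a
complex already passed over. `passes = 2` (the pipeline default) re-sweeps
once, re-scoring merged complexes when the ontology is supplied; in
practice the second pass clears the residue.

## Downstream analyses

**Co-complex pairs and PPI support.** `cocomplex_pairs()` enumerates all
within-complex protein pairs (each counted once) and `overlap_report()`
computes their percentage overlap with reference protein-protein
interaction sets — the standard external quality check for a catalogue:
compilation should raise the ratio by removing redundant, low-coherence
records.

**Drug-complex network.** A drug connects to a complex when the complex
contains at least one of its targets; the edge remembers which targets
support it. Hub tables are reported twice: raw (edge counts) and
de-duplicated, where each drug-target relationship counts once no matter
how many complexes carry the shared target. The two orderings answer
different questions — raw degree measures reach across the complexome,
de-duplicated degree measures genuine multi-target pharmacology. Note the
two counts are not ordered in general: a drug with two targets inside one
complex has raw degree 1 but de-duplicated degree 2.

**Drug-drug interactions.** Two drugs adjacent to the same complex form a
co-complex drug pair. `ddi_permutation_test()` counts how many known DDI
pairs are co-complex pairs and compares against draws of equally many
distinct random drug pairs. The sampling universe defaults to drugs with
at least one network edge (drugs outside the network can never be
co-complex, and including them would manufacture significance);
`universe = "all"` is available. Random pairs may coincide with known
DDIs — they are a null sample, not a complement. The empirical p-value
uses the add-one convention, bounded below by $1/(\text{reps}+1)$.

**Disease-complex association.** Per-study disease-gene p-values are
combined by Fisher's method ($-2\sum\ln p_i$ against $\chi^2_{2k}$) and
filtered at a cutoff (default $10^{-5}$, always logged — this is the
conventional genome-wide-scan scale and an explicit parameter, not a
constant). A complex of size $n$ with $t$ disease proteins, in a universe
of $N$ catalogue proteins of which $K$ are disease-associated, gets the
upper-tail hypergeometric p-value $P(X \ge t)$ — the observed overlap is
included in the tail, the standard enrichment convention.
Associations with $p < 0.05$ (unadjusted, with an optional
Benjamini-Hochberg switch that is off by default to preserve the
conventional raw cut) are significant. Disease genes outside the
universe are intersected away with a warning. The disease-specific
subnetwork keeps significant complexes with no adjacent drug as isolated
nodes: they mark disease biology not yet reached by pharmacology. Every
(disease, drug) adjacency is a repositioning candidate, with its
supporting complexes listed.

**Evaluating predicted complexes.** A prediction matches a reference
complex when the neighborhood affinity $|P \cap B|^2 / (|P||B|)$ reaches
$\omega$ (default 0.2, the convention of the complex-prediction
evaluation literature; all matched counts depend on it, so it is a
flag). Precision, recall and F-measure come from the matched counts;
Sn/PPV/Accuracy from the reference-by-prediction overlap matrix.
Predicted singletons are dropped by default (their affinity is
degenerate); `min_size = 1` keeps them. A prediction overlapping no
reference complex contributes zero to the PPV numerator and denominator;
if the whole denominator is zero the metrics are reported as 0 with a
warning rather than NaN.

## The synthetic-data generator

Real CORUM/HPRD/PINdb/DrugBank/GWAS snapshots are not bundled; the
generator (`synthetic_config()`, `simulate_bundle()`) produces every
input with planted, manifest-recorded structure:

* **Ontology and annotations** — a rooted random DAG (tree plus extra
  typed edges, all pointing from later to earlier terms, so acyclicity is
  structural). Each true complex owns a 2-term "theme" its members carry
  with probability 0.9, so within-complex similarity separates true
  complexes from random gene sets; background genes get 2-3 random terms
  and 5% stay unannotated to exercise the exclusion path.
* **Redundant raw catalogue** — 50 true complexes of 5-10 members over
  400 genes; 40% are re-emitted as 1-3 copies under pseudo-source names,
  each copy differing by one member added or removed (never crossing a
  Jaccard floor of 0.6). One single-member edit on a size-5-or-larger
  complex keeps the copy within Jaccard $\ge 4/6$ of its original, hence
  detectable at the 0.5 overlap threshold, while either survivor of the
  sweep stays within 0.8 of the truth — which is what makes near-total
  recovery the *expected* outcome rather than a tuned one.
* **PPI set** — co-complex pairs of the true catalogue at probability
  0.5, background pairs at 0.01.
* **Pharmacology** — 120 drugs; targets-per-drug follow a truncated
  discrete power law (exponent 2.2, max 8), mirroring the scale-free
  flavour of real drug-target tables, with 80% of targets drawn from
  complex members so the network is non-trivial. 150 DDI pairs are drawn
  with 4:1 odds in favour of co-complex drug pairs. Each of 5 diseases is
  planted in one true complex: its gene set is the members (10% leak)
  plus 15 random genes, encoded as 1-3 per-study p-values below the
  10^-5 cutoff, with above-cutoff decoys mixed in.

All draws hang off one seed; `write_bundle()`/`read_bundle()` round-trip
the bundle through exactly the text formats the readers consume.

What the generator does *not* emulate: identifier ambiguity across
databases (symbols are opaque strings by design), annotation bias toward
well-studied proteins, correlated study errors in GWAS extracts, and
biological DAG topology beyond random trees. Passing tests therefore
demonstrate algorithmic correctness and calibration on clean planted
structure, not robustness to the pathologies of real 2012-era snapshots.

## Numerical and scale choices

S-values are computed by worklist relaxation with per-term memoisation
(the DAG cache also memoises term-pair similarities, which dominates
catalogue scoring). Ties in max-propagation are value-identical, so no
tie-break is needed. Degenerate inputs are rejected early: empty member
sets, cyclic ontologies, edges to unknown terms, p-values outside
$(0, 1]$, a pair universe too small for the requested number of distinct
draws.

Test and reproduction problem sizes are desk-scale by design: catalogues
of 50-100 true complexes (up to ~200 raw records), permutation tests at
1000 replicates, calibration over 40 generator seeds, exhaustive
hypergeometric verification over all universes $N \le 12$. These sizes
put every planted effect many standard errors from its null while keeping
a full run in seconds.

## Known limitations

* One-pass compilation is order-dependent for equal-score complexes; the
  deterministic tie-break makes it reproducible but not order-free.
* Merged complexes keep the absorber's score within a pass; re-scoring
  happens only between passes and only when the ontology is supplied.
* The druggability baseline `p0` is a modelling input; published
  druggability p-values are not reproducible without the original's
  (unstated) baseline, so the package reports its own.
* No identifier mapping: catalogues mixing symbol namespaces will
  under-merge silently.
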