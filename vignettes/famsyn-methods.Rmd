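---
title: "Family delineation and lineage inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family delineation and lineage inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famsyn)
```

This vignette is the package's account of its method: the model behind
each stage, the parameters that matter, the numerical conventions, and
what the simulation-based validation does and does not establish.

## 1. Pairwise similarity and E-value statistics

Every pair of proteins is compared with an exact affine-gap local
aligner (Smith–Waterman via the Gotoh three-state recurrence, written
in C++). Throughout the package a gap of length $L$ costs
$g_o + L\,g_e$ — the BLAST convention — and the same convention is used
by the global aligner, so local statistics and global
identity/similarity figures are mutually consistent.

The raw score $S$ of the best local alignment between sequences of
lengths $m$ and $n$ is converted to an expectation value by the
Karlin–Altschul formula

$$E = K\,m\,n\,e^{-\lambda S},$$

the expected number of chance local alignments scoring at least $S$.
$(\lambda, K)$ pairs are taken from a built-in table of published
values keyed by (matrix, $g_o$, $g_e$); only supported combinations are
accepted (BLOSUM62 with 11/1 gapped, and ungapped), and an unsupported
combination is an error rather than a silent fallback — wrong
statistics are worse than no statistics. Because scores of hundreds of
residues drive $e^{-\lambda S}$ below double precision, all threshold
comparisons internally use $\log_{10} E$, which stays finite; the
stored `evalue` column may underflow to zero and is never used for
filtering.

Design notes:

* An exact aligner replaces heuristic seeded search. E-values from
  heuristic engines differ in their suboptimal tail, which is why the
  pipeline treats thresholds as order-of-magnitude cutoffs (integer
  exponents), never as exact values to be matched across engines.
* Only the best alignment per pair is scored (single-HSP model);
  sum statistics over multiple segments are out of scope.
* A pair is aligned once with a symmetric matrix, so the two
  directional E-values coincide and the edge weight is well defined as
  their minimum.
* Tie-breaking between equal-scoring alignments is deterministic: the
  first optimal cell in row-major order of the dynamic-programming
  matrix, with traceback preferring substitution over gap-in-subject
  over gap-in-query. Any fixed convention would do; this one is
  documented so outputs are reproducible bit for bit.
* Empty sequences yield a local score of 0 with no spans; the global
  aligner treats an empty input as an error, since percent identity
  over an empty alignment is undefined.

The bulk all-vs-all kernel is a linear-memory, integer-arithmetic
score-only variant of the same recurrence; an acceptance test verifies
that it agrees exactly with the traceback aligner, and both agree with
an independent full-matrix oracle on random sequence pairs.

## 2. Family delineation: constrain, traverse, sweep

The similarity network has proteins as nodes and significant pairwise
similarities as edges. Family extraction is graph traversal:
`constrain(net, x)` keeps edges with $E \le 10^{x}$, and
`traverse(net, seed)` returns the connected component of a seed
protein by breadth-first search (neighbours visited in lexicographic
order, so the visit order itself is reproducible).

`sweep_thresholds()` repeats this across exponents (default
$-30$ to $-12$) and `detect_ranges()` segments the retrieved-count
profile into maximal runs of constant count. Counts are provably
non-decreasing in the exponent (edges are only added), so plateaus —
*clustering ranges* — are the informative structure: a long plateau
means membership is insensitive to the threshold there, a jump means
another group merged in. Range detection uses exact count equality by
default; a `tolerance` argument allows small drift within a range,
since a plateau read off a plot by eye is tolerant of one-or-two
sequence wobbles. The package deliberately does **not** choose "the"
biological threshold: ranges inform a human decision.

`global_clusters()` labels every node with its connected component at
a given threshold, canonicalised to the lexicographically smallest
member ID so that cluster tables diff cleanly across runs. Components
are computed by the package's own BFS core; the test suite checks it
against an independent union-find oracle (and igraph) on hundreds of
random graphs, and checks the refinement property: the partition at a
stricter threshold always refines the partition at a looser one.

## 3. Topology screen

Candidate full-size transporters are screened with a hydropathy
predictor standing in for manual inspection of topology plots:

* Kyte–Doolittle index, sliding window of 19 residues (the classic
  span of a transmembrane helix plus flanks), threshold 1.6.
* A run of window positions at or above threshold supports the residue
  span from the run start plus `pad` to the run end plus
  $w - 1 - \mathrm{pad}$, with $\mathrm{pad} = \lfloor (w-1)/4
  \rfloor$: a qualifying window vouches for its central half. This
  keeps adjacent helices separated by short loops from bleeding into
  one another while still reporting realistic helix lengths.
  Overlapping spans are merged; spans longer than $2 \times$ the
  maximum are split at the interior hydropathy minimum nearest the
  span centre (nearest-centre, because on a flat plateau the global
  minimum is degenerate and an end-biased cut would shave one end
  repeatedly); spans longer than the maximum are trimmed centred;
  spans shorter than the minimum are dropped. Accepted lengths default
  to [17, 25] residues.
* A sequence is **full-size** when its length reaches 490 residues
  *or* its predicted span count reaches the expected 14 minus a slack
  of 2. The disjunction rescues short sequences with complete
  topology, and the slack absorbs predictor noise; both constants are
  arguments. The screen is monotone: adding residues or spans never
  demotes a full-size call.

The output carries a `method` attribute flagging the predictor as an
automated stand-in; borderline calls deserve manual review exactly as
in the original visual procedure.

## 4. Global alignment statistics

Per-cluster identity/similarity tables use true-global
Needleman–Wunsch with end gaps penalised and the needle default
penalties (gap open 10.0, extend 0.5, BLOSUM62). Identity is identical
columns over the full alignment length; similarity additionally counts
substitutions with a positive matrix score; gap columns count in the
denominator only. End-gap penalisation matters: an N-terminal
extension on one member then appears as a leading gap run and lowers
identity, which is the informative behaviour when comparing, say, a
full-length protein with a truncation of itself.

For each cluster with at least two members the table reports both the
minimum and the mean pairwise identity and similarity — both, because
a single summary number hides whether a cluster is tight or has one
divergent member. Singleton clusters print as `-`.

## 5. Synteny and lineages

The lineage criterion: two query genes assigned to the same sequence
cluster belong to one lineage if their neighbourhood windows share at
least one pair of *distinct* genes from one sequence cluster.

Conventions and their rationale:

* Windows are 15 genes each side (`W = 15`), counted in gene-order
  ordinals, never base pairs, and never crossing a contig boundary.
  Strand is ignored: gene order, not orientation, carries the signal.
* Neighbour homology uses the conservative E-30 clustering, limiting
  false shared pairs; edges found only under the relaxed E-15
  clustering are kept but tagged `relaxed`, so a curator can weigh
  them separately.
* The two connecting neighbours must be distinct genes. A gene that
  physically sits in both windows (overlapping windows of nearby
  queries) is not evidence of *conserved* neighbourhood, and this rule
  is also what makes unclustered neighbours (singleton clusters)
  incapable of forming evidence.
* Evidence whose shared cluster is the query cluster itself is
  excluded by default (`exclude_query_cluster`): tandem arrays of the
  query family would otherwise certify their own synteny.
* Query pairs within one species are compared as well as pairs across
  species — within-species paralogs can share a lineage — with a
  `heterospecific_only` switch for the stricter reading.
* Each evidence row carries the three strength criteria (closeness,
  pair E-value, shared-cluster size); `edge_report()` sorts rarest
  cluster first, then closest, which is the order a curator should
  read them in. Support counting is exhaustive: one physical
  neighbour may contribute to several pairs, and no minimum support is
  imposed — thresholds are the analyst's to apply to the report.
* Lineages are connected components over the query set; queries with
  no edge become singleton lineages. Sublineage delineation (and HGT
  interpretation of lineage discontinuities) remains a curation step;
  the edge report and the GraphML export with edge attributes are the
  material for it.

Query grouping uses the conservative clusters, not the relaxed ones:
at E-15, related families merge into supergroups, and two distinct
families that happen to lie within one window of each other would
otherwise be joined into a single "lineage" through their shared
neighbourhood.

## 6. Trees

Distances from a consumed multiple alignment (the package does not
align): per pair, columns with a gap in either sequence are skipped;
$p$ is the mismatch fraction and the Poisson-corrected distance
$-\ln(1-p)$ (capped, default 10, when $p \to 1$). These simple models
replace likelihood-based protein distances deliberately: the package's
trees serve cluster-composition work, and topology is what the
validation checks — branch lengths under richer substitution models
are out of scope. Neighbor-joining is delegated to the standard
implementation in `ape`, wrapped to clamp negative branch lengths to
zero with the clamped deficit recorded as an attribute. On additive
matrices NJ is exact; the tests verify Robinson–Foulds distance zero
and recovery of the generating path metric on random 10-taxon trees.
Rooting is manual, on the branch subtending a chosen outgroup leaf.

## 7. The simulator: what it emulates, what it does not

`simulate_universe()` grows an ancestral genome — one root copy per
marker family interleaved with filler genes, each filler a single-copy
family of its own — down a species tree (random coalescent scaled to
height 1, or user-supplied newick). Per branch of length $t$:

| process | model | default |
|---|---|---|
| substitution | per-site replacement prob. $1 - e^{-\sigma t}$, replacement drawn from background frequencies | $\sigma = 0.3$ |
| loss | per-gene prob. $1 - e^{-\mu t}$ | $\mu = 0.01$ |
| duplication | per-gene prob. $\delta t$; tandem with prob. 0.5, else relocated | $\delta = 0.01$ |
| HGT | Poisson($h t$) insertions copied from a contemporaneous genome in another clade | $h = 0.05$ |
| WGD | duplicate all genes on configured branches, keep each with prob. $\rho$ | off; $\rho = 0.5$ |
| inversion | Poisson($\iota t$) tracts, geometric length | $\iota = 0.2$, mean 4 |

Marker proteins are built as 14 hydrophobic stretches of 21 residues
joined by hydrophilic loops with terminal tails (500 residues total),
so they exercise the topology screen; fillers are 150-residue
background-frequency sequences. Fillers evolve exactly like markers —
they must, because synteny evidence quality depends on the sizes of
the neighbour clusters they form. These defaults are the package's
gentle validation regime: 8 species, 4 marker families, 40 fillers per
contig, 2 contigs, divergence deep enough that E-values span the
sweep range yet family membership at E-30 stays unambiguous.

Ground truth: each gene's *family* is its root family; its *lineage*
is the root copy — or HGT insertion — its history traces back to.
Duplication and WGD copies inherit the parent's lineage (a paralog
pair retained in its neighbourhood context is one lineage, as with
ohnolog pairs in post-WGD yeasts); an HGT copy founds a new lineage in
the recipient clade, which is precisely the discontinuity signature
the synteny method exposes. The event log records every birth, loss
and rearrangement, and a test verifies that every extant gene's
lineage label resolves to a root copy or a logged HGT insertion.

Simplifications, stated plainly: substitution is i.i.d. across sites
(no rate heterogeneity, no indels — family members stay equal length,
which is also what lets the tree stage consume simulated "alignments"
directly); HGT donors are drawn from already-simulated genomes in
other clades rather than from a strict time slice; HGT transfers the
gene alone by default (`hgt_with_context` transfers a one-gene flank
block instead); intergenic distances are uniform. Consequently,
passing the simulation-based tests shows the *inference machinery* is
correct under the stated generative model — it does not show
robustness to alignment artefacts, rate variation across sites, or
assembly fragmentation in real data.

Determinism: one seed drives everything; identical configuration and
seed reproduce every output byte for byte, and the test suite asserts
it.

## 8. Validation scales

The test suite validates: traversal/clustering against a union-find
oracle on 100 random graphs (up to 200 nodes, edge densities 0.01 to
0.2); sweep monotonicity and partition refinement on 20 random
networks with 5 seeds each; local and global alignment scores against
brute-force dynamic programming on 50 random pairs each (length up to
60); NJ on 100 random 10-taxon additive matrices; shared-pair
enumeration against the exhaustive oracle on 1,000 random window
pairs; exact lineage recovery on event-free simulations; and the full
pipeline on five simulated universes at the default regime, requiring
pairwise precision and recall of at least 0.9 against truth lineages
and adjusted Rand index of at least 0.9 against truth families. These
sizes keep the whole suite in the low minutes on one CPU while leaving
each property's failure modes (ties, empty windows, contig edges,
saturated distances) well covered.

`scripts/acceptance.R` re-runs the pipeline end to end on three
replicate universes and writes the measured recovery metrics, topology
screen fraction, sweep plateau count and NJ recovery rate as JSON;
the README shows how to invoke it.

## 9. Known limitations

* E-values are single-HSP Karlin–Altschul; no composition-based
  adjustment. Cross-engine E-value comparisons are meaningful only at
  order-of-magnitude resolution.
* The topology predictor is a hydropathy heuristic; it reports no
  inside/outside orientation and is not a substitute for HMM-based
  predictors when topology itself is the question.
* Lineage inference degrades gracefully but measurably when gene order
  is heavily rearranged or when a genome is assembled in many short
  contigs (windows truncate at contig ends).
* No automated sublineage cutting, no automated HGT calling, no
  bootstrap support on trees: these are curation steps by design.
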