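---
title: "Methods: inferring ancestral linkage groups and karyotype evolution"
author: "karyolg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring ancestral linkage groups and karyotype evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chromosome-level genome assemblies of slowly rearranging animal lineages
retain blocks of genes that have co-resided on one chromosome since their
deep common ancestor. These blocks — ancestral linkage groups — behave as
heritable characters: chromosome fusions merge them, fissions split them,
whole-chromosome duplications copy them, and inter-chromosomal
translocations slowly erode them one gene at a time. karyolg infers such
groups from ortholog placements across several genomes, reconstructs the
karyotype at every internal node of a dated species tree, calls the
per-branch rearrangement events, and estimates the background translocation
rate. A rearrangement simulator with an exact event ledger closes the loop:
every inference step is validated against synthetic data with known truth.

# Model and assumptions

The unit of observation is a *universal single-copy ortholog*: an ortholog
group with exactly one member in every analyzed genome. For genomes
$g = 1, \dots, G$ each such ortholog $o$ has an assignment vector

$$v_o = (c_{o1}, \dots, c_{oG}),$$

where $c_{og}$ is the chromosome of genome $g$ carrying $o$'s member. The
central assumption is that chromosomes are conserved wholesale: two
orthologs that were linked in the last common ancestor have identical
assignment vectors unless a translocation moved one of them. Fusions and
fissions change $c_{og}$ for *entire groups at once*, so they preserve
vector-class structure; only translocation noise breaks it. This is the
regime of slowly evolving macrosynteny; the method is not suitable for
lineages with pervasive genome shuffling, where vector classes dissolve.

Further assumptions:

* the species tree is known, rooted, bifurcating and dated (branch lengths
  in My);
* orthology is given or derivable from reciprocal similarity scores;
* gene order *within* a chromosome is free to change (inversions and local
  shuffling are ignored except by the mixing diagnostic);
* duplicated chromosomes are visible as two-copy ortholog groups.

# Algorithms

## Orthology (`mutualBestHits`, `chainToGroups`, `filterUniversalSingleCopy`)

From pairwise similarity scores, a pair $(a, b)$ is kept iff $b$ is $a$'s
unique top-scoring target and vice versa; a tie at the top removes the gene
entirely rather than picking arbitrarily. MBH pairs over all genome pairs
form a graph whose connected components are candidate ortholog groups, with
ids assigned by the sorted member list so results are independent of input
order. Groups are then split into the universal single-copy set (one copy
in every genome — the inference markers) and the duplication-evidence set
(two copies in exactly one genome, one elsewhere), which feeds the
duplication-vs-fission classifier.

## Linkage-group inference (`clusterLinkageGroups`)

Orthologs are grouped by exact identity of their assignment vectors. A
vector class with at least `minSupport` members (default 5) seeds a linkage
group; classes are processed in order of descending size so the numbering
1..L follows descending support deterministically. Every remaining ortholog
is attached to a seeded group iff its vector deviates from exactly one
group's consensus in at most $\lfloor \epsilon G \rfloor$ slots (default
$\epsilon = 0.05$; with $G = 7$ genomes that is 0 slots, i.e. strict).
Orthologs with no unique near-match form the *noise set* — these are the
translocation candidates that the rate estimator consumes, not discarded
data.

`minSupport` is an absolute count; on very small or noise-dense inputs,
strays that share a source and destination chromosome can themselves reach
`minSupport` and appear as spurious extra groups. With realistic marker
counts (hundreds per chromosome) and noise at the few-percent level this
does not occur; the test suite covers the failure mode explicitly.

## Chromosome homology test (`testChromosomeHomology`)

For a genome pair, each chromosome pair $(a, b)$ with $n_a$ and $n_b$
placed orthologs out of $N$ total and $s$ shared is scored with the
upper-tail hypergeometric probability

$$p = P(X \ge s), \quad X \sim \mathrm{Hypergeom}(N, n_b, n_a),$$

BH-adjusted across all chromosome pairs of the genome pair; significance is
called at $q \le \alpha$ (default 0.05). The suite checks these p-values
against literal subset enumeration.

## Ancestral states and events (`reconstructStates`, `callEvents`)

Each unordered linkage-group pair $(i, j)$ becomes a binary character:
1 in a tip iff both groups sit on the same consensus chromosome there.
Characters are polarized with Fitch small parsimony (down-pass
intersection/union, up-pass; root ambiguity resolved toward 0 = unfused, a
deliberately conservative choice for deep fusions), or alternatively Dollo
(each fusion gained once). A node's chromosomes are the connected
components of the graph on groups whose edges are the pairs reconstructed
as fused at that node — so a three-way fusion is one chromosome, not three
pairwise ones.

Comparing each parent/child pair of states yields events: a child
chromosome uniting $k$ parent chromosomes is decomposed into $k - 1$
pairwise FUSION steps sharing one merge id (minimum event count); a parent
chromosome split across child chromosomes is a fission candidate. A fusion
is flagged a *synapomorphy* when its cross-pairs are fused in every tip
below the branch and in none outside — the grouping-character notion of
shared-derived.

## Duplication vs fission (`classifyDupFission`)

A linkage group seen on two chromosomes of one genome is ambiguous: fission
partitions the members (single copies), duplication doubles them (one copy
per product). The call is DUPLICATION iff the fraction of the group's
members that carry two copies split across two chromosomes reaches
`dupThreshold` (default 0.5 — halfway between the noiseless expectations of
0 for fission and 1 for duplication); with no informative members it falls
back to FISSION with a warning.

## Mixing diagnostic (`mixingIndex`)

For a fused chromosome carrying $n$ markers with group labels of sizes
$n_i$, the observed number of heterologous adjacent pairs is divided by its
exact expectation under a uniformly random label permutation,

$$E = (n - 1)\left(1 - \frac{\sum_i n_i (n_i - 1)}{n (n - 1)}\right).$$

An index near 0 means intact ancestral blocks (a recent or translocation-
poor fusion); near 1, full interleaving. The `well_mixed` flag at index
$\ge 0.5$ is a reporting convenience, not a test.

## Translocation rate (`nonsyntenicFraction`, `translocationRate`)

For a genome pair, an ortholog is non-syntenic iff its chromosome differs
from its group's consensus in either genome. Noise-set orthologs are first
attributed to the group with the unique smallest Hamming distance to their
vector, so a gene moved only in genome A is charged to A and does not
inflate every other pair; ambiguous strays conservatively count against
both genomes of the pair. The rate is $r = c / t$ with $c$ the non-syntenic
fraction and $t$ the divergence time (per-lineage normalization $c / 2t$ is
available). This treats every off-consensus marker as one translocation —
adequate while $c \ll 1$; at saturation it underestimates.

# The simulator

`makeAncestor` lays out one chromosome per ancestral linkage group with
evenly spaced genes whose ids double as ortholog-group ids.
`evolveGenomes` walks the tree in preorder applying, per branch: scripted
events (operands named by ancestral group and resolved against the genome
*at event time*, so chained fusions work), Poisson background events, and
on terminal branches a translocation of `round(tipNoise * nGenes)` random
genes. Five event types are implemented: FUSION (with an interleaving
parameter $\pi$: 0 = block concatenation, 1 = full shuffle of the merged
order), FISSION at a breakpoint, whole-chromosome DUPLICATION (paralog ids
suffixed `.2`), TRANSLOCATION of $k$ genes, and within-chromosome SHUFFLE.

Every applied event is written to a ledger *with its realized outcome*
(gene orders, move destinations), so `replayLedger` reproduces all tip
genomes byte-identically without touching the RNG — the ledger is the
ground truth the suite replays. Each branch draws from an RNG substream
seeded from the global seed and the child label, so editing one branch's
script leaves the others' outcomes unchanged.

What the simulator emulates is the *karyotype-level* signal of real data:
chromosome counts, linkage-group co-residence, paralog copy number, and
stochastic marker leakage. It does not model sequence evolution, assembly
error, missing annotation, or gene family turnover; real inputs bring those
on top, which is why thresholds (`minSupport`, $\epsilon$) exist at all.

# The bundled scenario

`chitonScenario()` encodes the package's reference radiation: seven genomes
(a gastropod and a bivalve as outgroups, five chitons) descending from a
20-group ancestor, 4729 markers with strictly decreasing group sizes (so
the inferred support-ordered numbering coincides with the ancestral one on
noiseless runs). The scripted route: three stem fusions shared by all
chitons (4+16+18, 7+10, 8+9 — chiton ancestor 1n = 16), one further fusion
(1 onto 4+16+18) below the crown clade, lineage-specific fusions bringing
one deep lineage to 1n = 11 and another genome to 1n = 13, one fusion
(11+17) in the lineage whose variant also carries the optional
fused-then-duplicated chromosome, and an Acanthochitona-like ancestor at
1n = 10 whose two descendants each reach 1n = 8 via two *different*
fusions, 23 My apart. Groups 19 and 20 are never operands — a built-in
never-fused control. Fusions not pinned down by published chromosome
counts are this scenario's own choices and were picked to avoid
homoplastic pair-characters, so parsimony reconstruction provably matches
the ledger.

The scenario's duplication is optional (`duplication = TRUE`) because a
full-chromosome duplication removes its residents from the universal
single-copy marker set by construction; the default, fusion-only ledger is
what the 20-group recovery analysis runs on, while the duplication variant
exercises the classifier on truth-mapped markers.

# Numerical choices and problem sizes

* `minSupport = 5`: small enough to keep real ~100-marker groups, large
  enough that coincidental vector classes (expected size 1–2) never seed.
* $\epsilon = 0.05$: at most one deviating genome per 20 — with fewer than
  20 genomes this means exact matching, which is the honest default when a
  single translocation already breaks co-residence.
* $\alpha = 0.05$ with BH correction within each genome pair.
* `dupThreshold = 0.5`: midpoint of the two noiseless expectations.
* Reference problem size: 7 genomes x ~4.7k markers runs the full pipeline
  in a few seconds; the clustering is $O(\text{orthologs} \times
  \text{groups})$ and the character matrix has $\binom{L}{2}$ columns, so
  hundreds of linkage groups would need a sparse reformulation.

# Limitations

* Exact-identity clustering assumes translocation noise well below the
  within-group marker count; heavily shuffled genomes need the
  hypergeometric test output instead.
* Fitch parsimony with root-preference-0 can misplace a fusion that is
  immediately followed by reversal, and Dollo forbids reversal entirely;
  both modes are reported so disagreement is visible.
* The rate estimator assumes at most one move per marker per pair
  (unsaturated regime) and a correct divergence time.
* The synapomorphy flag requires perfect presence/absence across tips; one
  noisy tip consensus demotes a true synapomorphy to plain FUSION (counts
  are robust to this; the flag is strict by design).
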