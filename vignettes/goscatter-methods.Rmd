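---
title: "Methods: redundancy reduction and semantic-space embedding of GO term lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: redundancy reduction and semantic-space embedding of GO term lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`goscatter` summarizes a list of enriched Gene Ontology terms in four
stages: (1) clean the list against a specific ontology release, (2) score
all pairwise semantic similarities, (3) partition the list into groups of
similar terms and pick one representative each, (4) embed the
representatives in two dimensions and draw them. This vignette documents
the model behind each stage, the tunable parameters, the numerical choices,
and what the bundled synthetic-data generators do and do not emulate.

# Identifier cleaning and version awareness

GO identifiers rot: terms become obsolete, merge into others, or survive
only as `alt_id` aliases. Running a visualization against a different
ontology release than the enrichment analysis silently shifts both the
term set and the similarity structure, so every run records the loaded
`data-version` in its log and resolves each input identifier:

1. `alt_id` aliases are canonicalized first (the alias map is part of the
   ontology, and an alias may point at an obsolete term whose replacement
   must then be followed);
2. obsolete terms are updated through their `replaced_by` pointer,
   followed to a fixed point with a cap of 5 hops — chains occur in old
   inputs when a replacement itself later became obsolete, and the cap
   guards against pathological loops in hand-edited files;
3. obsolete terms without a replacement, and identifiers absent from the
   ontology, are dropped — each with its own log line, never silently.

Duplicate identifiers (including duplicates created by updates) collapse
onto the smaller p-value, with a warning. p-values of exactly 0, which some
enrichment tools emit for underflowed tests, are clamped to the smallest
positive p-value in the list so that log-scaling and the 50% ratio rule
below stay defined; a p-value of 0 is treated as data to be rescued rather
than rejected, whereas negative values or values above 1 are malformed and
fatal.

# Information content

For term $t$, $IC(t) = -\ln(n_t / N)$, where $n_t$ counts annotation lines
mapping to $t$ *after propagation*: every annotation contributes once to
the annotated term and once to each of its `is_a`/`part_of` ancestors,
using set semantics so diamond-shaped paths never double-count. $N$ is the
number of annotation lines in the corpus.

Two deliberate choices:

* **Propagation before frequencies.** Raw (unpropagated) frequencies do
  not guarantee that parents are at least as frequent as children, which
  the broad-term rule and the boundedness of Lin similarity both rely on.
  With propagation, `frequency(parent) >= frequency(child)` holds along
  every edge, hence `IC(parent) <= IC(child)`.
* **Natural logarithm.** The logarithm base only rescales IC values; Lin
  similarity is a ratio of ICs and is base-invariant (asserted by a test
  that recomputes similarities from a log10-scaled table). Reported IC
  values use $\ln$.

The same annotation-line denominator is used everywhere, including the 5%
broad-term rule. A per-protein denominator (counting distinct annotated
gene products rather than annotation lines) is a defensible alternative
but requires per-protein bookkeeping across the corpus; the annotation-line
convention keeps one denominator for both IC and the broad-term rule, and
is documented here because the two conventions can classify borderline
terms differently.

Terms present in the user list but absent from the annotation corpus have
undefined IC. They are never dropped: they score similarity 0 against
everything (including themselves), stay singletons, and are flagged in the
log. Dropping user data because a corpus is stale would defeat the tool's
purpose.

# Lin similarity

$$\mathrm{sim}(t_1, t_2) = \frac{2\,\max\{IC(a) : a \in \mathrm{anc}(t_1)
\cap \mathrm{anc}(t_2)\}}{IC(t_1) + IC(t_2)}$$

Ancestor closures are **reflexive** — a term is its own ancestor — so a
term with positive IC has self-similarity exactly 1. When the denominator
is 0 (both terms are corpus-saturated namespace roots with IC 0) the score
is defined as 0: two roots share no information. Only `is_a` and `part_of`
edges are traversed; `regulates`-type relations cross subtree boundaries
and are not subsumption, so they are ignored at parse time.

Terms from different namespaces are never compared — they share no
informative ancestor, so every cross-namespace similarity would be 0 and
would only distort the embedding. The pipeline splits the cleaned list by
namespace and produces one scatterplot per namespace (`_bp`, `_mf`, `_cc`
suffixes). Matrices are computed densely; input lists are
$O(10^2)$ terms, so sparse machinery would cost more than it saves.

# Grouping and representative selection

The grouping pass iterates over the cleaned list **in input order**. Each
term whose maximum off-diagonal similarity is at or above the threshold is
unioned (disjoint-set) with its most similar partner, ties broken by
earlier input position. After each union the incoming side's current
representative contests the target group's current representative through
the four-step rule (broad-term frequency ≥ 5%, then the 50% p-value ratio,
then ancestry, then incumbency). Design points the method itself leaves
open, resolved here:

* **Bridging merges.** When a later term's best partner links two existing
  multi-term groups, the groups merge and their two current
  representatives contest. Keeping the contest between representatives
  (rather than re-running it over all members) preserves the incremental,
  order-deterministic character of the pass.
* **"50% higher"** means `p_hi >= 1.5 * p_lo` on the parsed values, with
  exactly equal p-values falling through to the ancestry rule.
* **"Parent term"** in the ancestry rule means any ancestor through
  `is_a`/`part_of`, not only a direct parent — consistent with the closure
  used everywhere else.
* **Incumbency.** The final tie-break returns the first argument of the
  contest, which during grouping is always the group's current
  representative. Identical inputs therefore always produce identical
  partitions and representatives.

The partition is invariant in two useful ways, both under test: groups are
disjoint and covering at every threshold, and the number of groups is
non-decreasing in the threshold (raising the cutoff can only remove union
edges). The grouping is also provably identical to the connected components
of the functional graph $\{i \to \mathrm{argmax}_j \mathrm{sim}(i,j) :
\max_j \mathrm{sim}(i,j) \ge \tau\}$, which the test suite exploits as an
independent oracle.

# Embedding

Representatives are embedded by metric MDS on the dissimilarity
$d = 1 - \mathrm{sim}$, the simplest monotone transform that maps the
similarity range onto a bounded dissimilarity in $[0, 1]$. The solver is
SMACOF majorization (Guttman transform, unit weights) run to a relative
stress change of $10^{-10}$ or 300 iterations; reported stress is
normalised stress-1.

The configuration is initialised by classical scaling (`cmdscale`). This
choice does real work: it is deterministic and permutation-equivariant, so
the embedding needs no randomness at all by default, and shuffling the
input order changes the result only by a rigid motion (pairwise embedded
distances agree to $10^{-6}$, under test). Seeded random restarts with
best-stress selection are available (`restarts` argument) for
pathological configurations, but they are off by default because a
randomly-initialised winner cannot guarantee the permutation invariance.
The seed is recorded in the log either way. $n = 1$ and $n = 2$ use closed
forms (the origin; a symmetric pair on the x-axis at exactly distance $d$)
to avoid solver degeneracy.

Only relative positions in the embedding are meaningful; the axes are
list-specific and carry no functional interpretation.

# Plotting

Defaults: circles colored by log10 p-value on a gradient palette
(`viridis`), sized by member count over a 3–12 mm range, with the 10 most
significant representatives labeled by number and their descriptions
printed below the plot. Significance ranking is by the representative's own
p-value (the circle encodes the representative's significance, not the
group minimum), ties broken by group order. Palette names resolve
case-insensitively against the `hcl.pals()` and RColorBrewer registries;
an unknown name fails fast with the list of valid names. Identifier and
description label styles use ggrepel's automatic placement with a fixed
seed and arrows. The exact dataframe behind every figure is written as TSV
so plots can be rebuilt, restyled, or combined downstream; the figure
device is chosen by extension (png/pdf/svg/tiff), with svg rendered through
the cairo device.

# Synthetic study conditions

The generators produce miniature versions of the three real inputs:

* **Ontology**: 150 live terms per namespace, each non-root term with 1–3
  parents among earlier terms (acyclic by construction), 25% of edges
  `part_of`, 10% additional obsolete stanzas of which half carry
  `replaced_by`, 5% `alt_id` aliases. A few hundred terms is enough to
  produce multi-level DAGs with diamonds while keeping every test
  brute-forceable.
* **Annotation corpus**: 5000 lines, sampled with Zipf weight
  $\mathrm{rank}^{-1}$ over terms ranked most-specific-first. The skew
  reproduces the qualitative IC structure of real corpora — saturated
  roots, rare leaves — which is what exercises both directions of the
  broad-term rule.
* **Enrichment lists**: 60 terms (the scale of a typical filtered
  enrichment table), p-values log-uniform on $[10^{-8}, 0.05]$ — i.e.
  spanning the significance range a tool reports after cutoff filtering —
  with obsolete and duplicate identifiers injected to exercise cleaning.

These conditions are what the test suite and `scripts/acceptance.R` run
at; smaller ontologies (20–80 terms) are used where a property is checked
against a brute-force oracle over many random replicates. The generators do
**not** emulate the real GO's topology (fan-out, depth profile, inter-term
annotation correlations) or GOA's evidence-code and taxon structure, so
green tests demonstrate correctness of the algorithms, not fidelity of any
particular biological summary. Reproducing published group counts requires
the actual pinned GO and GOA releases, which are multi-gigabyte downloads;
the acceptance suite contains that reproduction and runs it when the
reference data are provided locally.

# Known limitations

* Per-annotation-line counting (no per-protein deduplication, no
  evidence-code or taxon filtering) can inflate frequencies of heavily
  re-annotated proteins.
* Only Lin similarity is implemented; Resnik, Jiang–Conrath, or Wang
  measures would slot into the same matrix interface but are out of scope.
* Grouping depends on input order where similarities tie exactly; the
  order rule makes this deterministic but means row-shuffled inputs can
  group tied terms differently.
* The embedding is a 2D compression of an $O(n^2)$ similarity structure;
  at stress above ~0.3 apparent proximity should be read together with the
  group-membership TSV rather than alone.
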