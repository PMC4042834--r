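---
title: "Summarizing gene lists with informative ontology terms: models and design choices"
author: "GOthemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summarizing gene lists: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A list of genes from a genome-scale experiment is annotated by hundreds to
thousands of Gene Ontology terms, most of them so specific that each covers
one or two genes. Enrichment analysis inherits that fragmentation; mapping
to a GO slim collapses everything onto a few near-root terms. `GOthemes`
navigates between the two extremes: it partitions the list into
non-disjoint subsets whose members are *functionally coherent*, and labels
each subset with a summarizing term chosen to balance generality against
the information lost by abstraction.

# Information loss on ontology edges

The biological_process ontology is represented as a rooted DAG of IS_A
edges (other relation types are counted and ignored). Annotations obey the
true-path rule: a gene annotated to a term is implicitly annotated to every
ancestor, implemented by propagating direct gene (and document) sets up the
DAG. Terms with no annotated gene anywhere beneath them are pruned, with
edges re-closed through removed terms so every retained term still reaches
the root.

Two metrics quantify the information lost when a child term $t_c$ is
collapsed into a parent $t_p$:

**Information content (IC).** $P(t)$ is the number of annotation instances
— distinct (gene, term) pairs — in $t$'s subgraph, divided by the total;
$IC(t) = -\ln P(t)$ and the edge weight is $|IC(t_c) - IC(t_p)|$. Because
instances are propagated, IC is monotone along root-to-leaf paths and every
weight is nonnegative; the absolute value makes the orientation of the
printed difference irrelevant. Instances are counted as distinct
(gene, term) pairs rather than raw annotation lines, so duplicate evidence
codes for the same association do not inflate the counts; and they are
propagated rather than direct, because interpreting the IC difference as a
*loss* requires monotonicity.

**Information bottleneck (IB).** Each term carries a word profile: token
counts from its name/definition, the names/definitions of its descendants,
and the titles/abstracts of all documents in its subgraph. Text is
lowercased, tokenized on non-alphanumeric boundaries, stopword-filtered
(Snowball list) and Porter-stemmed — a fixed deterministic pipeline frozen
by golden tests. The edge weight is

$$\delta I(t_c) \;=\; \frac{|t_c|}{|t_{root}|}\cdot\frac{|t_c|}{|t_p|}
  \cdot D_{KL}\!\left(p(w\mid t_c)\,\|\,p(w\mid t_p)\right),$$

with $|t|$ the self-inclusive descendant count, so $P(t_{root}) = 1$ and
leaves have $|t| = 1$ — the self-inclusive convention avoids division by
zero for leaf children. Natural logarithms are used throughout, so all
weights are in nats. Two details keep the divergence finite without
smoothing: a term's own name tokens are treated as a pseudo-document that
propagates to ancestors exactly like real documents, guaranteeing that a
child profile's support is contained in its parent's; and the divergence is
evaluated on the union vocabulary of the pair with the convention
$0 \ln 0 = 0$, which is equivalent to any larger global vocabulary. An
optional additive pseudocount (default 0) and a symmetric
Jensen–Shannon-style variant (mixture weights $|t_c|/|t_p|$,
$1-|t_c|/|t_p|$) are available behind arguments; the shipped weight is the
single KL term as defined above.

# The coherence statistic

The coherence of a gene set is the total weight $y_s$ of a Steiner tree
connecting the set's *direct* annotation terms, with IS_A edges treated as
undirected. Steiner trees are NP-hard; the package uses the classical
metric-closure 2-approximation (minimum spanning tree of the terminal
distance closure, expanded to shortest paths, followed by a spanning-tree
and leaf-pruning cleanup). All ties — shortest paths, spanning-tree edges,
merge candidates — break lexicographically by term id, making every
statistic deterministic. The test suite verifies against an exhaustive
enumeration oracle that the heuristic's weight lies between the optimum and
twice the optimum.

On the *augmented* graph, an extra edge joins every pair of terms sharing
$|g_{ij}| \ge 1$ directly annotated genes, with weight $d_{P5}/|g_{ij}|$,
where $d_{P5}$ is the 5th percentile (linear interpolation, zeros included)
of the base edge weights. This discounts the redundancy of one gene being
annotated to distinct but related terms by different curators: the tree can
hop between such terms for a near-minimal price instead of paying the full
ontology path. Sharing is computed on direct annotations — propagated
sharing would connect every term to its ancestors and erase the geometry.
Augmentation edges never increase the statistic (the augmented graph is a
supergraph), an invariant the tests assert.

# The null model

Functional coherence is judged against size-matched random gene sets drawn
uniformly, without replacement, from the annotated universe (genes with at
least one direct annotation in the pruned graph). The default size grid is
$\{5,10,\dots,50\} \cup \{60,80,\dots,200\}$ — finer where small-set
statistics change fastest — with 100 replicates per size; both are
configurable, and all draws derive from a single seed. The statistic's mean
and variance as functions of set size are smoothed by Nadaraya–Watson
regression with the Gaussian kernel $w_n(n_i) = \exp(-(n_i-n)^2/h)$,
bandwidth $h = 10$ as printed (the bandwidth enters unsquared; the kernel is
evaluated exactly as defined). An observed statistic maps to the lower-tail
Gaussian probability $\Phi((y_s-\hat\mu(n))/\hat\sigma(n))$: a *small*
p-value means less information loss than random sets of the same size,
i.e. coherence. Query sizes outside the trained grid extrapolate with a
warning; a zero estimated variance is an error rather than a silent
infinity. Calibration is checked by scoring fresh random sets and testing
the p-values for uniformity (Kolmogorov–Smirnov).

# The summarizer

The ontology is first restricted to terms covering at least one query gene
(with edges re-closed). Then, repeatedly: every leaf of the active graph is
paired with its minimum-loss parent (a multi-parent leaf merges into the
parent minimizing the loss), candidates are ordered by ascending loss, and
the cheapest merge is gated:

- the tested set is the query genes the **parent's subgraph annotates** — a
  summarizing term covers all genes beneath it, merged or not. Among the
  readings the sources allow, this static interpretation is the only one
  under which the stopping rule bites: if the gate tested only the genes
  accumulated by previously accepted merges, the first lineage to reach the
  top would always be absorbed with an unchanged gene set, and no merge
  near the root could ever be rejected.
- the gate statistic is computed within the subgraph beneath the parent
  (terminals outside it are dropped), using the same metric and scheme as
  the null model; sets smaller than the smallest trained null size cannot
  be tested and pass automatically, flagged `untested`.
- a rejected merge freezes the child as a final module covering the genes
  it accumulated; genes reachable only through a frozen subtree no longer
  count toward its ancestors' modules, but a sibling lineage can still
  merge into the same parent.
- merges **into the root are never accepted**. The root is the
  definitionally uninformative summary — every gene list is "summarized" by
  the root — and quantitatively, the union of two individually coherent
  clusters is itself nearly always more coherent than a random set of the
  combined size (the null mean is concave in set size), so without this
  rule the procedure would collapse any query made of coherent parts into
  a single root module. Lineages reaching the root's children freeze
  there.

The procedure terminates because every step removes one term. Remaining
active terms with genes become final modules, so every mappable query gene
appears in at least one module; modules may overlap because a gene
annotated in several lineages travels up each of them. Each module is
reported under the *most specific term whose subgraph covers its in-scope
annotation terminals* (deepest dominator, lexicographic tie-break): frozen
terms can sit higher than their gene content warrants after climbing
through annotation-free ancestors, and the re-anchored term is the
informative label the method seeks. Relaxing the p-value cutoff only
accepts more merges, so it yields fewer, larger modules — an invariant the
tests assert.

The shipped default is the IC metric on the augmented graph with cutoff
0.01 and minimum testable size 5.

# Evaluation utilities

`rocAnalysis` scores labeled coherent/random gene sets by their null-model
p-values and sweeps the classification threshold over the distinct
p-values plus 0 and 1 (trapezoid area; cross-checked against an independent
ROC implementation in the tests). p-values, not raw statistics, are the
ranking score, since raw statistics are not comparable across set sizes.
`ppiRatio` computes $I/\binom{g}{2}$, the fraction of realized interactions
among a gene set — the printed denominator of the source formula,
$g(1-g)$, is negative for $g>1$ and cannot be a count of possible pairs, so
the stated intent $\binom{g}{2}$ is implemented. `cutoffSweep` summarizes a
query at several cutoffs and reports the mean within-module interaction
ratio (modules need at least two genes to have a ratio).

# The synthetic data generator

The generator emulates every external input at toy scale: a complete
$b$-ary IS_A tree written as OBO 1.2 (optionally with one diamond edge), a
GAF 2.2 annotation file, a JSONL document corpus with a term-to-document
map, GMT reference sets and a two-column interaction network. Each artifact
consumes its own random stream derived from the master seed, so
regenerating one artifact never perturbs the others, and a fixed seed gives
byte-identical files.

Its design mirrors the structure of real annotation data that the method's
behaviour depends on:

- *Planted modules.* The genes of a module draw their annotations from a
  small pool of leaves (`moduleLeafPool`, default 3) beneath the deepest
  covering term of a dedicated anchor subtree, as consecutive segments of a
  ring over the pool — so module genes are strongly and *pairwise*
  co-annotated, as genes of one biological process are. Each annotation is
  relocated to a random leaf with probability `noiseRate` (default 0.1),
  and `moduleStrayAnnotations` of each gene's annotations can be drawn
  graph-wide, emulating pleiotropy.
- *Heterogeneous annotation depth and density.* `backgroundAnnotations`
  sets how many annotations non-module genes carry, and
  `leafPopularitySd` draws lognormal leaf popularities, reproducing the
  heavy-tailed annotation density of real ontologies (which in turn
  produces the near-zero tail of the edge-weight distribution that makes
  the $d_{P5}$ augmentation discount meaningful).
- *Topic-model corpus.* Each term has a topic over a shared pseudo-word
  vocabulary; a child's topic mixes its parent's with a fresh draw, the
  fresh fraction shrinking geometrically with depth and with
  `topicConcentration` (infinite concentration makes children identical to
  parents, driving IB weights toward zero — a limit the tests exercise).
- *Interaction network.* Within-module gene pairs connect with probability
  `pIn` (default 0.5), all other pairs with `pOut` (default 0.02).

Two canonical designs are frozen as constructors.
`discriminationBenchmarkSpec` (50 planted modules of 10 genes among 1500,
each module gene carrying one in-pool and one stray annotation, background
genes single-annotated with skewed leaf popularity) is the setting in which
the augmented scheme's advantage over the plain scheme materializes: with
homogeneous multi-annotation, per-gene shortcut discounts benefit random
sets as much as modules and the plain scheme's terminal-count signal
dominates, while heterogeneous depth starves random sets of shortcuts.
`interactionBenchmarkSpec` (5 anchored modules of 10 among 300 genes) is
the setting for the cutoff/interaction-density sweep; its queries add a
handful of background genes, enough to dilute modules when relaxed cutoffs
merge them but few enough that stragglers freeze as singletons rather than
as zero-ratio pair modules.

What passing tests on these fixtures do *not* show: real GO topology
(tangled DAGs, multiple namespaces, obsolete terms), realistic literature
text, annotation biases beyond the popularity skew, or the scale of a full
annotation corpus. The fixtures establish that the machinery is correct and
that the method's qualitative behaviours (calibration, discrimination
ordering, recovery, density trend) hold under controlled conditions — not
that the quantitative results transfer to any particular real dataset.

# Numerical choices and degenerate inputs

- Logarithms are natural everywhere; weights and statistics are in nats.
- Distribution sums are checked to $10^{-6}$; support violations in the KL
  divergence are errors naming the offending token, never silent
  infinities.
- Floating-point ties in shortest paths and spanning trees use a
  $10^{-15}$ comparison band with lexicographic resolution.
- The 5th percentile uses linear interpolation over the sorted weight
  multiset, zeros included; an all-zero weight vector (degenerate
  percentile) and a graph with fewer than 20 edges (meaningless percentile)
  are errors.
- Empty annotation tables, unannotated roots, disconnected terminals,
  zero-total word profiles, zero null variances and unknown term ids all
  fail fast with informative messages; annotations and documents mapping
  outside the graph are counted and reported, not dropped silently.
- Problem sizes in the tests and the acceptance script: the calibration
  graph is the default fixture (depth 5, branching 3, 500 genes; null of
  100 replicates at sizes 5–50, 500 fresh scoring sets); the
  discrimination benchmark uses 50 module/random set pairs; sweeps average
  10 fixture seeds.

# Known limitations

- The Steiner statistic is a 2-approximation; two runs are comparable
  because tie-breaking is deterministic, but the reported $y_s$ can exceed
  the true minimum.
- The Gaussian null is an approximation to the statistic's distribution;
  it is calibrated in the tested regime but has no guarantee in the extreme
  tails, and sizes outside the trained grid extrapolate.
- Evidence codes are kept by default (IEA included); filtering is
  available but changes the universe and hence the null.
- The IB metric needs enough text per term for stable profiles; with few
  documents its weights are noisy, which is precisely why the IC metric is
  the shipped default.
- No multiple-testing correction is applied to module p-values; they are
  stopping criteria, not hypothesis tests on a fixed family.
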