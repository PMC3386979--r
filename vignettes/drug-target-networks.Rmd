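---
title: "Drug-target networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtnet)
```

This vignette is the package's account of its own science: the network
model, the centrality statistic, the association test, the synthetic
cohort generator, and the design decisions taken where the problem was
genuinely open.

## The two-mode model and its projections

The atomic observation is a drug-target interaction pair.  A cohort of
such pairs defines a bipartite network: drug nodes, target nodes, and
cross-edges only.  Cross-edges carry an integer weight (the recorded
interaction frequency, `multiplicity`), but the package treats the
underlying facts as presence/absence: duplicate records are merged by
summing multiplicity into the two-mode edge weight, and *nothing
downstream* — projections, degrees, the targets-per-drug statistic — is
affected by multiplicity.  The rationale: a drug either has a target or
does not; frequency is retained only as an annotation for two-mode
export.  Drug and target identifier namespaces must be disjoint; an
identifier found in both roles raises a hard error rather than being
silently renamed, since a shared identifier would corrupt both
projections.

The one-mode projections follow the shared-neighbourhood rule: in the
drug-drug network the edge weight between two drugs is the number of
distinct targets they both address; in the target-target network, the
number of distinct drugs addressing both.  Pairs sharing nothing get no
edge (weights are never stored as 0).  Every node of the projected mode is
kept in the node list even when isolated: a drug with a private target set
is still a cohort member, its betweenness is a meaningful 0, and it can
still be dropped at export time (`drop_isolates`) for layouts where
degree-0 circles would only add clutter.  Alternative projection
weightings (Jaccard, collaboration weighting) are deliberately out of
scope.

```{r projection}
pairs <- drug_target_pairs(c("A", "A", "B", "C"), c("t1", "t2", "t2", "t3"))
net <- build_bipartite(pairs)
project(net, "drug")$edges   # A-B share one target; C is an isolate
```

## Betweenness centrality

For node $i$ in a network of $n$ nodes,

$$C_B(i) = \frac{1}{(n-1)(n-2)/2} \sum_{\{j,k\},\, j \ne i \ne k}
  \frac{g_{jk}(i)}{g_{jk}},$$

with $g_{jk}$ the number of geodesics between $j$ and $k$ and
$g_{jk}(i)$ the number passing through $i$.  Numerical and semantic
choices:

* **Unweighted geodesics.** Projection weights count shared partners —
  larger means *more* similar.  Interpreting them as path costs would
  invert their meaning, so shortest paths are by edge count on the
  unweighted skeleton.  This also matches the default behaviour of the
  classic desktop network tools for which these files are exported.
* **Normalization.** The divisor $(n-1)(n-2)/2$ is the undirected pair
  count, which is what guarantees the documented $[0,1]$ range; $n$
  counts *all* nodes, isolates included.  Networks with $n \le 2$ return
  all zeros.
* **Disconnected pairs.** When $g_{jk} = 0$ the pair contributes
  nothing; there is no per-component renormalization.  This is the
  plainest reading of the summation and keeps values comparable across
  networks with different component structure.
* **Algorithm.** Brandes' single-source dependency accumulation,
  $O(nm)$ time with floating-point accumulation.  Correctness authority
  is `betweenness_bruteforce`, an independent oracle that enumerates
  every geodesic explicitly through the predecessor DAG and is capped at
  64 nodes; the suite compares the two on hundreds of random graphs
  (including disconnected ones) at $10^{-12}$ tolerance, and checks the
  closed forms for stars, paths, cycles and complete graphs.
* **Ranking ties.** Ranked tables sort by betweenness descending with
  ties broken bytewise-lexicographically by node id and receive distinct
  consecutive ranks.  No tie rule is canonical; a deterministic one is
  required for diffable output.  Betweenness is printed with 7 decimal
  places throughout.

## The centrality-sales association

The association module inner-joins the drug centrality table with a
per-drug sales table (dropped drugs are reported, never imputed) and
computes Pearson's $r$ with the usual two-sided t-test on $n-2$ degrees
of freedom.  Sales are correlated raw by default; `log_sales = TRUE`
correlates $\log(\text{sales})$, the latent scale on which the synthetic
generator plants its correlation.  Because real sales distributions are
heavy-tailed, a permutation p-value accompanies the parametric one: $y$
is permuted `n_perm` times and
$p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\}) / (n_{perm} + 1)$.  The add-one
estimator's smallest attainable value is $1/(n_{perm}+1)$, so resolving
significance below $10^{-3}$ requires $n_{perm} \ge 1999$; the default is
999, and the package's own end-to-end checks use 1999.

## The synthetic cohort generator

No public, versioned snapshot of a curated drug-target table with matched
sales exists, so the generator is a stand-in built from the simplest
mechanisms that reproduce the qualitative features the analysis relies
on.  Defaults (all overridable in `synth_config`):

| parameter | default | meaning |
|---|---|---|
| `n_drugs` | 223 | cohort size, a decade of new molecular entities |
| `n_targets` | 400 | candidate target pool |
| `mean_targets` | 2.5 | mean distinct targets per drug |
| `popularity_exponent` | 1.0 | preferential-attachment strength |
| `n_classes` | 7 | therapeutic-class blocks |
| `within_class_bias` | 0.7 | probability a draw stays in the drug's class |
| `target_r` | 0.371 | planted betweenness-sales correlation |

Mechanisms and the reasons for them:

* **Zero-truncated Poisson target counts.**  Per drug, the distinct
  target count $k$ is zero-truncated Poisson with its *mean* equal to
  `mean_targets` ($\lambda$ solved from
  $\lambda/(1-e^{-\lambda}) = m$), so every drug has at least one
  target and the realized cohort mean is unbiased.  A mean below 1 is
  impossible for a zero-truncated count and is rejected.
* **Preferential attachment.**  Each of the $k$ targets is sampled
  without replacement with probability proportional to
  $(\text{current degree} + 1)^{\text{popularity\_exponent}}$, producing
  the hub targets (kinase- and GPCR-like clusters) that real cohorts
  show.  Exponent 0 recovers uniform popularity, which the suite verifies
  with a chi-square goodness-of-fit null check.
* **Class blocks.**  Drugs and targets get uniform random class labels
  (ATC level-1 style letters); each draw is restricted to the drug's own
  class with probability `within_class_bias`.  0.7 was chosen once as a
  value giving visible class clustering while leaving enough cross-class
  edges to keep the network connected enough for betweenness to be
  informative; there is no empirical estimate to calibrate against.
* **Planted sales.**  Sales are assigned *after* centrality is computed:
  with $z$ the standardized betweenness, latent log sales are
  $s = z + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$,
  $\sigma = \sqrt{1/r^2 - 1}$, which makes the population correlation
  between $z$ and $s$ exactly `target_r`; reported sales are
  $e^{s + \log 10^8}$ (an arbitrary positive currency-like scale).
  Planting against realized betweenness, rather than some structural
  property, is what makes parameter recovery well-posed.  When
  betweenness is constant (degenerate tiny cohorts), `assign_sales`
  refuses; `make_fixture` falls back to uncorrelated noise sales and
  records no realized correlation in its manifest.

What the generator does **not** emulate: the empirical degree
distribution of any real interaction database, approval-year dynamics,
therapeutic-area market-share structure, sales measurement error, or
correlated multi-target families from shared chemistry.  Passing the
pipeline's recovery checks therefore demonstrates *self-consistency* —
the machinery measures what was planted — not that any particular real
cohort has these properties.

## Problem sizes and runtime choices

The package's own verification uses sizes chosen to make the checks
sharp but cheap: oracle comparisons on networks of up to 12 nodes at
three densities (hundreds of replicates), projection oracles on random
bipartite networks up to 12x12, and the full pipeline at cohort scale
(223 drugs) across 100 seeds, where the recovered latent-scale $r$ is
required to land within $\pm 0.15$ of the planted 0.371 in at least 90%
of seeds — a band wide enough to hold at the sampling error of $r$ at
$n = 223$ ($\approx (1-r^2)/\sqrt{n} \approx 0.06$), verified by Monte
Carlo.

## File formats

Tab-separated tables (pairs, sales, centrality) use UTF-8, `#` comments,
optional auto-detected headers, and are byte-stable through
write-read-write.  Pajek NET output uses the undirected
`*Vertices`/`*Edges` subset with 1-based contiguous ids, doubled-quote
escaping and integer weights; `*Arcs` files are rejected.  A NET file
carries no drug/target mode, so `read_pajek` takes the mode as an
argument.  GraphML output is undirected with a `mode` node attribute and
an integer `weight` edge attribute, written in a canonical layout so
repeated exports are diffable.

## Known limitations

* Betweenness is exact, not sampled; networks far beyond a few thousand
  nodes would need an approximate variant, which is out of scope.
* The permutation test permutes sales against centrality and so tests
  exchangeability, not any causal claim.
* The headline statistics of a real cohort depend on the curation of its
  interaction table; with multiplicity deliberately inert, two curations
  differing only in recorded frequencies will agree here, but curations
  differing in which pairs exist will not.
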