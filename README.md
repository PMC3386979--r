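# dtnet

Network analysis of a drug cohort's target landscape, for researchers
studying polypharmacology and drug-market trends.

A cohort of drugs and their molecular targets forms a **two-mode
(bipartite) network**: drug and target nodes, with edges only between the
two classes.  `dtnet` builds that network from a plain table of drug-target
interaction pairs, projects it into the two **one-mode** networks the field
works with —

- the **drug-drug network**, where two drugs are tied by the number of
  targets they simultaneously address, and
- the **target-target network**, where two targets are tied by the number
  of drugs that address both —

and then quantifies each node's structural importance with **normalized
betweenness centrality**.  For node *i*,

```
C_B(i) = [ sum over pairs {j,k} of g_jk(i) / g_jk ] / ((n-1)(n-2)/2)
```

where `g_jk` is the number of geodesics (shortest paths by edge count)
between *j* and *k* and `g_jk(i)` the number passing through *i*.  The
divisor maps values to [0, 1]: 0 for an isolate, 1 for the centre of a
star.  Geodesics are computed on the unweighted skeleton, because
projection weights encode similarity (shared partners), not distance.
The implementation is Brandes' dependency-accumulation algorithm, and an
independent exhaustive geodesic-enumeration oracle
(`betweenness_bruteforce`) is shipped alongside it and tested against it.

High-betweenness drugs bridge otherwise separate therapeutic
neighbourhoods — typically multi-target drugs — and the package tests
whether that bridging position is associated with market sales: Pearson's
*r* between drug betweenness and sales, with a parametric t-test p-value
and a permutation p-value as a distribution-free check.

Because curated interaction tables and sales databases are often
proprietary, `dtnet` includes a synthetic cohort generator
(`synth_config`, `generate_pairs`, `assign_sales`, `make_fixture`) whose
defaults emulate a decade-scale FDA new-molecular-entity cohort: 223
drugs, a mean of 2.5 distinct targets per drug (zero-truncated Poisson),
hub targets via preferential attachment, therapeutic-class block
structure, and a sales variable with a planted betweenness-sales
correlation of 0.371.

## Worked example

```r
library(dtnet)

# a synthetic cohort at study scale (writes pairs.tsv, sales.tsv, manifest.json)
cfg <- synth_config(seed = 42)
fx  <- make_fixture(cfg, "cohort")

net <- build_bipartite(read_pairs("cohort/pairs.tsv"))
print(net)
#> bipartite drug-target network: 223 drugs, 241 targets, 574 edges
#>   avg targets per drug: 2.5740

ct_targets <- centrality_table(project(net, "target"))
rank_nodes(ct_targets, k = 5)
#>   rank node_id betweenness degree
#> 1    1 TGT0060  0.10966009     27
#> 2    2 TGT0184  0.10183566     22
#> 3    3 TGT0033  0.09702661     18
#> 4    4 TGT0088  0.07638229     17
#> 5    5 TGT0330  0.07606044     18

ct_drugs <- centrality_table(project(net, "drug"))
associate(ct_drugs, read_sales("cohort/sales.tsv"),
          log_sales = TRUE, n_perm = 1999, seed = 1)
#> centrality-sales association (n = 223, log sales)
#>   Pearson r = 0.3542, t-test P = 5.44e-08
#>   permutation P = 0.0005
```

The cohort averages 2.57 distinct targets per drug (the generator's target
is 2.5).  The top-ranked targets are the hub receptors/kinase-like nodes
the preferential-attachment mechanism creates; their betweenness says how
often they sit on shortest paths between other targets.  The recovered
correlation 0.354 is the planted 0.371 up to sampling noise at n = 223,
and both p-values put it far below 0.001.

`run_report()` wraps the whole analysis and writes a report bundle
(summary stats, top-k centrality tables, degree tables, association
result, Pajek `.net` and GraphML exports, with JSON twins of every
table).  The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/dtnet.R simulate --n-drugs 223 --seed 42 --out cohort
Rscript inst/cli/dtnet.R report --pairs cohort/pairs.tsv \
    --sales cohort/sales.tsv --out report_dir
```

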