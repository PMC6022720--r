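# mitohaplo

High-throughput classification of broad European, African, and Native
American mitochondrial haplogroups from a small targeted panel of mtDNA
SNPs, for studies where full mitochondrial sequencing is cost-prohibitive
(array-genotyped cohorts, biobanks). Input is the standard PED/MAP file
pair; output is a data frame / CSV of haplogroup calls with the full path
through the classification tree.

## Method

Human mtDNA is maternally inherited and non-recombining, so haplogroups —
clades sharing a set of inherited variants — can be recovered from a few
dozen well-chosen SNPs. The package ships a reduced phylogenetic tree of
46 common haplogroups below the mtDNA MRCA, keyed on a 63-marker panel in
rCRS coordinates (two markers, MT16189 and MT9540, are blacklisted for
assay reliability and take no part in classification).

Each tree node carries the (position, allele) genotypes a sample must
possess to belong to that haplogroup, and membership is recursive through
the node's ancestors. Classification proceeds in two steps:

1. **Accumulate.** The sample's genotypes enter the root and are carried
   down the tree; every node whose cumulative root-to-node requirements
   are met joins an accumulator. Back-mutations (e.g. the 10398A reversion
   that defines macrohaplogroup N, re-reverted to 10398G in J and K) are
   encoded as requirements that override an ancestor's allele at the same
   position.
2. **Rank.** Accumulated haplogroups are ranked by distance from the root;
   every label with a path shorter than the longest is dropped (a longer
   path = more SNPs checked = more specific). The survivor is the call;
   nothing beyond the root means `unclassified`.

Missing calls never count as evidence: a missing required SNP fails the
node, and samples missing key SNPs near the root come out `unclassified`.
Markers are filtered by genotyping call rate (default threshold 0.90,
inclusive) before classification.

## Worked example

Simulate a labelled 12-sample dataset (two mother/father/child trios),
classify it, and summarize founder-only frequencies:

```r
library(mitohaplo)

tr <- default_tree()
sim <- simulate_dataset(tr, n_samples = 12, n_trios = 2, seed = 42)
write_fixture(sim, "demo.ped", "demo.map", "demo_truth.csv")

res <- run_classify("demo.ped", "demo.map", "demo_calls.csv")
#> dropped 2 marker(s) [call rate < 0.9 or QC-blacklisted]: MT9540, MT16189
#> classified 12 of 12 samples (0 unclassified)

read.csv("demo_calls.csv")
#>    sample_id haplogroup                            path     status
#> 1    IND0001         U5 MRCA -> L3 -> N -> R -> U -> U5 classified
#> 2    IND0002          K  MRCA -> L3 -> N -> R -> U -> K classified
#> 3    IND0003         U5 MRCA -> L3 -> N -> R -> U -> U5 classified
#> 4    IND0004          J MRCA -> L3 -> N -> R -> JT -> J classified
#> 5    IND0005          Y            MRCA -> L3 -> N -> Y classified
#> ...
```

Each row is one sample: the assigned haplogroup (deepest satisfied node;
`;`-joined if tied, empty if unclassified) and its root-to-node path.
Offspring duplicate their mother's mtDNA, so frequency summaries exclude
them by default:

```r
freq <- haplogroup_frequencies(res, simulated_genotypes(sim)$fam, tr)
freq$lineage
#>                lineage count frequency
#> 1             European     5       0.5
#> 2              African     3       0.3
#> 3 NativeAmerican_Asian     2       0.2
```

Comparing two call sets (e.g. against an external classifier) uses the
finer-resolution tolerance rule — `A2` vs `A2x` is concordant — and
excludes unclassified samples from the denominator:

```r
rep <- concordance_table(read_callset("demo_calls.csv"),
                         read_callset("other_calls.csv"), tr)
```

The same three operations are available from a shell via the installed
`exec/mitohaplo` script (`classify`, `simulate`, `concord` subcommands).

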