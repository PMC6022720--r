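---
title: "Classifying mitochondrial haplogroups from a targeted SNP panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mitochondrial haplogroups from a targeted SNP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohaplo)
```

## The problem

Human mitochondrial DNA is maternally inherited, non-recombining, and
accumulates mutations sequentially along maternal lineages. Clades of
mtDNA sequences sharing an inherited variant set are called haplogroups,
and because they track ancient migrations they map closely onto continental
ancestry. Full mtDNA sequencing resolves haplogroups finely but is
expensive at biobank scale; a small panel of well-chosen SNPs genotyped on
an array recovers the broad European, African, and Native American/Asian
haplogroups at a fraction of the cost. `mitohaplo` classifies samples from
such a panel, taking standard PED/MAP files as input.

## The model: a reduced phylogeny with per-node genotype requirements

The package ships a curated reduction of the human mtDNA phylogeny to 46
common haplogroups below the most recent common ancestor (MRCA), keyed on a
63-marker panel in rCRS (revised Cambridge Reference Sequence, 1-based)
coordinates. Each node carries:

* a list of (position, required allele) genotypes a sample must possess to
  belong to that haplogroup,
* a parent node, and zero or more children,
* a lineage tag (`African`, `European`, `NativeAmerican_Asian`, or `Macro`
  for the deep Eurasian macrohaplogroups) used for frequency aggregation.

Membership is recursive: belonging to a haplogroup also requires meeting
the cumulative definition of every ancestor on the root-to-node path.

**Reversions.** Some branches back-mutate to the ancestral state — the
classic case is position 10398, where macrohaplogroup N is defined by the
ancestral A while both the deep African/M branches and the later J and K
branches carry the derived G. These are encoded as ordinary requirements
that contradict an ancestor's requirement at the same position, with
*descendant-overrides* semantics: in the cumulative requirement set of a
node, the deepest requirement at each position wins
(`required_genotypes_cumulative()`). This realizes a second hierarchy of
required genotypes without a separate data structure.

**Classification** (`classify_sample()`) is a two-step procedure. First,
the sample's genotypes are passed into the root and carried down the tree;
every node whose cumulative requirements are fully matched is added to an
accumulator. The descent abandons a subtree as soon as some required
position mismatches *and* no node deeper in that subtree requires the
position again — the only way a mismatch can be legitimately overridden is
a reversion further down, so this pruning is exact. Second, accumulated
haplogroups are ranked by distance from the root and every label shallower
than the deepest one is dropped: a longer path means more SNPs checked,
hence a more specific call. The surviving label(s) are reported with their
full root-to-node path.

The test suite cross-checks this traversal, on every tree node and on
noisy random samples, against an independent brute-force oracle that
evaluates each node's cumulative requirement set in isolation and keeps
the maximal-depth satisfied nodes; the two routes agree exactly.

Three policies are worth stating explicitly:

* **Missingness is never evidence.** A missing call at a required position
  fails the node. Samples missing key SNPs near the top of the tree
  therefore come out `unclassified` rather than being forced into a call.
* **Ties are reported, not broken.** If two nodes of equal maximal depth
  are satisfied, both labels are returned (joined by `;` in CSV output).
  The packaged tree keeps sibling requirements disjoint, so ties do not
  arise from its own structure; they can arise from corrupted input, and
  silently picking one label would hide that.
* **A root-only accumulator maps to `unclassified`**, not to an "MRCA"
  call: matching no informative marker is not a classification.

## The SNP panel and quality control

The panel holds 63 markers, each with an ancestral and a derived allele.
Two are blacklisted — MT16189, which sits in a hypervariable poly-C tract
with poor assay reliability, and MT9540, whose flanking primers
cross-amplify nuclear insertions of mitochondrial origin (NumtS) — and take
no part in any node definition; they are excluded from classification
regardless of observed call rate.

PED files encode mtDNA calls as diploid pairs although the molecule is
haploid. `read_ped_map()` collapses each pair: equal tokens give the
allele, `0 0` gives missing, and a discordant non-zero pair
(heteroplasmy-like, or assay noise) gives missing with a warning —
choosing either allele of a discordant pair would fabricate a call.

Marker-level QC (`filter_by_call_rate()`) drops markers whose genotyping
call rate falls below a threshold, default 0.90, with an *inclusive*
boundary: a marker called in exactly 90% of samples is retained. The
threshold is a fraction in [0, 1] and applies to whatever sample set the
function is given.

## The synthetic-data generator

`simulate_dataset()` produces ground-truth-labelled datasets so that every
component is testable without any external download. For a drawn
haplogroup it emits the cumulative required alleles and fills every other
panel position with the panel's ancestral allele. Ancestral fill is the
one background choice under which generation followed by classification
provably recovers the label (the closure property the tests rely on);
real samples carry additional private variation that the panel simply does
not interrogate. Haplogroups are drawn uniformly over the 29 terminal
nodes by default; any weighting over tree labels can be supplied.

Noise is injected per call, independently: `missing_rate` turns calls into
`0 0`, and `discordant_rate` turns calls into mismatched diploid pairs
that collapse to missing on read. Real assay failure is marker-correlated
rather than i.i.d., so a `knockout_markers` option forces chosen positions
missing in all samples, reproducing failure modes such as a key
branch-defining SNP dropping out platform-wide. Trios (`n_trios`) emit
mother/father/child triplets in which the child carries the mother's exact
haplotype and the pedigree columns link child to parents, so founder-only
analyses are testable; mothers are coded sex 2, fathers 1.

Passing tests on these simulations demonstrates the algorithm's internal
consistency — closure, monotone degradation under missingness,
deterministic seeded output — not concordance with sequence-based
classifiers on real samples, which depends on panel assay quality and on
variation the panel does not capture.

## Concordance scoring and frequency summaries

`concordance_table()` implements the comparison protocol used to evaluate
panel-based calls against an external call set: samples labelled
`unclassified` (or `unknown`) in either set are removed first and counted,
and two labels are concordant when they name the same haplogroup even if
one method resolved it more finely. The finer-resolution rule is
tree-aware when both labels are tree nodes (one must lie on the other's
root-to-node path, which handles `JT` vs `J` correctly); for labels
outside the reduced tree (external tools emit e.g. `A2x`) a string rule
applies: the longer label must extend the shorter one *and* the first
extra character must continue the letter/number alternation of haplogroup
nomenclature. A naive prefix rule provably over-matches — `H` would match
`HV`, which are different clades at the string level; under the tree rule
H *is* nested within HV, and the tree answers nesting questions wherever
it can.

`haplogroup_frequencies()` summarizes classified datasets. Because
offspring duplicate their mother's mtDNA, samples whose maternal id
resolves within their family are excluded by default (`founders_only`);
unclassified samples leave the denominator; and per-haplogroup frequencies
aggregate into continental lineages through the node lineage tags. Both
distributions sum to one. Tied multi-label calls contribute their first,
tree-order label — ties are rare and tree order puts the most canonical
label first; no weighting scheme was compelling enough to justify
fractional counts.

## Numerical and design choices

* Tree and panel live in one JSON document (`load_tree()`, `write_tree()`)
  chosen for diff-ability and hand-editability; loading validates
  uniqueness of names and positions, rCRS bounds (1–16,569), single-root
  acyclicity, allele sanity, and that node requirements reference
  non-blacklisted panel positions. Sibling nodes with identical cumulative
  requirements — which classification could never separate — trigger a
  lint warning, not an error.
* The root/MRCA is not counted among the 46 haplogroup nodes; the count
  check is a caller-supplied option (`expected_nodes`) so edited trees of
  any size load cleanly.
* Marker-to-panel joining is by rCRS position, never by marker name; names
  like `MT11251` are reporting sugar. Chromosome codes `26`, `MT`, and `M`
  are accepted as mitochondrial; anything else classifies with a warning.
* All subcommands are deterministic functions of inputs plus seed;
  repeated runs are byte-identical. Percentages print with one decimal.

## Problem sizes used in validation

The shipped checks run the oracle-equivalence comparison on 1,000 noisy
random samples, closure on all 46 nodes, the missingness degradation curve
at rates {0, 0.2, 0.5, 1} with 200 samples each, the QC boundary on a
100-sample set, and the PED round trip on 100 samples with 10 trios —
sizes at which every property is exercised in seconds on one CPU.

## Known limitations

* Resolution is broad by design: sub-haplogroups below the 46 nodes are
  out of reach, and the Asian portion of the phylogeny is thinner than the
  European/African/Native American portions (notably, Asian haplogroup B
  is classically defined by an 8,281–8,289 deletion that SNP genotyping
  does not target).
* With ~60 informative markers the method is not robust to missing
  genotypes: a handful of missing key SNPs near the root makes a sample
  unclassifiable, and the diagnostics (`missing_required`,
  `n_missing_required`) exist precisely to audit that.
* Input is PED/MAP only; VCF/BCF and PLINK binary formats, imputation,
  phasing, and heteroplasmy quantification are out of scope.
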