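---
title: "Methods: RGC_CAM site classification, homoplasy, and internode certainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RGC_CAM site classification, homoplasy, and internode certainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgccam)
```

## Model

A *rare genomic change from conserved amino acids with multiple
substitutions* (RGC_CAM) is an aligned protein column whose residue
replacements are hard to produce by chance: every pair of amino acids
observed at the column requires at least two nucleotide substitutions to
interconvert under the genetic code, and each amino acid is conserved in
at least two taxa. Such columns are expected to be rare, slowly evolving
characters whose shared states more often reflect common descent than
convergence, which makes them useful for resolving contested internal
branches of a phylogeny.

The package implements the full pipeline around that idea:

1. a 20 × 20 **minimum-substitution distance matrix** between amino
   acids, derived from a genetic code table;
2. a **column classifier** that applies three criteria to each alignment
   column;
3. mapping of informative columns to the **bipartition** (taxon split)
   they support;
4. **Fitch parsimony** scoring, a per-site **homoplasy index**, exhaustive
   tree search for small taxon sets, and bootstrap support;
5. **internode certainty** (IC, ICA) and **tree certainty** (TC, TCA)
   from bipartition support counts;
6. the associated statistics: Fisher's exact test on support/conflict
   contingency tables, and a seeded binning plus Wilcoxon rank-sum
   comparison of homoplasy between site classes;
7. a **seeded simulator** that plants labelled sites per bipartition, so
   each stage can be validated against known truth.

## The distance matrix

For amino acids $a$ and $b$, the distance is

$$ d(a, b) \;=\; \min_{\,c_1 \in C(a),\; c_2 \in C(b)} \; h(c_1, c_2), $$

where $C(x)$ is the set of codons translating to $x$ and $h$ is the
Hamming distance between codons (0–3). The matrix is computed by direct
enumeration over all codon pairs — at most $6 \times 6$ per amino-acid
pair — so no heuristics are involved. Any genetic code can be supplied;
the standard code is the default. Under the standard code most pairs are
one substitution apart; examples of multi-step pairs are
asparagine/cysteine ($d = 2$) and methionine/tryptophan ($d = 2$), while
aspartate/histidine is single-step ($d = 1$).

```{r}
m <- cam_matrix(genetic_code())
m["N", "C"]; m["M", "W"]; m["D", "H"]
```

## Column classification

A column is classified from its observed residues, after dropping
missing symbols (`-`, `X`, `B`, `Z`, `*`, `.`; see below):

* **RGC_CAM** — at least two distinct amino acids; each amino acid
  present in at least two taxa; every pair of observed amino acids has
  $d \ge 2$.
* **RGC_non-CAM** — the first two criteria hold but every pair has
  $d = 1$ (all replacements are single-step).
* **other** — anything else, including constant columns, columns with a
  singleton residue, and columns mixing single- and multi-step pairs.

A column with exactly two residue groups defines a bipartition of the
taxa: the taxa carrying one amino acid versus the taxa carrying the
other. Bipartitions are named by the smaller block, taxa sorted, so the
split {b, k} | {c, p, m} is `"bk"`. Columns with three or more residue
groups are classified but not assigned a single bipartition.

**Missing data.** By default missing symbols are ignored: the criteria
are applied to the remaining taxa, which must still satisfy the
two-taxa-per-residue rule. In `strict = TRUE` mode any missing symbol
disqualifies the column. The default matches the intuition that a gap
carries no evidence about the residues elsewhere in the column; strict
mode is available for conservative analyses.

## Homoplasy

For each informative column the **Fitch parsimony length** on a tree is
the minimum number of state changes needed to explain the column. It is
computed by the standard bitmask Fitch pass over a postorder traversal;
missing symbols are wildcards (all-ones masks). The minimum length over
*all* topologies is simply $k - 1$ for $k$ distinct observed states. The
per-site **homoplasy index** is

$$ \mathrm{HI} \;=\; 1 - \frac{\text{min length over all trees}}{\text{length on the given tree}}, $$

so $\mathrm{HI} = 0$ means the column fits the tree with no extra
changes, and larger values mean more convergence/reversal relative to
that tree. Constant columns are defined to have $\mathrm{HI} = 0$. On
five taxa a binary column either fits the tree (length 1, HI 0) or
requires two changes (HI 0.5), so the mean HI of a site class is half
its conflict rate.

For up to 8 taxa, `enumerate_unrooted_trees()` generates all
$(2n-5)!!$ unrooted topologies by stepwise addition (15 trees for 5
taxa, 10,395 for 8) and `parsimony_search()` returns the exact
maximum-parsimony tree(s). `bootstrap_support()` resamples columns with
replacement (multinomial weights over deduplicated column patterns) and
reports, per reference split, the percentage of replicates whose
optimal tree(s) contain it; `semantics = "strict"` requires the split
in *all* co-optimal trees, `"any"` in at least one.

## Internode and tree certainty

Let $n_0$ be the support count of a focal bipartition and
$n_1, \dots, n_k$ the counts of bipartitions that conflict with it
(two splits conflict when all four block intersections are non-empty).
With relative frequencies $p_i = n_i / \sum_j n_j$:

* **IC** uses the focal split and its single strongest conflict
  ($k = 1$, base-2 logarithm):
  $\mathrm{IC} = 1 + p_0 \log_2 p_0 + p_1 \log_2 p_1$.
* **ICA** includes every conflicting bipartition whose count exceeds
  5% of the total number of informative sites; if none does, it falls
  back to the single strongest conflict. The logarithm base equals the
  number of bipartitions included (focal plus included conflicts), so a
  perfectly even split always yields 0 and unanimous support yields 1.

**TC** and **TCA** are the sums of IC and ICA over the internal branches
of the reference tree. The 5% prevalence threshold and the adaptive
logarithm base are the two discretionary choices in this definition;
both are fixed constants of the method, not tuned quantities. Note that
ICA is a concentration measure: with a fixed included set it decreases
as a conflict grows toward the focal count, but rises again once the
conflict dominates.

```{r}
ct <- tree_certainty(yeast_tree(), yeast_support_table("RGC_CAM"))
ct
```

## Statistics

`fisher_support_test()` wraps `stats::fisher.test()` on the 2 × 2 table
of (supporting, conflicting) counts by site class. `compare_hi_bins()`
randomly assigns sites of each class to disjoint bins of a fixed size
(discarding any remainder), computes each bin's mean HI, and compares
the two sets of bin means with a Wilcoxon rank-sum test
(`stats::wilcox.test`, exact where feasible, otherwise the
normal approximation with continuity correction). Binning is seeded:
the first class uses `seed`, the second `seed + 1`, and identical seeds
reproduce identical assignments bit-for-bit.

## Simulator: scope and limits

`generate_alignment()` takes a plan of (bipartition, class, count) rows
and plants, for each row, `count` columns in which one residue of a
sampled pair occupies one block of the bipartition and the other residue
the complement; multi-step pairs for `RGC_CAM`, single-step for
`RGC_non-CAM`. Constant filler columns and a seeded column shuffle
complete the alignment. `full_scale_scenario()` builds a full-scale
five-taxon dataset (2,647 multi-step and 100,887 single-step sites
across ten bipartitions).

The generator works at the **amino-acid level**: it samples residue
pairs uniformly from the pairs of the requested distance class rather
than simulating codon evolution along branches. That is sufficient for
its purpose — producing columns with known class, bipartition, and
per-site homoplasy for validating the classifier, the parsimony
machinery, and the certainty calculations — but it is not a
substitution-process simulator: it has no branch lengths, no rate
heterogeneity, no among-site dependence, and plants at most two residues
per column. Conclusions about real sequence evolution should not be
drawn from its output.

## Numerical choices

* All counts are exact integers; IC/ICA use `log()` with an explicit
  base and are exact up to floating point. Published two-decimal values
  are reproduced by rounding the full-precision results.
* Fitch lengths use integer bitmasks (`bitwAnd`/`bitwOr`) over up to 26
  canonical states, vectorised across deduplicated column patterns, so
  scanning a 100,000-column alignment takes seconds.
* Tree enumeration is exact and restricted to $\le 8$ taxa
  (10,395 topologies); beyond that the factorial growth makes
  enumeration inappropriate and the functions refuse rather than
  approximate.
* Exact Wilcoxon p-values are used when sample sizes permit and there
  are no ties; otherwise the normal approximation with continuity
  correction is used, matching `stats::wilcox.test` behaviour.

## Limitations

* IC/ICA here are computed from site-support counts, not from gene-tree
  or bootstrap-replicate sets; the interpretation of the 5% threshold is
  tied to informative-site totals.
* The classifier treats each column independently; no correction is made
  for within-column rate variation or covarion behaviour.
* The homoplasy index is defined against a single reference topology;
  it is not a tree-independent measure of convergence.
* The simulator validates software correctness, not biological realism
  (see above).
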