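---
title: "Testing cultural traits against linguistic history: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing cultural traits against linguistic history: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexmantel)
```

## The problem

Cross-cultural correlations are haunted by Galton's problem: groups that
descend from a common ancestor culture, or that have been in prolonged
contact, resemble each other in many traits at once. Treating each group
as an independent sample then inflates the apparent association between
any two traits. A concrete instance: across Chinese provinces, the
proportion of cultivated land devoted to rice paddies correlates with
psychological measures of collectivism — but provinces also share deep
linguistic, hence historical, relationships, so the data points are not
independent.

lexmantel implements the distance-based workflow for making that history
empirically visible. Vocabulary is the proxy: varieties that split
recently still share cognates (words related by descent) and have small
edit distances between translation equivalents; prolonged contact
(borrowing) also pulls vocabularies together. If a trait's
between-province differences correlate with between-province lexical
distances, the trait tracks cultural history — and any synchronic
correlation involving it deserves a phylogenetic control.

## Distance measures

Three variety-level dissimilarities are available.

**LDN.** For two words, the Levenshtein distance is the minimal number of
single-symbol insertions, deletions and substitutions converting one into
the other; dividing by the longer word's length (the maximum possible
number of edits) gives the normalized distance LDN in $[0,1]$. Words are
compared as Unicode code points after NFC normalization; we deliberately
do not segment into multi-character sound symbols, which keeps the
measure deterministic and database-agnostic. The distance between two
varieties is the mean per-concept LDN over the concepts they share. When
a concept has several synonyms, the per-concept value is the *minimum*
LDN over all cross-variety form pairs — synonymy should not inflate
distance.

**LDND.** Two varieties with small sound inventories look similar by
chance alone. LDND corrects for this by dividing the mean same-meaning
LDN by the mean LDN over all *cross-meaning* form pairs (every form for
concept $i$ in one variety against every form for concept $j \ne i$ in
the other, over shared concepts). The normalizer is computed per variety
pair, not globally, so each pair is corrected for its own chance level.
LDND can exceed 1; it is 0 for identical vocabularies, and undefined when
every cross-meaning pair is identical (a degenerate input we refuse).

**Cognate distance.** When wordlists carry cognate-class codes, a shared
concept counts as cognate between two varieties when their class sets for
it intersect (synonyms may carry several classes). The distance is
$1 - \frac{\#\text{cognate concepts}}{\#\text{shared concepts}}$, a
proportion turned into a dissimilarity so that all three measures point
the same way. Cognate *detection* is upstream of this package: codes are
taken as input.

```{r worked}
w1 <- wordlist("A", list(c1 = "aa", c2 = "bb"))
w2 <- wordlist("B", list(c1 = "aa", c2 = "bc"))
variety_ldn(w1, w2)  # (0 + 0.5)/2
ldnd(w1, w2)         # cross-meaning pairs ("aa","bc"), ("bb","aa"): mean 1
```

## Aggregation and the trait matrix

Varieties map to groups (provinces). The distance between two groups is
the arithmetic mean of the variety distances over all *cross-group*
pairs; within-group pairs do not enter, because the quantity of interest
is a between-group distance. The trait matrix holds absolute differences
$|t_P - t_Q|$ of the bounded trait. Groups lacking either lexical or
trait data are dropped before testing (complete-case analysis), with the
dropped labels logged and recorded in the run report.

## The Mantel test

Distance-matrix entries are themselves non-independent, so significance
comes from a permutation test: the observed statistic is the Pearson
correlation over the $n(n-1)/2$ upper-triangle entries, and the null
distribution is built by jointly permuting the rows and columns of one
matrix. Defaults and their reasons:

* **tail = "greater"** — the substantive hypothesis is positive
  association (historically closer provinces are more similar in the
  trait); other tails are available and reports state the tail used.
* **10,000 permutations** by default, drawn uniformly with replacement
  over the permutation group; no deduplication.
* **add-one correction** — $p = (1 + \#\{r_\pi \ge r_{obs}\}) /
  (1 + n_{perm})$, counting the identity relabeling, so $p$ is never 0
  and the test is valid at any permutation count. Floating-point ties are
  counted as ties (tolerance $10^{-12}$).
* **Pearson** correlation by default; Spearman behind the `method` flag.

For $n \le 8$ labels, `mantel_exact()` enumerates all $n!$ relabelings
and returns the exact $p$ (no add-one term, since the identity is part of
the enumeration); the sampled test is checked against it in the test
suite.

## Tree estimation

A rooted tree of historical relations is estimated from the group
distances by agglomerative average-linkage clustering (UPGMA): repeatedly
merge the two clusters with the smallest average inter-cluster distance,
placing the merge at half that distance, so the result is ultrametric by
construction and reproduces ultrametric inputs exactly. UPGMA is the
default because the input is itself an average-based distance and the
analysis calls for a rooted tree (single and complete linkage sit behind
the `linkage` flag). Ties between merge candidates are broken toward the
lexicographically smallest label pair, which makes results identical
across platforms. `top_branches(tree, k)` undoes the $k-1$ highest merges
and returns the $k$ major branches; `to_newick()` serializes with branch
lengths equal to parent height minus child height, quoting labels that
contain Newick metacharacters.

## The synthetic-data generator

Because the original lexical and agricultural datasets are external, the
package ships a generator whose outputs have the statistical structure
the analysis assumes; it is first-class, tested code.

* **Tree of descent** — a pure-birth (Yule) topology with ultrametric
  branch lengths rescaled to total height 1 (`simulate_tree()`); the
  simplest scaffold consistent with divergence by descent.
* **Lexicon** — an ancestral vocabulary of random words (3–8 symbols,
  alphabet of 10 by default — word shapes of the same order as short
  standardized transcriptions). Along a branch of length $L$ each concept
  is *replaced* (new word, new globally unique cognate class) with
  probability $\min(1, \rho L)$ and otherwise each symbol substituted
  with probability $\min(1, \mu L)$. Two leaf forms share a cognate class
  iff no replacement separates them — exactly the ground truth the
  cognate distance estimates.
* **Borrowing** — geography is abstracted to a ring over the leaf order;
  each variety copies a concept's form and class from an adjacent
  neighbor with probability `borrowing_rate`, sequentially, with every
  event logged. A ring is a deliberate 1-D abstraction of spatial
  adjacency; a full lattice would add parameters without changing the
  qualitative phenomenon.
* **Trait** — Brownian motion on the same tree from root value 0 with
  variance `trait_variance` per branch unit, squashed to $[0,1]$ by the
  logistic function: a bounded trait that is heritable but causally
  unrelated to the lexicon.
* **Groups** — varieties are assigned to provinces as contiguous blocks
  of the tree's leaf (plot) order, so provinces are cladistically
  coherent, as real provinces roughly are; group traits are member means.

Defaults — 40 varieties, 18 groups, 100 concepts, alphabet 10, mutation
0.3, replacement 0.25, borrowing 0, trait variance 1 — are desk-scale
artifact defaults chosen so a dataset generates in well under a second
while leaving clear phylogenetic signal in both lexicon and trait; they
are not estimates of any real-world rates. What the generator does *not*
emulate: realistic phonology or sound-change typology, semantic shift,
population structure, or spatially realistic contact networks. Passing
tests therefore demonstrate the statistical machinery and the logic of
the inference, not calibration to real Sinitic data.

## What the pipeline shows

```{r galton}
ds <- make_dataset(simulation_config(seed = 206))
rep <- run_analysis(ds$wordlists, ds$group_map, ds$trait_table,
                    measure = "cognate", n_perm = 999, seed = 1)
rep
```

Here the trait and the lexicon share nothing but the tree, yet the Mantel
test typically rejects: with the package defaults the rejection rate at
$\alpha = 0.05$ is well above 50% across replicates, versus the nominal
~5% once the trait values are reshuffled across groups (both rates are
recomputed by `scripts/acceptance.R` and asserted in the test suite).
That is Galton's problem made tangible: a "significant" association that
is pure common descent.

## Numerical and design notes

* Matrix label order is first-appearance order of the input; all
  operations are order-covariant, and tests check it.
* Distance matrices round-trip through their TSV serialization to better
  than 12 significant digits; asymmetry beyond $10^{-9}$ on read is an
  error, smaller asymmetries are symmetrized.
* Problem sizes used by the test suite and the acceptance script — 100
  Galton replicates at 40 varieties/18 groups with 999 permutations,
  10,000-permutation runs at both 40- and 139-variety scales, 200
  type-I-error replicates at 18 labels, 100 10-leaf tree recoveries —
  were chosen to give stable Monte-Carlo estimates in a couple of minutes
  on one core.
* Known limitations: no partial Mantel (controlling for a third matrix),
  no bootstrap support on trees, no neighbor-joining (unrooted trees do
  not answer the rooted question asked here), no weighting of varieties
  by population, and no ancestral-state reconstruction. These are
  deliberate non-goals.
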