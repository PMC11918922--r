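---
title: "Reconstructing Y-chromosome lineages from targeted capture sequencing"
author: "Ylineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing Y-chromosome lineages from targeted capture sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Ylineage)
```

## The problem

The male-specific region of the Y chromosome is haploid and does not
recombine, so the derived alleles of Y-SNPs accumulate strictly along
paternal lines: the set of men carrying the derived allele of one SNP is
nested inside, equal to, or disjoint from the carrier set of any other SNP —
unless a site mutated more than once (recurrence) or a call is wrong. This
"perfect phylogeny" structure is what makes haplogroup trees possible, and
what `Ylineage` exploits.

The package reconstructs a haplogroup tree from per-sample, per-position
sequencing evidence, in five stages:

1. **Base calling** (`callBase`, `buildCallMatrix`): haploid,
   threshold-based. A base is called only from reads with phred quality at
   least 25, needs at least five such reads, and at least 95% of them must
   agree (all boundaries inclusive). Anything else is *missing*, never
   guessed. Discovery mode (`discoveryThresholds()`) relaxes depth to a
   single read for cataloguing candidate sites. Calls are polarized against
   each site's ancestral allele (by default the reference allele, with an
   override table for known back-mutations) into ancestral (`A`), derived
   (`D`) or missing; sites derived in no sample are dropped, so the
   `YCallMatrix` is polymorphic by construction.
2. **Pairwise classification** (`classifyPairs`): for every pair of sites,
   the samples called at both are cross-tabulated into `n11`, `n10`, `n01`,
   `n00` (derived/derived, derived/ancestral, ...). On a perfect phylogeny,
   `n11`, `n10` and `n01` can never all be positive; that pattern is
   *contradictory*. The other patterns read off the tree directly:
   *equivalent* (same branch), *nested* (ancestor/descendant), *disjoint*
   (parallel branches). Pairs with fewer than `min_informative` jointly
   called samples (default 2) are *uninformative*: a single shared sample
   cannot distinguish equivalence from nesting.
3. **Filtering and assembly** (`filterContradictory`, `groupEquivalent`,
   `buildHierarchy`, wrapped by `inferTree`): sites are removed greedily by
   descending number of contradictory partners (ties to the lower
   position) until no contradiction remains; equivalent sites are merged
   into branch-defining clusters (transitive closure), and clusters whose
   members disagree about a third site are removed as *ambiguous*. The
   remaining above/below relations form a DAG whose transitive reduction
   gives each cluster its unique immediate ancestor; clusters without one
   are ambiguous and reported rather than placed. Polytomies are left
   unresolved. Single-carrier clusters that are uninformative against every
   placed cluster are attached under the deepest placed cluster carrying
   their sample and flagged `tip-placed`.
4. **Reference anchoring** (`anchorTree`, `nameBranches`): clusters sharing
   a SNP name with a tabular reference tree adopt its lineage name
   (provenance `both`); reference branches without observed SNPs pass
   through unchanged (`database`); everything else is *novel* (`inferred`).
   Novel branches are named in the lineage-based style — the parent label
   extended by the next free child ordinal, alternating numerals and
   letters (Q, Q1, Q1b, ...), suffixed with the branch's alphabetically
   first SNP, e.g. `Q1b1a1a2-ZK9`.
5. **Assignment and QC** (`assignHaplogroups`, `resolutionReport`,
   `qcReport`): each sample walks the tree root-to-tip and is assigned the
   deepest branch supported by its calls; capture-specificity statistics
   summarise on/off-target ratios in concentration-sorted windows.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `minDepth` | 5 reads | quality-surviving reads needed for a haploid call |
| `minQuality` | 25 phred | per-read floor, applied before depth and majority |
| `baseMajority` | 0.95 | fraction of surviving reads that must agree |
| `min_informative` | 2 samples | jointly called samples needed to classify a pair |
| `minSupport` | 0.95 | derived fraction of a branch's typed SNPs for support |
| `rootLabel` | `"Q"` | haplogroup letter prefixed to root-level novel branches |

The strict calling triple (5 / 25 / 95%) is the validated setting for mixed
cohorts in which a large fraction of the data has no molecular-barcode error
correction; it trades call rate for a very low error rate, which matters
because a single wrong derived call can make two sites contradictory.
`min_informative` is kept at 2 because in sparse cohorts most variants are
singletons, and raising it would push many real relations to uninformative.
`minSupport = 0.95` mirrors the base-majority ethos at the branch level.

Two deliberate asymmetries are worth knowing. First, *missing is not
contradiction*: an assignment may descend through an entirely untyped
branch, but a branch whose typed SNPs are all ancestral blocks descent.
Second, the quality floor is not monotone in the way depth and majority
are: raising `minQuality` discards noisy reads and can thereby *rescue* a
call that failed the majority at a lower floor. That is the intended effect
of quality filtering; the monotonicity guarantees (stricter settings never
add calls) therefore hold for depth and majority at a fixed quality floor.

## The simulator, and what it does (not) emulate

`simConfig()` / `simulateTree()` / `simulatePileups()` generate a rooted
branch hierarchy by iterative uniform attachment (producing both chains and
polytomies), place at least one mutation per branch (Poisson, mean 11 by
default), attach samples to branches uniformly — internal branches
included, because real samples are routinely assigned to internal
haplogroups — and emit per-site pileup columns with negative-binomial
depth, normal phred qualities and uniform base-flip errors.

Defaults encode a three-group cohort: 130 modern admixed, 104 ancient
indigenous and 43 modern indigenous samples. Group missingness (0.32 /
0.92 / 0.10) reflects mean covered fractions of roughly 9.9 Mb, 1.2 Mb and
13.2 Mb: ancient DNA covers about ten times fewer sites than modern
samples, which is the dominant data feature the tree-building stage has to
survive. The mapping from covered basepairs to a per-site missingness
probability is a modelling choice of this package: coverage is drawn
independently per site and sample, with depth at covered sites
`1 + NegBin(mu = depthMean - 1, size = dispersion)` so that coverage is
governed by the missingness probability alone. About 1% of sites are
placed recurrently on two incomparable branches, matching recurrence rates
reported for capture panels of this kind, and 6.4% of sites are labelled
InDel-class for tally bookkeeping (read-level evidence stays single-base; a
single proxy base stands in for the inserted/deleted allele, and the InDel
identity lives in the site catalog and VCF REF/ALT strings).

The simulator does **not** model capture chemistry, GC-dependent coverage,
reference bias, ancient-DNA damage patterns (deamination), alignment or
duplex-consensus artefacts, or coalescent time scales. Passing recovery
tests therefore demonstrate that the algorithmic chain is correct under its
own assumptions — binary sites, independent missingness, symmetric read
error — not that real ancient DNA will behave as cleanly.

`coverAllBranches = TRUE` attaches the first `nBranches` samples one per
branch before uniform attachment. Recovery experiments use it because
exact recovery is only well-posed when every branch is observed: an
unobserved branch leaves no trace in the matrix, and a branch
indistinguishable from its parent (identical carrier sets) is correctly —
but unverifiably — merged.

## Numerical and degenerate-input choices

* Ties in the modal base cannot reach a majority above 0.5 and are missing.
* Called bases matching neither configured allele are missing (counted in
  the matrix metadata), not treated as a third allele.
* Greedy contradiction removal breaks ties by ascending site position;
  sibling order is descending carrier count, then ascending position; both
  make the whole pipeline deterministic in its input.
* Window "variation" is the sample standard deviation by default
  (variance and coefficient of variation are selectable); windows slide by
  one sample after sorting by concentration (ties by sample id), and a
  trailing partial window is excluded. The threshold tie-break takes the
  lowest mean concentration.
* Reported percentages round half away from zero to the nearest integer.
* Empty pileup columns, empty matrices, zero off-target counts and
  zero-variance correlations all return defined missing values (`NA`)
  rather than errors; genuinely unusable inputs (orphan reference parents,
  cyclic parent links, mismatched sample universes) raise errors naming
  the offending row.

## Design choices where the design was open

*Cluster-level aggregation.* After equivalence grouping, each cluster is
pooled into a single carrier profile (derived if any member is derived;
equivalence guarantees members never disagree on a jointly called sample).
Pooling uses more of the data than electing a representative member, and
two clusters that only become comparable through pooled coverage are merged
if equivalent. A cluster-level contradiction — impossible when site-level
filtering has run — defensively removes the smaller-carrier cluster, with a
report entry.

*"Most parsimonious" anchoring.* The merged tree inserts the minimal set of
nodes consistent with all non-contradicted pairwise constraints. The
reference ordering wins only on a true disagreement (an inferred parent off
the reference parent line, logged with carrier counts); when the inferred
hierarchy *refines* the reference — reference trees routinely skip levels —
the finer nesting is kept, so novel branches insert between reference
levels rather than duplicating them as siblings.

*Assignment ties.* Two supported branches at equal maximal depth on
diverging paths can only arise from conflicting calls; the sample is
assigned the deepest supported branch on their shared root path and
flagged, rather than silently picking a side.

## Problem sizes used by the test-suite experiments

Recovery and audit experiments run on 30-branch trees with 120-sample
cohorts over 20 replicate seeds; oracle-equivalence checks use 1000 random
matrices of up to 8 sites and 10 samples with up to 50% missingness, and
the QC statistics are verified against explicit two-pass formulas to
1e-12. These sizes exercise every code path (chains, polytomies,
recurrence, missingness) while keeping a full run in the order of a minute.

## Known limitations

* Sites are strictly binary; multi-allelic positions become missing calls.
* No branch lengths, ages or mutation-rate calibration; the hierarchy is
  purely topological.
* The greedy contradiction filter is near-optimal for the sparse
  contradiction graphs recurrence produces, but is not an exact minimum
  vertex cover.
* Anchoring resolves disagreements by single-reference precedence; it does
  not arbitrate between multiple references.
* With heavy missingness, shallow placement is preferred over guessing:
  ambiguous clusters are dropped and reported, so the tree under-resolves
  rather than over-resolves.
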