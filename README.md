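# Ylineage

Reconstruction of Y-chromosomal haplogroup phylogenies from targeted
capture sequencing of haploid lineages.

The male-specific Y chromosome is haploid and non-recombining, so the men
carrying the derived allele of any Y-SNP form a clade: carrier sets of two
SNPs are nested, equal or disjoint on a perfect phylogeny, and a pair of
sites that is derived together *and* derived separately in both directions
(`n11 > 0`, `n10 > 0`, `n01 > 0` in the joint cross-tabulation) is evidence
of recurrence or error. `Ylineage` turns per-position read evidence from a
mixed cohort — modern admixed, modern indigenous and ancient samples with
very different coverage — into:

1. a strictly filtered **call matrix** of ancestral/derived/missing states
   (haploid base-majority calling: read quality ≥ 25, depth ≥ 5, base
   majority ≥ 95%),
2. a rooted **branch hierarchy** of the variants, built purely from
   pairwise carrier-set comparisons with explicit removal of contradictory
   and ambiguous sites — designed to stay correct under heavy missing data,
3. a **merged, named tree** after anchoring to a tabular reference
   (ISOGG-style `branch / parent / SNPs`), with novel branches named in the
   lineage-based Y Chromosome Consortium style (`Q1b1a1a2-ZK9`),
4. per-sample **haplogroup assignments** with support and conflict counts,
   and panel-resolution comparisons,
5. **capture QC**: on/off-target specificity, concentration-sorted moving
   windows, the concentration threshold for stable capture, Pearson
   correlation, group-sharing partition, singleton and SNP/InDel tallies.

A synthetic lineage-and-sequencing simulator (`simConfig`, `simulateTree`,
`simulatePileups`) provides cohorts with known ground truth for recovery
testing, including group-specific missingness, recurrent mutations and
sequencing error.

## Worked example

```r
library(Ylineage)

cfg <- simConfig(nBranches = 12,
                 nSamples = c(ModAdmix = 20, AncNAM = 12, ModNAM = 8),
                 mutationsPerBranch = 3, recurrenceRate = 0.02,
                 depthMean = c(ModAdmix = 20, AncNAM = 8, ModNAM = 30),
                 depthDispersion = c(ModAdmix = 5, AncNAM = 2, ModNAM = 5),
                 missingness = c(ModAdmix = 0.1, AncNAM = 0.6, ModNAM = 0.05),
                 baseErrorRate = 0.002, seed = 42)
truth <- simulateTree(cfg)
pile  <- simulatePileups(truth, cfg)

refA  <- setNames(truth@sites$refAllele, truth@sites$position)
sites <- annotateVariants(discoverVariants(pile, refA, catalog = truth@sites))
cm    <- buildCallMatrix(pile, sites, t = callThresholds())
cm
#> YCallMatrix: 37 sites x 40 samples
#>   derived calls: 269; missing: 28.0%

tree <- inferTree(cm)
tree
#> BranchTree: 11 branches, 36 SNPs
#>   provenance: inferred=11
#>   removed variants: 1 (contradictory=1)

named <- nameBranches(anchorTree(tree, NULL), rootLabel = "Q")
asg   <- assignHaplogroups(cm, named)
head(asg[, c("sample", "haplogroup", "depth", "support", "status")], 4)
#>   sample haplogroup depth support    status
#> 1  AN001       <NA>     0      NA failed_qc
#> 2  AN002  Q1a4-ZK20     3       1  assigned
#> 3  AN003 Q1b1a-ZK13     4       1  assigned
#> 4  AN004   Q1a1-ZK1     3       1  assigned

st <- singletonStats(cm)
sprintf("%d of %d variants (%d%%) are singletons", st$count, st$total, st$percent)
#> "5 of 37 variants (14%) are singletons"
```

Reading the output: 40 simulated samples yield 37 polymorphic sites after
strict calling; 28% of cells are missing, driven by the ancient group's
60% site missingness and shallow depth. The tree builder removed exactly
one variant — the cross-lineage recurrent site injected at a rate of 2% —
and sorted the remaining 36 SNPs into 11 branches. One ancient sample had
no surviving calls and fails QC rather than being guessed; the others are
assigned with full support, and their haplogroup labels are generated from
the configured root letter because no reference tree was supplied
(`anchorTree(tree, ref)` with a reference names matched branches and
reports the rest as novel).

A thin command-line front end over the same functions ships in
`inst/cli/ylineage.R` with subcommands `simulate`, `call`, `tree`,
`anchor`, `assign` and `qc`.

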