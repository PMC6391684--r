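# vgenevar

Population-scale germline variation in the immune receptor V gene families.

The immunoglobulin heavy-chain variable (IGHV, chr14) and T-cell receptor
beta variable (TRBV, chr7) loci are tandem arrays of ~45 functional V gene
segments that supply the variable component of B- and T-cell receptors
through VDJ recombination. Both loci are riddled with copy-number variation
and segment duplicates so similar that short reads cannot tell them apart,
which makes standard variant calling unusable there. `vgenevar` implements a
read-depth genotyping workflow for these loci, aimed at quantifying
*sample-level* variation (variant frequencies, diversity summaries,
population structure) rather than clinical-grade individual genotypes. It is
written for immunogenetics and population-genetics researchers working from
short-read whole-genome summaries.

## What it computes

Near-identical segments (e.g. IGHV3-23 / IGHV3-23D) are first merged into
*operationally distinguishable groups* by single-linkage at ≥ 95%
global-alignment identity. For each individual and group, diploid copy
number is estimated from read depth:

    base_cov = kmer_cov · r / (r − k + 1)            (k-mer → per-base)
    plateau  = base_cov · L / (L − r + 1)            (trapezoid correction)
    CN       = 2 · plateau / genome_coverage

Integer CNV genotypes are then called per polymorphism by Ward/Euclidean
hierarchical clustering of the CN vectors, with clusters assigned to the
nearest diploid genotype class (all unordered sums of haploid variant
pairs). Downstream layers add: haploid variant relative abundances; regional
chi-squared goodness-of-fit tests; pairwise R² between segments (polymorphism
independence) and the implied haplotype-count product; the probability that
two individuals differ in their segment presence sets; a simplified
read-backed diploid phaser for two-copy segments; closest-allele matching
with the published novel-allele nomenclature
(`{ref}{alt}{position}{refAA}{altAA}`, e.g. `IGHV1-18*01_ag168ND`, with
`(P)` for premature stops and `(T)` for truncations) under the conservative
“called in ≥ 2 individuals” rule; diversity summaries (mean pairwise bp
difference, SNPs per segment, novel-allele fraction); region-private
variants; Weir–Cockerham FST on haplotype counts; SMACOF metric MDS of
allele copy vectors x ∈ {0,1,2}^m; and cross-species repertoire diversity
via package-authored affine-gap Smith–Waterman and Needleman–Wunsch
aligners.

Because the original cohort (SGDP) cannot be bundled, the package ships a
first-class synthetic cohort generator that reproduces the study design —
286 individuals across 7 geographic regions, of which 109 blood/saliva
samples are usable for IGHV (cell-line DNA has a VDJ-truncated IGHV locus) —
with fully known ground truth, so every stage is testable end to end.

## Worked example

```r
library(vgenevar)
res <- run_pipeline(pipeline_config("IGHV", seed = 1))
print(res)
#> <pipeline_result> seed 1, config da1f29fb
#>   stage 1 reference: 25 alleles in 13 operational groups
#>   stage 2 cohort: 109 of 286 individuals usable for IGHV
#>   stage 3 copy number: 5450 estimates over 50 groups
#>   stage 4 CNV: 5 polymorphisms called; mean off-block R^2 = 0.00614; haplotype product = 192
#>   stage 5 alleles: 24 alleles called over 11 two-copy groups; 27 SNPs
#>   stage 6 statistics: avg bp diff = 0.68%; SNPs/segment = 2.45; novel fraction = 2/24; overall FST = 0.0182
#>   stage 7 MDS: stress-1 = 0.33; regional silhouette = -0.0931
```

Reading the log: 109 of the 286 simulated individuals are blood/saliva and
enter the IGHV analysis; the five planted CNV polymorphisms are essentially
uncorrelated (mean off-block R² = 0.006), so the number of locus-wide CNV
haplotypes is estimated as the product of per-polymorphism variant counts
(here 2·2·2·6·4 = 192 for this realisation). The planted insertion
polymorphism is recovered at its simulated frequency:

```r
res$cnv$relative_abundance[["IGHV1-69_block"]]
#>   variant count  fraction   level
#> 1 dup_ins    83 0.3807339 haploid
#> 2  single   135 0.6192661 haploid
```

and both planted novel alleles are called under their exact expected names:

```r
subset(res$alleles$callset$table, novel,
       c(allele_name, n_haplotypes, n_individuals, frequency))
#>             allele_name n_haplotypes n_individuals frequency
#> 1   IGHV1-18*01_ag168ND           23            21 0.1090047
#> 2 IGHV3-7*01_gt234E_(P)           23            22 0.1121951
```

`min_max_haploid()` gives the copy-number bound used for high-copy groups:
a largest observed diploid total of 13 decomposes most evenly into 6 + 7,
so the largest haploid copy number is at least `min_max_haploid(13)` = 7
(likewise 7 → 4).

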