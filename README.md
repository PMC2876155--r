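# asppcr — allele-specific PCR assay design and gel-free SNP genotyping

`asppcr` is an R toolkit for SNP genotyping with allele-specific primers
(ASP) under standardized PCR conditions, aimed at plant geneticists who
need cheap multi-sample or multi-locus genotyping without
electrophoresis, probes or array hardware.

A codominant ASP assay interrogates one biallelic SNP with a *pair* of
PCR reactions sharing one reverse primer. Each forward primer places its
3'-terminal base on the SNP, so extension proceeds only from the matching
allele; an **artificial mismatch** at the third base from the 3' end
destabilizes extension from the non-matching allele and sharpens
discrimination. The allowed substitutions, and the replacement chosen for
a given template base, come from an empirical specificity matrix
(fraction of primers showing single-band allele-specific amplification,
out of 10 tested per substitution):

| matching base | →A | →T | →G | →C |
|---|---|---|---|---|
| A | 0% | 50% | 60% | 60% |
| T | 60% | 0% | **90%** | 10% |
| G | 50% | **90%** | 0% | 40% |
| C | 60% | 40% | 40% | 0% |

Only pairs whose both directions reach 50% are used: the A–G transition
and the A–T, A–C and G–T transversions. Because the artificial mismatch
also shifts primer Tm, primer lengths are tuned (nearest-neighbor
thermodynamics, unified parameter set, salt-corrected) so every assay
runs under one protocol: annealing at 58 °C, endpoint SYBR-type
fluorescence read at 75 °C. Amplification is then a binary optical
signal: with the allele-A and allele-B reactions in adjacent wells, the
quadrant rule *A-only → AA, B-only → BB, both → AB, neither → no call*
yields a codominant genotype. A 96-well plate genotypes 48 samples at
one SNP (multi-sample) or 48 SNPs of one sample (multi-locus).

Downstream, the package detects recombinants in F2 populations and
narrows a causal-locus interval from recombinant genotypes plus
homozygous-progeny phenotypes, summarizes marker spacing, draws graphical
genotypes (SVG + TSV), computes genotype distances (opposite homozygotes
1, heterozygote vs anything 0.5, identical 0) and builds neighbor-joining
trees with bootstrap support, written as Newick. A simulator generates
genomes, SNP panels, F2 meioses under the Haldane map function
`r = (1 − e^(−2d/100))/2`, diversity panels and two-channel fluorescence
plates with known truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(asppcr)

# a synthetic reference with one SNP, and its assay
ref <- simulate_reference(sim_config(seed = 42, n_chrom = 1,
                                     chrom_len_bp = 3000, n_snps = 1))
assay <- design_assay(ref$genome, ref$snps[1, ])
assay
#> ASP assay for S0001 (chr1:2160 C/T)
#>   fwd A:  primer [A+] 5'-GGCAACGGTACTCGACGTAAGACAC-3'  25nt  Tm 61.2  GC 0.56
#>   fwd B:  primer [B+] 5'-GGCAACGGTACTCGACGTAAGACAT-3'  25nt  Tm 59.6  GC 0.52
#>   shared: primer [none-] 5'-TCGGTAAAGTCTCCTCGTGTTCAAC-3'  25nt  Tm 58.6  GC 0.48
#>   product 100 bp, annealing 58 degC, mismatch A->C
```

Both forward primers end on the SNP (C vs T), share the same A→C
artificial mismatch at the third base from the 3' end, and sit near the
60 °C Tm target; the reverse primer is shared. The discrimination report
verifies the (1 vs 2)-mismatch pattern — each forward primer differs from
its own allele template only at the artificial mismatch, and from the
other allele template at the mismatch *and* the 3' terminus:

```r
check_allele_discrimination(assay, ref$genome)
#>    primer vs_allele n_mismatch expected   ok positions
#> 1   fwd_a         A          1        1 TRUE         3
#> 2   fwd_a         B          2        2 TRUE       3,1
#> ...
```

Simulated plates round-trip through the caller:

```r
truth <- simulate_f2(setNames(c(0, 15, 30), c("M1", "M2", "M3")),
                     48, seed = 43)
lay   <- make_layout("multi_sample", rownames(truth), colnames(truth))
sim   <- simulate_plates(truth, lay, sim_config(seed = 44, dropout = 0))
calls <- call_plates(sim$plate_data)
mean(calls[rownames(truth), colnames(truth)] == truth)  # 1
call_rate(calls)                                        # 1
```

A shell entry point with `design / call / map / tree / simulate /
layout` subcommands ships in `inst/cli/asppcr`:

```sh
Rscript inst/cli/asppcr design --fasta ref.fa --snps snps.vcf --out assays.tsv
Rscript inst/cli/asppcr call --plates data.csv --layout layout.tsv --out g.tsv
Rscript inst/cli/asppcr tree --genotypes g.tsv --reps 1000 --seed 17 --out t.nwk
```

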