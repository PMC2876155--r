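Package: asppcr
Title: Allele-Specific PCR Assay Design and Gel-Free SNP Genotyping
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for SNP genotyping with allele-specific PCR (ASP)
    under standardized conditions. Designs codominant ASP assays (two
    allele-specific forward primers whose 3' terminus sits on the SNP,
    sharpened by an artificial mismatch at the third base from the 3'
    end, plus one shared reverse primer), standardizes primer melting
    temperatures to a common annealing protocol, calls genotypes from
    gel-free endpoint-fluorescence plate reads, maps loci in F2
    populations from recombinant genotypes and progeny phenotypes,
    builds neighbor-joining trees with bootstrap support from
    multi-locus genotypes, and simulates every input (genomes, SNP
    panels, F2 meioses under the Haldane map function, fluorescence
    plates) with known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
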