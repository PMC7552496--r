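Package: asmphaser
Title: Haplotype Blocks from Allele-Specific DNA Methylation, SNPs and Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies DNA-methylation haplotype regions from whole-genome
    bisulfite sequencing. Adjacent partially methylated cytosines whose
    per-read methylation states co-segregate (two-sided Fisher exact test with
    Benjamini-Hochberg FDR control) are chained into allele-specific
    methylation blocks; heterozygous SNPs covered by the same reads are phased
    into the blocks; and blocks can be merged with Hi-C-derived phased blocks
    through a consistency-score (HapScore) algorithm. Includes a diploid
    bisulfite-read simulator with planted allele-specific methylation regions
    and known SNP phase for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
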