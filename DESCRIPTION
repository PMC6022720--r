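Package: mitohaplo
Title: Mitochondrial Haplogroup Classification from Targeted SNP Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns broad European, African, and Native American mitochondrial
    haplogroups from a small custom panel of mitochondrial DNA single nucleotide
    polymorphisms, using a reduced phylogenetic tree and an accumulator-based
    recursive tree descent. Genotypes are read from standard PED/MAP files and
    collapsed to haploid mtDNA calls, markers are filtered by genotyping
    call rate, and results are exported with the full root-to-haplogroup path.
    Includes a ground-truth-labelled synthetic genotype simulator (with
    pedigree trios, missingness, and discordant-call noise) for validation,
    plus concordance scoring between haplogroup call sets and founder-only
    haplogroup and lineage frequency summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
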