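Package: triokit
Title: Trio-Binning Read Partitioning, Haplotype-Switch Detection, Homology
    Scaffolding and Assembly QC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the computational stages of trio-binning
    haplotype-resolved genome assembly. Builds parent-specific (hap-mer)
    k-mer sets from parental short reads and partitions offspring long
    reads into parental bins; quantifies haplotype phasing of an assembly
    from window-based coverage differences of binned reads and detects
    haplotype-switch blocks; performs reference-guided ordering and
    orientation of contigs into AGP scaffolds and donor-based gap
    patching; computes assembly statistics, gap locations, telomere
    repeat profiles, heterozygosity estimates and dotplot tracks. A
    synthetic diploid-trio simulator with full ground truth supports
    validation of every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
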