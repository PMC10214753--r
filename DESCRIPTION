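Package: pilepool
Title: Pile-Based Haplotype Clustering for Pooled Long-Amplicon Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs gene-scale haplotypes from pooled high-fidelity
    long-amplicon reads by guide-anchored variant profiling, per-read "pile"
    error correction and cluster filtering; annotates target-site resistance
    (TSR) codons of the plastidic acetyl-CoA carboxylase gene (ACCase);
    cross-validates haplotype frequencies against pooled SNP allele
    frequencies; benchmarks individual-versus-pool haplotype recovery; and
    models the persistence of deleterious TSR alleles under genetic drift
    with a diploid Wright-Fisher simulation. A seeded synthetic-data
    generator produces reference amplicons with a multi-exon gene model,
    haplotype sets and HiFi-like reads with homopolymer-biased indel errors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    Matrix,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Genetics, PopulationGenetics, Clustering
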