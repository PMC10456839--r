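Package: crcmeiosis
Title: Cosegregation of Recombinant Chromatids: Meiosis Models and
    Population Genetics of Auto-Pseudogamy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time, individual-based models of automictic meiosis in
    sperm-dependent parthenogens (auto-pseudogamous nematodes) in which the
    first meiotic division fails and nonsister chromatids are retained in the
    oocyte. Implements an evolvable cosegregation bias b of the two
    recombinant chromatids (loss-of-heterozygosity rate beta = (1-b)/2), an
    island-model metapopulation life cycle with selection and migration,
    modifier-locus invasion experiments for the evolution of pseudogamy and
    of recombinant-chromatid cosegregation, genomic summary statistics
    (observed/expected heterozygosity, F_IS profiles, r^2 decay, sibling
    genotype-class tables, LOH tracts), a multinomial likelihood-ratio screen
    for heterogeneous read frequencies among sister individuals, an exact
    parity test for chromatid-paint counts in embryos, and synthetic-data
    generators for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'meiosis.R'
    'parity.R'
    'lifecycle.R'
    'sumstats.R'
    'sibhet.R'
    'synthetic.R'
    'io.R'
    'cli.R'
    'modifier.R'
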