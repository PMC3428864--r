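Package: clonehistory
Title: Subclonal Architecture and Life-History Reconstruction of Tumor Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the clonal evolution of a tumor from deep
    whole-genome sequencing: cancer-cell-fraction computation for somatic
    substitutions, sensitivity-corrected Bayesian Dirichlet-process clustering
    of clonal and subclonal mutations via a truncated stick-breaking Gibbs
    sampler, molecular-time dating of chromosomal gains from mutation
    multiplicity, early/late mutation-spectrum comparison, subclonal
    allele-specific copy-number estimation from phased germline haplotypes
    (Battenberg-style), read-pair phasing of somatic mutations, and
    pigeonhole-principle phylogeny assembly. A synthetic-tumor simulator with
    full ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
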