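Package: introscan
Title: Diagnostic SNP Calibration and Segregation Distortion Analysis for
    Interspecific Hybrid Crosses
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genomic porosity between two divergent
    species from biallelic SNP genotypes of parental populations and
    laboratory-bred hybrids. Implements technical-replicate and contamination
    detection from the multimodal distribution of pairwise genotype distances,
    allele polarization to a reference parental species, a diagnostic /
    discriminant SNP score with panel classification and chromosome-enrichment
    testing, validation of obligate heterozygosity in F1 hybrids (volcano
    statistics), group-mean imputation with Patterson-normalized PCA and
    Tracy-Widom axis significance, a per-individual hybrid index, and per-locus
    segregation-distortion analysis of F2 cohorts (allele-transmission t-test,
    exact Hardy-Weinberg test, signed heterozygote-excess D statistic, eight-way
    locus categories). A synthetic two-species cross simulator with full ground
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
Config/testthat/edition: 3
biocViews: SNP, PopulationGenetics, Genetics, QualityControl,
    PrincipalComponent, StatisticalMethod
RoxygenNote: 7.3.3
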