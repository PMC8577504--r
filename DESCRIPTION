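Package: rarevarqc
Title: Rare-Variant Quality Control for Two-Channel SNP Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Array QC", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulation, genotype calling, and quality control of rare variants
    (minor allele frequency below 1 percent) on two-channel SNP genotyping
    arrays.  Provides a synthetic intensity generator with injected array
    pathologies (bubble/scratch artifacts, plate-level batch shifts,
    cross-hybridizing probesets), prior-regularized Gaussian-mixture genotype
    calling in contrast space, a replicate-probe rare-het adjustment that
    demotes inconsistent heterozygous calls to no-calls, plate-shift detection
    and renormalization within batches, consolidation of the two adjustment
    algorithms with conflict filtering, a minor-allele-frequency concordance
    filter against reference sequencing frequencies on a log2-ratio scale, and
    disease-panel screening evaluation (PPV/NPV per MAF bin) against a gold
    standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
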