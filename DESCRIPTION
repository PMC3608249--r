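Package: famethyl
Title: Family-Based Analysis of CpG Methylation with Pedigree Variance Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based epigenome-phenotype association studies of
    targeted CpG regions measured by mass-spectrometric bisulfite assays.
    Provides pedigree parsing and recursive kinship computation, an in-silico
    model of EpiTYPER-style base-specific cleavage and fragment-mass
    quantification (CpG units, the 16 Da per-methylation mass shift, mass
    collisions), replicate-level quality control, rank-based inverse normal
    transformation, maximum-likelihood polygenic variance-component models
    (heritability with the boundary chi-square mixture test, covariate and
    association scans), effective-number-of-tests multiple-testing correction,
    and a synthetic extended-family cohort generator for parameter-recovery
    and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
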