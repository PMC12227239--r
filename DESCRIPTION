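Package: orthotherm
Title: Comparative Thermal Stability of Orthologous Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying interspecies divergence in protein
    thermostability. Implements thermal proteome profiling (TPP) analysis
    from peptide-level reporter intensities: spike-in standardization,
    melt-curve fitting with a four-parameter logistic model, bootstrap
    confidence intervals for melting temperatures, cross-dataset
    temperature-vector renormalization, and allele-specific handling of
    interspecific hybrid data. Provides comparative statistics on ortholog
    pairs (sign tests, hybrid-versus-parent contrasts, annotation
    enrichment, abundance-adjusted species effects), two-state van 't Hoff
    fits to circular dichroism melts, five-parameter logistic estimation of
    half-inhibition temperatures from growth and residual enzyme activity,
    and antisymmetric aggregation of forward/reverse per-substitution
    folding free-energy predictions. A synthetic-data generator with known
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
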