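Package: mediaopt
Title: Active-Learning Optimisation of Microbial Growth Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed Design-Build-Test-Learn (DBTL) pipeline for
    data-efficient optimisation of fermentation media, built around
    lipopeptide (surfactin) production in Bacillus subtilis. Provides a
    synthetic-data generator for titre landscapes, correlated metabolite
    panels, flow-injection mass-spectrometry traces and growth curves;
    centred Latin-hypercube and block-randomised 96-well plate designs;
    signal processing (asymmetric least-squares baseline correction,
    trapezoid peak integration, IQR outlier filtering, per-batch M9
    normalisation); a heteroskedastic Matern-5/2 Gaussian-process
    surrogate with analytic marginal-likelihood gradients; Monte-Carlo
    batch noisy expected improvement (qNEI) acquisition; a loop
    orchestrator tracking uncertainty maps and the performance cliff; and
    downstream analyses (Spearman correlation clustering, PCA,
    Pareto trade-offs, directional anisotropy profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    withr,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
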