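Package: hpcsi
Title: Simulation and Analysis of Hyperpolarized 13C Chemical Shift Imaging Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating and analyzing dynamic two-dimensional
    chemical shift imaging (CSI) of co-injected hyperpolarized
    [1-13C]pyruvate and [13C]urea in the rodent brain. Provides a two-site
    pyruvate-lactate exchange simulator with RF-depletion losses and its
    closed-form AUC-ratio identity, a physics-based dynamic CSI k-space
    generator, the quantification chain (spatial zero-filling, Fourier
    reconstruction, time-summed spectra, three-peak Lorentzian fitting,
    lactate/pyruvate and vascular-normalized urea maps, cohort z-score maps,
    bilinear heatmap rendering), synthetic pre/post-gadolinium T1 image
    pairs with an enhancement-volume endpoint, a latent-burden multi-animal
    cohort generator with correlated ex vivo markers, and the group
    statistics used for treatment-response studies (one-way ANOVA with
    Tukey HSD, Kruskal-Wallis with Dunn pairwise tests and the
    Benjamini-Krieger-Yekutieli two-stage step-up FDR, Pearson correlation
    and simple linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
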