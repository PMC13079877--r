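Package: gibbsnn
Title: Thermodynamically Consistent Neural Excess Gibbs Energy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hard-constrained neural networks for the molar excess Gibbs energy
    of liquid mixtures. Activity coefficients are obtained by exact
    differentiation of a learned excess-Gibbs-energy surface built from
    molecular embeddings, temperature and composition, so Gibbs-Duhem
    consistency, pure-component limits and permutation invariance hold by
    construction. The package implements the full forward pass (embedding
    refinement, similarity-based lumping, Muggianu projection onto binary
    subsystems, deep-set binary interactions), Lipschitz-regularized training
    on five thermodynamic data types (VLE with and without vapor composition,
    infinite-dilution activity coefficients, liquid-liquid equilibria, excess
    enthalpies), a differentiable surrogate solver for binary liquid-liquid
    phase splits, convex-envelope phase-split computation, bubble-pressure
    calculations, classical ground-truth models (Margules, NRTL) with a
    synthetic data generator, and system-wise evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
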