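Package: seqfeatsim
Title: Monte Carlo Simulation of Biological Sequences and Correlated
    Feature Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates large Monte Carlo simulated data sets from small
    DNA/RNA/protein sequence collections or numerical feature tables.
    Sequences are simulated from length and composition blueprints drawn
    from fitted log-spline-family densities, or from a profile hidden
    Markov model built on a user-supplied multiple sequence alignment.
    Numerical feature matrices are simulated through a Gaussian copula
    (Cholesky decomposition of a rank-correlation matrix) so that both
    the per-feature marginal distributions and the pairwise or triplet
    between-feature correlations of the original data are preserved.
    Simulated sequences can be projected into feature space
    (pseudo-amino-acid composition, dinucleotide physicochemical
    properties, GC content) and filtered by a rejection sampler that
    combines per-feature quantile bounds with a multivariate Mahalanobis
    distance rule, so that the accepted set matches the feature-space
    distribution of the originals. Diagnostics cover rank-correlation
    and normality detection, original-versus-simulated comparison, and
    reference classifiers (Gaussian naive Bayes and probabilistic neural
    networks) with accuracy, F-score and Matthews correlation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    grDevices,
    jsonlite,
    optparse,
    seqinr,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
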