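---
title: "Simulating biological sequences and correlated feature data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating biological sequences and correlated feature data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(seqfeatsim)
```

Many sequence-analysis projects start from a data set that is too small for
the model one wants to build: a few dozen experimentally validated
transcripts, a handful of peptides from one family, a short table of
measured physicochemical features. `seqfeatsim` addresses this by Monte
Carlo simulation: it fits the *distributions* that characterize the small
original set — sequence lengths, residue compositions, per-feature marginals,
between-feature rank correlations — and then samples arbitrarily many new
records from those fitted distributions, with an optional rejection step
that discards simulated sequences whose feature-space projection does not
look like the originals.

This vignette is the package's account of the underlying methods: the
models, their assumptions, the tunable parameters, and the design decisions
that were genuinely open.

## De novo sequence simulation: the blueprint model

`fit_blueprint_model()` treats each original sequence as one observation of
a *(length, composition)* pair. The length distribution and, separately,
the distribution of each core symbol's per-record fraction (4 nucleotides
or 20 amino acids) are fitted with a smooth one-dimensional density
(next section). `simulate_sequences()` then repeats, for each new record:

1. draw a length from the fitted length density, round it, floor at 1;
2. draw each symbol's fraction from its fitted density, clip negatives to
   zero and renormalize the vector to sum to 1 (a *blueprint*);
3. emit that many residues i.i.d. from the blueprint composition.

Two modelling choices deserve emphasis. First, length and composition are
sampled **independently**, not resampled jointly per original record; a
record-level bootstrap would preserve any length–composition coupling but
reproduces only observed combinations, which defeats the purpose of
simulating beyond the data. Second, residues within a sequence are i.i.d.
given the blueprint: the de novo module models *composition*, not residue
order. Order structure (motifs, conserved cores) is the profile-HMM module's
job, and dinucleotide-level properties of de novo simulated sequences are
instead controlled downstream by the rejection sampler.

```{r blueprint}
fam <- make_sequence_family(50, alphabet = "dna",
                            length_law = list("unif", 80, 200),
                            concentration = c(6, 4, 4, 6), seed = 7)
model <- fit_blueprint_model(fam)
sim <- simulate_sequences(model, 2000)
ks_distance(nchar(sim$sequences), nchar(fam$sequences))
```

Ambiguity codes (`N` for nucleotides, `X` for proteins) are accepted on
input but excluded from composition denominators and never emitted: no
published convention exists for simulating ambiguity, and emitting it would
contaminate downstream feature extraction.

## The density engine

Every scalar characteristic goes through `fit_density()`, which models the
log-density as a cubic B-spline. The fit uses Lindsey's device: bin the data
into a fine histogram (between 50 and 200 bins, scaled to *n*), regress the
counts on a B-spline basis of the bin midpoints under a Poisson likelihood,
and exponentiate the linear predictor. The spline's degrees of freedom are
chosen by BIC over the candidate grid {4, 6, 8, 10, 12} — small enough to be
cheap, wide enough to cover unimodal through clearly bimodal shapes. Two
fallbacks exist: a Gaussian KDE with Silverman bandwidth and boundary
reflection at finite support bounds, and the raw empirical distribution,
which is selected automatically below 10 distinct values (a common regime:
the package targets inputs of tens of records). All-identical values
degrade to a point mass with a warning.

Sampling is by inversion on a precomputed CDF grid of 2048 points spanning
the data range extended by 1% on each side (clamped to any declared bounds);
the same grid serves the copula quantile transform, so direct sampling and
correlated simulation share one numerical path. The grid resolution bounds
the inversion error at roughly range/2048, negligible relative to sampling
noise at the package's scales. Integer characteristics such as lengths are
fitted as continuous and rounded at sampling time — discreteness matters
only at the resolution of single residues, far below the length variation
being modelled.

## Profile-HMM simulation

For homologous families, composition alone is the wrong model.
`build_profile()` consumes a multiple sequence alignment (alignment is an
*input* — use any aligner — so the package carries no alignment code) and
builds a minimal match/insert/delete profile HMM: columns with gap fraction
below 0.5 become match states (the standard heuristic), match emissions are
pseudocount-smoothed column counts, insert states emit the overall residue
background, and transition probabilities come from the observed per-row
state paths with the same Laplace pseudocount (default 0.1; small enough
not to swamp five-row toy alignments, large enough to keep every transition
reachable and traversal termination guaranteed). The topology has no
flanking/local-alignment states: simulation only needs the glocal core.
`sample_from_profile()` walks begin → end stochastically and returns
ungapped sequences.

```{r hmm}
aln <- msa(c("ACGTTGCAAC", "ACGTTGCAAC", "ACGATGCAAC",
             "ACGTTGCAAC", "ACGTTGCAAC"), alphabet = "dna")
hmm <- build_profile(aln, pseudocount = 0.1)
profile_consensus(hmm)
```

## Correlated feature simulation: the Gaussian copula

`fit_correlation_model()` + `simulate_features()` reproduce a numerical
feature table in two senses at once: each feature's marginal distribution,
and the between-feature association structure. The dependence target is the
**Spearman rank correlation** — rank correlation is invariant under the
monotone marginal transforms the copula applies, so it is the quantity the
machinery can actually promise to preserve (and the natural validation
statistic). Internally the Spearman matrix is mapped to the normal-score
scale by the exact relation for Gaussian copulas,

$$ r = 2 \sin\left(\frac{\pi \rho_S}{6}\right), $$

Cholesky-factored, and used to color independent standard normals; the
normal CDF maps these to uniforms, and each feature's fitted marginal
quantile function maps the uniforms to data scale. Because the last step is
exactly the marginal's inverse CDF, the copula cannot distort marginals: the
per-feature fidelity of correlated simulation is identical to independent
(1D) simulation by construction, and the test suite asserts both.

Association can be preserved at three scopes: `pairwise_2d` and
`triplet_3d` simulate declared (or greedily auto-formed, strongest-|rho|
first) groups jointly with independence between groups — useful when only
low-order associations are trusted at small *n* — and `full` uses one joint
copula. A rank-deficient or indefinite target (e.g. duplicated features) is
repaired by eigenvalue clipping at 1e-10 followed by rescaling to unit
diagonal; the repair is never silent — the Frobenius distance moved is
recorded on the model and reported.

```{r copula}
R <- matrix(c(1, .6, .3, .6, 1, .45, .3, .45, 1), 3)
orig <- make_correlated_features(1500, R, seed = 11)
cmod <- fit_correlation_model(orig, mode = "full")
sim <- simulate_features(cmod, 1500)
round(cor(sim, method = "spearman"), 2)
```

## Feature extraction

Three projections from sequence to feature space are built in:

* **Pseudo-amino-acid composition** (`pseudo_aa()`): the 20 residue
  frequencies augmented with λ sequence-order correlation factors, where
  factor *j* is the mean squared difference of standardized physicochemical
  properties between residues *j* apart, averaged over the classical three
  scales (hydrophobicity, hydrophilicity, side-chain mass; each standardized
  to mean 0, unit SD over the 20 residues). The vector is normalized to sum
  to 1 with the conventional weight *w* = 0.05. λ ranges 1–10; λ = 4 is the
  conventional working depth for protein-family problems and the package
  default.
* **Dinucleotide property averages** (`dinuc_features()`): for each property
  in a 16-column table, the mean over all overlapping dinucleotide windows.
  The bundled table carries 12 literature-derived conformational and
  thermodynamic scales (nearest-neighbor enthalpy/entropy/free energy,
  melting temperature, stacking energy, and B-DNA step geometry); larger
  catalogs load from a user TSV in the same documented dialect. Tables are
  DNA-keyed; RNA is handled by a U→T lookup shim, and windows containing `N`
  are skipped.
* **GC content** (`gc_content()`), with `N` excluded from the denominator.

## Feature-space rejection

Composition-blueprint sequences match length and residue composition but
nothing forces their *derived features* to match. The rejection sampler
closes that gap: `simulate_sequences_with_features()` generates candidate
batches, projects them into the chosen feature space, and keeps only
candidates that (i) fall inside every feature's empirical `[q, 1−q]`
quantile bounds computed from the originals, and (ii) have squared
Mahalanobis distance from the originals' mean within the chi-square
`1 − α` quantile at df = number of features — the standard calibration,
under which a multivariate-normal feature cloud is accepted at rate
`1 − α`. Defaults are q = 0.025 and α = 0.025, i.e. mild two-and-a-half
percent trimming per rule; both are exposed, and tightening either is
guaranteed monotone (never grows the accepted set). Batch size defaults to
`max(target_n, 1000)` with a 50-round cap; shortfalls return a partial set
with a warning rather than looping forever, and zero acceptance raises a
diagnostic error naming the thresholds.

## Diagnostics and reference classifiers

`compare_sets()` reports per-feature two-sample Kolmogorov–Smirnov
statistics, both Spearman matrices and their absolute difference, and
Freedman–Diaconis histogram specifications for plotting.
`normality_tests()` flags 1D normality per feature (Shapiro–Wilk,
subsampling above its 5000-observation limit) and 2D/3D multivariate
normality per declared group (Mardia's skewness and kurtosis; a group is
flagged normal only when both components fail to reject at 0.05).
Significance is fixed at 0.05 and deliberately uncorrected for multiple
testing: the flags are descriptive screening, not inference, and the raw
p-values are returned for users who want to correct.

For end-to-end validation the package ships three reference binary
classifiers (`train_classifier()`): Gaussian naive Bayes — implemented
directly so that zero-variance features can be floored at 1e-9 with an
explicit notice rather than producing infinities — and probabilistic neural
networks (Parzen kernel classifiers) with Gaussian and Exponential kernels,
bandwidth defaulting to the mean nearest-neighbor distance of the training
points. `classification_metrics()` returns accuracy, F-score and the
Matthews correlation coefficient (0, flagged, when a confusion-matrix
marginal vanishes), and `feature_combination_search()` evaluates every
non-empty feature subset (capped at 10 features). The intended experiment:
train once on original data and once on rejection-filtered simulated data,
evaluate both on one held-out set, and confirm the accuracies agree — the
package's acceptance checks run exactly this at desk scale.

## What the synthetic generators do and do not emulate

`make_sequence_family()` (Dirichlet-composition families with optional
mutated motifs) and `make_correlated_features()` (a Gaussian-copula sampler
built from parametric quantile functions and `MASS::mvrnorm`, sharing no
code with the fitted-density simulation path) provide ground truth with
known parameters. They emulate compositional heterogeneity, length
variation and low-order rank dependence — the structures the simulator
models — but not phylogenetic relatedness, indel evolution, codon
structure, or heavy-tailed/discrete marginals. Green tests therefore
demonstrate that the machinery preserves what it claims to preserve, not
that simulated data carry the full complexity of real sequence families.

## Problem sizes and numerical choices

The package's own validation runs at deliberately modest scales — 50-record
families simulated to 2000 sequences; copula recovery at n = 4000; marginal
KS at 5000 vs 5000; rejection calibration on 10,000 candidates; classifier
parity with 300 training rows per class — sizes at which the sampling bounds
being asserted (KS < 0.08, |Δρ| < 0.05, acceptance 0.975 ± 0.01) have
comfortable margins under the generators' known laws. Tie-breaking and
degenerate-input policy throughout: point masses warn and propagate;
empirical fallbacks notify; covariance singularity falls back to the
pseudo-inverse with a message; correlation repair records its Frobenius
distance. All stochastic functions consume R's global RNG stream, so a
single `set.seed()` (or the CLI `--seed`) makes any pipeline byte-for-byte
reproducible.

## Known limitations

* Composition components are sampled independently per symbol and
  renormalized, not jointly on the simplex; a Dirichlet joint fit would
  respect negative dependence between fractions and is a documented
  alternative.
* The profile HMM has no local-alignment or flanking states and uses plain
  Laplace pseudocounts, not Dirichlet mixture priors; it is a simulator,
  not a homology-search profile.
* Explicit dependence grouping stops at triplets (`full` covers the general
  case); vine and t-copulas are out of scope.
* Rejection sampling cannot repair a generator that never proposes
  acceptable candidates; the acceptance rate in the report is the signal to
  revisit the sequence model rather than tighten thresholds.
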