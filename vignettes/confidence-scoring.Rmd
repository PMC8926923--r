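---
title: "Confidence scoring for small-molecule structure annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence scoring for small-molecule structure annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confmet)
```

## The problem

In-silico structure annotation of tandem mass spectra returns, for each
query spectrum, a ranked list of candidate structures from a database; the
top-ranked candidate is the *hit*. Raw scorer output is good at ranking
candidates *within* a query but nearly useless for deciding *between*
queries which hits to trust: incorrect hits can have high raw scores and
correct hits low ones, because every correct candidate competes with
orders of magnitude more incorrect ones, and because the correct structure
may be absent from the database altogether. `confmet` implements a
confidence-scoring workflow that orders hits across queries so that a user
(or a downstream FDR procedure) can concentrate on the annotations most
likely to be correct. It does not re-rank candidates within a query and it
never discards annotations.

## Score calibration by kernel density E values

For one query, let $x$ be the hit score and $x_1,\dots,x_n$ the scores of
candidates from a very large background structure database ("proxy
decoys": true decoys do not exist for small molecules). On the log scale
$y = \ln x$, the decoy scores are modeled by a Gaussian kernel density
estimate with Silverman's rule-of-thumb bandwidth
$h = 1.059223841\,\hat\sigma\,n^{-1/5}$, where $\hat\sigma$ is the sample
standard deviation (denominator $n-1$; the scale choice is recorded in the
object so calibration is reproducible). The E value is the expected number
of candidates, out of the $m$ candidates in the *target* search database,
scoring at least as high as the hit:

$$E = \frac{m}{n}\sum_{i=1}^{n}\left[\tfrac12 -
  \tfrac12\,\mathrm{erf}\!\left(\frac{y-y_i}{\sqrt2\,h}\right)\right].$$

Each bracket is the upper tail of one Gaussian kernel, so `e_value()`
evaluates the sum through `pnorm((y_i - y)/h)` — an exact identity, not an
approximation — and $P = E/m \in [0,1]$. The tests verify the closed form
against numerical integration of the KDE tail to $10^{-6}$ relative error.
Raw scores need not be positive: the default `shift_log` transform shifts
by $1 - \min(x_i)$ before the log when needed. Queries with fewer than two
decoy scores cannot be calibrated and flow into the single-candidate model
path with the calibrated feature marked missing. The feature handed to the
classifier is $-\log_{10}(E + \varepsilon)$, so better hits get larger
values.

## The sign-constrained linear SVM

The confidence score is a linear SVM over standardized hit features,
trained on labeled reference data, with *enforced directionality*: for
each feature we decide up front whether larger values may only increase
(direction $+1$) or only decrease ($-1$) confidence. A high raw hit score,
for instance, must never lower confidence, whatever the training sample
happens to suggest — this is the main guard against overfitting, together
with the restriction to a linear model. The default schema ships eight
features (raw hit score, calibrated score, score gap to the runner-up,
log candidate count, explained intensity fraction, fingerprint
cardinality, fragmentation-tree score, fingerprint quality), all
direction $+1$ except the log candidate count ($-1$: more candidates make
a query harder). The schema is data-driven; users register further
features with `feature_schema()`.

Directionality is enforced without a constrained solver: for each
constrained feature $j$ one synthetic positive training sample is added
whose only non-zero entry is $d_j\beta$ on feature $j$ (in standardized
space, so $\beta$ has an unambiguous scale). For large $\beta$ an optimal
solution must use the feature in the declared direction, and the exact
value of $\beta$ is immaterial; the default is $\beta = 10^7$ and the
tests check that $10^8$ and $10^9$ give matching weights. The underlying
problem — $\ell_2$-regularized squared hinge loss — is solved by an
active-set Newton iteration with a backtracking safeguard (each step
solves a ridge-like system on the margin-violating samples; the objective
is convex and piecewise quadratic, so this converges to the global
optimum). The regularization constant is selected from
$C \in \{10^{-5},\dots,10^5\}$ by internal 5-fold cross-validation
(fold count is our choice; accuracy is the selection criterion, ties
resolve to the smaller, i.e. more regularized, $C$). An independent
projected-gradient solver of the explicitly sign-constrained problem
serves as a test oracle only.

Decision values are mapped to $(0,1)$ by Platt scaling,
$P_{A,B}(f) = 1/(1+\exp(Af+B))$, fitted by penalized maximum likelihood
with a Newton iteration and the usual prior-corrected targets that keep
the fit finite under perfect separation. $(A,B)$ are fitted on the
training-set decision values. The resulting confidence score orders hits;
it is explicitly *not* a calibrated probability of correctness.

Two further application-time guards: feature values are capped to the
range observed in training before standardization (out-of-range features
cannot produce exaggerated decision values), and separate models are
trained per collision energy (10, 20, 40 eV and merged pseudo-ramp
spectra) and per candidate-count regime. Queries whose filtered candidate
list has exactly one structure are scored by a single-candidate model
without comparison features; multi-candidate training rows enter that
model with one uniformly selected candidate (seeded RNG). At scoring time
the model with the nearest collision energy is chosen — a 35 eV query
takes the 40 eV model; exact ties resolve to the lower energy, an
arbitrary but deterministic choice.

## FDR machinery

With known labels, the *exact* FDR of a reported list is simply the
fraction of incorrect hits (`exact_fdr()`, reported in percent). Without
labels, confidence scores are converted to estimates: treating one minus
the confidence as a posterior error probability $p_j$ and ordering hits by
confidence, $\widehat{\mathrm{FDR}}_k = \frac1k\sum_{j\le k} p_j$, which
is monotone and therefore also the q-value estimate. `ranked_hits()`
containers carry labels and/or posteriors; `roc_curve()`,
`hop_curve()` (both counts normalized by the total number of queries, so
the endpoint satisfies $x+y=1$ and methods with different annotation
yields stay comparable), `fdr_threshold_report()` and
`qq_estimated_vs_exact()` implement the evaluation side. Threshold ties
are handled step-wise: all hits sharing the cutoff score enter together.
The exact FDR of an empty list is reported as 0 with an `NA` threshold.

## The spectral noise model

Reference library spectra are cleaner than biological ones. To emulate
biological quality, `noisify()` distorts a spectrum in four ordered steps:
(1) a global relative mass bias drawn once per spectrum from
$N(0,\sigma_{mb}^2)$ — per spectrum rather than per dataset, the reading
most consistent with shifting every peak of a spectrum coherently; (2)
independent per-peak relative mass deviations from $N(0,\sigma_{md}^2)$;
(3) per-peak multiplicative intensity distortion from
$N(1,\sigma_{id}^2)$, then subtraction of $0.03\times$ the
(post-distortion) maximum intensity, then discarding peaks below
$10^{-3}\times$ the maximum; (4) injection of $\mathrm{round}(\alpha n)$
noise peaks. The `medium` preset uses
$\sigma_{mb}=\sigma_{md}=(10/3)\times10^{-6}$ (a 10 ppm $3\sigma$ window),
$\sigma_{id}^2=1$, $\alpha=0.2$; `high` uses $(15/3)\times10^{-6}$ and
$(20/3)\times10^{-6}$ (15/20 ppm), $\sigma_{id}^2=2$, $\alpha=0.4$.

Noise peaks are not uniform-random masses (those would be trivially
recognizable); they are harvested from donor spectra as the peaks with no
molecular subformula decomposition of the donor's precursor formula
within tolerance (`build_noise_peak_pool()`, bounded enumeration over a
CHNOPS+halogen monoisotopic mass table, adduct-shifted, default
$[\mathrm{M+H}]^+$). Their stored intensities are relative to the donor's
maximum and are rescaled by the receiving spectrum's maximum — the
under-specified "adjusted for maximum peak intensities" is resolved this
way. Spectra left with at most one peak are removed (`filter_sparse()`).
`tune_noise_model()` scales $(\sigma_{id}^2, \alpha)$ by bisection until
the median original-vs-distorted cosine reaches a user target; on real
reference data one would target medians like 0.88 (medium) or 0.71
(high), but on synthetic spectra only the tunability itself is a testable
property.

Spectral plumbing: MGF/MSP readers and writers, 7 ppm one-to-one greedy
peak matching (closest pairs first — deterministic, and on centroided
spectra equivalent to maximum-cardinality matching, which the tests check
against an augmenting-path oracle), normalized-dot-product cosine with
optional square-root intensities and precursor exclusion (peaks within
7 ppm of the precursor m/z), and pseudo-ramp merging of collision
energies: per-spectrum normalization to maximum 1, 7 ppm clustering,
intensity-weighted mean mass, summed intensity. Normalizing per energy
before combining is our choice (scale-free and reproducible); the
alternative — combining raw intensities — would let the highest-energy
spectrum dominate.

## Structure comparison

`tanimoto()` is the Jaccard index over any user-supplied binary property
sets (the package is fingerprint-agnostic). For highly similar molecules
the Tanimoto coefficient saturates, so `mces_distance()` computes the
exact maximum-common-edge-subgraph edge-deletion distance between
hydrogen-free molecular graphs: the minimum total number of edge
deletions after which the edge-induced remainders are isomorphic, with
element labels and bond multiplicities required to match and connectivity
of the remainder *not* required. Deletions are counted across both graphs,
so equal-edge-count non-isomorphic pairs have distance at least 2 (and
even). The solver iterates the number of retained edges downward from an
edge-type-multiset upper bound, pruning subset pairs by their type
signature before a colored VF2 isomorphism test; it is exact, refuses
instances above `max_size` (default 30 combined edges) rather than
falling back to a heuristic, and ignores isolated vertices (molecular
graphs have none). 2D identity (`structures_identical_2d()`) strips
stereo markers and compares canonical SMILES via local Open Babel
canonicalization — a deliberate replacement of any external
standardization web service, so results are reproducible offline but may
differ for exotic tautomers.

## What the synthetic generators do and do not emulate

`gen_scores()` draws candidate scores from log-normal mixtures — the
shape observed for real in-silico scorers, including occasional
multimodality. `gen_hit_dataset()` plants class-separated Gaussian
features with user-set effect sizes, a configurable correct-hit fraction
and a log-normal candidate-count distribution with single-candidate
queries mixed in; correctness is independent across queries.
`gen_spectrum()` places peaks on subformula masses so decomposability is
guaranteed by construction, with optional provably non-decomposable
planted noise peaks. None of this emulates real fragmentation chemistry,
correlated features, instrument-specific intensity response, or the
non-random structure of incorrect hits in real databases. Passing tests
therefore demonstrate that the machinery is implemented correctly and is
self-consistent — e.g. that estimated q values track exact q values when
posteriors are well specified — not that any particular performance level
will be reached on real data; on real data, FDR estimates from Platt
posteriors are known to be of mediocre, typically conservative, quality.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-spread decoy samples fall
back to a configurable bandwidth $\varepsilon = 10^{-6}$ with a warning;
all-equal decision values trigger an intercept-only Platt fit; constant
feature columns standardize with scale 1; empty candidate lists are
errors for feature extraction and are expected to be excluded (and
logged) upstream. Top-candidate ties break lexicographically by candidate
id. Models serialize to versioned JSON with full precision.

The test suite runs at deliberately desk-scale sizes — hit datasets of a
few hundred to 2,000 queries for training checks, 10,000-hit lists over
100 seeds for the random-AUC property, 1,000 spectra for noise-moment
checks, molecular graphs with up to six edges against the brute-force
MCES oracle — chosen so the whole suite completes in well under a minute
while keeping Monte-Carlo error comfortably inside the asserted
tolerances.

## Limitations

The package scores and evaluates annotations; it does not produce them.
Fingerprint prediction, fragmentation trees, molecular-formula
determination and candidate retrieval belong to upstream tools, and the
corresponding features are consumed as given. Negative-ion adduct
chemistry is reduced to a configurable adduct mass. The exact MCES solver
is exponential and intended for small molecules only. Confidence scores
are ranking scores: thresholds such as 0.64 (which corresponded to about
10% FDR on the reference evaluations that motivated this workflow)
transfer to new data only approximately and with no guarantee.
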