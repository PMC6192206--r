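---
title: "Ensemble scoring and decoy-split filtering of PSMs: methods and design"
author: "psmEnsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble scoring and decoy-split filtering of PSMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In metaproteomics an MS2 run is searched against a metagenome-derived
protein database that is simultaneously enormous (10^5–10^6 proteins)
and incomplete: a large fraction of spectra originate from peptides the
database does not contain. Both properties hurt a single scoring
function — the huge search space inflates the best random match, and
foreign spectra have no correct answer at all, so their best match is
noise with a plausible-looking score. This package combines three
scoring functions with very different mathematics, uses their agreement
as a confidence signal, and turns the whole thing into a supervised
classification problem whose error rate is controlled with a held-out
decoy split.

## The search model

Proteins are digested in silico with full tryptic specificity (cleavage
C-terminal to K/R, suppressed before P), up to 3 missed cleavages,
peptide length 6–60. Decoys are whole-protein sequence reversals with a
configurable identifier prefix (`Rev_` by default); reversal is an
involution, preserves composition and length statistics, and is the
standard decoy construction for this estimator. Peptides are indexed by
neutral monoisotopic mass (residue masses + water 18.0105647 Da; proton
1.00727646677 Da for m/z conversion; carbamidomethyl C +57.02146 Da as
the sole default fixed modification). I and L are distinct residues with
identical mass. Candidates for a spectrum are all peptides within the
precursor tolerance (default 0.05 Da; ppm available).

Fragmentation is modeled as singly charged b/y ladders, plus doubly
charged fragments for precursors of charge ≥ 3. No neutral losses,
a/c/x/z ions, isotope-error windows or flanking-bin augmentation: every
scored quantity stays simple enough to verify against a brute-force
oracle, which the test suite does.

### The three scoring functions

**MVH.** The spectrum keeps its most intense peak per 1 Da window;
surviving peaks are ranked by intensity and split into 3 classes with
sizes in geometric proportion 1:2:4 (unit `floor(T/7)` clamped to ≥ 1,
remainder to the weakest class). The m/z range of the retained peaks,
cut into 1 Da bins, is the candidate universe; bins without a retained
peak form an "empty" class. Each predicted fragment greedily claims the
nearest unclaimed peak within the fragment tolerance (0.5 Da default).
The score is the negative log multivariate hypergeometric probability of
the observed per-class match counts. Matches into the sparse,
high-intensity classes are combinatorially rarer and score higher. The
universe is clamped to at least (retained peaks + predicted fragments)
bins so the probability is always well defined, which matters only for
pathologically narrow spectra.

**Xcorr.** Square-rooted intensities are accumulated into bins of
1.0005079 Da (offset 0.4, the classical peptide-mass spacing), the
occupied range is split into 10 regions each max-normalized to 50, and
the fast transform subtracts from every bin the mean of its ±75-bin
neighbourhood (excluding itself, constant divisor 150, zero-padded at
the edges). The score is 0.005 times the dot product with the binary
theoretical spectrum — algebraically the cross-correlation at lag zero
minus the mean over lags ±75. The cumulative-sum implementation is
checked against the O(n·w) definition to 1e−9.

**WDP.** `Σ w_type · sqrt(I_obs/I_total) · (1 − |Δmz|/tol)` over
predicted fragments matched within 0.5 Da, with b/y weights both 1.
This concrete form — intensity-share weighted, mass-error discounted —
is this package's fixed definition of a weighted dot product.

### Two-tier orchestration

MVH is the cheapest and most memory-friendly scorer, so it screens all
candidates; the top 50 by MVH are rescored by Xcorr and WDP, and the
union of the top 5 per scorer is reported with all three scores and
per-scorer ranks. Tier depth and output depth are configuration
constants; for spectra with ≤ 50 candidates the two-tier result is
provably identical to exhaustive three-scorer scoring, and the test
suite asserts exactly that. Ties anywhere are broken by higher score,
then lexicographically smaller peptide, then target before decoy, which
makes results invariant to batch size and worker count (also asserted).

## The filtering model

For each spectrum each scorer nominates a rank-1 peptide; agreement
partitions spectra into unanimous, majority/minority and discordant
classes. Ten features feed the classifier: MVH, Xcorr, WDP; their score
differentials `Δ = (Sc − Sb)/Sb` where Sb is the best score of *other*
reported PSMs of that spectrum under the same scorer; the absolute
precursor mass error; the missed cleavage count; and the pre-filtering
spectrum counts of the peptide (#PEP, all charge states pooled) and of
the PSM's best parent protein (#PRO, the parent with the largest count
when a peptide maps to several).

Positive training data are unanimous PSMs from target proteins — the
agreement of three mathematically unrelated scorers is itself strong
evidence, so this class is clean enough to train on without knowing the
answer. Negative training data are decoy PSMs whose parent decoy
protein fell in the *training* half of a random by-protein split of the
decoys (seeded, default seed 20170922, α = 0.5). Decoys from the test
half enter neither training set; they are reserved for the error
estimate, so the classifier can never have memorized them. The
production classifier is ridge-penalized logistic regression on
standardized features; random forest (200 trees, minimum 50 samples per
leaf) and AdaBoost (200 depth-1 stumps, SAMME) are available for
benchmarking. The classification score is the predicted positive-class
probability.

Each spectrum keeps exactly one PSM — the rank-1 candidate with the
highest classification score (ties: target before decoy, then smaller
peptide). The acceptance threshold is swept over the sorted scores and
set to the most permissive cutoff whose estimated FDR

FDR = #TestDecoy / (α · #Target)

stays at or below the target (default 1%), where α is the *realized*
test fraction. Scaling the test-decoy count by 1/α estimates how many
decoys would have passed had all decoys been available to the estimator.
Training-split decoys are excluded from the numerator and from the
accepted set; in the sweep, tied scores are resolved decoys-first so a
block of tied targets can never slip in above the decoys that price
them. Peptides (any accepted PSM identifies its peptide) and protein
groups (proteins with identical accepted-peptide sets merged; a group
needs ≥ 1 group-unique peptide) are assembled from the accepted PSMs,
and the same estimator is applied at each level, with thresholds
re-swept per level on a quantile grid of at most 1000 cutoffs when
requested.

## Numerical and design choices

- **Differential guards.** Eq.-style differentials divide by the
  runner-up score. Denominators below ε = 1e−6 are replaced by ±ε, a
  single-PSM spectrum gets a fixed +1, and the result is clamped to
  [−5, 5]: an unclamped ratio against a near-zero WDP runner-up reaches
  10^6 and single-handedly destabilizes any standardized linear fit
  while meaning nothing more than "much better than the alternative".
- **Ridge penalty.** The glmnet lambda is 0.01·`l2_strength`,
  deliberately independent of training-set size. With a size-scaled
  penalty, a small and nearly separable training set (a few dozen decoy
  negatives) drives the coefficients to divergence and the predicted
  probabilities saturate to exactly 1.0, erasing the score ordering the
  threshold sweep depends on.
- **Spectrum-count population.** #PEP/#PRO count every reported PSM
  (the top-5 union) before filtering; a switch restricts them to
  rank-1-by-any-scorer PSMs. The full reported depth is the more literal
  reading of "before filtering", and in a small, densely covered search
  space the rank-1-only variant turns #PRO into a target/decoy label —
  target proteins accumulate genuine support — which quietly breaks the
  exchangeability the decoy estimator rests on.
- **Uniqueness scope.** Peptide uniqueness for protein inference is
  judged against groups (a peptide shared only by the members of one
  merged group still counts as unique), with a protein-scope switch.
  Subset proteins are not subsumed — only exact peptide-set equality
  merges.
- **Charge handling.** Spectra without a charge annotation are searched
  at assumed charges {2, 3} and the best row per (scan, peptide) is
  kept.
- **pepXML dialect.** One `spectrum_query` per (scan, charge), one
  `search_hit` per reported PSM, the three scores as `search_score`
  entries named `mvh`/`xcorr`/`wdp` — the minimal shape third-party
  filters consume; round-trip and a standard-parser read are tested.

## The synthetic-data generator

`syntheticConfig()` defaults define the study conditions: 500 proteins
of 100–400 residues drawn i.i.d. with K/R at 5.5% each (tryptic-site
density), 1000 spectra, 30% foreign, ≤ 1 missed cleavage and length
8–25 for sampled peptides, log-normal fragment intensities
(meanlog 7, sdlog 0.6), Gaussian fragment m/z jitter σ = 0.05 Da, 20
uniform noise peaks per spectrum, charges 2–3. About 70% of in-database
spectra draw a fresh peptide so that some peptides carry several
spectra and the count features have signal.

Foreign spectra emulate the incomplete-database condition. Their
peptides are *independent* random tryptic-like sequences
rejection-sampled until the mass lands within 0.05 Da of some
target-or-decoy database peptide, so they fall into populated search
windows as hard negatives. Independence is the load-bearing property:
a foreign peptide derived from a specific database entry (for example
by shuffling it) would carry its source — always a target — inside its
own search window, so junk matches would be systematically targets and
invisible to a decoy-based error estimate. With independent foreign
peptides the junk matches split evenhandedly between the species, which
is exactly how real out-of-database spectra behave.

What the generator does **not** emulate: realistic fragment-intensity
patterns, chimeric spectra, retention time, precursor m/z error
(in-database spectra have exact precursors, so the ΔM feature is nearly
degenerate here), modified peptides, and homology structure between
proteins. Passing tests on this fixture therefore demonstrate the
correctness of the machinery and the directional behavior of the
method, not instrument-grade performance.

## Problem sizes and limitations

The test suite runs the full pipeline at the default conditions (1000
spectra against ~86k indexed peptides, ~20 s per run) and a 20-seed
calibration study at the same scale; oracle checks (exhaustive MVH
enumeration, naive cross-correlation, WDP recomputation) run on small
instances where enumeration is exact.

Two limitations are worth stating plainly. First, the estimator
`#TestDecoy/(α·#Target)` carries no small-sample correction: at the
chosen threshold the next test decoy is always just below the cut, so
the estimate sits a step of roughly 1/(α·#Target) below the rate it
estimates. Second, training on unanimous target PSMs and using
peptide/protein count features couples acceptance mildly to the target
species, which pushes the true error slightly above the decoy estimate
under heavy foreign load. The calibration test measures the resulting
gap between mean estimated and mean ground-truth FDR across seeds, and
the acceptance script reports both numbers side by side for a single
run; on real metaproteomes the same directionality applies, which is
why entrapment-style checks with known-negative proteins remain good
practice on top of decoy estimates.
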