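---
title: "Methods: sequence-derived condensate analysis of fusion oncoproteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-derived condensate analysis of fusion oncoproteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focondense)
```

## The problem

Fusion oncoproteins (FOs) — chimeric proteins created when a chromosomal
translocation joins the N-terminal part of one parent protein ("head") to
the C-terminal part of another ("tail") — frequently form micron-scale
round intracellular assemblies (condensates, "puncta") when expressed in
cells. Whether a given FO does so is strongly constrained by the
physicochemistry of its sequence: disorder content, charge patterning,
prion-like composition, pi-contact propensity. `focondense` implements a
complete sequence-based pipeline around that observation: feature
computation, reference normalization, feature selection, clustering of
condensate formers into feature groups, a supervised condensation
classifier with per-feature attributions, model-guided mutagenesis, and
fusion-network summaries. An experimental FO is called puncta-positive
when condensates are detected in at least 17% of transfected cells
(inclusive, `classify_puncta()`); nucleolar and otherwise-structured
records pass through and are excluded from feature analyses.

## The 39 physicochemical features

`compute_features()` produces one row of 39 named features per record
(`feature_names()` fixes the names and order). The calculators:

* **Composition.** Counts and fractions of positive (R/K), negative
  (D/E), neutral, polar (Q/N/S/T/G/H), hydrophobic (A/I/L/V/M), aromatic
  (F/Y/W), chain-expansion-promoting (E/D/R/K/P) and proline residues;
  sequence length; average molecular weight; isoelectric point by
  bisection (tolerance 1e-4 pH units) on the Henderson–Hasselbalch net
  charge with the EMBOSS pKa set; fraction of disorder-promoting
  residues (positive values of the shipped disorder-propensity scale).
  Counts are integers before division, so `fraction * length = count`
  holds exactly.
* **Charge patterning.** The blob statistics use sliding windows of 5 and
  6 residues, averaged. Local charge asymmetry is
  $\sigma = (f_+ - f_-)^2 / (f_+ + f_-)$; $\delta$ is the mean squared
  deviation of blob $\sigma$ from the sequence value; $\kappa =
  \delta/\delta_{max}$, where $\delta_{max}$ is the largest $\delta$ over
  a constructive family of maximally segregated arrangements of the same
  composition (single-sign charge blocks separated by a neutral spacer of
  33 widths, with remaining neutrals split between the termini) *and* the
  observed arrangement itself, so $\kappa \le 1$ holds by construction.
  A diblock (all E then all K) attains $\kappa = 1$ exactly because the
  diblock is in the candidate family. $\Omega$ applies the same formalism
  to the two-class grouping {D,E,K,R,P} versus the rest. NCPR is the mean
  signed charge. SCD is the exact double sum
  $\frac{1}{N}\sum_{i<j} q_i q_j \sqrt{j-i}$. Sequences shorter than 6
  residues return missing blob statistics with a warning; a sequence with
  no charged residues has no defined $\kappa$.
* **Hydropathy.** Mean Kyte–Doolittle hydropathy normalized to [0, 1]
  ("Mean hydrop. 1"); the mean of a simulation-derived hydropathy scale
  ("Mean hydrop. 2"); and four patterning statistics applying the blob
  formalism to each hydropathy scale alone and to the charge-shifted
  value $h + q/2$, normalized by the sorted (fully segregated)
  arrangement and clipped to [0, 1].
* **Disorder and low complexity.** The default disorder provider maps
  the per-residue disorder-propensity scale through a centered moving
  average (window 25) and linearly onto [0, 1]. IDRs are maximal runs
  whose 11-residue moving average exceeds 0.45, with runs fewer than 12
  residues apart joined (gap residues included) and joined runs shorter
  than 60 residues discarded; the moving-average window shrinks
  symmetrically at the ends so length-60 terminal IDRs are not lost.
  "# Disorder AAs" is the total IDR length. LCD length counts residues
  covered by at least one 12-residue window whose base-2 Shannon entropy,
  normalized by $\log_2 12$, is below 0.78; the cutoff and normalization
  are configurable because entropy units are convention-dependent.
* **Acidic/basic tracts.** Within each IDR trimmed of its first and last
  residue, tract seeds are 8-residue windows with windowed |NCPR| at or
  above 0.5 and a single charge sign; overlapping same-sign seeds merge
  and the merged interval is trimmed to its outermost charged residue.
  ABT valence is the summed absolute tract charge, ABT density the
  valence per assessed IDR residue, ABT balance the tract residue count
  per unit valence. All three are missing when no IDRs exist — roughly a
  fifth of realistic fusion sets — and are filled downstream by
  class-conditional median imputation, mirroring how such missingness
  arises in practice.
* **Providers.** Prion propensity 1 (best 41-residue windowed mean
  log-likelihood ratio of a prion-domain composition table against
  background), Prion propensity 2 (windowed prion-aggregation propensity
  scale), PScore (mean pi-contact propensity, defined only at 140
  residues or more) and the predicted NLS count (merged runs of
  10-residue windows holding at least 6 K/R) are produced by registered
  provider functions. Any provider can be replaced by an adapter around
  an external predictor; a missing provider yields a missing value with
  a warning and the pipeline continues. The shipped provider parameter
  tables (prion composition, aggregation propensity, pi-contact scale,
  urea transfer energies, PPII propensities) are package-curated
  approximations of the published scales: they preserve the documented
  ordering of residue preferences, and no test or result in this package
  depends on their absolute values. The disorder provider was
  deliberately built on a published per-residue propensity scale rather
  than a reconstructed pairwise-energy matrix: a 20-value scale can be
  shipped faithfully, a 20×20 energy table cannot be reproduced from
  memory without fabrication, and the provider interface keeps both
  options open.

## Reference statistics and enrichment

Z-scores are taken against a folded-protein reference set:
`build_reference()` computes per-feature means and standard deviations
(missing values dropped per feature; constant features flagged and
refused for Z-scoring) and the pooled residue composition. Amino-acid
enrichment is the percent-ratio identity
$100 \times \mathrm{pct}_{seq} / \mathrm{pct}_{ref} - 100$, optionally
restricted to IDR intervals; a letter at twice its reference frequency
scores +100%, an absent letter −100%. The package does not ship a real
folded-proteome reference; `default_reference()` is a seeded synthetic
stand-in (500 sequences, three quarters folded-like, a minority of
disorder-leaning sequences so that IDR-dependent features retain nonzero
variance). Users reproducing real-data scales supply their own FASTA or
a precomputed statistics TSV (`read_reference()`).

## Feature selection

`mutual_information_matrix()` discretizes each feature by equal-frequency
binning into $\lceil n^{1/3} \rceil$ bins and computes plug-in empirical
MI in nats; the diagonal is the per-feature entropy. Equal-frequency
binning makes the estimate invariant under strictly monotone transforms
up to ties. The plug-in estimator is biased upward by roughly
$(b-1)^2/2n$ nats for independent features — at $n = 10{,}000$ and 22
bins that is ≈ 0.022 — which is why the redundancy cutoff (default 0.5)
is interpreted against this binning and both the bin count and cutoff
are configurable. `redundancy_filter()` removes features greedily: while
any pair exceeds the cutoff, the member of the maximal pair with the
larger mean MI to the survivors is dropped (ties drop the later feature
in canonical order); an explicit keep-list reproduces any published
feature set exactly. `discriminatory_features()` runs Welch's two-sided
t-test per feature (computed from the textbook formula and cross-checked
against `stats::t.test` in the test suite), keeps features with
$p \le 0.05$, reports Cohen's d, and deliberately applies no
multiple-testing correction, matching standard practice for this kind of
screening step.

## Clustering with bootstrap confidence

`hierarchical_groups()` clusters records on their Z-scored
discriminatory features with Manhattan distances and Ward.D2 linkage,
cutting the tree into k groups (default 4 for condensate-positive sets,
3 for negative sets in typical use) labeled in dendrogram left-to-right
order. `au_pvalues()` estimates cluster confidence by multiscale
bootstrap: at each scale $r \in \{0.5, \ldots, 1.4\}$,
$\lceil r p \rceil$ feature columns are resampled with replacement
(features, not records, are resampled: the records are the objects being
clustered and the features are the replicated dimension; with only a
dozen features these AU values are noisy, which is flagged rather than
hidden), the records reclustered, and the per-cluster bootstrap
probability recorded. The probit-transformed probabilities are fitted by
weighted least squares to $z_r = v\sqrt{r} + c/\sqrt{r}$ and
$AU = 1 - \Phi(v - c)$; probabilities are clipped to
$[1/(B{+}1), B/(B{+}1)]$ before the probit. Two degenerate cases bypass
the fit: a cluster never reproduced at any scale gets AU = 0 with a
flag, and a cluster reproduced in every replicate at every scale gets
AU = 1, the monotone upper limit (the WLS fit of a clipped constant
would otherwise report a meaningless mid-range value for a perfectly
stable cluster).

## The condensation classifier

`train_classifier()` fits a gradient-boosted tree ensemble with binary
logistic loss: 50 trees (fixed, following the published model this
pipeline re-implements), depth 5, learning rate 0.1, no subsampling —
the last three are declared defaults, since only the tree count is
reported for the original model and an AutoML search is out of scope.
Stratified 25-fold cross-validation produces out-of-fold probabilities
and the CV metrics (AUC, AUCPR, accuracy at 0.5, F1); the decision
threshold is chosen separately by `select_threshold()`, which maximizes
F1 over the sorted unique probabilities (ties take the smallest) — the
shipped default threshold is 0.83, and the comparison is inclusive:
probability exactly at the threshold predicts positive. Missing feature
values are routed natively by the trees, which is what allows the
provisional classification of unlabeled records before their missing
values are imputed with the stored training medians.

SHAP contributions are computed by an exact path-dependent TreeSHAP
implementation (compiled, double precision) over the fitted trees with
cover-weighted expectations, so the local-accuracy identity
`bias + sum(contributions) = margin` holds to machine precision against
`predict_margin()`; agreement with the booster library's own
single-precision TreeSHAP is asserted in the tests at 1e-5. Split
comparisons cast to single precision to reproduce the library's routing
bit-for-bit. Positive contributions push toward the condensate-forming
class. `match_group()` assigns new records to feature groups by Pearson
correlation with the group mean Z-profiles; with 12 clustering features
the asymptotic p-value uses 10 degrees of freedom and the assignment
requires the largest positive r with $p \le 0.05$, else the record is
unmatched.

## Model-guided mutagenesis

`propose_mutations()` builds a deterministic substitution plan within
detected IDRs: target letters default to the most-enriched IDR residues,
occurrences are enumerated N-to-C, a fraction of 0.5 mutates every
second occurrence (1st, 3rd, ...; a seeded random half is available
behind `random_half`), and replacement letters alternate through the
replacement list. `evaluate_design()` applies the plan, recomputes
features, SHAP and probability, and escalates — first raising the
fraction to 1, then widening the target set by the next-enriched letter
— until the prediction switches or `max_iter` is reached, recording a
snapshot per iteration. Substitutions never change sequence length.

The replacement choice must point toward the model's negative class. In
the real study acidic substitutions (D/E) weaken condensation because
acidic content is depleted among condensate formers there; in the
synthetic world of this package charge tracts are a *positive* signal,
so the condensation-weakening scheme used in tests and the acceptance
script is charge-neutralizing (`replacements = "A"`). Both schemes are
expressible; the default `mutation_scheme()` keeps the D/E convention.

## The fusion-parent network

`build_parent_network()` keeps one edge per fusion event (a multigraph
as a tidy edge list); degree counts incident fusion events, with a
self-fusion counting once, so degrees total twice the non-loop edges
plus the loops. `degree_stats()` reports, per parent above a degree
cutoff (default 3), the percentage of condensate-positive fusions, plus
class-average degrees compared by a Welch test (the test behind the
published class comparison is unstated; Welch over per-parent class
degrees is this package's declared choice). `term_enrichment()`
estimates one-sided over-representation p-values by resampling
equally-sized sets with replacement (default 100,000 resamples, floored
at 1/resamples); with-replacement resampling makes the null exactly
binomial, which the tests exploit as a closed-form oracle.

## The synthetic study conditions

`simulate_fo_set()` generates labeled chimeras of archetype segments:
prion-like polar (G/Q/S/N/P-rich), acidic-tract and basic-tract
(disordered backgrounds carrying 2–4 charged blocks of 8–14 residues),
folded-hydrophobic, and proteome-background. Positives carry at least
one condensate-prone segment; negatives combine only the neutral
classes. All archetypes share one segment-length range (150–350
residues) so that class labels cannot leak through sequence length or
molecular weight — substitution-only mutagenesis can never change
length, and a length-keyed classifier would be unswitchable by design.
Breakpoints are recorded in the output for provenance; parent symbols
are drawn from small skewed pools so network tests see multi-degree
parents. Default study sizes follow the real study's scale: 300
training chimeras (60% positive), a 500-sequence reference, 25-fold CV.

What the generator does *not* emulate: evolutionary sequence structure
(domain boundaries, repeats, conserved motifs), realistic disorder
predictor behaviour on folded domains, correlated noise between
metadata and sequence, or specific real FOs. A passing pipeline on this
generator demonstrates that every stage computes what it claims and
that the stages compose correctly — not that the classifier's synthetic
CV metrics transfer to real fusion data, which additionally depend on
external feature providers and curated datasets.

## Numerical choices and limitations

* Coordinates are 0-based, half-open throughout.
* Non-canonical residues (X, B, Z, U, J, O, `*`) are stripped when at
  most 1% of a sequence, else the record is rejected: every feature
  formula is defined only on the 20-letter alphabet.
* $\delta_{max}$ (and the hydropathy-pattern normalizers) are
  constructive approximations of a combinatorial maximum; including the
  observed arrangement in the maximization guarantees the [0, 1] range
  at the cost of reporting 1 for arrangements more segregated than any
  candidate.
* Equal-frequency binning splits ties deterministically by position;
  heavily tied features can therefore bin differently after transforms.
* AU p-values from 12 feature columns are intrinsically noisy; treat
  them as a stability screen, not a hypothesis test.
* The classifier's hyperparameters beyond the tree count are declared,
  not published values; exact reproduction of the original model's
  metrics is out of scope and requires its training data and providers.
* Problem sizes in the test suite (e.g. 1,000 random profiles for the
  IDR oracle, 200 random 50–200-mers for the patterning oracles, 10,000
  resamples for the enrichment calibration) were chosen to exercise the
  asymptotics while keeping a full run in the minutes range on one CPU.

## A worked run

```{r, eval = FALSE}
library(focondense)

study <- simulate_fo_set(300, pos_fraction = 0.6, seed = 1)
ref <- default_reference()

feats <- compute_features(study)
imp <- impute_missing(feats, study$label)

survivors <- redundancy_filter(mutual_information_matrix(imp))$kept
disc <- discriminatory_features(imp, study$label)

model <- train_classifier(imp, study$label, folds = 25, seed = 1)
glance(model)

z <- zscore_features(imp, ref, subset = head(disc$kept, 12))
groups <- z[study$label == "puncta_pos", ] |>
  hierarchical_groups(k = 4) |>
  au_pvalues(nboot = 500, seed = 1)
glance(groups)

plan <- evaluate_design(study[1, ], model, ref,
                        mutation_scheme(replacements = "A",
                                        fraction = 0.5))
glance(plan)
```
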