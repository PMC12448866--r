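---
title: "Binned lipid fingerprints and PCA-LDA classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binned lipid fingerprints and PCA-LDA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidlda)
```

## The measurement and its preprocessing

A sampling event is one ~10-second ambient-MS acquisition from one site on a
tissue specimen, averaged into a single negative-mode centroided spectrum
over 100–1000 Da. A specimen typically contributes several events from
different sites, so the data are hierarchical: class → specimen → event.
Event quality is summarized by its signal duration and total ion count
(TIC); an event with duration ≤ 3 s is "bad" data and takes no further part
in modeling or metrics — the boundary is inclusive by definition, so 3.0 s
is bad and 3.0001 s is good.

Peaks are summed into fixed half-open bins [lo + iw, lo + (i+1)w) with
w = 0.1 Da over [100, 1000), labelled by their midpoints (the peak at m/z
860.6646 lands in the bin labelled 860.65). The half-open convention is
load-bearing: it is the unique convention under which all the marker-array
target masses map to their published bin labels, and it makes the upper
range edge exclusive (a peak at exactly 1000.0 Da is dropped and counted,
not binned). Total in-range intensity is conserved exactly by binning, and
binning is invariant to peak order.

After binning, every nonzero row is divided by its own sum (TIC
normalization). The source study reports order-of-magnitude TIC variation
between events ((3 ± 2)·10⁶) but does not state its preprocessing; TIC
normalization is the minimal correction that removes that nuisance scale,
so it is the default and the only transformation applied. Log or Pareto
scaling were deliberately not adopted: nothing in the source material
constrains them, and an unconstrained extra knob is worse than a documented
minimal default. All-zero rows (empty acquisitions) are flagged, never
errored on.

Peak lists are read from plain CSV/TSV (`event_id`, `mz`, `intensity`) plus
a metadata TSV (`event_id`, `specimen_id`, `class_label`, `duration_s`,
`tic`). Inputs are assumed centroided; no profile-mode peak picking is
implemented because no peak-picking algorithm is specified for the
instrument workflow. An mzML reader was considered and dropped: no mzML
parsing package is available in the supported dependency set, and the
text formats cover the pipeline's needs.

## The 41-lipid marker array

`lipid_marker_array()` ships the static table of 41 ions (Cer, HexCer, PC,
PE, SM, FA species and one PS) identified by LC-MS/MS as the discriminating
chemistry behind the classification. The package treats these
identifications as a fixture — it never recomputes them — and uses the
array in two ways: as the anchor bins for synthetic class signatures, and
as the feature subset for sparse (low-complexity) classification via
`restrict_features()`.

One row required a judgment call. The printed source table gives the
Cer(d34:0) bin as 574.55, but its own target m/z (574.4844), LC-MS m/z
(574.4964) and theoretical m/z (574.4972) all lie in [574.4, 574.5), whose
midpoint label is 574.45. The `bin` column therefore carries the
mass-consistent 574.45 and `bin_printed` preserves the original value; the
test suite pins both the 41/41 mass→bin consistency of the corrected column
and the fact that exactly this one printed label deviates.

## PCA-LDA

`fit_pcalda()` mean-centers the event × bin matrix (constant bins dropped,
the retained subset recorded in the model), takes the smallest k principal
axes explaining ≥ 95 % of variance — capped at min(100, n − C − 1), floored
at C − 1 — and then fits Fisher discriminant axes maximizing between- over
within-class scatter. The component-count rule is a design choice: the
original analysis software publishes neither its k nor its covariance
conventions, so the standard variance-capture default is used and recorded
in the model artifact; `n_components` overrides it with either a fraction
or an explicit integer.

Class priors are equal throughout. The rationale comes from the imbalanced
six-class setting the source work warns about: priors proportional to
cohort composition would encode banking frequency, not clinical prevalence,
into every posterior, and the cluster-overlap language of the method treats
classes symmetrically.

Within-class scatter is the unweighted mean of per-class covariances
(matching the equal-prior stance) and is ridge-regularized by 1e-8 × trace
(escalating tenfold if needed) whenever it is not safely positive definite
— which happens routinely for sparse 41-bin models on small cohorts.
Discriminant axes are unit-normalized with a deterministic sign convention
(largest-magnitude coefficient positive), so refits are reproducible and
label renaming changes scores at most by axis sign.

In discriminant space each class gets its own centroid and covariance; a
class with too few events for a stable covariance falls back to the pooled
covariance with a warning. Per-class (rather than pooled) covariance is the
default because the method's "cluster overlap within a predetermined
standard deviation" reads as a per-cluster spread; whether the original
implementation pooled is unpublished, so the pooled matrix is also kept in
the model object.

`rank_loadings()` composes the principal loadings with the discriminant
weights back to bin space and scores each bin by the L2 norm of its
coefficients across all discriminant axes — a single "contribution" per
m/z, aggregated across axes because the downstream use (a ranked candidate
list for lipid identification) needs one number per bin. Ties are broken by
ascending bin label, deterministically.

## Class calls, the SD gate, and posteriors

A projected query x is scored by squared Mahalanobis distance to every
class. The "predetermined standard deviation" acceptance rule is
implemented as a chi-square gate: a 3 SD ellipsoid in d dimensions is the
χ²_d quantile at the two-sided normal level 2Φ(3) − 1 ≈ 0.9973. If
min_c d²_c exceeds the gate the event is an outlier (unclassifiable);
otherwise the argmin class is called, with ties broken by model class
order. This is the dimension-correct generalization of "n SD" — a fixed d²
cutoff would change its coverage with d.

The "probability of prediction" is the normalized equal-prior Gaussian
posterior p_c ∝ |Σ_c|^(−1/2) exp(−d²_c/2), stabilized by max-subtraction.
It is a posterior, not a tail p-value: the workflow compares it to 0.95 as
a per-class probability, and the comparison is strict (> 0.95). Whether
the original "Mahalanobis distance maps" used a posterior or a tail area is
unpublished; the posterior is the reading consistent with thresholding at
95 % "probability in prediction".

Event accounting is an invariant, not a convention: classifiable = total −
bad − outlier in every report, and bad/outlier events appear in no metric
denominator.

## Validation machinery

*Event-level CV* (`crossval_event()`) realizes "80 % model / 20 % test" as
stratified 5-fold CV, so every event is tested exactly once and the
partition is reproducible from the seed. Its documented caveat is the
point: events of one specimen can span model and test sets, so when
intra-specimen correlation is high its accuracy is optimistically biased.
*Full-group CV* (`crossval_fullgroup()`) holds out all events of one
specimen per iteration and is the unbiased counterpart; the test suite
constructs a near-duplicate-events cohort where the event-level estimate
materially exceeds the specimen-level one, demonstrating the leakage
rather than asserting it.

*Permutation nulls* (`permute_labels()`) operate at specimen level: each
true class's specimens are dealt round-robin (random order, random start)
across pseudo-classes, so every pseudo-class mixes ~equal numbers of
specimens — hence events — from every true class while pseudo-class sizes
stay within one specimen of balance. Permuting at specimen level matters:
an event-level shuffle combined with event-level CV would leak pseudo-labels
through specimen identity. The expected behavior, asserted in the
acceptance suite, is full-group CV accuracy inside the 95 % binomial band
around 1/C.

*Learning curves* (`learning_curve()`) subsample specimens, never events,
stratified by class, and rerun full-group CV; fraction 1.0 is the anchor
and equals the full-data CV exactly. Accuracy at 50 % usage within 2 points
of 100 % usage is the plateau criterion used to argue cohort sufficiency.

*Metrics* follow the standard one-vs-rest definitions, reported to 2
decimals, computed twice — over all classifiable events and over the
strictly-above-threshold subset — mirroring the two column blocks of the
published tables. Averaged metrics use the arithmetic mean and the
population SD (divide by n), each rounded half away from zero to integer
percent: this is the unique combination among the obvious candidates
(sample vs population SD, banker's vs half-away rounding) that reproduces
the published (92 ± 5) % and (96 ± 2) % from their per-class values, which
is why it is the package convention. Zero denominators yield flagged NA,
never silent zeros. Spatial concordance is reported both ways the phrase
can be read — fraction of classifiable events correct, and fraction of
specimens with all classifiable events correct — because the published
definition is ambiguous between them.

## The synthetic cohort generator

No patient spectra are deposited, so `simulate_cohort()` provides the
stated world every test runs in: per class a signature over the 41 marker
bins (shared log-normal base abundance, class-specific Gaussian log-effects
of SD `separation` on the planted subset) plus ~150 shared background bins;
per specimen a log-normal random effect per bin (σ = 0.25); per event
log-normal noise (σ = 0.15), Gaussian m/z jitter (0.02 Da — small against
the 0.1 Da bins but enough to exercise edge handling), a TIC drawn from
N(3·10⁶, (2·10⁶)²) truncated below, and a duration from N(13 s, (2 s)²).
A 5 % fraction of events gets duration ≤ 3 s (bad) and 3 % get a
class-free uniform profile (outliers) — all of these are the reported
conditions of the source cohort (13 ± 2 s, (3 ± 2)·10⁶, ~5 % bad, 3 %
unclassifiable). The intra- vs inter-specimen variance split is *not*
published; σ_specimen > σ_event was chosen once so that specimen-level
leakage is a real phenomenon the CV contrast can detect, and these are
tunable parameters, not estimates. The desk-scale default of 3 classes ×
12 specimens × 8 events keeps CV plus permutation runs in seconds.

Outlier events are uniform over the cohort's bins rather than a shifted
Gaussian: they must be far from every class cluster for the gate to have
something to catch, and a uniform profile is class-free by construction.

What a green test does establish: the pipeline recovers planted structure
(markers, class separations, chance-level nulls, plateaus) under this
generative model. What it does not: instrument drift, isotopic envelopes,
lock-mass error, population-level biological variance, or the real data's
intra/inter-specimen variance ratio. Published headline accuracies
(98.84 % / 96.27 % CV, 92.34 % blind concordance) depend on the withheld
patient spectra and are deliberately not asserted anywhere.

## Numerical choices and degenerate inputs

- Bin index uses floor((mz − lo)/w + 1e-9): the tolerance keeps exact edge
  values (860.7) in their upper bin despite floating-point division.
- Covariance regularization: ridge of 1e-8 × trace, escalating ×10 until
  positive definite.
- Posterior stabilization: max-subtraction before exponentiation.
- Argmin ties: model class order. Loading ties: ascending bin label.
- Single-feature fits degenerate gracefully to a 1-D threshold classifier;
  single-class posteriors are 1 by normalization.
- All randomness is seed-driven; CLI runs derive per-stage sub-seeds below
  2³¹ from one top-level seed and record them in the run manifest.

## Known limitations

The SD gate's covariances are estimated in-sample, and Fisher axes compress
training classes; on truly blind specimens the discriminant-space spread is
wider, so the 3 SD gate rejects more than its nominal 0.27 % — increasingly
so the more principal axes the 95 %-variance rule keeps (i.e. the weaker
the class separation). The package reports this honestly rather than
recalibrating: gate level and component count are explicit parameters, and
the resubstitution-vs-blind contrast is visible in the README example
(19/144 blind outliers at moderate separation). Other limitations: no
lock-mass recalibration, isotope deconvolution or adduct annotation; no
nonlinear embeddings or unsupervised clustering; abstention policies beyond
gate + threshold are out of scope.
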