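---
title: "Seafood label authentication: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seafood label authentication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labelaudit)
```

## The problem

Market seafood is sold under common names and umbrella terms ("flake",
"snapper", "calamari") that pin the product down to very different
taxonomic resolutions. Authenticating a label therefore involves three
distinct questions that this package keeps strictly separate:

* **Specificity** — what is the finest taxonomic rank the written label
  determines? (species = 4, genus = 3, family = 2, higher = 1)
* **Misnaming** — is the name on the label an approved standard name at
  all? This is pure nomenclature; a misnamed product can be biologically
  correct.
* **Mislabelling** — is the species identified from the product's DNA
  barcode outside the set of species the label may legitimately denote?

The molecular identity comes from a COI barcode: paired Sanger reads are
quality-trimmed, aligned, collapsed to a consensus, matched against
reference databases, and the surviving hits curated into a single
species call. Because a coarse label can only be contradicted by a
coarse mismatch, raw mislabelling rates are not comparable across label
resolutions; a right-censored survival model standardises them to the
rate that would be seen if every product were assessed at species level.

## Sequence processing

**Trimming** (`trim_read`) mirrors a conventional Sanger QC chain: 30
bases off the 5' end, a 10-base sliding window from the 3' end removed
while its mean Phred quality is under 20, truncation at 250 bases, and
rejection of reads shorter than 100 bases or with mean quality under 20
after trimming. All five numbers are fields of `trim_config()`.

**Pairwise alignment** (`align_pair`) is an exact Needleman–Wunsch
global alignment with match +1, mismatch −1, gap −2. For two sequences
an optimal pairwise alignment does everything a general multiple
aligner would be asked to do here, with two advantages: no external
binary, and a fully specified tie-break (diagonal over up over left at
traceback) that makes every downstream result reproducible and lets the
test suite compare scores against an independently written dynamic
programme. An `overlap` mode (free end gaps) serves query-in-reference
comparisons in the synthetic hit emulator.

**Consensus** (`call_consensus`) emits the shared base where the reads
agree; at a base-vs-base disagreement the base with the higher Phred
score wins, and an exact quality tie emits N rather than silently
preferring a strand. Where one read has a gap, the other read's base is
emitted regardless of quality: the gap carries no quality information
to compare against, and discarding the base would shorten the barcode
for no reason. Both conventions are deliberate extensions of the
quality-wins rule, which covers only base-vs-base conflicts.

**Hit curation** (`filter_hits`) retains a reference hit only when
query coverage ≥ 98%, identity ≥ 98% (both inclusive — "above 98%" is
read as ≥ 98 and the threshold is configurable), e-value ≤ 1e−10, the
hit's name is a clean Latin binomial, the per-species hit count is at
least 1% of that species' database entry count, and the species has
more than one database entry. The entry counts are data (a column of
the hit table), not constants: database snapshots differ. The
per-(query, species) hit count is derived once from the input table
and preserved, which makes filtering idempotent and order-independent.

**Assignment** (`assign_species`) ranks surviving species
lexicographically by best identity, then best coverage, then hit
support; residual ties are broken alphabetically and flagged as
ambiguous rather than hidden. A best-supported species on the product's
exclusion list (a declared co-ingredient, e.g. pig in a pork-and-prawn
dumpling) is reported as `contamination_excluded`. QC sub-statuses are
assigned mechanically: both reads absent means failed amplification; a
trimming rejection means low quality; hits present but none surviving
the filters means low confidence.

## Labels, regimes, misnaming

The label-to-species table is long-format CSV (term, regime, species)
so that audits and diffs are line-based. Synonyms are resolved to
accepted names at load time — a reference database that stores *Penaeus
plebejus* under *Melicertus plebejus* must not create a fake
mislabelling event — and all comparisons afterwards use accepted names.
Four regimes are configured: `comprehensive` (umbrella terms cover all
species actually sold under them), `afns` (the stricter standard-names
reading), and the single-term variants `strict_flake` ("flake" means
only *Mustelus antarcticus* and *M. lenticulatus*) and `lenient_flake`
("flake" additionally admits holocephalans). Universal generics
("fish", "fillet") resolve to the whole taxonomy: they can never be
mislabelled but they stay in denominators. Unknown terms are surfaced
with a flag and excluded as unassessable, never silently counted as
mislabelled.

Misnaming compares the normalised main label and maximum-detail string
against the approved-name list under an optimal-string-alignment
distance (transposition-aware) with a bound of 2 — generous enough for
plurals and transposed letters, tight enough not to bridge distinct
names; the matching function's tuning is not published, so the bound is
declared, configurable, and covered by a monotonicity test (tightening
the bound can only create misnamings). Labels carrying a valid
scientific binomial are never misnamed. Misnaming and mislabelling are
computed from disjoint inputs; no code path reads one to decide the
other.

## Rates and intervals

Stratum mislabelling rates are proportions among *assessed* products
with Wald 95% intervals truncated to [0, 100]; unassessable products
are tallied so that assessed + unassessable always equals the total.
Specificity-level shares use Goodman's simultaneous multinomial
intervals with the Bonferroni-adjusted chi-square quantile
`qchisq(1 - alpha/k, 1)`; the per-category bounds follow the published
quadratic. Coverage of the simultaneous intervals is verified by Monte
Carlo in the test suite rather than asserted.

The definition-regime sensitivity analysis recomputes overall and
per-group rates under each regime on the identical assessed sample set
and refuses to compare regimes whose assessable sets differ. Shrinking
a permitted set can only move products from correct to mislabelled, so
overall rates must satisfy strict-flake ≥ comprehensive ≥
lenient-flake; this monotonicity is a tested invariant.

Vendor verbal claims are compared with the DNA identity but never
alter the adjudication, which uses the written label only; the summary
reports agreement, disagreement, and how many mislabelled products a
claim would have rescued.

## The censored standardisation model

Each assessed product contributes an observation on the ordinal
specificity axis (1–4, unit spacing; the coding is a convention, and
the spacing is exposed for sensitivity probing through the encoded
table). A correct product is right-censored at its label's level; a
mislabelled product is an event there. A parametric accelerated
failure time model (`survival::survreg`; Weibull by default, lognormal
and log-logistic selectable) is fitted over all subsets of the
candidate covariates; converged fits are ranked by AIC, Akaike weights
`exp(-delta/2)` normalised, the smallest prefix with cumulative weight
at least 0.95 kept as the confidence set, and coefficients averaged
with zero filled in for absent terms (the "full" average; conditional
averaging would upweight terms that appear only in strong models, and
which convention the original analysis used is not stated). Term
importance is the renormalised sum of weights of confidence-set models
containing the term.

Two event likelihoods are offered because the data admit two readings:

* `event_coding = "exact"` (default) treats the label's level as the
  exact event time. This is the conventional coding for survival
  software, and on survey-like data — where vague labels carry most of
  the substitutions — it extrapolates an amplified species-level rate.
* `event_coding = "interval"` treats a mislabelled product as
  left-censored at its level: permitted species sets nest, so a
  mismatch observed at level *l* would also be visible at any finer
  level, and all the data say is that the first contradiction lies at
  or before *l*. This is the consistent likelihood when the data come
  from a latent first-contradiction process, and it is what the
  recovery simulations use. Its limitation is the mirror image of its
  virtue: on data where coarsely labelled products are mislabelled
  *more* often than finely labelled ones, no monotone cumulative
  incidence exists, and the interval likelihood degenerates towards a
  flat stratum-wise constant (enormous fitted scale). The exact coding
  has no such failure mode, which is why it is the default for survey
  data.

Prediction (`predict_incidence`) evaluates each product's cumulative
mislabelling probability `F(l) = 1 - S(l)` at every level from the
averaged linear predictor and averaged log-scale; the population curve
is the mean over products and its value at level 4 is the
species-level standardised rate. The 95% band propagates each
product's interval on the linear predictor (per-model standard errors
combined with between-model spread, the usual unconditional variance
formula) through `F` and averages the bounds. Averaging bounds rather
than applying the delta method to the population mean reproduces the
wide, asymmetric bands this design genuinely has — a heavily censored
cohort simply does not constrain species-level incidence tightly.
Covariates can be frozen at their median (numeric) or most common
(categorical) value to report a standardised curve.

Missing prices are imputed by predictive mean matching: a linear model
of log price on market covariates is fitted to the observed rows, and
each missing row receives the observed price of one of the five donors
with the nearest predicted value, so imputations are always members of
the observed support.

Label specificity itself is modelled by a cumulative-logit ordinal
regression (`MASS::polr`) with price entering through a natural cubic
spline basis with 4 degrees of freedom — a generalised-additive
treatment of the single continuous covariate — run through the same
selection-and-averaging machinery, reporting per-model explained
deviance. Apparent separation (non-finite or extreme estimates, a
failed Hessian) is flagged as non-convergence, not reported as a
result.

## The synthetic survey generator

The generator emulates a national market survey: 7 states × 96
products, an exact 48:48 domestic:imported split per state, six
seafood groups in the surveyed proportions (106, 116, 97, 112, 128,
113 of 672), outlets 196:238:238, label specificity mixes per group
chosen to mirror the reported pattern (squid/cuttlefish and sharks
labelled overwhelmingly above family level, tuna and hoki mostly at
species or genus level), per-(group × level) substitution
probabilities highest for sharks and snapper and lowest for hoki,
log-uniform prices on the observed range $3.43–$299.90 per kg with
5.5% missing completely at random, and vendor claims mostly at
fishmongers and restaurants that are right only a little over half the
time. Where the design called for a number the source survey does not
state (the specificity mixes, per-cell substitution rates, claim
frequencies), a value was chosen once to be qualitatively faithful and
is documented in `study_design()`; none of these defaults are tuned
against test outcomes.

Integer stratum targets use largest-remainder rounding with
lexicographic tie-breaks, so counts are exact and deterministic for
any seed; only the cross-classification and per-product draws are
random, and regeneration under the same seed is bit-identical.
Substituted products draw their true species from a per-group
confusion pool (holocephalans for flake, tilapia/barramundi and other
out-of-family fish for snapper) filtered to lie outside the label's
comprehensive set, falling back to any out-of-set species; the truth
table therefore matches comprehensive adjudication by construction,
which is what lets the statistical layer be tested against known
rates.

The toy reference database derives one ancestral sequence per family,
mutates it per genus (10%) and per species (4%), so identity-based
filtering sees realistic structure (congeners a few percent away,
confamilials further). Reads are near-fully overlapping mates of a
short amplicon with substitution errors and declining 3' qualities.
The emulated reference search overlap-aligns each consensus against
every reference and emits one row per matched database entry with a
monotone e-value proxy; real BLAST tabular output is accepted as-is
and e-values are never recomputed.

What the generator does *not* emulate: chromatograms and basecalling,
indel sequencing errors, primer artefacts, heteroplasmy or mixed
templates, database misannotation beyond the synonym-label and
single-entry devices, geographic structure, and any correlation
between price and substitution. Green tests on synthetic cohorts
therefore demonstrate the pipeline's logic and the estimators'
calibration under the stated mechanisms — not robustness to every
artefact of real trace data.

For recovery experiments the substitution matrix is set to a
cumulative first-detection curve `p(l) = p4 * l/4`: a label at level
*l* detects a substitution with probability proportional to *l*, so
the species-level truth is exactly `p4` and coarser labels detect
proportionally less. That is the precise sense in which "true
species-level mislabelling" is defined for calibration runs.

## Numerical conventions and degenerate inputs

* Alignment traceback prefers diagonal, then up, then left; overlap
  mode resolves edge ties towards consuming more of both sequences.
* Quality ties at disagreeing consensus columns emit N.
* All-subset model fits that error, warn, or return non-finite
  estimates are dropped from averaging and counted; if nothing
  converges the averaging stops with an error rather than averaging
  nothing.
* An all-event degenerate cohort collapses the survreg scale to its
  boundary; the fit is flagged and excluded from averaging.
* Empty label-term resolutions, zero-denominator strata, and all-zero
  Goodman totals raise or flag rather than return silent zeros.
* Problem sizes in the test suite (cohorts of 672–2,002 products, 100
  seeds for calibration properties, 10,000 Monte Carlo replicates for
  interval coverage, 20 seeds for the censoring recovery) were chosen
  as the smallest sizes at which the binomial or Monte Carlo noise is
  comfortably below the tolerances being asserted.

## Known limitations

COI cannot separate some congeners (notably within *Thunnus*), cannot
place a sample geographically, and cannot say where in the supply
chain a substitution happened or whether it was deliberate; the
package accordingly never reports such inferences. The shipped
reference tables are a small demonstration set — a real audit must
supply its own curated label-to-species table, taxonomy, and
standard-name list, which load through the same CSV interfaces. The
species-level standardisation inherits the structural assumptions of
the survival framing; the two event codings bracket the reasonable
readings, and reports should state which was used.
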