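---
title: "Rare-variant QC for two-channel SNP arrays: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant QC for two-channel SNP arrays: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarevarqc)
```

# The problem

Array genotyping calls a variant by clustering probeset signals across
samples.  A rare variant (MAF < 1%) gives a batch a heavily degenerate
clustering problem — often zero or one minor-allele carrier among thousands
of wild-type samples — so the minor-allele components cannot be estimated
from data alone, and three array pathologies become the dominant error
sources: localized hybridization artifacts (air bubbles, scratches) that
inflate one replicate probe's signal, plate-level batch shifts that displace
a whole plate's signal cloud inside its batch, and cross-hybridization with
non-target sequences.  Each pathology produces *false minor-allele calls*,
which is the failure mode that matters in screening: positive predictive
value collapses even while overall concordance looks excellent.

This package implements a QC procedure for that regime, together with a
synthetic-data generator that produces all of its inputs with known ground
truth, so every stage is testable without access to restricted cohort data.

# Signal model and calling

**Contrast/size transform.** Per probe, contrast = log2(A+ε) − log2(B+ε)
and size = (log2(A+ε) + log2(B+ε))/2 with pseudocount ε = 1, averaged over
the probeset's replicate probes; per-replicate contrasts are retained for
the rare het adjustment.  The log-ratio form (rather than the normalized
difference (A−B)/(A+B)) was chosen because an additive shift in log2
intensity on one channel becomes an *additive* shift in contrast, which is
exactly the structure advanced normalization estimates and reverses.  It
also makes calls invariant to a common rescaling of both channels.

**Mixture model.** Per probeset and *batch* (the physical processing unit —
24 plates in production, configurable), a 3-component Gaussian mixture in
contrast is fitted by EM with conjugate-style pseudo-observations: each
component carries `pseudo_n = 2` prior observations at its prior center
(+3, 0, −3 contrast units, A-homozygote positive) with prior variance 0.25.
Clusters with no assigned samples therefore *retain* the prior — the one
property that makes a variant with zero observed carriers callable, in the
spirit of the prior-regularized EM used by commercial array callers.  The
EM is one-dimensional; size is kept only as a QC covariate, which is
sufficient for the pathologies modeled here.  Components are relabeled by
descending mean to enforce AA > AB > BB.  Calls are posterior argmax with
confidence = the winning posterior; below `confidence_threshold` (default
0.95, a design choice — vendor thresholds are unpublished) the cell is
NoCall.  A probeset whose EM fails to converge is set wholly to NoCall.

Tunables (all in `pipeline_config()`): `epsilon` (1, intensity counts),
`prior_center` (3, contrast units — about the separation of real genotype
clouds in log2 space), `prior_variance` (0.25), `prior_pseudo_n` (2),
`confidence_threshold` (0.95).

# Rare het adjustment

A true het's replicate probes agree; an artifact hits *one* replicate.
"Uncertain replicate signal distribution" is operationalized as a two-part
test on each AB call: replicate dispersion
D = max|contrast_i − median(contrast)| > `d_max`, or any replicate whose
nearest cluster (z-distance under the batch model) is not AB.  Either
condition demotes the call to NoCall with provenance `rarehet`.  `d_max`
defaults to 1.0 contrast units ≈ 4 within-cluster SDs under the default
simulation parameters, putting collateral demotion of clean true hets at
effectively zero while an artifact factor of 4–16× on one channel of one
replicate (a 2–4 contrast-unit displacement, diluted 3-fold by replicate
averaging) trips one or both conditions.  Only AB calls are ever touched,
so the operation is idempotent and AA/BB/NoCall cells pass through
bit-identical.  Demotion is per *cell*, not per probeset: the adjustment
accounting is call-level, and discarding a whole probeset for one bad cell
would throw away good calls.

# Advanced normalization

Rare-variant probesets are ≥98% wild-type, so the *median* plate contrast
robustly locates the plate's major-allele cluster regardless of how its
samples were called.  The per-probeset plate shift is estimated as

δ = median(plate contrasts) − median(plate medians across the batch).

Two deliberate choices here.  First, the estimate uses no genotype calls:
a strongly shifted plate may have had *every* sample miscalled (the mixture
captures the plate in the wrong component), so conditioning on calls would
remove exactly the samples carrying the signal.  Second, the batch center
is the median of *plate medians*, not of pooled samples — pooling lets a
large shifted plate drag the batch median by ~0.1 contrast units and fails
the ±0.1 recovery requirement; the median-of-medians is immune as long as
fewer than half of a batch's plates are shifted.  A single-plate batch
gives δ = 0 exactly.  Plates with |δ| > `shift_threshold` (0.5) and at
least `min_plate_n` (8) samples are flagged; flagged cells have δ
subtracted from their contrast and are re-called against the *original*
batch model — no refit, keeping the operation deterministic and idempotent.
Changed calls get provenance `advnorm`.

# Consolidation

The two algorithms run in parallel from the same base calls.  Per cell: no
change keeps the base; a change by exactly one algorithm is kept; agreeing
changes are kept; disagreeing changes become NoCall with provenance
`conflict` — the conservative reading of "filtering" conflicts, consistent
with the rare-het philosophy of preferring an absent call to a wrong one.

One interaction is worth knowing about.  On a strongly shifted plate the
contaminated mixture can both mis-call the plate (repaired by advnorm) and
distort an empty component's variance enough that the rare-het
cluster-membership test fires on the same cells.  Those cells end as
conflict NoCalls rather than rescued calls: call rate is sacrificed, PPV is
protected.  The adjustment summary classifies every variant with ≥1
pre-adjustment AB call as *adjusted to wild-type* (no minor-allele call
remains), *het count modified*, or *unchanged* — an exact partition,
asserted at run time — with percentages rounded half-up to two decimals
(half-up, not banker's, because that is how such tables are conventionally
printed).

# MAF-concordance filter

Per variant, array MAF = (n_AB + 2·n_BB)/(2·n_called) is compared to the
reference sequencing MAF as r = log2(array/ref); variants with r outside
[`t_lower`, `t_upper`] = [−2, 1.72] are excluded.  The asymmetric defaults
reflect the asymmetric failure mode: cross-hybridization and residual false
hets inflate array MAFs, rarely deflate them.  When either MAF is zero, r
is undefined and the variant is *indeterminate* — routed to experimental
validation, not excluded, because a reference cohort of ~3,370 genomes
cannot resolve frequencies below ~0.01%.  Diagnostics (slope and R² of
log2 array MAF on log2 reference MAF over the retained set, through an
intercept) and per-bin exclusion rates are reported;
`optimize_thresholds()` offers an explicit R²-maximizing grid search with
ties broken toward the widest interval, but never silently overrides the
defaults.

# Screening evaluation

Every minor-allele call on a panel variant goes onto the validation
worklist; the gold standard (wet-lab confirmations in production, the
simulation truth table in synthetic mode — same schema) classifies each as
TP or FP.  NPV is estimated from a seeded random sample of negative calls
(default fraction 1.35%).  Reporting is per panel and per reference-MAF bin
(`0.01% < MAF ≤ 1%` vs `MAF ≤ 0.01%`, boundary in the lower bin; variants
above 1% are rejected as not rare).  Ratios with empty denominators are
flagged undefined (`NA`), never 0 — a 0 would be indistinguishable from
"all positives refuted".

# What the simulator does and does not emulate

The generator draws Hardy–Weinberg genotypes at each probeset's true MAF
and emits per-replicate log2-normal channel intensities (per-channel SD
0.177 → within-cluster contrast SD 0.25; cluster separation 3 contrast
units; 3 replicate probes, the minimum allowing outlier detection).
Pathologies are injected explicitly and recorded in the ground truth:
artifacts multiply one replicate's one channel by 2^U(2,4) (4–16×,
"extremely high signal"); batch shifts add a constant log2 offset to one
channel on designated plates; cross-hyb probesets draw their *array* signal
at a contamination MAF while the reference cohort sees the true MAF.
Reference MAFs are an independent binomial draw (2 × 3,370 alleles by
default), so array and reference frequencies differ by sampling noise even
for perfect probesets, as they do between a genotyping cohort and a
separately sequenced reference panel.

Not modeled: probe sequence and GC effects, hybridization thermodynamics,
intensity-dependent variance, plate spatial structure within a plate,
linkage between variants, and chrX/chrY ploidy.  A green synthetic test
therefore establishes that the algorithms do what they claim *on the
pathology classes they target*, at desk scale — not that they reproduce
any specific production cohort's numbers; cohort-scale counts printed in
the literature are treated as scale context, and the acceptance checks
rest on exact worked-example arithmetic plus these property suites.

# Numerical and degenerate-input choices

* EM: convergence when the largest mean update < 1e-6, max 100 iterations;
  variances floored at 1e-4; non-convergence → all NoCall for the probeset.
* Posterior ties: resolved toward the first (highest-contrast) cluster —
  irrelevant in practice because a 0.5 posterior is below any sensible
  confidence threshold.
* Zero intensities: guarded by ε = 1 before log2; negative intensities are
  an input error.
* All-NoCall variants: array MAF undefined and flagged; such variants are
  indeterminate in the concordance filter.
* Percentages: half-up rounding to two decimals throughout, with a 1e-9
  guard against binary representation of exact halves.
* Seeding: one run seed; every stochastic operation (simulation, reference
  draw, NPV negative sampling) derives its stream from it with a fixed
  offset, so identical configuration + seed reproduces every output file
  byte for byte (floating-point TSV round-trips excepted at the last ulp).

# Known limitations

* With two plates per batch, a shift on one plate cannot be attributed to
  either plate (the median-of-medians center sits between them); three or
  more plates per batch are required for shift detection.
* The concordance filter is powerless below ~0.01% MAF (indeterminate
  verdicts) — by design, mirroring the resolution limit of the reference
  cohort; those variants must be resolved experimentally.
* The conflict rule trades call rate for PPV on strongly shifted plates
  (see Consolidation above).
* Batches are assumed internally exchangeable apart from plate shifts; a
  gradient *within* a plate is invisible to the plate-median estimator.
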