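---
title: "Detecting medication selection errors by terminology double-check"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting medication selection errors by terminology double-check}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxmatch)
```

## The problem

When an outpatient pharmacy processes an electronic prescription, staff
transcribe it by selecting a concrete drug product in the dispensing
software. The e-prescription carries a *representative* NDC (an 11-digit
labeler–product–package code) and a free-text drug description; the
dispensing record carries the *specific* NDC of the product handed to
the patient. The two NDCs are almost never equal — the same clinical
drug is sold under many NDCs — so they cannot be compared directly.
They can, however, both be resolved to a terminology-level *semantic
clinical drug* (SCD) concept: ingredient + strength + dose form. If the
two sides resolve to different clinical drugs, a selection error may
have occurred during transcription, and an automated system can flag it
for review before the medication reaches the patient.

`rxmatch` implements this double-check end to end: NDC normalization,
concept resolution through a terminology backend, SCD matching, a
clinical-significance taxonomy for mismatches, and confusion-matrix
evaluation under two alerting policies.

## The procedure

For every record pair the pipeline performs:

1. **Cleaning.** Pairs whose free-text names contain a signal word
   (`duplicate`, `cancel`, `wrong`, `denied` by default) are removed —
   these annotations mark administratively invalid pairs, not
   dispensing events. Pairs with a blank NDC on either side are
   removed. Matching is case-insensitive substring so inflections
   ("CANCELLED", "duplicated") are caught; the word list is
   configurable. The funnel report conserves counts: removals plus
   retained always equal the input.
2. **Resolution.** Each NDC is normalized to the 11-digit 5-4-2 form
   and looked up. The concept's term type decides the clinical-drug
   identity: an SCD stands for itself; a branded drug (SBD) or branded
   pack resolves to its related generic concept(s); concepts outside
   the curated scope of the terminology resolve to themselves and are
   flagged. Obsolete NDCs and retired concepts are followed to their
   current active concept before comparison, so stale codes do not
   masquerade as mismatches.
3. **Matching.** The pair is `MISSING_RXCUI` if either side resolved to
   nothing, `MATCH` if the resolved sets intersect, `MISMATCH`
   otherwise. Intersection (not equality) is used because a branded
   concept can legitimately resolve to several clinical drugs; sharing
   any clinical-drug identity means the same product was selected.
4. **Classification.** Mismatches fall through a severity cascade —
   outside-terminology, ingredient, strength, pack quantity, dose form,
   qualitative — and the first difference found names the category.
5. **Labeling and metrics.** Ingredient and strength mismatches could
   harm the patient and are true positives; the other categories are
   false positives (alerts that would typically not prevent harm).
   Matches are true negatives unless ground truth (available in
   synthetic runs) shows the mapped concepts lied about equivalence, in
   which case they are false negatives. Accuracy, sensitivity,
   false-positive rate, specificity, precision and F1 are computed for
   the full stream (a static alerting system) and for unique ordered
   NDC pairs (a learning system that adjudicates each distinct pair
   once); the alert budget `(TP+FP)/TP` summarizes alert fatigue in
   each mode.

## Design choices

Several points of the procedure are genuinely open; the package commits
to the following, for the stated reasons.

**Generic packs are clinical-drug-level.** A pack concept (GPCK)
bundles counted units of a clinical drug. Resolving a pack to its
component tablet would erase the pack count, and a 12-tablet pack
dispensed in place of a 4-tablet pack would then compare as a match —
precisely the "different pack quantity" error the taxonomy exists to
name. Packs therefore resolve to themselves (a generic pack is the most
specific *generic* identity of a pack product), while branded concepts
resolve across the brand/generic axis only. Pack-vs-pack mismatches are
then classified by their `pack_quantity` attribute.

**Category precedence is severity order.** A compound difference (say,
ingredient *and* form) is named by its most harmful component, so the
category ranking is ingredient > strength > pack quantity > form >
qualitative. The outside-terminology screen runs first because
attributes simply do not exist for uncurated concepts; nothing finer
can be said.

**Strength comparison is exact, with canonical units.** Unit strings
are case-folded and trimmed ("MG" equals "mg") but never converted
(1000 mg is *different from* 1 g). Unit conversion would require a
dimensional model the source attributes do not justify, and a
false "different strength" alert is the safe failure direction.

**Ambiguous codes are rejected, not guessed.** A hyphenated 10-digit
NDC reveals its dialect through segment lengths (4-4-2, 5-3-2, 5-4-1)
and is padded accordingly. An *unhyphenated* 10-digit code is
ambiguous — any of three segments might be the short one — and is
rejected with a distinct error code rather than guessed. Structurally
invalid codes are not dropped at cleaning by default; they flow to the
matcher and surface in the missing-concept stream, where they are
counted and reportable (malformed representative NDCs are themselves a
data-quality signal). A strict flag drops them at cleaning instead.

**Uniqueness is the ordered NDC pair.** Learning-mode deduplication
keys on the ordered (prescribed NDC, dispensed NDC) pair: prescribing A
and dispensing B is a different adjudication from the reverse, and the
first occurrence is kept.

**Ties break on the smallest identifier.** When a side resolves to
several clinical drugs and no intersection exists, the attributes of
the lexicographically smallest rxcui on each side are compared. The
choice is arbitrary but deterministic and auditable.

**Rounding.** Reported metrics are rounded to 5 decimals and
percentages to 2 (full precision is kept internally); alert budgets are
rounded half-up — `(4+546)/4 = 137.5` reports as 138 alerts per
clinically significant alert, and `(4+90)/4 = 23.5` as 24 — since
banker's rounding would understate the budget half the time. Metrics
with a zero denominator are undefined (`NA`), never an exception.

## Terminology backends

The pipeline is written against a backend contract with two
implementations. The **fixture store** holds a snapshot in four
plain-text tables (concepts, NDC map, SCD attributes, related concepts)
and is a pure function of those tables. The **live client** speaks to
the public RxNorm REST API (`ndcstatus`, `rxcui/{id}/properties`,
`rxcui/{id}/related?tty=SCD`), with a persistent on-disk response cache
keyed by endpoint and argument (a full pharmacy stream generates
millions of lookups; caching makes re-runs deterministic and polite),
request-rate limiting, and retry with exponential backoff. Transport is
injectable, so the test suite exercises the full live code path against
recorded responses without a network.

Live attribute lookups have known fidelity limits: qualifier tags
(releasing mechanism, sugar-free) are not recoverable from the REST
properties and come back empty; multi-ingredient strength strings are
assigned to ingredients positionally; and compound units ("mg/mL")
defeat the strength-string parser. Classification fidelity is therefore
highest on fixture snapshots carrying explicit attributes, which is
what the test suite and synthetic validation use.

## The synthetic generator

`generator_config()` + `build_fixture_terminology()` +
`generate_record_pairs()` produce a self-contained validation world: a
formulary grid (every ingredient at every strength level in every dose
form), sugar-free qualifier twins, branded counterparts, pack families
in two sizes, two uncurated concepts, an obsolete NDC remapped to an
active concept, and several NDCs per concept under the reserved
synthetic labeler `99999`. Record pairs are then drawn with one
multinomial type draw per pair; a mismatch pair swaps *exactly one*
attribute (a different ingredient, a different strength level, the
sibling pack size, a different form, the qualifier twin, or the second
uncurated concept), so the classifier cascade is exercised category by
category and the intended outcome of every pair is recorded as ground
truth.

The false-negative channel is structural: with
`rate_mapping_corruption > 0` the terminology itself contains NDCs
mapped to the wrong concept, and pairs drawn through them match at the
concept level while being truly non-equivalent — an error class the
double-check *cannot* see, which is exactly what a false negative is.

Default rates are the frequencies observed in a real 527,009-pair
mail-order stream: roughly 5.7×10⁻⁶ (ingredient), 1.9×10⁻⁶ (strength),
5.4×10⁻⁴ (pack quantity), 1.3×10⁻⁴ (form), 7.6×10⁻⁵ (outside),
3.0×10⁻⁴ (qualitative), no mapping corruption, and about 1.8% of raw
pairs removed at cleaning. The cleaning removal is split 0.010/0.008
between signal-worded and missing-NDC rows — the stream-level retention
(98.2%) is observable but its split is not, so an even split was chosen
once and kept. At these rates a desk-scale run contains almost no
ingredient or strength events, so validation runs raise the category
rates to the 0.5–2% range (and corruption to 0.5%) to make per-category
recovery measurable; the validation suite uses 20 seeds × 10,000 pairs
and checks that detected per-category counts equal the ground-truth
draws *exactly* (generation and detection share one terminology, so any
daylight between them is a pipeline defect) and that pooled detected
rates sit inside the 99% binomial band of the configured rates.

What the generator does **not** emulate: free-text naming noise (names
are regenerated from concepts, so cleaning recall on real misspelled
signal words is untested), the therapeutic-class mix of a real
formulary, NDC reuse across products over time, terminology churn
between snapshot versions, and the scale and irregularity of the full
RxNorm graph. Passing the synthetic validation shows the pipeline is
internally coherent and recovers known structure; it does not certify
performance on a particular pharmacy's feed.

## Worked example

The package ships a hand-built snapshot encoding one prototypical
detected error — a diltiazem extended-release capsule prescribed but a
Protonix (pantoprazole) tablet dispensed — plus one pair per taxonomy
category:

```{r}
fx <- inpaper_fixture()
out <- check_pairs(fx$pairs, fx$backend)
out[, c("pair_id", "status", "category", "label")]
```

The two clinically significant categories label as TP, the other four
as FP, and the match as TN; `run_check()` wraps the same flow and adds
funnel, matrices, metrics, budgets and the frequency table:

```{r}
cfg <- generator_config(n_pairs = 2000, seed = 42,
                        rate_ingredient = 0.01, rate_pack_quantity = 0.02)
be <- build_fixture_terminology(cfg)
gen <- generate_record_pairs(be, cfg)
report <- run_check(gen$pairs, be, ground_truth = gen$truth)
report$metrics
```

## Limitations

* The TP/FP split is a binary clinical-significance scheme; no graded
  harm scoring is attempted.
* Match semantics are intersection-based; a terminology that mapped two
  truly different products to one concept would hide the error (the
  false-negative channel above measures exactly this exposure).
* The live backend trusts the terminology service's remapping of
  obsolete identifiers; NDC reuse across the five-year reassignment
  window cannot be detected from a single snapshot.
* Unique-pair metrics assume the first adjudication of a pair
  generalizes to its repeats — the premise, not a finding, of the
  learning alerting mode.
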