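---
title: "Transparency screening: instrument, scoring, classification and tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transparency screening: instrument, scoring, classification and tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcreen)
library(dplyr)
```

## The screening instrument

`transcreen` codes each journal article against a transparency instrument
of 17 items: clarity of the study type; availability statements, claimed
access modes and actual accessibility for **materials**, **data** and
**analysis scripts** (the data chain continues to documentation and
completeness of the shared files); **pre-registration** (statement,
accessibility, and which of hypotheses / methods / analysis plan it
covers); a **linked protocol** and its aspects; and the presence of
conflict-of-interest, funding and open-access indicators for the article
itself.

The schema (`new_records()`, `read_records()`, `validate_records()`)
enforces the instrument's gating structure rather than leaving it implicit
in the data: an "accessible?" answer is `NOT_APPLICABLE` unless the parent
statement says the resource is available; data documentation and
completeness follow the chain *statement → accessible → documented →
complete*; aspect sets require an accessible pre-registration or a linked
protocol. Tri-state answers use an explicit `NOT_APPLICABLE` token instead
of blank cells so that "not screened because gated off" is distinguishable
from "screened, answer no". Validation returns a violation table instead of
raising, so a whole screening session can be audited at once; `read_records(strict = FALSE)`
drops invalid rows with a count for the same reason.

Non-empirical articles (reviews, editorials, commentaries) keep only their
conflict-of-interest, funding and open-access items: such articles have no
materials, data or analysis to share, so they are excluded from scoring and
classification but remain in corpus-level tallies.

## The accessibility score

Each of the 17 criteria is worth one point; an article's score is the
satisfied fraction of the criteria **applicable to its study type**. Two
study types — meta-analyses / systematic reviews and non-clinical
secondary-data analyses — cannot have shareable materials, so the two
materials criteria are removed from their denominator (15 instead of 17).
Three decisions follow from defining the denominator per study type rather
than per article:

* gated criteria stay in the denominator even when their gate is closed
  (an article with no data statement simply fails the four data criteria);
* `NOT_APPLICABLE` on a gated item counts as unsatisfied, never satisfied;
* the score is monotone: satisfying one more applicable criterion can
  never lower it.

All criteria are equally weighted. A weighting or hierarchy of criteria
would require a defensible ranking of their importance, which is exactly
the kind of subjective judgement the instrument avoids; the package
exposes none.

A satisfied conflict-of-interest criterion means any unambiguous COI
statement — "there are conflicts" and "there is no conflict" both count;
only a missing statement fails.

## Potential repeatability

`resource_availability()` reduces an article to four booleans — materials,
data, scripts stated available, and *methods*, meaning an accessible
pre-registration **or** a linked protocol. `classify_repeatability()` then
applies two triples:

| status | replicable (new data) | reproducible (re-analysis) |
|---|---|---|
| PARTIAL | any of materials, scripts, methods | any of data, scripts, methods |
| FULL | all three | all three |

An article with either partial status is *partially repeatable*. The
classifier describes potential only: nothing is re-executed, and a stated
availability is taken at its word. Two stricter variants exist because
screening practice varies: `basis = "accessible"` requires that the files
were actually openable, and `require_methods_aspect = TRUE` requires the
pre-registration/protocol to contain the METHODS aspect rather than merely
exist. Both default to off, matching the presence-based yes/no counts the
instrument reports.

## The comparison battery

`group_summary()` reports n, mean and *sample* standard deviation per
group (SD is undefined and reported as `NA` for singleton groups).

`two_way_anova()` fits `score ~ study_type * journal` by least squares.
Screening corpora are unbalanced — study types are not evenly spread over
journals — so main effects use Type II sums of squares (`car::Anova`),
the conventional default when no factor ordering is stated; the
interaction is tested from the full model. Two numerical edge cases are
fixed deliberately: a constant response yields F = 0, p = 1 for every
effect (the 0/0 ratio is read as "no effect", not "undefined"), and a
factor with a single observed level is an error rather than a silent
degenerate fit.

`chi2_homogeneity()` is the k×2 test of homogeneity with margin-derived
expected counts and **no continuity correction**; `fisher_exact_2x2()` is
the fallback for sparse pairwise tables. Two-sided Fisher p-values are
defined several ways in the literature; this package uses the
point-probability rule — the sum of hypergeometric point probabilities no
larger than the observed table's — with a relative tie tolerance of 1e−7
so floating-point noise cannot flip the inclusion of a tied table. The
fallback triggers on any observed zero cell by default
(`fallback = "zero-cell"`); a stricter any-expected-count-below-5 trigger
is available but off, because the zero-cell rule is the one the screening
protocol states.

`bonferroni_adjust()` is `min(1, m·p)`: multiplying small p-values by the
family size can exceed 1, and a probability above 1 is meaningless, so
values are capped at exactly 1.

`resource_battery()` assembles these into the full comparison: one omnibus
k×2 test per resource and every pairwise 2×2 test, with study types below
`min_n` articles excluded (default 15 — small-type comparisons are
underpowered and their expected counts unstable) and materials comparisons
skipping the materials-incapable types. Bonferroni families default to the
number of omnibus tests (4) and the number of pairwise tests actually run
(24 for four eligible types); both are configurable because "the number of
tests performed" is genuinely ambiguous when omnibus and pairwise tests
coexist. Significance uses α = 0.05 on adjusted p-values.

## The synthetic generator

`default_config()` encodes the marginal proportions published for a
screened 2019 corpus of 639 cardiovascular articles (393 empirical) in
three journals:

* journal mix ∝ (226, 193, 220); non-empirical share 246/639;
* materials stated available 56/393 (materials-capable types only), data
  125/393, scripts 43/393;
* conditional chain links where printed: materials accessible 1/56, data
  accessible 13/125, documented 9/13; scripts accessible 1/43;
  pre-registration stated 107/393, accessible 106/107, with aspects
  hypotheses 44/106, methods 106/106, analysis plan 27/106; protocol
  linked 10/393 with aspects 7/10, 9/10, 5/10;
* open access 605/639; funding statement absent 276/639; COI statement
  present 93% (57% reporting a conflict).

Cells never printed are set once to realistic values and flagged here as
**uncalibrated**: the empirical study-type split (constrained so case
studies are 21/393 and the four types large enough for comparison sum to
354, the margin implied by the published methods-availability table), the
mode split among stated availabilities (predominantly `UPON_REQUEST`, the
reported modal answer), the 5% share of negative statements that state
unavailability outright, completeness of documented data (0.5), the
open-access route split (half via an OA button), the funding split of the
non-absent share, and the country mix.

Items are sampled **independently given study type**, and gated chains as
Markov chains on their conditional probabilities; one integer seed drives
a single RNG stream, so equal seeds give bit-identical record sets and
every generated record passes validation by construction. Two consequences
matter for interpreting tests:

* marginal proportions converge to their configured values (the suite
  checks each within 3 binomial standard errors at n = 10,000, its
  standard simulation size for calibration; smaller corpora of 200–639
  records are used where only structure matters);
* joint quantities — how many articles are fully reproducible, which
  pairwise differences reach significance — are *emergent* and are **not**
  calibrated to any published joint count. Real screening data are also
  correlated across items (a group that shares data likely shares code),
  and per-study-type prevalences differ in reality; passing tests on
  synthetic corpora therefore validate the pipeline's logic, not any
  substantive claim about the literature.

## Reporting conventions

Percentages are computed by `percent()` with rounding **half away from
zero** — the convention consistent with printing 1.78% as 2% and 14.25% as
14% — and the summary emits both 0- and 1-decimal variants because
published reports mix precisions sentence by sentence. The score histogram
uses ten left-closed bins of width 0.1, with a score of exactly 1.0
assigned to the top bin so counts always sum to the number of scored
articles. `summarize_records()` is a pure function of the record table;
identical inputs give identical reports.

## Known limitations

* The generator's independence assumption understates the clustering of
  good practice; emergent joint counts should not be compared to published
  joint counts.
* Dataset-dependent statistics from any particular screened corpus (mean
  scores by type or journal, ANOVA F and p values, specific pairwise
  p-values) require that corpus's per-article records; the package
  recomputes them for whatever records it is given but does not attempt to
  reconstruct any unpublished dataset.
* The classifier equates "stated available" with "available" unless the
  stricter accessibility basis is selected; both readings are defensible
  and the choice is exposed, not hidden.
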