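---
title: "Methods: connected-language measures, factor scores and trajectory models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connected-language measures, factor scores and trajectory models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: what is
modelled, which choices were open and how they were resolved, what the
synthetic-data generators emulate, and what the passing test suite does
and does not establish about real data.

## The measurement model

A *language sample* is a picture description segmented into C-units (an
independent clause plus all of its modifiers). Disfluent material —
filled pauses, unfilled pauses, repetitions, revisions, false starts —
is coded as *mazes* and excluded from all content counting; it
contributes only to the maze index. Scripted examiner prompts are
parsed, counted, and excluded from every measure; their time is part of
the sample duration, which is why rate measures (words per minute,
semantic units per minute) use the full recorded duration.

Ten measures feed four latent factors (Semantic, Syntax, Lexical,
Fluency); five further measures (total words, total semantic units,
MLU, words per minute, semantic units per minute) are descriptive. The
counting conventions that were genuinely open, and how they are fixed
here:

* **Word-count denominator.** `total_words` counts non-maze,
  non-filled-pause, non-nonword tokens. This is the standard
  language-sample convention: maze material is disfluency, not content.
* **Percent nouns / percent verbs.** The denominator is `total_words`,
  consistent with reading these as proportions of meaningful content
  words relative to total words.
* **Unique words.** Distinct lower-cased *surfaces*, not lemmas — the
  type-token-ratio convention. Tokens are lower-cased at parse time and
  punctuation terminators are never tokens, so counting is
  deterministic.
* **Proposition density.** Implemented directly as the stated ratio of
  proposition-bearing words (verbs, adjectives, adverbs, prepositions,
  conjunctions) to total words, not as a full rule-engine
  implementation of an idea-density rater.
* **Semantic units (SUID).** Although sometimes labelled a density,
  the measure is implemented as a deduplicated *count* of content units
  matched against a configurable checklist (consistent with its use
  alongside "total semantic units"). The checklist is data, not code: a
  Cookie Theft unit inventory ships in
  `inst/extdata/cookie_theft_units.yaml` and any YAML/JSON lexicon can
  replace it. A unit matches if any trigger lemma pattern occurs
  contiguously within one C-unit's non-maze lemma sequence; each unit
  counts at most once.
* **Maze index.** The numerator counts filled pauses, false starts,
  revisions and repetitions. Unfilled pauses are coded in transcripts
  but excluded from the index by default, because the index definition
  lists filled pauses only; `include_unfilled_pauses = TRUE` widens the
  numerator for sensitivity analyses.
* **Zero denominators.** Undefined ratios (no nouns + pronouns, no
  grammatical relations) are returned as `NA` and flagged — never
  silently coded 0, which would fabricate a worst-or-best score.

## The CHAT dialect

Only the codes the measures need are supported, as a documented subset:
`@Participants`, `@ID`, `@Duration` headers; `*PAR`/`*EXA` main lines;
`%mor` entries `pos|lemma` over the non-maze, non-filled-pause tokens
(using the package's closed ten-tag POS vocabulary); `%gra` entries
`dependent|head|LABEL` over the same index space, with head 0 denoting
the virtual root and a fixed label set (COMP, CMOD, XCOMP, ...) marking
syntactic embeddings; and maze markers `&-word`, `(.)`, `<...> [/]`,
`[//]`, `[/-]`. `write_chat()` is the exact inverse of `parse_chat()`
on every valid transcript, which the suite checks as a round-trip
property. A misaligned `%mor` tier (entry count differing from the
main line's non-maze token count) is a parse error naming the line —
tier misalignment is the most common hand-transcription fault and must
not shift tags silently. When no `%mor` tier is present a pluggable
tagger fills tags; the built-in fallback is a small closed-class
lookup and is deliberately crude — gold tags belong in the tier.

**Reliability.** Percent agreement between two transcriptions aligns
token sequences globally by minimum edit distance with unit costs,
breaking ties toward substitution, and reports
100 · matches / alignment length. Whether published agreement figures
used token-, utterance- or code-level alignment is not stated in the
source literature; token-level alignment is this package's documented
choice, with `level = "semantic_coding"` aligning matched content-unit
codes instead.

## Factor scores

Each measure is standardized against a reference sample
(`calibrate_reference()` stores the sample means and SDs), multiplied
by its loading, summed within factor, and the Semantic and Fluency
factors are multiplied by −1 so that higher always means better
performance (e.g. more mazes → lower Fluency, more pronouns → lower
Semantic).

Two genuinely open choices are resolved as follows:

* **Scores are weighted sums of standardized indicators**, not
  regression-based factor estimates. The original factor loadings are
  not published; the default configuration uses equal unit-magnitude
  loadings within each factor, signed by each measure's raw direction
  inside its construct, and any true loadings can be dropped in via
  `read_factor_weights()`. The pipeline's statistical layers are
  agnostic to the weights.
* **Missing constituents propagate.** A missing measure yields a
  missing factor score with the affected factors named in an
  attribute. Re-normalising the remaining weights would silently change
  the construct being measured.

## Trajectory models

The longitudinal model for each factor score is a random-intercept
linear mixed model fitted by REML:

$$y_{ij} = \beta_0 + \beta_1\,\mathrm{age}^c_{ij} + \beta_2\,\mathrm{male}_i
 + \beta_3\,\mathrm{lit}_i + \beta_4\,\mathrm{eMCI}_i
 + \beta_5\,\mathrm{age}^c_{ij}\cdot\mathrm{eMCI}_i + b_i + \varepsilon_{ij}$$

with $b_i \sim N(0, \tau^2)$, $\varepsilon_{ij} \sim N(0, \sigma^2)$.
Time is operationalised as age at visit, centered at 63 years (ages
carried at two-decimal precision), so the diagnosis main effect is the
group contrast at age 63 and the interaction is the excess annual slope
of the eMCI group. Random slopes are deliberately out of scope: the
random part is exactly a subject intercept.

Conventions and their rationale:

* **Coding.** eMCI = 1 / CH = 0 and male = 1 / female = 0, reproducing
  the usual sign conventions for these models.
* **Literacy scaling.** The literacy covariate (a reading standard
  score) enters z-scored over the analysis sample by default
  (`standardize_literacy = FALSE` restores raw scoring). Published
  coefficient magnitudes for this covariate are inconsistent with
  per-raw-point scaling, so the package treats the standardized scale
  as its convention and the simulator generates under the same
  convention — recovery is therefore well-defined regardless of how
  the original analyses scaled it.
* **Inference.** Wald t statistics with a residual degrees-of-freedom
  convention (observations − fixed effects), two-sided tests, 95%
  Wald intervals. The df method for mixed models is famously
  unsettled; residual df is simple, deterministic and accurate at this
  design's size (528 observations, ≤ 8 fixed effects), though mildly
  anticonservative for within-subject terms — the model-selection
  false-retention rate sits slightly above the nominal α and inside
  the tolerance the test suite checks.
* **Model selection.** The base model (age, sex, literacy, diagnosis)
  is extended by each diagnosis interaction *one at a time*; those
  significant at α = 0.05 (unadjusted by default; a Bonferroni option
  exists) are retained and the final model is refitted by REML. A
  secondary refit adds depression, anxiety and sleep as fixed effects
  and reports whether any is significant.
* **Degenerate inputs.** Rank-deficient fixed designs error naming the
  collinear columns; optimizer non-convergence and singular
  (boundary, $\hat\tau^2 = 0$) fits are flagged on the result object;
  single-visit-per-subject data are allowed and produce a flagged
  boundary fit whose fixed effects coincide with OLS. Wald SEs on
  fully degenerate zero-variance fits are reported as `NA`.

Adjusted baseline comparisons use ANCOVA: a linear model with group
plus covariates, group means evaluated at the covariate grand means.
Correlations among factor scores and covariates use Spearman's rank
correlation (several neuropsychological covariates are heavily
skewed), pairwise-complete, with constant variables yielding flagged
`NA` cells. Correlation values published from the original cohort's
real recordings are not reproduction targets here — they depend on
data that is not deposited; the operation itself is validated on
constructed data.

## What the generators emulate

**Transcripts.** `transcript_plan()` fixes per-C-unit POS composition,
the maze schedule by kind, embedding/total relation counts, the
content units to mention, a unique-word target and the duration. The
generator realises the plan exactly: content-unit triggers occupy the
earliest noun slots, fresh vocabulary is drawn without replacement
until the unique-word target is met, and later slots reuse an earlier
same-class surface (exact type-token-ratio control). Every feature is
then computable from the plan in closed form, giving the extraction
pipeline an *exact* oracle — the suite requires equality, not
approximate agreement, on 100 random plans. Generated text is not
linguistically natural and does not emulate discourse coherence,
morphological variety, or speaker idiosyncrasy; passing the oracle
shows the counting layer is correct, not that the measures are valid
for real speech.

**Cohorts.** `simulate_cohort_scores()` draws a two-visit cohort of
264 subjects (200 CH / 64 eMCI) with the confounding structure the
ANCOVA stage must handle: eMCI subjects are older (baseline age
N(64.2, 5.9) vs N(61.1, 6.5), overall ≈ 62 ± 6.5) and more often male
(0.44 vs 0.30); literacy is N(106.7, 9.3) in both groups; visit gaps
are N(2.0, 1.5) years truncated below at 0.25. Outcomes follow the
random-intercept model with the published final-model coefficients as
defaults and intercepts of 0 (factor scores are centered constructs).
The variance components are not published; the defaults τ = 0.7,
σ = 0.5 give visit-to-visit stability consistent with the reported
test-retest behaviour of factor scores, both are configuration, and
fixed-effect recovery holds for any stated values. Depression, anxiety
and sleep are generated as opaque covariates with zero effects, so the
secondary refit has a known null to find.

## Problem sizes and numerical tolerances

The suite uses the sizes the methods are claimed at: recovery runs 200
replicate cohorts of 528 observations per protocol; selection
behaviour uses 500 interaction-free replicates (nominal-level check)
and 150 replicates per effect-bearing factor; the feature oracle runs
100 random plans. Exact-count comparisons use `identical()`; the
LMM-vs-OLS boundary property uses 1e-6 on fixed effects; Monte-Carlo
recovery uses two Monte-Carlo standard errors of the replicate mean.
Alignment ties break toward substitution; `sample()`-based generation
is wrapped so that seeded calls never disturb the caller's RNG stream.

## Known limitations

* The replication power for the Fluency age-by-diagnosis interaction
  is limited: with the default variance components the design's
  interaction SE is close to the published SE (≈ 0.02), so a
  generating effect of −0.03 is a borderline detection, and repeated
  simulation retains it in fewer than half of replicates (the Semantic
  interaction, −0.04, is retained in a clear majority). The test
  suite measures and asserts this behaviour directly; the shortfall is
  a property of the published effect size under these conditions, not
  of the estimator, whose mean estimates recover the generating
  coefficients closely.
* The discourse measures assume gold POS tags and maze coding from the
  transcript tiers; the fallback tagger is not a substitute for proper
  morphological annotation.
* The content-unit checklist shipped as a default is a reasonable
  Cookie Theft inventory but is configuration — studies comparing
  semantic-unit counts must hold the lexicon fixed.
* Type-token ratio is sensitive to sample length; the package reports
  it as defined and leaves length-corrected diversity indices to the
  analyst.
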