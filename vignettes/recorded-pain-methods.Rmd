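---
title: "Methods: phenotyping recorded pain in mental-health notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping recorded pain in mental-health notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painrecord)
```

## The problem and the outcome definition

Mental-health EHR systems rarely capture physical pain in structured fields;
what exists is written into clinical notes. The phenotype of interest is
therefore *recorded* pain: a patient is **class 1** if at least one sentence
in an in-window note carries a pain-keyword mention that is *relevant* —
physical pain affecting the patient — and **class 0** otherwise. Class 0
deliberately pools patients with no keyword hits and patients whose hits are
all not-relevant (negated, form boilerplate, misspelling artefacts,
hypothetical, metaphorical). Absence of recorded pain is not absence of
pain: the outcome is a documentation phenotype, and every downstream
association must be read that way.

## Pipeline stages and their assumptions

**Eligibility.** A patient enters the cohort when aged at least `min_age`
(default 18 years) at the index date, under active referral, and holding at
least one note of at least `min_doc_chars` raw characters (default 30,
counted with whitespace) dated inside `[window_start, window_end]`. Both
window endpoints are inclusive — the most permissive reading of a stated
"between" window — and this choice is pinned by tests. Character counting on
the raw string is the simplest reproducible reading; whether any
preprocessing should come first is genuinely undecidable from the outside,
so none is applied.

**Sentence segmentation.** A rule-based splitter: a sentence ends at a run
of `.`, `!` or `?` followed by whitespace or end of text, or at a newline.
This is deliberately unsophisticated — determinism and offset fidelity
(every sentence is an exact slice of its note, 1-based inclusive offsets in
the R string convention) matter more here than handling abbreviations,
because the classifier operates on sentences and audit requires exact
provenance.

**Keyword matching.** Case-insensitive, word-boundary matching of lexicon
terms, every term tolerating a plural "s", verb-flagged terms ("ache") also
matching "-ed"/"-ing" forms. Overlap resolution is longest-match-first:
"back pain" suppresses the inner "pain". The bundled lexicon is a compact
default built around common pain surface forms; any one-term-per-row CSV can
replace it. "pained" and "painful" are ordinary lexicon entries: such hits
*should* reach the classifier (where form/misspelling/metaphor rules dispose
of them), mirroring how a keyword prefilter behaves on real notes.

**Relevance rules.** Families apply in fixed precedence: form >
misspelling > negation > hypothetical > metaphorical > affirmed. The
precedence is this package's choice — the taxonomy itself does not order the
categories — and puts structural, high-precision cues (questionnaire
boilerplate) ahead of lexical ones. Negation follows a NegEx-style
convention: a cue within 5 tokens before the hit, or a sentence-initial
governing cue, with the conjunction "but" resetting scope. Hypothetical cues
("risk of", "fear that", "may cause", …) use a 10-token window.
Metaphorical and misspelling detection are closed pattern lists: misspelt
DIY "pained and decorated …" is annotation noise to be filtered, not a
linguistic phenomenon to model, so no spell-checker is involved. All cue
lists and scopes live in a YAML rule set and are user-replaceable; the
boundary between "hypothetical" and "metaphorical" encodes one defensible
partition of the canonical examples, and borderline sentences will follow
whichever cue fires first.

**Classification granularity.** Labels attach to keyword hits, not
sentences: a sentence with two hits can yield discordant labels, and
patient roll-up counts hits. This matches mention-level reporting
conventions and makes the planted-truth bookkeeping exact.

**Anatomy.** One gazetteer pass over relevant sentences, built from the
body-part surface forms of the seven-region aggregation (lower limbs; upper
body excluding back; upper limbs; stomach/abdomen; head and neck;
non-specific; back), with regular-plural tolerance and longest-match-first
("lower back" beats "back" — inert for region totals since both map to the
back region, but pinned). The intermediate binary "anatomy mentioned?"
decision is the gazetteer hit itself: at this scale the decision surfaces
coincide. Region percentages are computed over mapped anatomy mentions —
the only convention under which they sum to 100. Optional concept
identifiers (e.g. SNOMED CT) are inert metadata columns, not a service
dependency.

**Primary-care coding.** Coded pain is any event whose code appears in a
medication, diagnosis or treatment list, dated in the same (inclusive)
window as the cohort. The bundled lists are small synthetic fixtures in a
Read-code-like style (`synthetic_codes_*.csv`) for tests and examples.
Linkage itself ("does this patient have primary-care records?") is an input
flag: record linkage happens upstream of this package. In the overlap
partition, both-pain and primary-only percentages use the linked subset as
denominator while linkage and secondary-only use the full cohort; every
output row names its denominator to keep that auditable.

**Statistics.** Unadjusted odds ratios are cross-products ad/bc with Wald
intervals on the log scale — the only formulation hand-checkable from a
printed two-class table — and zero cells raise an error rather than apply a
silent continuity correction. Logistic models enter age linearly per 10
years and dummy-code categoricals against male / white / IMD decile > 5 /
non-SMI references. "Not known" levels are retained as estimable levels in
adjusted models but excluded from named pairwise 2×2 contrasts. Wald (not
profile) intervals are used throughout for consistency with the 2×2
arithmetic; significance is flagged at p < 0.001 with no multiple-testing
correction. The diagnosis contrast is direction-sensitive: the SMI-exposed
cross-product and its inverse (non-SMI-exposed) are both legitimate
summaries of the same table, and published tables can disagree on the
direction, so `unadjusted_or()` carries explicit term/reference labels and
callers choose the direction.

## The synthetic-EHR generator

The generator exists so every stage is testable without access to the
restricted source databases. Its defaults *are* the study conditions:

* **Marginals** shaped like a large urban secondary mental-health cohort:
  gender ≈ 49.5/50.4% with 0.11% "not known"; six ethnicity categories
  (white 48.3%, black 21.6%, not stated 17.3%, Asian 5.5%, other 4.4%,
  mixed 2.9%); IMD deciles with 72.25% at decile ≤ 5 and 3.2% missing; SMI
  32.9%.
* **Age** from a truncated normal (mean 44, SD 17.5 years, truncated to
  [18, 100]), matching the reported mean/SD under the 18+ filter.
* **Effects** (log odds on recorded pain): female log(1.42), Asian
  log(1.30), black log(1.49), other log(1.12), mixed log(1.03), not-stated
  log(0.31), gender-not-known log(0.69), deprived log(1.64), SMI log(0.43),
  age log(1.17) per 10 years, centred at 44. The intercept default (−0.07)
  was calibrated analytically from those marginals and effects to give
  overall prevalence near 52%.
* **Notes**: each patient gets `1 + Poisson(mean − 1)` notes (default mean
  5), dates uniform over the window. The guaranteed first note keeps the
  configured covariate marginals intact through the eligibility filter. The
  per-patient document count in such cohorts is not publicly characterized
  (only a database-wide average of ~90 documents/patient, which would be
  prohibitive at test scale), so 5 is a deliberate desk-scale stand-in.
* **Mention planting**: truth precedes text. Latent pain status is drawn
  first; pain-positive patients then receive Poisson(3)-per-note relevant
  mentions (at least one overall), each with probability 0.5 of carrying a
  body part drawn from the configured seven-region distribution (defaults
  20/19/17/16/15/8/5%). Not-relevant mentions are planted per note per
  category (negated 0.15, form 0.05, misspelling 0.02, hypothetical 0.05,
  metaphorical 0.05) in both classes, from the bundled template sentences —
  the same canonical examples the rule engine is built against. The mean of
  3 relevant mentions per pain-positive note is a runtime-conscious
  stand-in: the reported "mean of 10 mentions per document" is ambiguous
  about which hits it counts.
* **Linkage**: 17.7% of patients have primary-care records; coded pain
  occurs with probability 0.60 among linked pain-positive and 0.30 among
  linked pain-negative patients, chosen so the linked-subset overlap cells
  land in the reported range.
* **Seeding**: one integer seed; each block (patients, latent pain, notes,
  coded events) reseeds from a fixed LCG scramble of it
  (`seed·69069 + offset·104729 mod 2³¹−1`) rather than plain `seed+offset`:
  Mersenne-Twister streams initialized from adjacent seeds are not
  independent, and that cross-stream correlation leaks dependence between
  covariates and the latent outcome. The scrambled derivation keeps the
  null-effect interval-coverage check in the test suite calibrated while
  preserving byte-identical reproducibility per seed.

**What the generator does not emulate** — and therefore what green tests do
*not* establish about real notes: realistic clinical prose (templates only),
misspellings outside the closed pattern list, abbreviation and section
structure, longitudinal disease trajectories, correlation between
covariates (all are drawn independently, so non-collapsibility effects on
marginal odds ratios are mild), and classifier errors: because generator
templates and rule engine share one taxonomy, end-to-end planted recall is
exactly 1.0 by construction. That property validates the plumbing, not
NLP accuracy on clinical language.

## Numerical and degenerate-input choices

* Probability tables must sum to 1 within 1e-9 at configuration time.
* The logistic-versus-2×2 identity on single-binary-covariate data is
  asserted to 1e-6; the cross-product inverse identity to 1e-12.
* Zero 2×2 cells, single-level covariates, non-convergence and unstable
  standard errors (|SE| > 50, a separation symptom) are explicit errors
  naming the offending cell/level, never silent fixes.
* Empty inputs (no notes, no mentions, no linked patients) return empty
  tibbles or zero-count tables, never errors or divisions by zero.
* Ties in keyword matching resolve longest-match-first, then left-to-right.

## Problem sizes used in the checks

Marginal fidelity and effect recovery run at 20 000 patients (covariates
and latent labels only, which is why `generate_patients()` exists as a
text-free fast path); interval-coverage checks use 40–50 seeded replicates;
the end-to-end text pipeline runs at 2 800 patients, which yields over
10 000 planted anatomy mentions for the region-distribution check. These
sizes keep the full suite under a minute while leaving the binomial
3-standard-deviation bands narrow enough to be informative.

## Known limitations

The rule engine encodes one reading of the not-relevant taxonomy and will
misclassify constructions outside its cue lists; the lexicon and gazetteer
are compact defaults, not the exhaustive production resources; the package
does not distinguish acute from chronic pain; and the overlap analysis
treats linkage as given. All of these are interface points — lexicon, rule
set, region map and code lists are plain files, and the classifier contract
(mention in, label/category/trigger out) admits a learned model drop-in.
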