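---
title: "Methods: concept frequency, overlap, and CDE extraction in odmcde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concept frequency, overlap, and CDE extraction in odmcde}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odmcde)
```

## The analysis model

`odmcde` treats a clinical documentation landscape as a corpus of forms,
each belonging to one *documentation context* (routine care, registry,
study CRF, eligibility criteria, quality assurance, official
recommendation, risk score — an open label set). Every form item may
carry a *concept*: a non-empty set of UMLS CUIs. One CUI is a
precoordinated concept; two or more express a postcoordinated
combination. Concept identity is the **unordered, deduplicated CUI
set**, rendered canonically as the sorted, space-joined string. We chose
unordered identity because annotation order carries no meaning in
postcoordination and unordered matching merges trivially reordered
annotations; nothing downstream depends on CUI order.

The pipeline then asks three questions:

1. **Frequency.** How often does each concept occur across the corpus,
   and how concentrated are occurrences? Occurrences of the same
   concept within one form count separately — forms re-ask concepts in
   follow-up subsections, and collapsing them would understate true
   documentation burden. Excluded items (nondistinct or administrative,
   see lints below) never enter any statistic. The cumulative coverage
   curve sorts concepts by frequency and accumulates occurrence
   percentages; its head size at 50% measures the size of the *de
   facto* core dataset.
2. **Overlap.** After merging each context's forms into one
   unique-concept set, every pair of contexts is compared by the
   *directional relative overlap* `100·|A∩B|/|A|` (and its mirror).
   This statistic, unlike Jaccard, answers "what share of context A's
   concepts also appear in B", which is the operational question for
   standardization; Jaccard is reported as an extra column. Matching is
   exact on canonical keys — no terminology-graph similarity — because
   annotation-level equivalence is the only relation the input data
   supports without a Metathesaurus service.
3. **CDE extraction.** A concept becomes a common data element when its
   total frequency is at least `min_frequency` (default 2) **and** it
   occurs in at least `min_contexts` distinct contexts (default 2).
   Both defaults encode the weakest meaningful notion of "common":
   anything seen once, or only inside one documentation silo, is not
   common. Raising either threshold can only shrink the list
   (monotonicity, property-tested).

### Coding-principle lints

The annotation conventions the package expects are: prefer a single
precoordinated CUI; use at most two CUIs when postcoordinating; assign
no code when even that fails. `lint_coding()` materializes these as
checks: concepts with more than two CUIs are flagged (a warning by
default, an error in strict mode — third-party files may legitimately
violate a house rule, so failing hard is opt-in), uncoded items are
reported as information, and configurable case-insensitive patterns
(seeded with "other medication", "other comments", "technician id")
propose `nondistinct` / `administrative` exclusions that can be applied
in place. Code review by humans is represented declaratively: a
two-column cleaning map (old key → new key) that is closed over chains
and rejected if cyclic, so one application is a fixpoint.

## ODM representation choices

Forms are CDISC ODM 1.3 metadata (`Study → MetaDataVersion → FormDef /
ItemGroupDef / ItemDef`). Concept annotations are read from item-level
`<Alias>` elements whose `Context` attribute is `"UMLS"` or
`"UMLS CUI"` (configurable — editors differ and no single convention
can be assumed). Postcoordination is accepted both as one alias holding
a space-separated CUI list and as multiple UMLS aliases on one item;
both normalize to the same set. On write, the single space-joined alias
is emitted.

ODM has no standard slot for a documentation context. We carry it as a
study-level alias (`Context="DocumentationContext"`) on write, and on
read let a sidecar context map override whatever the file says — the
sidecar wins because corpus curation happens outside the files, and
this keeps the XML standard-conformant. Unknown ODM datatypes map to
`text` with a diagnostic rather than failing; a `CodeListRef` marks the
`codelist` datatype. Duplicate form ids across files are resolved by
deterministic suffixing (`#2`, `#3`, in input order) so that corpus
statistics are reproducible regardless of how a batch was assembled.
Invalid annotation strings leave the item *unannotated with a recorded
diagnostic* — parsing never silently drops or invents annotations, and
round-trip identity (write then read) is property-tested on random
forms.

## Numerical conventions

* **Rounding** is half away from zero (`round_half_up()`), not R's
  banker's rounding: one decimal for relative frequencies and overlap
  percentages, two decimals for annotation coverage. All statistics are
  computed and stored at full precision; rounding is display-only
  (`rel_a_display`, export `digits`), with precision 0 available where
  integer rendering is wanted.
* **Tie-breaking** for equal frequencies is canonical key ascending.
  This makes the coverage curve, head sizes, and all exports invariant
  under permutation of the input forms (tested).
* **Thresholds** in `head_size_for_coverage()` compare with `>=` (and a
  1e-9 guard for floating error at the 100% endpoint): reaching exactly
  50.000% counts as covering 50%.
* **Denominator** of relative frequency defaults to *all* non-excluded
  items, including uncoded ones — a concept's share of the
  documentation, not of the annotatable part; `"coded_items"` mode is
  available.
* **Degenerate inputs**: an itemless corpus has *undefined* annotation
  coverage and returns `NA`, never 0 or 100; an empty frequency table
  yields an empty curve, and asking a head size of an empty curve is an
  error; a single-context corpus makes the default CDE thresholds
  unreachable and errors unless `min_contexts` is lowered explicitly.

## The synthetic corpus generator

Real multi-context form collections cannot be redistributed, so every
pipeline stage is exercised against generated corpora whose statistical
structure matches what the analysis assumes:

* a pooled vocabulary of synthetic concepts split into a **core** block
  shared by all contexts and a **private** block per context;
* concept sampling weights proportional to `rank^(-zipf_exponent)` over
  the pooled vocabulary, with core concepts occupying the top ranks (so
  the frequent head is also the shared part, and private deep ranks
  supply the singleton tail);
* per-form item counts uniform in a per-context range; a small
  within-form repeat probability (`p_repeat_within_form = 0.02`)
  modeling follow-up subforms;
* items uncoded with probability `1 − p_annotatable` (default
  `p_annotatable = 0.98`) — emitted, not omitted, so coverage is
  exercised;
* vocabulary concepts postcoordinated (two CUIs) with probability
  `p_postcoordinated = 0.06`.

Synthetic CUIs live in a reserved `C9xxxxxx` block so they can never
collide with real published codes used in fixtures. Generation is fully
deterministic given the configuration (including its seed), restores
the caller's RNG state, and returns a **ledger** of ground truth
(per-concept core/private assignment, realized per-context occurrence
counts, uncoded counts, postcoordinated keys). Tests demand *exact*
agreement between the ledger and a full rescan of the emitted corpus,
and between pipeline-measured pairwise mutual counts and ledger-realized
shared usage — not merely agreement in expectation.

### The calibrated preset

`acs_corpus_preset()` targets a published-scale acute-coronary-syndrome
collection: 86 forms over seven contexts (routine 4, registry 7, study
CRF 2, eligibility 55, quality assurance 6, recommendation 2, risk
score 10 — per-context item ranges follow the characteristic sizes of
those form types: risk scores 5–14 items, study CRFs 300–520, routine
hospital forms 110–160), with expectations of roughly 3700 items, 840
unique concepts, 98% annotatability, 6% postcoordination, a head where
about the top 7% of concepts cover half of all occurrences, and a
majority-singleton tail. The free constants — core vocabulary 150,
private vocabulary 350 per context, Zipf exponent 0.6 — were fixed by a
one-time grid search against those expectations and then frozen;
across seeds 1–10 the preset yields 803–859 unique concepts, 50%-head
shares of 6.8–7.6% of the vocabulary, and singleton shares near 60%.
The exponent is deliberately mild: steep Zipf weights concentrate
occurrences on a handful of concepts and kill both the vocabulary size
and the singleton tail.

What the generator does **not** emulate: clinically meaningful item
texts, correlated concept co-occurrence within a form, eligibility-
criteria phrasing, or any particular between-context sharing structure
beyond core-vs-private — so a green parameter-recovery test establishes
that the pipeline measures what the generator planted, not that real
corpora follow this generative family.

## Design decisions that were genuinely open

* **86-form split.** The preset's per-context form counts must total
  86; the exact split across contexts is not recoverable from published
  summaries, so counts for the small contexts follow their reported
  source counts and the remainder is absorbed into eligibility-criteria
  forms, the most numerous and smallest form type.
* **Cleaning is user-supplied.** Roughly-1%-scale manual code
  harmonization cannot be reconstructed without the reviewers; the
  package ships the mechanism (closure, cycle detection, change log)
  and leaves the content to a CSV.
* **Expert review of the CDE list** (clinical relevance, category
  assignment) is represented only by the user-editable category and
  display-name maps; `odmcde` makes no automated relevance judgment.
* **Sub-concept grouping** is display-only: an optional parent map
  could group entries for presentation, but counting is always per
  canonical key, because any other attribution rule would be invented.
* **CLI config format** is YAML with flags overriding the file; every
  command writes a provenance record (option echo plus input MD5s) and
  refuses to write into a non-empty directory unless forced.

## Known limitations

* Exact-key matching understates semantic overlap: `Troponin I` and
  `elevated cardiac markers` are distinct keys even though they are
  clinically related. Resolving this needs a terminology service, which
  is deliberately out of scope.
* No statistical testing is offered for frequency or overlap
  differences between contexts; the statistics are descriptive.
* Annotation quality is taken as given: the package validates CUI
  syntax, not concept existence or appropriateness.
* The generator's Zipf-over-pooled-vocabulary family is the simplest
  model reproducing a head-plus-singleton-tail shape; real corpora may
  have different tail behavior, and conclusions from synthetic runs are
  about the pipeline, not about clinical documentation.
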