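---
title: "Methods: linking lncRNA peak catalogues to RNA-chromatin contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking lncRNA peak catalogues to RNA-chromatin contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromlink)
```

## The problem

Catalogues of histone-modification peaks whose signal correlates with a
lncRNA's expression across cell types make an implicit mechanistic claim:
if the lncRNA helps establish ("+" peaks) or remove ("-" peaks) the mark,
it should physically contact chromatin near those peaks. Databases of
experimentally detected RNA-chromatin contacts provide the evidence to
check that claim. chromlink implements the three computational steps such
a cross-database integration needs:

1. **Gene reconciliation** — the two resources annotate genes with
   different releases (e.g. GENCODE v31 vs v35), so identifiers and
   coordinates do not align directly; a one-to-one correspondence table is
   built from coordinate overlap.
2. **Peak confirmation** — a peak counts as *confirmed* (supported) when at
   least one contact of the *same* lncRNA, extended by a window of ±w
   bases, shares at least one base with it.
3. **Sign-stratified enrichment** — per lncRNA × histone mark, a 2×2 table
   (sign × confirmed) is tested with one-sided Fisher's exact tests: the
   right tail asks whether "+" peaks are better supported than "-" peaks,
   the left tail the reverse.

## Gene reconciliation

`overlap_pairs()` enumerates every same-chromosome pair of genes sharing at
least one base (half-open arithmetic; strand is deliberately ignored, since
coordinate intersection tools default to strand-blind overlap and nothing
in the procedure conditions on strand). Three similarity metrics are
scored per pair:

* `name_match` — exact, case-sensitive symbol equality. No alias
  dictionaries or fuzzy matching: a fallback metric should be strict.
* `id_match` — identifier equality after stripping the `.N` version suffix
  (configurable via `match_config(version_insensitive_id=)`). Across
  releases the version almost always changes, so version-sensitive
  comparison would make this metric uninformative.
* `jaccard` — overlap length / union length of the two intervals.

`classify_groups()` bins pairs by which metric subset they satisfy (binary
encoding of the triple; typically six subsets are occupied). The numbering
is a canonical reconstruction — there is no external standard for which
group is "group 2" — and only the Jaccard bit matters downstream: groups
passing `jaccard > 0.99` are eligible for unambiguous correspondence.

`resolve_one_to_one()` then works in two stages:

* **Stage 1 (primary):** every A gene with exactly one pair passing the
  Jaccard threshold takes it (`method = "jaccard"`). A genes with several
  passing pairs are resolved by a deterministic tie-break — largest Jaccard
  index, then lexicographically smallest B identifier — and reported in
  `ambiguous_a`. The tie-break rule is a design choice: multi-hits within
  the eligible set are rare but must be resolved reproducibly, so we prefer
  a stated deterministic rule plus full reporting over silently dropping
  them.
* **Stage 2 (fallback):** remaining A genes with exactly one name-matching
  pair take it (`method = "name_fallback"`). Uniqueness is required — a
  fallback that guesses among several same-named genes would be unsound.

A genes appear at most once (asserted at run time). B-side uniqueness is
*not* enforced — the correspondence is a function on A genes only — but
multiply-used B genes are flagged in the `b_reused` column.

**Threshold.** The Jaccard cut-off defaults to 0.99 (strict inequality).
At that level two annotation releases must agree on >99% of a gene's span,
which tolerates boundary revisions of a few hundred bases on a typical
multi-kb lncRNA gene while excluding genuinely different loci.

## Peak confirmation and the extension window

Experimental protocols localise a contact imprecisely: the true interaction
may sit tens of kb from the detected fragment. Confirmation is therefore
assessed after extending the **contact** coordinates by ±w, with
w ∈ {0, 1, 5, 10, 25, 50} kb by default (`default_windows()`). The
interfaces built on such data extend the *peak* locus instead; the two are
equivalent — extending contacts by w or peaks by w yields identical
verdicts — and the test-suite asserts that symmetry on random fixtures, so
the code canonically extends contacts.

Numerical conventions, stated because "confirmed" is otherwise ambiguous:

* coordinates are uniformly 0-based half-open internally; display strings
  (`"chr13:21045572-21046978"`) are 1-based inclusive, and
  `parse_locus()`/`format_locus()` are exact inverses;
* overlap requires ≥1 shared base — adjacency (`end == start`) does not
  confirm; equivalently, a raw contact confirms at window w iff its genomic
  gap to the peak is ≤ w − 1, an identity the oracle tests assert;
* extension clamps the start at 0; the end is clamped only if chromosome
  sizes are supplied;
* contacts of a different lncRNA never confirm a peak, whatever the
  geometry. Internally the overlap query runs on composite
  (lncRNA, chromosome) keys, so attribution is structural, not filtered
  after the fact, and results are independent of input row order.

`confirmation_sweep()` reports, per lncRNA and window, the proportion of
its peaks confirmed; proportions are non-decreasing in w by construction
(confirmed sets are nested). Peaks are pooled over all marks of an lncRNA;
a per-mark breakdown is available through `enrichment_scan()`.
`lncrna_level_summary()` gives the coarser census: how many lncRNAs have
any contact at all, and how many have at least one confirmed peak.

## Sign-stratified Fisher tests

For one lncRNA × mark pair with confirmation flags at window w (default
25 kb), `build_contingency()` counts a = "+" confirmed, b = "+"
unconfirmed, c = "-" confirmed, d = "-" unconfirmed.
`fisher_one_sided()` computes exact central hypergeometric tails with
margins (a+b, c+d, a+c) fixed — right tail P(A ≥ a), left tail P(A ≤ a) —
via R's exact hypergeometric distribution functions; no normal
approximation is involved. A degenerate row margin (no "+" peaks or no "-"
peaks) returns p = 1 with a flag rather than an error: such pairs carry no
sign contrast.

`enrichment_scan()` applies the published procedure:

* **Support filter (default 0.4):** per lncRNA, the supported-peak
  proportion is computed for each mark (signs pooled); the lncRNA enters
  testing when its best mark exceeds the threshold, and all of its marks
  are then tested (`gate = "lncrna"`). The source procedure's wording
  ("supported … for at least one histone mark exceeded 40%") gates the
  lncRNA, which is what the default reproduces; because the wording is
  ambiguous, `gate = "pair"` switches to gating each lncRNA × mark pair by
  its own proportion.
* **Both tails, raw p-values, α = 10⁻³:** verdicts are `plus_enriched`
  when the right tail is below α and `minus_enriched` when the left tail
  is. No multiple-testing correction is applied to the verdicts — that
  mirrors the published procedure of thresholding raw p-values — but
  Benjamini–Hochberg-adjusted columns (`p_right_bh`, `p_left_bh`) are
  emitted so users can apply the better practice.
* Output is sorted by (lncRNA, mark) and invariant under permutation of
  the input rows.

## The synthetic generator

`generate_annotation_pair()` and `generate_peaks_and_contacts()` emulate
the statistical structure the pipeline assumes, with planted ground truth:

* **Annotation pair.** Annotation A places genes with log-uniform lengths
  (1–100 kb) on non-overlapping slots separated by 10 kb gaps, so the
  Jaccard truth is well defined. Annotation B renames a fraction of
  symbols (default 0.1), bumps a fraction of ID versions (default 0.3),
  jitters boundaries with truncated-normal noise and shuffles row order.
  The jitter SD defaults to 0.002 × gene length — proportional noise
  matches how boundary revisions scale with gene size and keeps the
  planted Jaccard index above 0.99 for essentially all genes; the
  generator warns if more than 1% of planted matches are destroyed.
* **Peaks and contacts.** Each of 30 lncRNAs carries 3 marks; each
  lncRNA × mark pair is labelled plus-enriched, minus-enriched or null
  with equal probability, and receives 60 peaks (half "+", lengths
  0.5–2 kb). For a plus-enriched pair a contact (fixed 100 bp, mimicking a
  ligation fragment) is planted uniformly within ±25 kb of each "+" peak
  with probability 0.8 and of each "-" peak with probability 0.2
  (swapped for minus-enriched; the average, 0.5, for null pairs), so a
  planted contact always confirms its peak at the 25 kb truth window.
  Peaks of one lncRNA sit on slots wider than twice the truth window, so a
  planted contact cannot confirm a neighbouring peak of the same lncRNA.
  500 background contacts with random lncRNA attribution are scattered
  uniformly. Everything is deterministic given `seed`.

The defaults are the study conditions of the whole test-suite. Under them
the per-pair power of the right-tailed test at α = 10⁻³ is ≈ 0.96
(30 "+" vs 30 "-" peaks at 0.8 vs 0.2), which is why the planted-truth
acceptance check expects ≥ 90% recovery with zero false verdicts; the null
configuration (equal planting probabilities, 700 lncRNAs = 2,100 pairs)
checks that the rejection rate stays at or below α, as the discreteness of
the exact test makes it conservative.

**What the generator does not model**, and hence what passing tests do not
show about real data: chromatin-contact distance decay, expression-driven
detection bias of all-to-all protocols, overlapping or nested genes,
per-mark peak-density differences, and biological correlation between
marks of one lncRNA. Results on real databases depend on those features;
the synthetic scenario only validates the *logic* of matching,
confirmation and testing.

## Problem sizes and numerical choices

The test-suite runs the exact-test oracle over all 2×2 tables with row
margins ≤ 30 (agreement to 10⁻¹² with direct probability-mass
enumeration), brute-force overlap oracles up to 400 × 400
peak × contact instances, 100-fixture monotonicity sweeps, and the 2,100
pair null calibration — small enough to run in about a minute yet large
enough to exercise every branch. Ties in the hypergeometric tails need no
special handling (the tails are closed, `P(A ≥ a)` includes `a`);
degenerate tables are flagged rather than dropped; and the locus parser
rejects reversed or zero display coordinates rather than repairing them.

## Known limitations

* Gene matching is transcript-blind and build-blind: no liftover between
  genome assemblies, no synonym resolution.
* The URL builder byte-matches the documented single-locus navigation link;
  the two list-mode URLs reuse its parameter vocabulary but their exact
  server-side schema is undocumented, so they are best-effort
  reconstructions.
* Statistical significance of *individual* peak–contact overlaps (as
  opposed to sign stratification) is out of scope; dedicated
  interval-co-occurrence tests exist for that question.
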