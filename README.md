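# chromlink

Integrating lncRNA histone-modification peak catalogues with RNA–chromatin
contact databases.

## The problem

Some databases catalogue histone-modification peaks whose signal correlates
with a lncRNA's expression across cell types: a "+" peak suggests the
lncRNA helps establish the mark, a "−" peak that it helps remove it. Other
databases catalogue experimentally detected RNA–chromatin contacts: loci a
given RNA physically touches. If a correlation-based peak prediction is
real, the lncRNA should contact chromatin near the peak. chromlink is for
bioinformaticians who want to run that cross-validation:

1. **Gene reconciliation** — the two resources use different annotation
   releases (e.g. GENCODE v31 vs v35), so gene IDs and coordinates don't
   align. chromlink builds a one-to-one correspondence table from
   coordinate overlap: pairs with Jaccard index
   `J(a, b) = |a ∩ b| / |a ∪ b| > 0.99` are matched directly, the
   remainder fall back to a unique gene-name match.
2. **Peak confirmation** — a peak is *confirmed* when ≥ 1 contact of the
   same lncRNA, extended by ±w bases (w ∈ {0, 1, 5, 10, 25, 50} kb),
   overlaps it by ≥ 1 base.
3. **Sign-stratified enrichment** — per lncRNA × histone mark, the 2×2
   table (sign × confirmed) with cells (a, b, c, d) is tested with exact
   one-sided Fisher tests under the central hypergeometric law with margins
   (a+b, c+d, a+c) fixed: right tail `P(A ≥ a)` ("+" peaks better
   supported), left tail `P(A ≤ a)` ("−" peaks better supported), with a
   support filter (best-mark supported proportion > 0.4) and α = 10⁻³.

A synthetic-data generator plants annotation pairs, signed peaks and
contacts with known ground truth, so the whole pipeline is testable
offline. Cross-database navigation URLs round out the toolkit.

## Worked example

```r
library(chromlink)

cfg <- synthetic_config(seed = 1)

## 1. reconcile two annotation versions
ap <- generate_annotation_pair(cfg)
corr <- match_annotations(ap$genes_a, ap$genes_b)
corr
#> Gene correspondence table
#>   matched A genes:   200 (200 via Jaccard, 0 via name fallback)
#>   unmatched A genes: 0
#>   ambiguous A genes: 0 (tie-broken deterministically)
```

All 200 planted gene correspondences are recovered through coordinates
alone, even though 10% of the B genes were renamed and 30% had their ID
versions bumped.

```r
## 2. confirmation sweep across extension windows
pc <- generate_peaks_and_contacts(cfg)
sw <- confirmation_sweep(pc$peaks, pc$contacts)
aggregate(cbind(n_confirmed, n_peaks) ~ window, sw, sum)
#>   window n_confirmed n_peaks
#> 1      0          89    5400
#> 2   1000         194    5400
#> 3   5000         593    5400
#> 4  10000        1111    5400
#> 5  25000        2709    5400
#> 6  50000        3563    5400
```

The confirmed proportion grows monotonically with the window
(1.6% → 50.2% → 66.0%): contacts were planted within ±25 kb of their
peaks, so most support only becomes visible once the contacts are extended
toward that scale.

```r
## 3. sign-stratified Fisher tests at the 25 kb window
scan <- enrichment_scan(pc$peaks, pc$contacts, w = 25000)
head(as.data.frame(scan)[, c("lncrna_id", "mark", "a", "b", "c", "d",
                             "p_right", "p_left", "verdict")], 5)
#>    lncrna_id     mark  a  b  c  d      p_right      p_left       verdict
#> 1 LNCRNA0001  H3K4me2 23  7  9 21 3.172851e-04 0.999963534 plus_enriched
#> 2 LNCRNA0001  H3K4me3 28  2  3 27 1.554553e-11 1.000000000 plus_enriched
#> 3 LNCRNA0001   H3K9ac 13 17 24  6 9.994034e-01 0.003637393          none
#> 4 LNCRNA0002  H3K27ac  8 22 20 10 9.996827e-01 0.002012728          none
#> 5 LNCRNA0002 H3K27me3 24  6  7 23 1.133636e-05 0.999999226 plus_enriched
```

Row 1: of 30 "+" peaks for LNCRNA0001 × H3K4me2, a = 23 are confirmed,
versus c = 9 of 30 "−" peaks; the right tail (p ≈ 3.2 × 10⁻⁴ < 10⁻³)
flags the pair `plus_enriched`. Rows 3–4 have left tails just above 10⁻³
and get no verdict at the raw-p threshold.

```r
## 4. jump to the contact browser for a locus of interest
build_rnachrom_url("XIST", 227896, "Homo sapiens",
                   locus = "chrX:23456-24253566")
#> https://rnachrom2.bioinf.fbb.msu.ru/basic_graphical_summary_dna_filter?locus=chrX:23456-24253566&name=XIST&rnaID=227896&organism=Homo+sapiens
```

A command-line wrapper over the same functions ships at
`inst/cli/chromlink.R` (`match`, `confirm`, `enrich`, `link`, `simulate`,
`parse-locus`, `validate` subcommands).

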