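---
title: "miRNA set enrichment: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA set enrichment: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsea)
```

## The model

`mirsea` treats category annotation of a miRNA list as an urn problem. A
catalog of curated miRNA sets defines a reference population of `P` miRNAs
(the union of all set members, or a user-supplied background intersected
with it). The input list contributes `HP` miRNAs found in that population.
For a category of `S` members, the overlap `HS` between input and category
is, under the null of no association, hypergeometric:

$$\Pr(x = HS) = \frac{\binom{HP}{HS}\binom{P-HP}{S-HS}}{\binom{P}{S}}$$

Over-representation is the upper tail $\sum_{h=HS}^{S}\Pr(x=h)$,
under-representation the lower tail $\sum_{h=0}^{HS}\Pr(x=h)$. The upper
sum runs literally to $S$; terms with $h > HP$ are over-draws whose binomial
coefficient vanishes, so the literal formula and the truncated one agree.
The two tails share the point mass at `HS`, giving the identity
`p_over + p_under − pmf = 1`, which the test suite checks on ten thousand
random count tuples.

The model's central assumption is that all four counts refer to *one* urn.
Consequently, when a custom background is supplied, category sizes are
recomputed inside it: members outside the background leave the urn rather
than being counted in `S`. Categories that shrink below
`min_category_size` (default 2) are skipped and recorded — a one- or
zero-member set produces only uninformative p-values and inflates the
correction burden.

## Numerical path

Tail sums are computed by summing `lchoose` terms in log space, factoring
out the largest term before exponentiating. A single numeric path covers
both the desk-scale regime and catalog-scale populations: agreement with
direct term enumeration is verified to 1e−12 absolute error over all valid
counts with `P ≤ 60` and spot-checked at `P = 5000`, and the tail at the
worked-example scale matches the frequency of 10^5 simulated hypergeometric
draws within Monte-Carlo error. We deliberately do not carry an exact
bignum-rational code path: at the population sizes where the test is
meaningful the log-space sum is already exact to well below the error that
would change any reported digit.

Multiple-testing corrections (Bonferroni and Benjamini–Hochberg step-up)
are delegated to `stats::p.adjust` behind the `bonferroni_adjust()` /
`bh_fdr_adjust()` surface; the tests compare them against naive
$O(m^2)$ step-up implementations. By default one correction family spans
*all* categories tested in a run; `correction_scope = "per_class"` corrects
within each of the five class labels instead, for users who regard the five
schemes as separate hypothesis families. The global default is the more
conservative reading.

## Catalog construction

**Families.** miRBase-style family tables (miFam stanzas or long-format
TSV) become one category per family. Families with fewer than two distinct
members after normalization (and optional species filtering) are dropped:
they cannot be enriched.

**Clusters.** Genomic clusters are the connected components of
single-linkage chaining: loci on the same chromosome are linked when the
gap between their intervals is at most `max_gap` (default 50,000 bp,
inclusive — the classical co-transcription distance). The gap is the count
of bases strictly between intervals, 0 for touching or overlapping ones.
We chain on inter-interval gaps rather than start-to-start distances; the
choice is explicit so the brute-force oracle in the tests can mirror it,
and `max_gap` is a parameter for users who prefer another convention.
Strand is ignored by default (polycistronic clusters are co-transcribed
from one strand, but curated coordinates often mix precursor annotations);
`same_strand = TRUE` restricts chaining within strands. Internally the
chaining is `GenomicRanges::reduce(min.gapwidth = max_gap + 1)`; the
boundary case — a gap of exactly 50,000 bp — is covered by a dedicated
test. Coordinates stay 1-based inclusive end to end, exactly as GFF3
stores them.

**Tissue specificity.** miRNAs with a tissue specificity index at or above
0.7 (inclusive — an index of exactly 0.7 qualifies) are grouped by their
tissue label. The TSI itself is consumed, never computed: deriving it
requires an expression compendium outside this package's scope.

**Functions and diseases.** Curated membership tables (set name, class,
member) are unioned per set name, with a provenance tag recorded in the
display name.

**Identifiers.** Matching is by normalized name: lowercase, whitespace
removed, and a leading 3–4 letter species prefix stripped when the
remainder is itself a miRNA stem (`mir`/`let`). Arm suffixes (`-5p`/`-3p`)
and lettered variants are *not* stripped: collapsing them would silently
merge distinct mature species. This direct-name matching is also how
cross-species inputs (e.g. rat microarray names against a human catalog)
are resolved; it is a pragmatic convention, not an ortholog map, and names
that do not match are always reported as dropped rather than silently
discarded.

## Prediction of novel related miRNAs

Members of a significantly over-represented category that are absent from
the input are nominated as candidate related miRNAs. Nomination gates on
the **raw** p-value at `alpha` (default 0.05): category follow-up is
exploratory, and in a catalog of hundreds of sets a family-wise gate would
suppress modest but real signals — in the packaged worked example the
nominating category (p = 0.04) would survive no Bonferroni correction
across a full catalog. FDR gating is available (`use_fdr = TRUE`).
Depletion runs never nominate: absence from a depleted set carries no
positive evidence. A miRNA supported by several significant categories
appears once per category, and `summarize_predictions()` collapses it to
one row ranked by best category p, ties broken by the number of supporting
categories, then name — the ranking is this package's own convention.

## The synthetic generators and the packaged worked example

`make_random_catalog()` and `make_random_loci()` are pure functions of a
`fixture_spec()` (seed included). Synthetic universes use the reserved
`mir-s#` namespace so they can never collide with real identifiers; loci
generators draw gaps from a mixture with one component below and one above
50 kb, so cluster tests exercise both sides of the boundary.

The AMI worked example embeds the printed study data: 8 up- and 8
downregulated miRNAs from a rat myocardial-infarction microarray
experiment, and the 11-member muscle-development category containing two of
them (miR-1, miR-499). The study's own reference population is not printed
(only that the category database spanned more than 400 distinct miRNAs),
so the fixture pads the 25 distinct real names with synthetic filler
categories (`mir-syn###`, labelled synthetic) to a universe of 531 — the
size at which the upper-tail p of the (2 of 11 in 16 of P) overlap equals
the reported 0.04. This calibration pins down the one free quantity from
the two published ones; it was fixed once, from those numbers alone.

```{r}
fx <- ami_fixture()
fit <- mirsea(fx$input, fx$catalog)
fit$results[fit$results$category_id == "muscle-development",
            c("HS", "S", "HP", "P", "fold", "p_value")]
predict(fit)[predict(fit)$source_category == "muscle-development", "mirna"]
```

What the fixtures do *not* emulate: real catalogs are overlapping and
correlated (families overlap clusters; disease sets share cancer cores),
real backgrounds are platform-dependent, and cross-species input matching
hides ortholog ambiguity. Passing tests therefore demonstrate the
correctness of the machinery — counts, tails, corrections, chaining,
round-trips — on data of realistic shape, not the biological validity of
any particular catalog.

## Problem sizes in the test suite

Oracle-equivalence sweeps cover every valid count tuple for populations up
to 60 (strided above 20); complementarity runs on 10^4 random tuples up to
`P = 500`; the simulation check uses 10^5 hypergeometric draws at the
worked-example scale (P = 400, HP = 16, S = 11); cluster oracles run on up
to 30 random loci per case against an $O(n^2)$ components search. These
sizes make the whole suite complete in well under a minute while covering
the regimes the package is used in.

## Known limitations

- Results are only as good as the catalog: the package ships format
  support and builders, not a curated category collection.
- The hypergeometric null treats categories independently and miRNAs as
  exchangeable; co-family correlation structure is not modelled.
- Direct-name matching across species is a convention, not orthology.
- Tissue categories depend on an externally computed TSI table.
- p-values from overlapping categories are corrected jointly but are not
  independent; the BH correction is valid under the usual positive-
  dependence conditions, not guaranteed ones.
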