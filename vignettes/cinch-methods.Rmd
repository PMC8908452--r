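---
title: "Scoring chromosomal instability and clonal heterogeneity in biomonitoring cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chromosomal instability and clonal heterogeneity in biomonitoring cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinch)
```

## The problem

Occupational biomonitoring studies of genotoxic exposure (pesticides,
solvents, radiation) compare an exposed cohort against matched controls on
cytogenetic endpoints read from cultured peripheral-blood lymphocytes. Two
complementary assays dominate:

* **G-banded metaphase analysis.** Each analysable metaphase is described
  as an ISCN karyotype string. Aberrations fall into numerical alterations
  (monosomies, trisomies, marker chromosomes), structural alterations
  (deletions, translocations, inversions, ...), chromatid/chromosome
  breaks, fragile-site expression, and heterochromatic variants (1qh+,
  9qh+, 16qh+ and the pericentric inversion of chromosome 9), which are
  polymorphisms rather than damage but are tracked alongside.
* **Interphase FISH with centromeric probes.** Counting hybridisation
  signals per nucleus for a panel of chromosome-enumeration probes
  (here chromosomes 2, 3, 8, 11, 15 and 17) measures cell-to-cell
  variation in chromosome copy number — numerical chromosomal
  instability (CIN) — and, through the distribution of per-cell count
  signatures, clonal heterogeneity (CH).

`cinch` implements the full analysis chain for both assays, plus a
synthetic-cohort generator with known ground truth so that every estimator
in the chain can be validated end to end.

## Karyotype parsing and aberration profiling

The parser covers the ISCN-2020 subset that occurs in constitutional
biomonitoring reports: numerical terms (`+22`, `-20`, `+mar`), the
structural categories `del`, `t`, `add`, `der`, `inv`, `dic`, `dup`, `i`,
`r`, the damage markers `fra`, `chtb`, `chrb`, and the heterochromatic
variants. Mosaicism slashes, stemline shorthand and uncertainty marks
(other than `?` as the unknown material of an `add`) are rejected with an
error naming the offending span: for records feeding frequency tables,
refusing to guess is safer than silently mis-filing an event.

Two parsing decisions deserve a note:

* **`45,X` is ambiguous on its own** — it does not say whether an X or a Y
  was lost. The parser records the complement verbatim and the classifier
  resolves the loss against the individual's constitutional sex from the
  metadata (`45,X` in an XY individual is a monosomy of Y).
* **Pericentric inversions of chromosome 9** (one breakpoint per arm, as
  in `inv(9)(p21q22)` or `inv(9)(p21q21)` — both spellings circulate for
  the common variant and both are accepted) are classified as the
  heterochromatic variant `cv_inv9`, not as structural damage. Paracentric
  inversions of chromosome 9, and all inversions of other chromosomes,
  remain structural. This follows how the variant is tabulated in
  biomonitoring frequency tables; a true pericentric chromosome-9
  rearrangement outside the heteromorphic region would be mis-filed, a
  limitation we accept for this assay's scope.

Formatting is canonical and round-trip safe: `parse_karyotype()` after
`format_karyotype()` reproduces every field, a property the test suite
exercises against the generator.

**Clonality.** A clone is called by the standard cytogenetic convention:
the same structural aberration or the same whole-chromosome gain in at
least 2 cells, or the same whole-chromosome loss in at least 3 cells
(losses get the stricter threshold because random chromosome loss during
harvest is a common artifact). Events meeting the threshold are clonal
(CCA), the rest non-clonal (NCCA); fragilities, breaks and variants are
tallied per occurrence but never given clonality calls.

**Frequency tables.** Two layouts are produced. The carrier table counts
individuals with at least one event of a category per group (percentages
rounded half-up to 1 decimal) and attaches a two-sided Fisher exact
p-value on the 2×2 carrier table. The paired table reports each
individual's total event count as a percentage of the *group's* total
metaphase count, rounded half-up to 2 decimals — the group denominator,
rather than the individual's own metaphase count, matches how paired
tables are conventionally printed, and the per-pair Fisher test is run on
`[events, group_total − events]`, the closest well-defined reading of that
layout. Rounding is half-up throughout because that is what published
tables use; base R's round-half-even would disagree on boundary cells.

## CIN from FISH signal counts

For each probe the **modal signal count** of the individual's nuclei is
the reference (computed per individual rather than fixed at 2, so a
constitutively trisomic individual is not scored as 100% unstable). Ties
are broken toward the diploid count 2, then toward the smaller value. The
per-chromosome CIN is the percentage of nuclei deviating from the modal
count; the individual's CIN is the unweighted mean over the six probes;
25% is the class boundary, with a mean of exactly 25 classified **high**.

Nuclei with zero signals for a probe count as deviant by default — the
scoring protocol admits intact nuclei without an exclusion rule, and a
lost hybridisation is indistinguishable from a true nullisomy at the
single-probe level. `drop_zero = TRUE` treats them as hybridisation
failures and removes them before scoring, for labs that prefer that
convention.

A minimum of 100 nuclei per individual is expected; fewer triggers a
warning and flags the profile rather than refusing, since pilot data are
often thinner.

**Chromosome stability** within a group is ranked by mean per-chromosome
CIN with a Kruskal–Wallis omnibus test across the six probes' per-individual
distributions (ranks, not raw percentages, because the distributions are
bounded and skewed).

## Clonal heterogeneity

Cells are grouped into clones by their **full six-probe signature** at the
individual level, or by the single chromosome's count at the chromosome
level. Whether published analyses use full signatures or averaged
per-chromosome indices is usually not stated; we default to the full
signature (it is the only choice that actually distinguishes co-occurring
aneuploidies) and expose the per-chromosome marginals alongside.

From the empirical clone abundances \(p_i\):

* **Shannon diversity** \(H = -\sum_i p_i \ln p_i\) (natural log
  throughout — the true-diversity identity below only holds in nats);
* **true diversity** \(TD = e^{H}\), the effective number of equally
  abundant clones (the order-1 Hill number), which is the recommended
  scale for reporting CH because it is linear in "number of clones";
* the **CH class**: TD below 1.5 is low, above 2 high. The published class
  bounds leave the interval (1.5, 1.6) unaddressed; we close the gap by
  making \([1.5, 2]\) intermediate, so every value is classifiable.

Both indices are plug-in estimates: with 100 cells the plug-in entropy is
biased low by roughly \((k-1)/200\) nats for \(k\) clones, negligible at
the clone counts seen here, so no bias correction is applied.

## Statistics layer

All tests are two-sided at \(\alpha = 0.05\). Group comparisons of CIN,
SDI and TD are gated the way biomonitoring papers describe their
workflow: Shapiro–Wilk on both samples; if both pass, Student's t
(Bartlett's test choosing pooled versus Welch), otherwise the Wilcoxon
rank-sum (signed-rank when paired). Constant samples are routed down the
rank branch since Shapiro–Wilk is undefined for them. Every result carries
a `gate_trace` recording exactly which branch fired, so a report is
auditable. The Fisher exact two-sided p is the conventional sum of
hypergeometric probabilities not exceeding the observed table's.

Correlation analysis is plain pairwise Pearson with a |r| > 0.5 flag, sex
encoded 0/1. A point-biserial caveat applies to correlating a binary sex
code, and Pearson on a TD–CIN pair measures only linear association; both
caveats are noted here rather than "fixed", because the flagged matrix is
meant to reproduce the field's reporting convention. No multiple-testing
correction is applied — none is conventional in these reports — but the
manifest records the number of tests performed so a reader can apply one.

## The synthetic cohort

The generator exists to give every estimator a known truth; it emulates a
two-group study of 34 + 34 individuals.

**FISH side.** Each individual is a mixture of clones: a dominant diploid
clone and two minor aneuploid clones — a *broad* clone deviating on all
six chromosomes with frequency \(f_s\) and an *unstable-set* clone
deviating on chromosomes 2, 3, 11 and 15 with additional frequency
\(f_u - f_s\). The marginal deviant fraction is therefore exactly \(f_u\)
on the unstable chromosomes and \(f_s\) on the stable pair (8, 17), which
is recorded as ground truth. Per individual, \(f_u\) and \(f_s\) are drawn
from truncated normals whose defaults place the exposed group mean CIN
near 34.6% (sd ≈ 5.6) and the unexposed near 6.5% (sd ≈ 2.9), with
chromosomes 8 and 17 the most stable in both groups — the group-level
conditions reported for pesticide-exposed farmers versus controls. With
these defaults the exposed group sits mostly above TD 2 (high CH), the
unexposed mostly below 1.5–2, and the exposed:unexposed TD ratio comes out
near 2. Deviant copy numbers are monosomic with probability 0.6, trisomic
otherwise.

Technical noise acts independently per probe per nucleus: each true signal
is missed with probability `p_dropout` (default 0.005), then one spurious
signal is added with probability `p_split` (default 0.0025) — the simplest
identifiable model producing the zero-signal and extra-signal artifacts
real FISH shows, at rates typical of good hybridisations. Noise slightly
inflates estimated CIN (by roughly 1 point at the defaults) and inflates
TD by fragmenting signatures; recovery tests that need exactness set the
noise to zero. `exact = TRUE` fixes the clone census by largest-remainder
apportionment instead of multinomial sampling, so a planted fraction is
hit exactly up to rounding — used when validating estimator bias separately
from sampling error.

**Karyotype side.** Per metaphase, each aberration category draws an event
count from a Poisson rate; chromosomes and bands come from a small fixed
catalog of major bands (full ideogram resolution is out of scope —
recurrence analyses only need a consistent band vocabulary; simulated
inversions are paracentric so they never collide with the chromosome-9
variant). Default rates for the two group presets reproduce the observed
per-metaphase event frequencies of the emulated study (about 1.0 and 0.2
events per metaphase, dominated by fragile-site expression at 9q12), and
metaphase counts per individual are uniform on 19–95, the range such
studies analyse. Clonal injections copy a given token verbatim into a
chosen number of metaphases, for planting CCA signals. Losses and gains
are drawn on autosomes; sex-chromosome numerics enter only through real
data, where the classifier resolves them.

All randomness flows from one explicit seed; there is no silent clock
seeding, and identical seeds give bit-identical output.

**What the generator does not emulate.** Clone phylogenies and selection
dynamics, culture artifacts correlated across probes, scorer-to-scorer
variation, and the long tail of rare complex rearrangements. Passing
recovery tests on this generator therefore demonstrates estimator
correctness under a clean mixture model, not robustness to every failure
mode of real slides.

## Problem sizes and numerical choices

The validation suite runs the estimator-recovery and calibration checks at
the study's own scale: 100 nuclei per individual, 34 individuals per
group, 200 replicate cohorts for the type-I-error calibration of the gated
CIN comparison (observed false-positive rate ≈ 4–6% at \(\alpha=0.05\)),
and 200 replicates for CIN recovery (mean absolute error under 1
percentage point at zero noise). Exhaustive Fisher validation enumerates
every 2×2 table with all margins ≤ 15 against a binomial-coefficient
oracle. Degenerate inputs are defined, not special-cased ad hoc: a zero
carrier margin yields p = 1, an all-tied Kruskal–Wallis yields H = 0 and
p = 1, constant columns yield flagged-undefined correlations.

## Worked example

```{r example, eval = FALSE}
library(cinch)
report <- run_pipeline(run_config(seed = 7, out_dir = "run1"))
report$carriers          # carrier table with Fisher p-values
report$cin               # per-individual CIN profiles
report$comparisons       # gated CIN/SDI/TD group tests with gate traces
report$stability$exposed # chromosome stability ranking
```

The manifest written to `out_dir` records the seed, configuration,
package version, all summary tables and every gate trace, and contains no
timestamps: a rerun with the same configuration reproduces it byte for
byte.

## Known limitations

* The ISCN subset is deliberately narrow; complex derivative chromosomes
  are recorded as `der` plus cited chromosomes only.
* Carrier-table inference treats individuals as exchangeable; matched-pair
  structure is used only in the paired table.
* Plug-in SDI/TD are not bias-corrected (see above).
* The CIN class boundary (25%) and CH bounds (1.5, 2) are conventions of
  the emulated assay, exposed as configuration rather than re-derived.
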