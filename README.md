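# cinch

Chromosomal instability (CIN) and clonal heterogeneity (CH) scoring for
cytogenetic biomonitoring cohorts.

Occupational-exposure studies compare an exposed group against matched
controls on two cytogenetic endpoints read from cultured blood
lymphocytes: ISCN-coded metaphase karyotypes (numerical and structural
chromosomal alterations, breaks, fragile sites, heterochromatic variants)
and per-nucleus centromeric FISH signal counts for a six-chromosome probe
panel (2, 3, 8, 11, 15, 17). `cinch` implements the full analysis chain
for both:

* an **ISCN-2020 subset parser** with canonical, round-trip-safe
  formatting (`parse_karyotype()`, `format_karyotype()`);
* **aberration profiling**: per-metaphase classification, clonal (CCA)
  versus non-clonal (NCCA) calls (≥2 cells for identical structural
  aberrations or gains, ≥3 for identical losses), per-individual tallies,
  carrier and paired frequency tables with Fisher exact tests, and
  recurrently altered band reports;
* **CIN scoring**: per chromosome, the percentage of nuclei whose signal
  count deviates from that population's modal count; per individual, the
  unweighted mean over the six probes, classed low/high at 25%
  (`cin_individual()`, `chromosome_stability()`);
* **clonal heterogeneity**: cells grouped by their six-probe copy-number
  signature, Shannon diversity `H = -Σ p_i ln p_i`, true diversity
  `TD = exp(H)` (the effective clone number), and low/intermediate/high
  CH classes at 1.5 and 2 (`clonal_diversity()`);
* a **gated statistics layer**: Shapiro–Wilk-gated t/Wilcoxon
  comparisons with Bartlett-selected variance handling, Kruskal–Wallis
  omnibus tests, Fisher exact tests and flagged Pearson correlation
  matrices, every result carrying a `gate_trace`;
* a **synthetic cohort generator** (`simulate_cohort()`,
  `simulate_karyotypes()`) producing FISH clone mixtures and karyotype
  records with known ground truth for every downstream estimator.

## Worked example

```r
library(cinch)

# One individual: 97 diploid nuclei, 3 with an extra chromosome-2 signal
m <- fish_counts(rbind(matrix(2L, 97, 6),
                       matrix(c(3L, 2L, 2L, 2L, 2L, 2L), 3, 6, byrow = TRUE)),
                 individual_id = "E01")
cin_individual(m)
#> <cin_profile> E01: mean CIN 0.50% (low)
#>  chr2  chr3  chr8 chr11 chr15 chr17
#>     3     0     0     0     0     0
clonal_diversity(m)
#> <diversity_result> E01: SDI 0.1352, TD 1.1448 (low CH; 2 clone signature(s))

# A full simulated two-group study, analysed end to end
report <- run_pipeline(run_config(seed = 7))
report
#> <cinch_report>
#>   68 individuals, 1784 + 1955 metaphases
#>   mean CIN: exposed 33.89%, unexposed 8.90%
#>   3 group comparisons, 10 carrier categories
```

The simulated exposed group carries clone mixtures whose deviant
fractions put its mean CIN near 34.6% against roughly 6.5% for controls,
with chromosomes 8 and 17 the most stable — so the report's carrier
tables, CIN comparison (Wilcoxon or t, chosen by the normality gates) and
chromosome stability ranking can be checked against known truth
(`report$truth`). Karyotype parsing works the same way on real data read
with `read_karyotypes()` / `read_fish_counts()`.

```r
parse_aberration("t(7;14)(p22;q12)")
#> <aberration_event> t(7;14)(p22;q12) [t] chrom: 7;14 bands: p22;q12
```

## Documentation

The methods vignette (`vignettes/cinch-methods.Rmd`) describes the
models, parameter conventions, gate logic, the generator's assumptions
and its limits, and the numerical choices (rounding, tie-breaks,
degenerate inputs).
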