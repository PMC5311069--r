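# clonexpand

Clonal expansion analysis of paired T cell receptor (TCR) repertoires.

## The problem

In T cell-mediated allergy (e.g. allergic contact dermatitis to hair-dye
haptens), antigen exposure drives a small set of blood T cell clones to
proliferate. High-throughput TCR sequencing of a blood sample taken *ex
vivo* and of paired 6-day *in vitro* cultures — medium only, carrier
protein only, and hapten–carrier conjugate — lets that response be read
out clone by clone: an antigen-responsive clonotype becomes many-fold
more abundant only in the antigen culture. `clonexpand` implements this
analysis end to end, for anyone studying antigen-driven repertoire
focusing with paired pre/post-culture clonotype tables.

## The statistic

For each clonotype observed after culture, the **stimulation index** is

> SI = log2( n_culture / max(n_ex_vivo, 1) )

where `n` are UMI-corrected abundance counts and an ex vivo abundance of
0 (clone not sampled) is imputed as 1, so SI approximates the number of
cell doublings if death is ignored. The expanded set is `SI > 3`
(eightfold, three divisions). Around that:

* **Specificity** — clones with SI > 8 in the antigen culture that are
  also present (SI > 1) in the carrier culture; antigen-specific
  expansion shows high antigen abundance with uniformly low carrier
  abundance.
* **Pre-expansion enrichment** — per-abundance-bin comparison of the
  expanded set's ex vivo abundances against all ex vivo clonotypes,
  with a pooled two-proportion z-test per bin (flagged at p < 0.01).
* **V/J usage skew** — gene frequencies of the expanded set against a
  resampling null (100 equal-sized abundance-weighted draws from the
  ex vivo repertoire); genes outside mean ± 2 SD are over/under-used.
* **CDR3 similarity** — Levenshtein distances between expanded CDR3
  amino-acid sequences, Ward (`ward.D2`) clustering into families,
  center-star alignment and sequence logo of a family, and mean
  pairwise distance compared with equal-sized random draws.

A fully seeded synthetic generator (`make_paired_experiment()`)
produces paired four-condition repertoires with known ground truth —
Zipf clone sizes (ex vivo mean ≈ 1.3, median 1), non-uniform V/J
usage, a division-time growth model (24 h first division, 16–18 h
thereafter, 6-day culture), planted CDR3 families, and multinomial
depth sampling — so every stage is testable without sequencing data.

## Worked example

```r
library(clonexpand)

params     <- generator_params(seed = 42)        # default study conditions
experiment <- make_paired_experiment(params)     # alpha + beta, 4 conditions
report     <- run_analysis(experiment$repertoires, analysis_config(seed = 1))
report
#> TCR clonal expansion report
#>   expanded clonotypes (SI > 3, antigen, all chains): 40
#> # A tibble: 6 x 9
#>   chain condition n_expanded n_cultured n_ex_vivo n_union frac_of_cultured
#> 1 alpha medium             0       5220      5886    7909         0
#> 2 alpha carrier            1       5305      5886    7936         0.000189
#> 3 alpha antigen           20       3436      5886    7180         0.00582
#> 4 beta  medium             0       5192      5732    7804         0
#> 5 beta  carrier            0       5118      5732    7746         0
#> 6 beta  antigen           20       3992      5732    7315         0.00501
```

All 40 planted responders are recovered in the antigen cultures and
essentially nothing expands in medium or carrier — the qualitative
pattern of an antigen-specific recall response. The expanded set is
biased toward pre-expanded clones and toward particular V genes, and
its CDR3s are only slightly less diverse than random draws:

```r
glance(report$enrichment$beta)
#>   frac_gt2_expanded frac_gt2_all n_flagged alpha
#> 1               0.2        0.148         2  0.01

dplyr::bind_rows(report$diversity)
#>   chain expanded_mean random_mean random_sd     z
#> 1 alpha          8.94        10.2     0.378 -3.27
#> 2 beta           8.76        10.1     0.417 -3.30

dplyr::filter(report$usage$beta_V, flag != "ns")
#>   gene     observed null_mean null_sd flag   fold
#> 1 TRBV12-3     0.25    0.0455  0.0456 over   5.49
#> 2 TRBV2        0.5     0.183   0.0970 over   2.73
```

`autoplot()` on `report$si$beta`, `report$usage$beta_V` or
`report$enrichment$beta` draws the SI histogram, the usage-vs-null
scatter, and the enrichment bars. A thin command-line wrapper is at
`inst/scripts/clonexpand.R` (`simulate` and `run` subcommands).

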