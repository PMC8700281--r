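# ctdnascreen

Quantitative feasibility modelling of circulating tumor DNA (ctDNA) for
early-cancer screening.

ctDNA is tumor-derived cell-free DNA (cfDNA) in plasma. For screening,
the binding constraint is not assay chemistry but arithmetic: a blood
draw contains only a few thousand genome equivalents of cfDNA, so a
small tumor's mutant allele fraction (MAF) translates into a *fraction*
of one tumor genome copy per tube. `ctdnascreen` implements that
argument as a tested package for biostatisticians and assay developers
who want to explore it under their own constants:

* **Biophysical chain** — spherical tumor geometry
  (V = π/6 · (d/10)³ cm³, density 1 g/cm³, 10⁹ cells/cm³), a
  volume-proportional MAF model (1 cm³ → 1:10,000 by default), and the
  cfDNA mass-to-genome-equivalents conversion (5 ng/mL with a
  2 × 10¹² Da genome ≈ 1500 genomes/mL plasma).
* **Detection limits** — genome copies captured by a draw are
  Poisson-sampled; inverting the chain gives the minimum detectable
  tumor volume/diameter and the MAF limit of detection, in closed form
  for the expected-value criterion (MAF_min = k/G) and by deterministic
  bisection for probabilistic criteria.
* **Screening statistics** — Bayes PPV/NPV and expected confusion
  counts at configurable sensitivity/specificity/prevalence, with a
  published multi-cancer test's stage-stratified sensitivities packaged
  as a reference scenario (`grail_ccga3()`).
* **Synthetic cohort** — a seeded Monte Carlo screening population that
  recovers the analytic results with Wilson 95% intervals.
* **Reference table & report** — the tumor-characteristics table
  (diameter → weight → volume → cells → MAF → genomes per draw) in
  published-verbatim and exact-recomputation modes, and a JSON summary
  report.

## Worked example

```r
library(ctdnascreen)

# how much DNA does a 10 mL blood draw (4 mL plasma) actually hold?
genome_equivalents_per_ml(shed_model())
#> [1] 1505.535                  # ~1500 genome equivalents per mL plasma

# expected tumor genome copies for a 1 cm^3 tumor (tabulated 6000/draw)
expected_cancer_genomes(tumor_spec(volume_cm3 = 1), genomes_per_draw = 6000)
#> [1] 0.6                       # most draws hold no complete tumor genome

summary_report()
#> ctDNA screening feasibility report
#>   genome equivalents: 1505.5 /mL plasma, 6022 per draw
#>   min detectable tumor: 1.66 cm^3 (diameter 14.7 mm)
#>   MAF detection limit: 0.000166 (decade convention 0.01%)
#>   screening PPV: 17% (sens 0.1, spec 0.995, prev 0.01)
```

Reading the report: a single-molecule expected-value criterion puts the
detection floor at a ~1.7 cm³ tumor (14.7 mm diameter — a size imaging
already finds) and a MAF of 0.01% at the decade convention; and a test
with 10% early-cancer sensitivity and 99.5% specificity screening a 1%
prevalence population yields a PPV of 17%, i.e. five of six positive
screens are false alarms.

The Monte Carlo layer validates the analytic numbers:

```r
cfg <- cohort_config(n = 100000, prevalence = 0.01, seed = 2021,
                     test = test_performance(0.10, 0.995))
empirical_metrics(generate_cohort(cfg))[, 1:4]
#>        metric   estimate     lower     upper
#> 1 sensitivity 0.09560976 0.0790882 0.1151511   # analytic 0.10
#> 2 specificity 0.99482698 0.9943604 0.9952551   # analytic 0.995
#> 3         ppv 0.16065574 0.1336524 0.1919064   # analytic 0.168
#> 4         npv 0.99067311 0.9900563 0.9912520   # analytic 0.991
```

A thin command-line wrapper ships at `inst/cli/ctdnascreen.R` with
`table1`, `report`, `detect`, `screen` and `simulate` subcommands:

```sh
Rscript inst/cli/ctdnascreen.R screen --sensitivity 0.10 \
    --specificity 0.995 --prevalence 0.01 --n 100000
#> PPV: 17% (0.168067)
#> NPV: 99% (0.990946)
#> expected counts: TP 100, FP 495, TN 98505, FN 900
```

See `vignettes/ctdna-detection-limits.Rmd` for the full model account,
parameter meanings and limitations.

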