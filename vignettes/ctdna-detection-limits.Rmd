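---
title: "Modelling the detection limits of ctDNA-based cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the detection limits of ctDNA-based cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnascreen)
```

## The question

Circulating tumor DNA (ctDNA) is fragmented DNA shed into the blood by
dying cancer cells. It is an established marker for prognosis and
treatment monitoring, where tumors are large and the mutant allele
fraction (MAF) — the ratio of tumor-derived to total cell-free DNA
(cfDNA) molecules in plasma — is comfortably above 0.1%. Whether the
same signal can support *screening*, i.e. detecting small asymptomatic
tumors in a general population, is a quantitative question: how many
tumor genome copies does a realistic blood draw actually contain, and
what does a positive test mean at population prevalence?

`ctdnascreen` implements that back-of-the-envelope argument as a tested,
configurable model with three layers:

1. a deterministic biophysical chain from tumor size to the expected
   number of tumor genome copies in a blood draw;
2. a Poisson sampling model that turns those expectations into detection
   probabilities and detection limits;
3. analytic screening statistics (PPV/NPV) plus a seeded Monte Carlo
   cohort simulator that recovers the analytic results empirically.

## The biophysical chain

A tumor is modelled as a spherical nodule of diameter $d$ mm, so its
volume is $V = \frac{\pi}{6}\left(\frac{d}{10}\right)^3$ cm³. Standard
tissue figures apply: density 1 g/cm³ and $10^9$ cells per cm³, so a
1 cm³ tumor weighs 1 g, holds a billion cells, and has a diameter of
about 1.2 cm.

Shedding is modelled as MAF proportional to tumor volume,

$$\mathrm{MAF}(V) = c \cdot V, \qquad c = 10^{-4}\ \mathrm{cm}^{-3}
\text{ by default},$$

anchored so that a 1 cm³ tumor circulates at 1:10,000 and a 10 cm³
tumor at 1:1000. Whether shedding is truly linear in volume is an open
empirical question; the constant `maf_per_cm3` is therefore a plain
model parameter, not hard-coded. The MAF is capped at 1, a cap that
never triggers at realistic sizes.

On the plasma side, healthy cfDNA concentrations lie between 1 and
10 ng/mL; the default uses the 5 ng/mL midpoint. With a haploid genome
mass of $2 \times 10^{12}$ Da (about 3.3 pg via Avogadro's constant,
$6.02214 \times 10^{23}$), 5 ng/mL corresponds to

```{r}
genome_equivalents_per_ml(shed_model())
```

genome equivalents per mL — about 1500 at two significant figures, or
about 6000 in the 4 mL of plasma that a 10 mL blood draw yields. The
expected number of *tumor* genome copies in a draw is then simply
total genome equivalents × MAF:

```{r}
expected_cancer_genomes(tumor_spec(volume_cm3 = 1), genomes_per_draw = 6000)
```

A 1 cm³ tumor — already beyond many early-detection ambitions — puts an
*expected* 0.6 tumor genomes into the draw: most draws contain no
complete cancer genome at all.

### The fixed-6000 table convention

The packaged tumor-characteristics table (`generate_table1()`) fixes the
total genome equivalents per 10 mL draw at exactly 6000 rather than the
model-derived 6022.1, because the published column it reproduces was
computed at that round figure; this keeps the column bit-reproducible
(6, 0.6, 0.3, 0.15, then the "<0.1" token). All other functions default
to the model-derived total, with a `genomes_per_draw` override
available. The two conventions differ by 0.4%, well inside every
rounding used downstream.

The table's `"printed"` mode preserves the published values verbatim —
including their internal rounding quirks. The published diameter column
follows a rounded halving series, not exact sphere arithmetic (the 5 mm
row lists 62 mg where the sphere gives 65.4 mg; the 1.1 mm row does not
match the exact 1.24 mm at any standard rounding), and the MAF ratio
column is a doubling series rounded to two significant figures (1:80,000
at 0.12 cm³ where the exact reciprocal of the volume-proportional MAF is
1:83,333). No reconciliation is attempted: `"exact"` mode recomputes
every derived column from the sphere model at the same diameters and
flags cells whose relative difference from print exceeds 5% — the
granularity of two-significant-figure rounding, the display convention
the published values use. A strict equality test at two significant
figures would misclassify the anchor rows (an exact 6.18 genomes against
a printed 6), so the 5% rule is the deliberate definition of
"differs from print".

## Poisson sampling and detection limits

Tumor genome copies are sampled into the plasma aliquot from an
enormously larger circulating pool at a tiny fraction, so the number
captured is Poisson distributed around the expectation — a Poisson
rather than binomial choice, since the pool size is effectively
infinite relative to the draw. Two detection criteria are supported:

* **expected-value mode** (default): a draw is deemed informative only
  if the *expected* copy number reaches `min_molecules` (default 1).
  This is the deliberately optimistic convention behind the headline
  argument — if even the expectation is below one molecule, no assay
  chemistry can rescue the draw.
* **probabilistic mode**: requires
  $P(X \ge k) \ge$ `prob_threshold` for $X \sim
  \mathrm{Poisson}(\lambda)$; the principled extension when one cares
  about the probability of capture rather than its expectation.

Inverting the chain gives the detection limits. In expected-value mode
the closed forms are $\mathrm{MAF}_{\min} = k/G$ (with $G$ the total
genome equivalents) and $V_{\min} = k/(G c)$; probabilistic mode solves
the same inversion numerically, with the volume bisection run to a
fixed $10^{-6}$ cm³ tolerance so results are deterministic. For the
defaults:

```{r}
min_detectable_volume(genomes_per_draw = 6000)
min_detectable_diameter(genomes_per_draw = 6000)
100 * maf_decade_limit(genomes_per_draw = 6000) # percent
```

The minimum detectable tumor is about 1.67 cm³ — a diameter of 14.7 mm,
inside the 10–15 mm band where ctDNA detection becomes predictable, and
a size already visible to imaging. The exact MAF threshold is
$1.67 \times 10^{-4}$; detection limits are conventionally quoted at
the decade, so the package also reports the largest power of ten
strictly below the threshold, 0.01%. Whether the 10–15 mm band should
be swept across the full 1–10 ng/mL cfDNA range is left as a reporting
choice (`cfdna_conc_ng_per_ml` is a parameter) rather than baked into
the headline numbers. Doubling the plasma volume exactly halves the MAF
limit in expected-value mode — larger draws help, but only linearly.

What the model deliberately ignores: assay-level sensitivity (sequencing
error, duplicate consensus), cfDNA fragment-size and methylation signal,
tumor-type-specific shedding, and mutant cfDNA from clonal hematopoiesis
in healthy subjects. "A molecule is present in the draw" is equated with
"a detectable molecule" — every simplification errs on the side of the
assay, which strengthens rather than weakens the detection-limit
conclusion.

## Screening statistics

For a test with sensitivity $se$ and specificity $sp$ applied at
prevalence $\pi$:

$$\mathrm{PPV} = \frac{se\,\pi}{se\,\pi + (1-sp)(1-\pi)}$$

```{r}
scenario <- screening_scenario(test_performance(0.10, 0.995), 0.01)
ppv(scenario)
format_percent(ppv(scenario))
expected_confusion(screening_scenario(test_performance(0.10, 0.995),
                                      0.01, n_screened = 100000))
```

At the 10% early-cancer sensitivity / 99.5% specificity / 1% prevalence
reference scenario the PPV is 17%: roughly five of every six positive
screens are false alarms, and in a population of 100,000 the 495
expected false positives dwarf the 100 true positives. At 0.1%
prevalence the exact Bayes value is 1.96%; a linearly scaled 1.7% is
sometimes quoted for that scenario, but the package always reports the
exact computation and treats the linear scaling as a rounding artifact.
Display follows the convention that recovers the quoted figures: nearest
integer percent at or above 10%, two significant figures below.

The stage-stratified sensitivities of a published multi-cancer
methylation test (Stage I 17%, Stage II 40%, Stages I–II 28%,
Stages III–VI 84%, overall 52%, at 99.5% specificity) ship as reference
constants under `grail_ccga3()` — external trial results packaged
verbatim, never recomputed.

## The synthetic cohort

`generate_cohort()` emulates a screened population: per-subject cancer
status is Bernoulli at the configured prevalence; cases receive tumor
diameters from a configurable size distribution; the tumor genome
copies captured by each case's draw are Poisson around the model
expectation; non-cases shed zero tumor genomes. Test positivity comes
from one of two mechanisms:

* with an attached `test_performance`, positivity is Bernoulli at the
  stated sensitivity (cases) and 1 − specificity (non-cases) — the right
  emulation when validating the analytic PPV/NPV of a test whose error
  rates are taken as given;
* without one, positivity follows mechanistically from the detection
  criterion applied to the draw, and non-cases are never positive — the
  right emulation of the sampling physics itself.

No published population tumor-size distribution exists for a screening
cohort, so the default is lognormal with median 8 mm and log-sd 0.5 —
chosen once so that the population straddles the 10–15 mm detectability
band, with no claim of epidemiological realism; `fixed` and
`table1_grid` alternatives support controlled experiments. Whether the
99.5% specificity is biological (clonal hematopoiesis) or assay noise
cannot be separated here; the simulator treats it as a single Bernoulli
rate. A single seeded RNG stream drives the whole cohort, and identical
configurations produce byte-identical output.

```{r}
cfg <- cohort_config(n = 100000, prevalence = 0.01, seed = 2021,
                     test = test_performance(0.10, 0.995))
m <- empirical_metrics(generate_cohort(cfg))
m[, c("metric", "estimate", "lower", "upper")]
```

Empirical sensitivity, specificity, PPV and NPV carry Wilson 95% score
intervals (via `prop.test` without continuity correction); at
$n = 10^5$ the analytic values fall inside them. Metrics with empty
denominators (e.g. PPV in a cohort with no positives) are flagged `NA`
rather than propagating NaN. `sensitivity_by_size()` bins the cases by
diameter and shows the detection fraction rising through the
detectability band; empty bins report `NA`, not zero.

The test suite exercises the simulator at $10^4$–$10^5$ subjects —
sizes at which binomial noise is a fraction of the tolerances checked
while the whole suite still runs in seconds.

## Numerical and design notes

* All unit conversions are centralized: diameters mm, volumes cm³,
  weights mg, plasma mL, concentrations ng/mL, genome mass Da.
* Degenerate inputs are legal where the science is well defined: zero
  diameter/volume propagates to zero everywhere; a zero-molecule
  criterion detects everything (limit 0); an empty draw or an
  impossible criterion yields `NA` with a warning rather than an
  error deep in a pipeline.
* `min_molecules = 0` is admitted as the degenerate always-positive
  criterion even though practical criteria start at 1.
* Monotonicity, linearity and round-trip identities (diameter↔volume,
  MAF↔volume to $10^{-9}$ relative error) are enforced by
  property-style tests, and the Poisson tail is cross-checked against
  brute-force probability-mass sums up to $k = 20$.

## Limitations

The model is a feasibility envelope, not a biology simulator. Real
shedding varies by tumor type, vascularization and necrosis; cfDNA
concentration varies within and between subjects; real classifiers
integrate fragmentation and methylation features this model does not
represent. Passing tests show that the implementation reproduces its own
model exactly and that the Monte Carlo layer agrees with the analytic
layer — not that the model's constants describe any particular assay.
The conclusions it supports are the robust, order-of-magnitude kind: a
draw of a few mL of plasma holds a few thousand genome equivalents, so
tumors below roughly 1.7 cm³ leave less than one expected genome copy in
the tube, and at screening prevalence even a highly specific test yields
mostly false positives.
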