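---
title: "Dissecting a qualitative terpene phenotype in an interspecific F2: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a qualitative terpene phenotype in an interspecific F2: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terpseg)
```

## The problem

Wild tomato (*Solanum habrochaites*) type-VI glandular trichomes can
accumulate sesquiterpenes such as 7-epizingiberene at levels far beyond what
a cultivated tomato, or even an interspecific F1 hybrid, produces. When an F1
is selfed, the resulting F2 population segregates for a "high terpene"
phenotype that behaves qualitatively: a small minority of plants reach
parental levels while most do not. terpseg asks the classical question — how
many unlinked loci, and of what dominance, are required from the wild parent
to explain the observed high:low split — and wraps the measurement
arithmetic around it: GC-MS quantification, parental-reference
classification, trichome-density and storage-cavity phenotyping, and a
synthetic-population generator that lets the whole chain be exercised
without any raw data.

## The segregation model

A candidate gene model is an ordered set of locus requirements, each
`recessive` (the plant must be homozygous for the wild allele) or `dominant`
(at least one wild allele). With unlinked loci and a fully heterozygous F1,
each locus segregates 1:2:1 in the F2, so a recessive requirement is met
with probability 1/4 and a dominant one with 3/4. The phenotype requires
*all* loci jointly — a pure AND combination, with no further epistasis — so
the expected high fraction is

$$ f = \prod_{\ell} \begin{cases} 1/4 & \text{recessive} \\ 3/4 & \text{dominant} \end{cases} $$

and the displayed segregation ratio is $1{:}k$ with $k = (1-f)/f$ rounded
half away from zero. Exact odds need not be integers: two recessive plus one
dominant locus give 61:3, displayed as 1:20; three recessive plus one
dominant give 253:3, displayed as 1:84.

`fit_segregation()` scores each candidate against the observed counts with
the uncorrected Pearson chi-square on the two phenotype cells,

$$ \chi^2 = \frac{(n_\mathrm{high} - nf)^2}{nf} + \frac{(n_\mathrm{low} - n(1-f))^2}{n(1-f)}
          = \frac{(n_\mathrm{high} - nf)^2}{nf(1-f)}, $$

with df = 1 (two cells, no estimated parameters) and the upper-tail p-value.
Models are ranked by descending p — equivalently ascending chi-square at a
common df; no AIC-style penalty is applied because the classical analysis
uses none. Ties break by fewer loci, then label order, so the ranking is
deterministic.

```{r}
fit <- fit_segregation(12, 380, table1_models())
fit
```

### The two expectation bases

`basis = "exact"` uses the product-form $f$. `basis = "printed_ratio"` (the
default) first rounds the odds to the integer ratio $1{:}k$ and tests
against $f = 1/(k+1)$. The second convention exists because published
segregation tables in this field were computed from the rounded ratios: the
chi-square of 2.50 for the two-recessive-plus-one-dominant model against
12:380 is reproduced only with $f = 1/21$, not with the exact $3/64$
(which gives 2.32). Both bases are first-class; reproduction work should use
the default, simulation work the exact form.

Not every published chi-square is recoverable from the observed 12:380
under either basis (for instance the four-locus two-dominant model prints
1.15 where both bases give well under 1). The package reproduces the rows
that are arithmetically recoverable (6.80 for 1:15; 2.50 for 1:20) and the
statistic-to-p mapping for every printed statistic, and makes no attempt to
guess the inputs behind the remaining rows.

No Yates continuity correction is applied by default — the reproduced values
match the uncorrected statistic — but `correct = TRUE` is available.

## Quantification conventions

`normalize_peaks()` expresses an integrated peak as
$(\mathrm{peak}/\mathrm{IS}) \times \mathrm{dilution} \times
(V_\mathrm{extraction}/V_\mathrm{injection}) / D$, with $D$ the mg fresh
weight or the number of collected glands. The extraction and injection
volumes enter as a simple linear ratio; because every step is linear the
order of corrections does not change the final quantity, only intermediate
columns. Output is an internal-standard ratio by default; passing the
spiked IS concentration (0.5 ng/uL benzyl acetate in the standard protocol)
rescales it to IS-equivalent nanograms. `quantify_peaks()` applies
calibration slopes from authentic standards (or a surrogate standard such as
beta-caryophyllene for 7-epizingiberene and its derivatives); compounds
without a slope are flagged `semi_quantitative` rather than dropped.

Classification against the wild parent uses
`mean ± 1.96 · sd / sqrt(n)` of the parental replicates (n = 4 by default).
"Parental levels or higher" is operationalized as at or above the *lower*
CI bound — the CI is the only threshold object the extraction protocol
defines — with `rule = "mean"` available as the stricter alternative. With
only four replicates the estimated bound is noisy and the rule is mildly
conservative (it misses a borderline fraction of genuinely high plants),
which is visible in the simulation tests and consistent with a qualitative
screen.

Histogram binning for the skewed F2 distribution isolates exact zeros
(non-detects) in a first bin, then uses consecutive left-open right-closed
bins of width one parental standard deviation; an optional detection limit
zeroes sub-threshold values first. Reported percentages and folds round
half away from zero (a 62.5% reduction prints as 63%), folds at ten or
above round to integers, below that to one decimal.

## Phenotyping conventions

Trichome counts come from r = 2 mm leaf discs on both surfaces; replicate
discs are averaged within a side, then the sides are summed. Field summaries
use both the raw two-sided sum and a per-mm^2 density; since the protocol
never states the denominator for the summed quantity, `summed_density()`
reports both, with `per_mm2` dividing the two-sided sum by one disc area
(pi r^2). Density classes are K = 10 equal-width right-closed bins over the
observed range — edges are not published, so they are emitted alongside the
assignments for audit.

Storage cavities are prolate spheroids with semi-axes a = width/2,
b = height/2. The default volume is the *printed* protocol formula
$(4/3)a^2b$, which omits the factor $\pi$ of the geometric spheroid volume;
whether published picolitre values include $\pi$ cannot be determined from
the protocol text, so both conventions are supported (`include_pi`) and
every ratio-based summary (fold change, percent reduction) is identical
under either. 1 picolitre = 1000 um^3.

The density-versus-terpene relationship is ordinary least squares with the
squared Pearson correlation and the two-sided slope p-value, plus a 95%
confidence band, via `stats::lm`.

## What the generator emulates

`simulate_f2_population()` produces the joint structure the analysis
assumes, with defaults fixed to the studied cross:

* **Genetics** — per locus, two alleles drawn uniformly from {wild,
  cultivar} (selfed heterozygous F1), loci independent; the phenotype class
  is the deterministic classification of the genotype.
* **Levels** — class-conditional lognormals: the high class at 70 ng/mg FW
  (the parental 7-epizingiberene level) with CV 0.3, the low class at
  1.1 ng/mg (the F1 level) with CV 0.8 and a 0.8 zero-inflation (the large
  non-detect bin of the F2 screen, which had notable levels in only 84 of
  392 plants). The lognormal family and the CVs are declared modelling
  assumptions — real within-genotype variance components are not published —
  chosen for strictly positive, right-skewed levels.
* **Density** — negative-binomial per-disc counts (mean 50, size 5),
  independent of the phenotype loci, reflecting that density and per-gland
  productivity segregate independently; `activity_link` exists as a
  sensitivity knob to couple them.
* **Glands and cavities** — an active/lazy latent class with per-gland
  totals 17.7 vs 0.118 ng (a 150-fold spread), leaf totals proportional to
  density x gland content, and cavity volume proportional to gland content
  (25 pl at 17.7 ng/gland). With a constant gland content the
  density–leaf-total r^2 is near 1; the 150-fold spread collapses it toward
  0, mirroring the observed lack of density–terpene correlation.

A single global RNG stream is seeded from the config, every emitted CSV
carries the seed in a comment header, and identical seeds give bit-identical
tables. The generator does **not** emulate chromatogram-level noise,
linkage, genotyping error or environmental covariates — so passing tests
show the *arithmetic and inference chain* is correct under the stated
stochastic model, not that the model captures every feature of real
trichome data.

## Calibration and test sizes

The goodness-of-fit calibration check simulates 10,000 populations of
n = 392 under the best-fitting model (two recessive + two dominant loci,
f = 9/256) at the count level and requires the rejection rate at alpha =
0.05 to sit in 0.05 ± 0.01; exact enumeration over the binomial support
puts the true rate of this discrete design at 0.0540, so the band leaves
roughly four Monte-Carlo standard errors of room. Bound-coverage checks use
1,000 populations per model, correlation contrasts use n = 84 plants (the
size of the measured subset), and convergence checks use 100,000 genotypes;
these sizes keep the full suite under ten seconds while leaving the
statistical margins above three standard errors.

## Known limitations

* Linkage, recombination, QTL mapping and backcross designs are out of
  scope; only the AND-combination of locus requirements is modelled.
* The printed-ratio basis intentionally reproduces a rounding convention;
  its f values are not the mathematically exact expectations.
* Published figure-level quantities that depend on unpublished raw tables
  (exact bin counts, the exact r^2 of the density scatter) are not asserted
  anywhere — only their qualitative structure is.
* Raw chromatogram processing is excluded; inputs are integrated peak
  tables.
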