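---
title: "Methods: genome scans, inversion karyotyping and telemetry-based behaviour"
author: "fjordcod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome scans, inversion karyotyping and telemetry-based behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fjordcod` re-implements, as a tested and reusable pipeline, the
computations needed to characterize sympatric population divergence in a
coastal marine fish from two data streams: whole-genome SNP genotypes and
acoustic-telemetry detection logs. The package covers five stages —
synthetic data generation with known ground truth, genotype filtering,
windowed genome scans, inversion karyotyping with frequency tests, and
behavioural/fitness model ladders — and every stage is exercised end to end
on simulated data, so no external downloads are required to validate it.

This vignette records the models, the tunable parameters that matter, the
numerical choices, and what the synthetic tests do and do not demonstrate
about real data.

# The synthetic genotype generator

## Population structure

Neutral background SNPs follow the Balding–Nichols model: each SNP draws an
ancestral frequency $p \sim \mathrm{Uniform}(0.05, 0.95)$, each population
draws its own frequency

$$p_k \sim \mathrm{Beta}\!\left(\frac{p(1-F)}{F},\; \frac{(1-p)(1-F)}{F}\right),$$

and genotypes are $\mathrm{Binomial}(2, p_k)$. The Beta parameterization
makes the expected Weir–Cockerham fixation index among populations equal
$F$ (`fst_target`); $F = 0$ is handled specially by using $p_k = p$
exactly, since the Beta parameterization degenerates there. The model was
chosen because it is the simplest generator with a directly tunable
$F_{ST}$; it does not model linkage, selection, or demographic history.

## Inversions

A chromosomal inversion is modelled as a single non-recombining bi-allelic
*arrangement locus*. Each chromosome copy carries either the ancestral or
the inverted arrangement (drawn at the population's configured inverted
frequency), and each arrangement indexes its own pool of SNP allele
frequencies; the two pools differ by `pool_divergence` in mean absolute
allele frequency (the offset direction is random per SNP, with frequencies
clamped to $[0.02, 0.98]$). A genotype is the sum of two pool-conditioned
haplotype draws with no recombination between pools. This reproduces the
empirical signatures that the karyotyping stage relies on — three PC1
clusters with heterozygotes intermediate, elevated within-region LD, and
elevated heterozygosity in arrangement heterozygotes — without simulating
recombination maps. Very small pool divergence makes the pools
statistically indistinguishable; calling accuracy then degrades smoothly
(this is a documented property, not an error).

The default region coordinates ship with the four large inversions of the
Atlantic cod reference assembly (LG01 9,114,741–26,192,386; LG02
18,609,260–23,660,985; LG07 13,622,710–23,019,113; LG12 426,531–13,445,150;
`cod_inversion_regions()`).

# The genotype filter chain

Filtering follows the standard two-level chain, with genotype masking
applied before site filters:

1. **Genotype level** (`apply_genotype_filters()`): a genotype is kept iff
   $DP > 3$ and $GQ > 20$ (strict inequalities). For landscape
   (population-level) statistics an additional mask sets genotypes with
   $DP < 7$ missing, because heterozygote call probability is biased at
   low coverage and per-population coverage differences would otherwise
   leak into frequency-based statistics; $DP = 7$ is retained.
2. **Site level** (`apply_site_filters()`): a site is kept iff missing
   fraction $< 0.20$ (count-based comparison, so a fraction exactly at the
   threshold is removed without floating-point leakage), minor allele
   count $> 2$, minor allele frequency $> 0.03$ (computed on called
   genotypes only), one-sided heterozygote-*excess* exact test
   $p \ge 0.001$, and mean depth across called genotypes $< 30$.
3. **LD pruning** (`ld_prune()`): within 10-kb sliding windows, scanning
   left to right, the later member of any pair with $r^2 > 0.8$ is
   dropped. The greedy left-to-right order makes pruning deterministic and
   idempotent.

The heterozygote-excess rule is deliberately one-sided: inbreeding-like
heterozygote deficits are biologically expected under population structure
(Wahlund effect) and must not remove sites, whereas excess heterozygosity
flags paralogous collapse. Caller-level annotations (FS, MQRankSum, QD,
...) belong to variant calling and are out of scope; the chain starts from
GT/DP/GQ.

# Windowed genome scans

Windows tile each chromosome as nonoverlapping half-open intervals
$[0, w), [w, 2w), \dots$ with $w$ = 50 or 100 kb; a trailing partial window
is kept and flagged. Per window:

- $F_{ST}$: per-site Weir–Cockerham variance components $a$ (among
  populations), $b$ (among individuals within populations) and $c$
  (within individuals), combined as the **ratio of sums**
  $\sum a / \sum (a+b+c)$ — the standard, less biased choice compared with
  averaging per-site ratios. Sites with zero total variance are skipped;
  negative window estimates are retained rather than clamped so that
  genome-wide summaries stay unbiased.
- $d_{xy} = \sum_s [p_A(1-p_B) + p_B(1-p_A)] / L$ with $L$ the window
  length in bp: unreported sites are assumed invariant, so the statistic
  is per-bp and comparable across windows.
- $\pi = \sum_s \frac{n}{n-1} 2 p (1-p) / L$, the unbiased per-site mean
  pairwise difference, again per-bp.
- $d_f$: the proportion of *variant* sites fixed for alternate alleles
  ($|p_A - p_B| = 1$). The denominator is the variant-site count, not bp —
  a per-bp "proportion" would not be a proportion. Users who want the
  per-bp variant can divide by $L$ themselves.
- mean $r^2$: mean pairwise squared Pearson correlation of dosage vectors
  over all SNP pairs in the window, pairwise-complete over missing data.

A site enters the between-population statistics only with at least 4
called chromosomes per population (a tolerance choice; below that the
frequency estimates are too noisy to be useful). All of these statistics
are validated in the test suite against independently coded oracles
(scalar textbook implementation for Weir–Cockerham; chromosome-pair
enumeration for $\pi$ and $d_{xy}$; explicit-sum correlations for $r^2$),
and the windowed $F_{ST}$ is checked to recover the generating
Balding–Nichols $F$ at 0.02/0.05/0.1.

# Inversion karyotyping

## Region PCA

`region_pca()` uses smartPCA-style normalization: dosages are mean-centred
per SNP and scaled by $\sqrt{p(1-p)}$ with the shrunk frequency
$p = (1 + \sum g) / (2 + 2n)$; missing dosages are imputed to the column
mean before scaling. For a segregating inversion, PC1 separates the two
homozygote arrangement classes with heterozygotes intermediate.

## Calling states

`call_karyotypes()` runs 1-D k-means on PC1 with $k$ chosen from
$\{1,2,3\}$: $k = 2$ and $k = 3$ compete by average silhouette width, and
$k = 1$ is chosen when the best silhouette falls below 0.75. The threshold
exploits a large gap: unstructured (Gaussian) PC1 scores have an expected
silhouette near 0.57 under a forced 2-split, while genuine inversion
clusters sit near 0.9. With $k = 3$ the middle cluster is `het` and the
*minor* extreme cluster is `inv` — the ancestral arrangement is by
definition the more common one in these populations; with $k = 2$ the
minor cluster is `het`, and $k = 1$ calls everything `anc`. The
orientation is validated against an independent signal: the `het` cluster
must have the highest mean observed heterozygosity across region SNPs,
otherwise calls are flagged low-confidence. PC1 sign is fixed so the
inverted-homozygote cluster is positive. Whether the original analyses
called states algorithmically or by visual cluster inspection is unknown;
this rule is a reproducible stand-in validated against simulated truth
(>= 95% accuracy at pool divergence 0.4, monotone in divergence).

## Arrangement-frequency tests

Arrangements are counted at chromosome level (2 per diploid individual):
`anc_chr = 2*anc + het`, `inv_chr = 2*inv + het`. The bootstrap
over-representation test draws, for each population × arrangement, $B$
replicates of $\mathrm{Binomial}(2n, q)$ at the pooled frequency $q$
across all populations, with one-sided p-value
$(1 + \#\{X \ge \text{obs}\}) / (B + 1)$ (the $+1$ correction keeps
$p > 0$). The production default is $B = 10^6$; the test suite uses
smaller $B$ where the Monte-Carlo error bound allows. Bonferroni
correction multiplies by the number of tests in the invocation — whether
the original correction family was per-region or global is unknown, so
the family is simply everything tested in the call, which is the more
conservative reading for a single-region call set. Derived groups sampled
inside another population can be excluded from the pool to avoid double
counting.

Hardy–Weinberg equilibrium uses the exact conditional (Levene)
distribution of the heterozygote count given allele counts, summing
probabilities of configurations no more probable than the observed one
(two-sided). The same machinery restricted to the excess tail drives the
site filter.

## Combination census and coverage

Across three regions there are $3^3 = 27$ possible diploid state triples;
`combination_census()` enumerates them and reports the observed subset.
`combo_coverage_probability()` estimates by Monte Carlo the chance that an
iid sample of $N$ individuals contains all 27 triples, with triple
probabilities the product of per-region genotype frequencies (the regions
segregate independently); $N < 27$ returns exactly 0 without simulation.

# Telemetry processing

## From detections to traits

- **False detections**: any fish-day (calendar day, local time zone,
  default Europe/Oslo) with fewer than 2 detections for that fish is
  dropped entirely.
- **Post-mortem truncation**: a dead fish with a live transmitter pings
  from a constant depth. Scanning each fish's record, the earliest time
  $t^*$ is found such that depth SD within every subsequent 24-h window
  stays below 0.5 m through the end of the record (and the flat tail
  spans at least one full window); detections after $t^*$ are removed and
  the fish flagged. The original study did this by visual inspection;
  the variance rule is the package's reproducible operationalization.
- **Centres of activity** (COA): per fish per 30-min bin, the mean of
  detecting-receiver coordinates over all detections in the bin (receivers
  thereby weighted by detection counts), and mean depth likewise.
- **Day/night**: solar elevation above 0° at the site, via the NOAA
  solar-position algorithm (validated against an independent Michalsky
  ephemeris to within 2 minutes at sunrise across a year). A fixed-hours
  alternative is trivially achieved by bucketing timestamps upstream.
- **DVM**: per fish-day, mean daytime depth − mean night depth (positive
  = deeper by day); monthly value = mean over days with both defined.
- **Daytime depth**: mean over days of daily daytime means — days weigh
  equally regardless of detection counts.
- **Home range**: monthly 95% kernel utilization distribution area. COAs
  are projected to planar metres (equirectangular about the array
  centroid), smoothed by a product-Gaussian KDE with the normal-reference
  bandwidth per axis (`stats::bw.nrd`), evaluated on a 256×256 grid padded
  by 3 bandwidths; the area is that of the smallest set of grid cells
  holding 95% of the mass. Fish must be present ≥ 20 distinct days and
  ≥ 30 COAs in the month. For bivariate-normal positions the 95% KUD area
  converges to $\pi \chi^2_{2,0.95} \sigma^2 \approx \pi\, 5.9915\,
  \sigma^2$ inflated by the smoothing factor $(1 + h^2/\sigma^2)$; at
  $n = 500$ this bias is ~9%, inside the 15% tolerance the calibration
  tests use.
- **Fate**: *dead* when post-mortem truncation fires, or when
  transmissions stop early while the final COAs are interior; *dispersed*
  when the last $k = 10$ COA distances to the array centroid trend outward
  (regression slope ≥ 0 with non-negative net displacement — COAs are
  receiver-weighted means, so strict monotonicity would be defeated by
  receiver quantization noise) and the modal receiver among the final
  detections lies in the outermost distance band (top decile); otherwise
  *alive*. Days survived run from tagging to the last valid detection
  (alive fish: to battery end — the censoring endpoint is configurable).
- **Relative longevity**: $S_i = d_i / \bar d$ over non-dispersed fish;
  mean $S$ is exactly 1 by construction.

## The telemetry simulator

The generator emulates a fixed array of 33 receivers on a regular grid
over a 3 km × 1 km rectangle (the real array geometry is not
machine-readable, so the layout is schematic by design), transmitters
pinging every 110–250 s, depth = mean + diel sinusoid + mean-reverting
(OU) noise, a reflected random walk for horizontal position, and
distance-decaying detection probability $e^{-d/\rho}$ with $\rho$ = 250 m
(a monotone decay; no empirical range-test curve is implied). Timestamps
are UTC internally; Europe/Oslo is applied for day/month bucketing.

One calibration detail: a sinusoid with peak $A$ has a day-minus-night
mean difference of $(4/\pi)A$ over 12-h halves, so the generator scales
the sinusoid peak to $\texttt{diel\_amplitude\_m} \cdot \pi/4$. The
configured amplitude is then *exactly* the expected DVM estimate, and the
identity is robust to day-length asymmetry because the day and night
integrals of a zero-mean diel cycle cancel. Death produces a
constant-depth, fixed-position tail until battery end; dispersal is a
2-day monotone glide to the outermost receiver followed by silence.

# Behavioural and fitness models

## Trait mixed models

`fit_trait_lmm()` fits

$$BT_{im} = c_0 + c_1 S_m + c_{2..4}\,LG_{i} + c_5 L_i + c_6 GS_i +
  \text{(interactions with } S) + u_i + \varepsilon_{im}$$

with a fish-level random intercept $u_i$, by **maximum likelihood** (not
REML) so that AIC values are comparable across fixed-effect structures —
the estimation choice is documented here because it matters for ladder
comparisons and REML would make them invalid. Factor codings use
treatment contrasts with the conventional reference levels: ancestral
arrangement, female sex, feeding season (months May–December; spawning =
January–April). Home range is log-transformed with the natural log (the
base is a package choice; it only shifts coefficients by a constant
factor). Wald standard errors and normal-approximation p-values are
reported; singular fits warn rather than pass silently.

Variance partitions report $ICC = \sigma^2_{id} / (\sigma^2_{id} +
\sigma^2_{res})$ and the Nakagawa-style marginal $R^2 =
\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \sigma^2_{id} +
\sigma^2_{res})$. The published "fixed effects explained X%" phrasing is
treated as this marginal $R^2$; the exact original definition is unstated,
so equivalence is documented as an interpretation, not asserted.

## AIC ladders

`aic_select()` fits all candidates by ML on identical rows (differing row
sets are rejected) and ranks by AIC with ties broken toward fewer
parameters. `aic_two_step()` reproduces the two-step protocol: first
choose the body-size/sex structure while retaining the full
inversion-state terms, then choose the inversion-state structure given
that winner. `select_min_aic()` applies the same selection rule to
precomputed ladder tables.

## Selection gradients

`fit_selection_model()` is the Lande–Arnold linear regression of relative
fitness on traits by OLS: $S = c_0 + c_{1..3}\,LG + c_4 L + c_5 GS$.
Coefficients are selection differentials on the fitted scale; multiple
$R^2$ is reported, and rank deficiency is flagged.

## Generator calibration for parameter-recovery checks

`default_behaviour_effects()` freezes the three generating conditions used
by the recovery checks:

- **Daytime depth**: intercept 14.759, fjord-genotype offset +3.67 m,
  body length 0.015, male +1.264; 48 fish × 12 months. The random part is
  anchored on the reported variance decomposition — fixed
  effects explain 12% of total variance in the genotype depth model and
  the intraclass correlation is 0.23 — which, given
  $\mathrm{var}(X\beta)$ under the covariate distributions, pins
  $\sigma_{id} = 2.52$ m and $\sigma_{res} = 4.61$ m.
- **Log home range**: the full reported coefficient set including the
  LG07-inverted × spawning interaction 0.557; 60 fish × 12 months; fixed
  effects 18% of variance at ICC 0.25 give $\sigma_{id} = 0.411$,
  $\sigma_{res} = 0.620$. Under these conditions the per-replicate SE of
  the interaction (~0.19) sits near the published 0.24, and the AIC
  ladder retains the interaction in >70% of replicates.
- **Relative longevity**: intercept 0.702, LG12 het +0.070, LG12 inv
  −0.372, length 0.007 at 64 fish; residual sd 0.40 and an LG12
  inverted-arrangement frequency of 0.35 were chosen once so the fitted
  standard errors reproduce the published magnitudes (0.087 het / 0.160
  inv).

Covariates are drawn as: karyotypes at Hardy–Weinberg proportions from
per-region inverted frequencies (defaults 0.25/0.30/0.35 for
LG02/LG07/LG12), body length from a truncated normal (mean 46 cm, sd 9,
range 30–75 cm, matching the tagged sample), sex and genotype class
balanced. The generator redraws covariates (up to 100 times) until every
factor level referenced by the model is present, so each replicate design
is estimable; replicates are therefore conditioned on estimability, a
deliberate choice documented here.

# Numerical choices and degenerate inputs

- Exact-threshold comparisons in the missingness filter are count-based to
  avoid floating-point leakage at fractions like 2/10 vs 0.20.
- k-means ties are broken by a fixed seed; quantile-based starting centres
  make the 1-D clustering effectively deterministic.
- The HWE exact test works in log-space (lgamma) and is validated against
  a recurrence oracle and a brute-force allele-assignment enumeration.
- Zero-variance regions, empty windows, all-dispersed fate tables, and
  populations smaller than a downsampling target all raise informative
  errors naming the offending object; no silent NA propagation.
- Every `simulate_*` function is bit-reproducible under a fixed seed and
  restores the caller's RNG state.

# Problem sizes

The shipped test-suite and acceptance computations use desk-scale sizes
chosen to keep the whole suite around a minute while leaving Monte-Carlo
error well inside each tolerance: genome simulations of 1–5 × 10³ SNPs
with 50–200 individuals; 200 replicate datasets for each
parameter-recovery check; 2,000 simulated tables (B = 2,000 each) for the
bootstrap null-calibration check; bootstrap oracle comparisons at
B = 5 × 10⁴–10⁶; and 500-point COA clouds for the kernel home-range
calibration.

# What passing tests do and do not show

The simulators reproduce the *statistical structure* the methods rely on:
Balding–Nichols divergence at a target $F_{ST}$, non-recombining
arrangement pools, HWE karyotype proportions, diel depth cycles,
distance-decaying detection, and linear(-mixed) trait generation. They do
not emulate linkage beyond the inversions, demographic history, sequencing
error profiles, receiver shadowing/bathymetry, tidal or seasonal movement
trends, or behavioural autocorrelation beyond the OU depth process.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated models, not that the original field data would
yield identical numbers. Known limitations worth flagging: fate
classification cannot distinguish an interior death without a flat depth
tail from dispersal if the track happens to drift outward; the KDE home
range carries the usual ~$(1 + h^2/\sigma^2)$ smoothing inflation; and the
genotype-class assignment threshold $\tau = 0.5$ is a conservative
ambiguity rule, not an optimized classifier.
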