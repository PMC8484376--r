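---
title: "Mapping a fully penetrant plumage-pattern locus with pooled sequencing and a backcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a fully penetrant plumage-pattern locus with pooled sequencing and a backcross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcross)
```

## The problem this package addresses

Autosomal barring in chicken — regular black-and-white striping of individual
feathers — segregates as a Mendelian trait in experimental crosses between a
patterned breed (Fayoumi-type, "line A" throughout this package) and a plain
wild-type breed (Light Brown Leghorn-type, "line B"). `poolcross` implements
the statistical machinery used to map such a locus:

* a **pool-seq F~ST~ genome scan** comparing phenotype pools of backcross
  progeny,
* a **pooled-heterozygosity (H~p~ / Z~Hp~) scan** across breed pools to look
  for a shared identical-by-descent (IBD) haplotype,
* **marker selection filters**, the backcross **genotype matrix**, and
  detection of the **non-recombining interval** that delimits the candidate
  region,
* **segregation-distortion chi-square**, **two-point LOD**, and the
  **double-heterozygote expectation** for the cross design, and
* **ΔΔCt relative expression** and **allelic-imbalance** statistics for the
  follow-up feather-follicle assays.

Because the raw sequencing pools of the original experiment are not needed to
exercise any of this machinery, the package ships a first-class synthetic
backcross generator; all tests and the bundled analysis scripts run on it.

## The cross and its simulator

The design is a two-generation backcross: five line-A dams crossed to two
line-B sires, twelve F1 dams backcrossed to a further line-B sire, and 365
backcross (BC) progeny. Founders are fixed for alternative alleles at every
marker, so each BC animal carries one non-recombinant line-B paternal
haplotype and one recombinant maternal gamete from its F1 dam — each progeny
is one informative meiosis.

**Recombination model.** Maternal gametes are drawn under the Haldane model:
the number of crossovers per chromosome is Poisson with mean equal to the map
length in Morgans, positions are uniform on the genetic map, and there is no
interference. We chose Haldane because the only information available about
the genome in question is an average rate (about 4 cM/Mb for chicken, the
package default) and the existence of a recombination-suppressed segment at
the distal end of chromosome 11; nothing constrains interference. The
suppressed segment is modelled as a `cold_region` — a physical interval with
its own cM/Mb rate (default 0.04 cM/Mb over chr11:18.80–19.93 Mb, which
yields on the order of 0.1 expected crossovers in 365 meioses and therefore
interval borders "based on a single recombinant", as observed in crosses of
this size).

**Default genome.** Simulations use two chromosomes at approximately their
real chicken lengths: chr1 (197 Mb) as the neutral background carrying the
modifier locus, and chr11 (19,932,279 bp) carrying the causal locus at the
MC1R coordinate 18,840,646. A genome much smaller than this misrepresents a
whole-genome scan: the linked signal region then forms a large fraction of
all windows and inflates the genome-wide standard deviation against which
window Z scores are computed. The modifier is placed at chr1:50 Mb, inside
the chromosome-1 candidate region of the original cross; the exact
coordinate is a synthetic stand-in, as the true position is not required by
any analysis.

**Transmission-ratio distortion** is a single Bernoulli parameter: the
probability that the maternal gamete carries the line-A allele at the causal
locus (default 0.5; `distorted_transmission()` = 159/365 reproduces the
carrier deficit seen in the real cohort). It is implemented by drawing the
crossover pattern first and then choosing the origin of the leftmost segment
so that the causal-locus allele has exactly the requested probability — the
recombination process itself is untouched.

**Phenotype model.** Categories are AB (autosomal barring), WT (wild-type),
UNCLEAR (irregular pattern) and RB (red belly). The default conditional
table `default_phenotype_table()` encodes the structure observed in the real
cohort: no AB or UNCLEAR bird lacks the causal allele, carriers are never
plain WT, and RB is male-limited. The joint distribution over causal ×
modifier genotypes is not observable from published marginals, so it is
completed with one assumption: the modifier acts only among causal-allele
carriers, shifting the AB-vs-UNCLEAR split (66/69 with the modifier, 36/61
without, the ratios among patterned carriers in the observed margins).
RB rates are 2·29/159 for carrier males and 2·3/206 for non-carrier males
(doubled because RB is male-limited while the printed rates are per
carrier row). The whole table is an argument to `phenotype_model()`, so any
other completion can be substituted.

**Pooled reads.** A pool is a named membership predicate plus a target
coverage and an error rate. Per variant, depth is Poisson(coverage), each
read is drawn from the pool allele frequency (members contribute two
chromosomes each, equally), and flipped with a symmetric per-read error
(default 0.001; no quality scores are modelled). Backcross phenotype pools
default to 45×, breed pools of five birds to 10×, matching the sequencing
depths of the experiment the generator emulates. Breed pools draw
independent allele frequencies per breed from a uniform distribution on
[0.05, 0.95] — a deliberately featureless stand-in for neutral diversity —
and are all fixed for one shared haplotype inside an optional IBD segment.

What the generator does **not** emulate: linkage disequilibrium within
breeds, realistic site-frequency spectra, mapping and calling artefacts,
indels and multi-allelic sites, coverage autocorrelation along the genome,
or pool construction error. Passing tests therefore demonstrate that the
estimators recover what the model plants, not that they are robust to every
artefact of real pool-seq data.

## The genome scans

**Per-variant F~ST~.** For pools with alt-read fractions $p_1, p_2$:
$$F_{ST} = \frac{\pi_{between} - \pi_{within}}{\pi_{between}},\qquad
\pi_{within} = \frac{2p_1q_1 + 2p_2q_2}{2},\quad
\pi_{between} = p_1q_2 + p_2q_1.$$
Only the ratio form is conventionally reported; the $\pi$ estimators above
are the simplest frequency-based reading and are what `variant_fst()`
documents and computes. $F_{ST}\le 1$ always, with 1 at a fixed difference
and 0 exactly when $p_1 = p_2$; variants with $\pi_{between}=0$ (both pools
fixed for the same allele) or zero depth are flagged undefined and excluded
from windows.

**Windows.** `window_scan()` averages the per-variant statistic over a
deterministic grid anchored at the chromosome origin (0-based half-open
coordinates, default 30 kb windows). The default step equals the window:
"sliding" windows with an unspecified step make the Bonferroni denominator
ill-defined, so overlap is opt-in via `step_bp` and the number of tested
windows is always explicit. Windows with fewer than `min_variants` variants
(default 10) are dropped — the threshold for "too few variants" is a free
choice and is surfaced as a parameter.

**Z scores and calls.** `zscore_windows()` standardizes the window statistic
genome-wide with the sample standard deviation, takes a one-tailed normal p
(upper tail for F~ST~, lower for H~p~, matching the direction each statistic
is informative in), and flags windows with $p \cdot n_{windows} < \alpha$
(default 0.05). The Bonferroni denominator is the number of retained windows
after the `min_variants` filter. For the heterozygosity scan the
conventional fixed cutoff $Z_{Hp} \le -4.70$ is reported alongside.

**Pooled heterozygosity.** Per variant, reads are summed across all breed
pools and split into major (`nMAJ`) and minor (`nMIN`) counts, ties broken
toward the reference allele. Per window:
$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}{(\Sigma n_{MAJ} + \Sigma n_{MIN})^2}$$
which is bounded in $[0, 0.5]$, attains 0.5 only at perfectly balanced
counts, and is 0 when every variant in the window is monomorphic. A variant
numerator $2\,\Sigma n_{MIN}$ (without the $\Sigma n_{MAJ}$ factor) appears
in some method descriptions; it is not scale-invariant in read depth, but is
available via `literal_numerator = TRUE` for comparison.

**Resolution of the scan.** With a fully penetrant locus, every window
inside the span where no pooled meiosis recombined has *identical* expected
pool allele frequencies; at 4 cM/Mb and ~300 pooled members this plateau
extends a few hundred kb, and a configured cold region extends it further.
Which of those windows ranks first is therefore decided by read-sampling
noise, and single-window localisation of the causal position is not
achievable by this design — the meaningful mapping result is the *span* of
Bonferroni-significant windows, which in the bundled experiments contains
the causal locus essentially always, with no significant window on the
background chromosome. The test suite asserts both statements; the
single-window one documents the resolution limit rather than a property the
design can deliver.

## Markers, genotype matrix, interval

`select_markers()` applies the genotyping-panel filters — region, ≥ 20 reads
per pool, alt fraction within [0.4, 0.6] in the case pool and < 0.2 in the
control pool (or, in `min_fst` mode, per-variant F~ST~ above a floor) — and
then thins survivors left-to-right, drawing the next marker uniformly at
random (seeded) among candidates whose gap falls in the target range
189–322 kb; when no candidate is in range the nearest one beyond it is taken
and the oversized gap counted. "Frequency" here is the pool alt-read
fraction, the only frequency observable from pooled data. Because the
minimum spacing exceeds half the maximum, a selected panel re-filters to
itself (idempotence), which the tests exercise.

`build_genotype_matrix()` codes each BC genotype by its count of
line-A alleles (HOM_WT / HET / HOM_FAY, with MISSING), and
`find_nonrecombining_interval()` extends from an anchor marker — by default
the marker whose heterozygosity is perfectly associated with the carrier
predicate, leftmost on ties — while adjacent marker pairs show zero code
changes across all individuals. Borders are reported as the positions of the
first flanking markers with at least one recombinant (both the interval end
and the flanking-marker coordinate are exposed, since either convention is
defensible). MISSING cells break the adjacent-pair comparison without
counting as events.

`classify_pool_state()` labels a pool at a variant as fixed-reference,
fixed-alternative, or segregating using a symmetric threshold t (default
0.1). With pools of five birds a single heterozygote gives an expected alt
fraction of exactly 0.1, so t is a real trade-off and is surfaced and
reported rather than hidden.

## Cohort statistics

`segregation_chisq()` is the textbook Pearson statistic against an expected
ratio with df = classes − 1 and no continuity correction — the uncorrected
statistic is what reproduces the reference value 6.05 for 206 vs 159 against
1:1 (Yates would give 5.69). `two_point_lod()` treats each BC progeny as one
informative meiosis: $\hat r = R/N$ and
$\mathrm{LOD} = R\log_{10}(\hat r/0.5) + (N-R)\log_{10}((1-\hat r)/0.5)$,
with limit $N \log_{10} 2$ at $R = 0$; only the two-point backcross case is
implemented, where this closed form is the exact maximum-likelihood answer —
general multipoint pedigree likelihoods are a different tool and out of
scope. `double_het_expectation()` returns $(1-r)/2$, the probability that
the single maternal gamete transmits both founder alleles: 50% for fully
linked loci down to 25% for unlinked ones.

## Expression and allelic imbalance

`relative_expression()` implements ΔΔCt with two housekeeping genes:
$\Delta Ct = Ct_{target} - \mathrm{mean}(Ct_{HK1}, Ct_{HK2})$ (the
arithmetic mean of Cts equals a geometric mean of linear quantities under
the fixed efficiency-2 assumption; no efficiency correction is applied),
$\Delta\Delta Ct$ is referenced to the calibrator-group mean, and the group
fold change is $2^{-\mathrm{mean}(\Delta\Delta Ct)}$ — the geometric form,
which makes the calibrator fold exactly 1 by construction; the SEM is
reported from per-sample folds. Adding a constant to all Cts of one sample
(a plate shift) cancels exactly. `group_compare()` is the classical
equal-variance Student's t test (Welch behind a flag), and
`allelic_imbalance()` summarizes founder-allele fractions in heterozygotes
by template and tests cDNA against the genomic-DNA control, where a 50:50
ratio is expected. Whether a published "±" is SEM or SD is often ambiguous;
all output here is labelled SEM.

## Numerical and degenerate-input choices

* All randomness flows from a single integer seed per operation
  (`withr::with_seed`), so every result is bit-reproducible.
* Windows with zero retained variance, scans with < 2 windows, empty pools,
  off-map loci, and all-`NA` meiosis vectors raise errors naming the
  problem; undefined F~ST~ variants and zero-depth pool states are flagged
  rather than dropped silently.
* Ties: major allele ties go to the reference allele; anchor-marker ties go
  to the leftmost position.
* Degenerate constant groups with equal means return t = 0, p = 1 in
  `group_compare()`; with unequal means they are an error (infinite t).

## Problem sizes used by the tests and scripts

The bundled experiments simulate 365 BC progeny on the two-chromosome
genome with line-diagnostic variants every 2.5 kb (~87,000 variants,
~12 per 30 kb window), phenotype pools at 45× and six breed pools of five at
10×; scan-power and sweep-detection properties use 20 seeds, estimator
consistency 50 seeds, and the Haldane/double-heterozygote Monte-Carlo checks
10,000 progeny. These sizes give the binomial checks standard errors an
order of magnitude below the asserted tolerances.

## Known limitations

* Pool allele frequencies are read-count fractions; no correction for
  unequal individual contributions or finite pool size is applied.
* Only biallelic variants are handled; the VCF reader skips others with a
  message.
* The H~p~ scan assumes pooled breeds are independent; shared ancestry
  between breeds would inflate apparent IBD.
* The phenotype model is a conditional table, not a developmental model;
  its joint causal × modifier structure is an assumption (see above).
* Single-window localisation is limited by the recombination plateau, as
  discussed under the genome scans.
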