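# poolcross

Pool-seq genome scans and backcross linkage analysis for mapping a fully
penetrant Mendelian locus — built around the design used to map autosomal
barring (regular black/white feather striping) in chicken to the distal end
of chromosome 11.

`poolcross` is aimed at geneticists analysing experimental crosses with
pooled whole-genome resequencing. It provides, as tested reusable functions:

* **Pool F<sub>ST</sub> scan** — per-variant
  F<sub>ST</sub> = (π<sub>between</sub> − π<sub>within</sub>)/π<sub>between</sub>
  from pool allele-read fractions, averaged in 30 kb windows, Z-transformed
  genome-wide, Bonferroni-called in the upper tail
  (`variant_fst()`, `window_scan()`, `zscore_windows()`, `fst_scan()`).
* **Pooled-heterozygosity scan** — per window
  H<sub>p</sub> = 2·ΣnMAJ·ΣnMIN/(ΣnMAJ + ΣnMIN)² from major/minor read
  counts summed across breed pools, with the lower-tail Z transform and the
  conventional fixed cutoff Z<sub>Hp</sub> ≤ −4.70 for candidate
  identical-by-descent regions (`hp_windows()`, `hp_scan()`).
* **Marker selection and the non-recombining interval** — the
  genotyping-panel filters (alt fraction 0.4–0.6 vs < 0.2, ≥ 20 reads,
  189–322 kb spacing, or an F<sub>ST</sub> > 0.35 mode), the
  HOM_WT/HET/HOM_FAY genotype matrix, and the maximal zero-recombination
  marker run around a perfectly associated anchor
  (`select_markers()`, `build_genotype_matrix()`,
  `find_nonrecombining_interval()`, `classify_pool_state()`).
* **Cohort statistics** — Pearson segregation chi-square against an
  expected ratio, phenotype × genotype association tables, the exact
  two-point backcross LOD (LOD = R·log₁₀(r̂/0.5) + (N−R)·log₁₀((1−r̂)/0.5),
  r̂ = R/N), and the double-heterozygote expectation (1−r)/2
  (`segregation_chisq()`, `association_table()`, `two_point_lod()`,
  `double_het_expectation()`).
* **Expression follow-up** — ΔΔCt relative expression with two housekeeping
  genes (fold = 2<sup>−ΔΔCt</sup>), Student's t group comparison, and the
  pyrosequencing allelic-imbalance test of cDNA heterozygotes against the
  genomic-DNA 50:50 control (`relative_expression()`, `group_compare()`,
  `allelic_imbalance()`).
* **A seeded backcross simulator** — 2 sires × 5 dams, 12 F1 dams, 365
  backcross progeny, Haldane recombination with an optional cold region,
  transmission-ratio distortion, a conditional phenotype model with the
  observed structural zeros, pooled binomial read sampling at 45× and
  breed pools of five at 10× with an optional shared IBD segment
  (`simulate_cross()`, `simulate_pool_reads()`, `simulate_breed_pools()`).

Counts tables are plain tibbles (`chrom`, `pos`, `ref`, `alt`,
`<pool>_ref`, `<pool>_alt`) readable/writable as TSV or as VCF with
per-pool AD fields (`read_pool_counts()`, `write_pool_vcf()`).

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → F<sub>ST</sub> scan → H<sub>p</sub> scan → markers/interval →
segregation/LOD → expression), writing tables under `results/`. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fst_scan.R
```

prints, for the default study configuration (seed 17):

```
<pedigree> 86773 markers; BC=365, F1=12, P=8; seed 17
phenotype margins: AB=116, RB=40, UNCLEAR=28, WT=181
7230 windows scanned; 146 Bonferroni-significant, all on: chr11
significant span: 13920000-19920000 (causal locus at chr11:18840646)
top window chr11:19440000-19470000, mean Fst 0.552, z = 6.97
```

i.e. the scan maps the planted causal locus (chr11:18,840,646) into a block
of significant windows on distal chromosome 11 with no false signal on the
197 Mb background chromosome; single-window resolution is limited by the
recombination plateau around a fully penetrant locus (see the vignette).
The remaining scripts localize the non-recombining interval
(`chr11:18,840,646–19,930,000` across 365 meioses in the run above), test
segregation distortion — the observed cohort's 206 vs 159 carriers gives
χ² = 6.05, df = 1, p = 0.014 against 1:1 — and recover programmed expression
effects, e.g.:

```
MC1R: fold change 2.5 ± 0.3 (mean ± SEM vs non_barred), p = 1.9e-06, Student's t test
MC1R: founder-allele expression 42.5 ± 0.59% (cDNA hets, mean ± SEM), cDNA vs gDNA p = 2.1e-10
```

A quick interactive taste:

```r
library(poolcross)
segregation_chisq(c(206, 159))
#> Segregation chi-square: X2 = 6.05, df = 1, p = 0.0139
100 * double_het_expectation(c(0, 0.5))
#> [1] 50 25
```

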