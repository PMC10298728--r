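# tetragp

Genomic prediction and inbreeding analysis for autotetraploid crops.

Potato (*Solanum tuberosum* L.) is a self-compatible, highly heterozygous
tetrasomic polyploid (2n = 4x = 48). Selfing a cultivar exposes its
deleterious-mutation load as inbreeding depression, while crossing two
cultivars produces heterogeneous F1 families whose best members may beat
the best parent. Breeding programs that want to exploit either route need
(a) field designs that can score hundreds of unreplicated offspring against
replicated parental checks, and (b) genomic prediction of breeding values
(GEBVs) from SNP allele dosage so poor offspring can be discarded before
field testing. `tetragp` implements that full analysis chain, together with
a tetrasomic-inheritance simulator that makes every stage testable without
proprietary field data.

## What is inside

* **Tetrasomic simulation with IBD tracking.** Founders are simulated at
  unlinked biallelic SNPs with dosage 0–4 (nulliplex … quadriplex). A gamete
  carries 2 of the parent's 4 allele copies (all C(4,2) = 6 pairs
  equiprobable); with probability `alpha` a gamete instead carries two
  copies of one parental allele (double reduction, off by default). Every
  allele copy has a founder label, so realized inbreeding F — the
  probability two allele copies within an individual are identical by
  descent — is read off directly. One selfing of a non-inbred parent gives
  E(F) = 1/6.
* **Augmented-design adjustment.** Replicated checks in each incomplete
  block give per-block correction factors
  `CF_j = (block check mean) − (grand check mean)`, subtracted from every
  plot (`Y′ = Y − CF`). A checks-by-blocks ANOVA supplies the error mean
  square on `(c − 1)(r − 1)` df, the design-validity rule
  `r > 10/(c − 1) + 1`, LSDs for the classical comparison cases, and the
  three generation contrasts: S0 vs S1 (inbreeding depression), S0 vs F1
  (average heterosis), S1 vs F1.
* **Tetraploid GRM.** `G = W Wᵀ / Σ 4 p (1 − p)` with `w = dosage − 4p`
  (the full-autotetraploid VanRaden scaling; expected diagonal `1 + 3F`),
  plus a pseudodiploid contrast method and optional PSD repair.
* **GBLUP.** `y = μ1 + u + e`, `u ~ N(0, σg²G)`, fitted by exact spectral
  REML (profile likelihood over λ = σg²/σe², golden-section refined) and by
  a conjugate Gibbs sampler (scaled-inverse-χ² variance priors, default run
  15,000 burn-in + 15,000 samples). GEBVs for unphenotyped individuals via
  `G_test,train (G_train,train + (σe²/σg²) I)⁻¹ (y_train − μ̂)`.
* **Cross-validation.** 50 random 70/30 partitions with Pearson accuracy,
  and a family-structured scheme matrix (training family × testing family)
  with pedigree relatedness classes (full-sib / half-sib / unrelated).
* **Pipeline.** `run_pipeline()` drives simulate → adjust → grm → fit →
  cv → report with file-based handoff, a resolved config copy and an MD5
  manifest.

## Worked example

Simulate a study shaped like a northern-latitude potato trial — 4 founder
cultivars, one selfed (S1) family each, two half-sib F1 families sharing a
common female parent, 9 incomplete blocks with the founders as replicated
checks — then adjust, test the generation contrasts, and run genomic
prediction:

```r
library(tetragp)

study <- simulate_study(study_config(
  n_founders = 4, n_loci = 500, n_blocks = 9, test_plots_per_block = 20,
  s1_family_size = 25, f1_family_size = 40, maf_min = 0.05, seed = 2024
))

aa  <- anova_augmented(study$trial, "weight_total")
adj <- adjust_phenotypes(study$trial, "weight_total")
generation_contrasts(adj, study$pedigree, aa)
#> # A tibble: 3 × 6
#>   contrast estimate    se    df statistic  p.value
#>   <chr>       <dbl> <dbl> <dbl>     <dbl>    <dbl>
#> 1 S0 vs S1    1986.  42.3    24     47.0  3.93e-25
#> 2 S0 vs F1    -103.  43.7    24     -2.37 2.64e- 2
#> 3 S1 vs F1   -2089.  32.6    24    -64.0  2.45e-28
#> proportional inbreeding depression (S1 vs S0): 0.755
```

The S1 families sit about 2 kg/plot below their parents (about three
quarters of the parental mean lost — the simulator's default inbreeding
penalty for total tuber weight), the F1s are slightly below the parents
(no average heterosis), and S1 vs F1 strongly favours the hybrids.

```r
grm   <- build_grm(impute_missing(study$dosage), maf_min = 0.01, repair = TRUE)
tests <- dplyr::rename(dplyr::filter(adj, !is_check), id = entry)

fit_gblup(tests, grm, trait = "adjusted")
#> GBLUP fit (reml) for trait 'adjusted', n = 180
#>   mu = 1570, sigma2_g = 3.251e+05, sigma2_e = 8.097e+05, h2 = 0.287

random_cv(tests, grm, n_reps = 10, seed = 1)
#> Cross-validation (reml, trait 'adjusted'): mean accuracy 0.470
#>   (sd 0.087, 10/10 valid reps)

am <- scheme_cv(tests, grm, study$pedigree, within_reps = 5, seed = 1)
head(tidy(am), 3)
#> # A tibble: 3 × 7
#>   training testing trait    accuracy relatedness n_train n_test
#>   <chr>    <chr>   <chr>       <dbl> <chr>         <dbl>  <dbl>
#> 1 S1_S0_1  S1_S0_1 adjusted  -0.398  full_sib         17      8
#> 2 S1_S0_1  S1_S0_2 adjusted  -0.164  unrelated        25     25
#> 3 S1_S0_1  S1_S0_3 adjusted  -0.0682 unrelated        25     25
```

The 36-cell accuracy matrix (6 families × 6 families, per trait) is the
package's analogue of a training/testing-set accuracy table; `autoplot(am)`
draws it as a tile map and `write_accuracy_tsv()` round-trips it as long
TSV. Plot-level accuracies of individual family cells are noisy at these
family sizes — negative cells are expected, which is exactly why the
relatedness classes and replicate averages matter.

## Documentation

The methods vignette (`vignettes/tetragp-methods.Rmd`) describes the
generative model, the adjustment and GRM algebra, the REML and Gibbs
machinery, the numerical choices, and what the simulator does and does not
emulate about real field data.
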