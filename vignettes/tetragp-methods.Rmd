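---
title: "Models and methods behind tetragp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tetragp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tetragp` analyses inbreeding depression and genomic prediction in
autotetraploid breeding populations, and ships a tetrasomic-inheritance
simulator so that the whole chain — field-trial adjustment, relationship
matrices, GBLUP, cross-validation — can be exercised and validated without
access to any particular program's field data. This vignette records the
models, the defaults and why they were chosen, the numerical decisions, and
the limits of what the simulator can show.

## 1. The tetrasomic generative model

### Founders

Each founder is simulated at `n_loci` unlinked biallelic SNPs. A locus gets
a true allele-1 frequency drawn uniformly on `[maf_min, 1 - maf_min]`
(default `maf_min = 0.01`, matching a panel filtered to minor-allele
frequency of at least 1%), and the founder's four allele copies are
independent Bernoulli draws at that frequency. This is Hardy–Weinberg-like
independence across copies; no linkage disequilibrium and no linkage map
are simulated (see §7). Loci monomorphic across the sampled founders are
redrawn so every locus segregates; the *realized* sample MAF can still fall
below `maf_min` because founders are a finite sample.

Every allele copy carries a globally unique integer label. Labels are the
simulator's book-keeping for identity by descent (IBD): two copies at the
same locus with equal labels descend from the same founder allele copy.

### Gametes and double reduction

A tetrasomic gamete receives, per locus independently:

* with probability `1 - alpha`: two of the parent's four copies sampled
  without replacement, all six unordered pairs equiprobable — random
  bivalent segregation;
* with probability `alpha`: two copies of a single uniformly chosen
  parental copy — double reduction.

`alpha = 0` is the default, i.e. double reduction off; the parameter exists
because it is the one well-known tetrasomic anomaly whose consequences are
exactly enumerable, which makes it ideal for property tests
(`gamete_dosage_distribution()` is the closed-form enumeration). Under this
rule the classical identities hold and are asserted in the test suite:
selfed offspring of a non-inbred parent have expected realized inbreeding
`F = (1 + 2 alpha) / 6` (so 1/6 at `alpha = 0`), parent–selfed-offspring
co-ancestry is 1/4, and parent–outcross-offspring co-ancestry is 1/8.

### Traits and inbreeding depression

A plot phenotype is

```
intercept + block effect + sum_j(dosage_j * effect_j)
          - id_coefficient * F_ibd + Normal(0, residual_sd^2)
```

where `F_ibd` is the individual's realized IBD homozygosity fraction (the
proportion of the six within-individual allele pairs per locus sharing a
founder label, averaged over loci). The linear penalty on realized
homozygosity is a directional-dominance proxy: the field phenomenon —
performance falling with inbreeding after selfing — is well established,
but no generative model for it is standard, so the simplest directional
form was chosen and exposed as one coefficient per trait.
`default_trait_models()` provides ten tuber traits (total weight and five
grading sizes in grams per 4-plant plot, two 1–9 uniformity scores, eye
depth, reducing sugar). The weight-trait penalties are calibrated so one
selfing (F = 1/6) costs on the order of three quarters of the total plot
weight — the magnitude a high-latitude potato trial can show — while score
traits lose a few tenths of a point. Because additive effects are drawn
randomly per study, the realized proportional loss varies a few tenths
around that target from seed to seed; it is a qualitative emulation, not a
fitted quantity.

### Study design

`simulate_study()` builds 4 founders, one S1 family per founder, and two F1
families sharing the first founder as common female parent (so the two F1s
are half-sibs of each other and of three of the S1 families). The field
layout is an augmented design: every founder appears as a replicated check
once per incomplete block; each S1/F1 entry occupies exactly one plot of
one block, assigned at random. Defaults are 9 blocks of 100 test plots and
families of 150 (4 × 150 + 2 × 150 = 900 = 9 × 100), echoing the scale of
a single-site program trial; tests and the demo pipeline scale these down.

## 2. Augmented-design analysis

The correction factor of block *j* uses only the replicated checks:
`CF_j = mean(checks in block j) - grand check mean`, equivalently
`(1/g) [sum_i Y_ij - (sum_ij Y_ij) / r]` with `g` checks per block and `r`
blocks. `Y'_ij = Y_ij - CF_j` is applied to every plot; adjusted check
values are averaged over blocks. Two identities are asserted in the tests:
`sum_j CF_j = 0`, and a constant `k` added to every plot of one block is
absorbed up to the common offset `k / r` that every entry shares (the grand
check mean moves), so all comparisons among adjusted values are invariant.

The experimental error comes from the checks-by-blocks two-way ANOVA: the
interaction mean square on `(g - 1)(r - 1)` df. The design-validity rule
`r > 10 / (c - 1) + 1` (error df above 10) is exposed as
`validate_design()`. LSDs are reported for the four classical comparison
cases (two checks; two tests, same block; two tests, different blocks; test
vs check), with the different-blocks case as headline.

Generation contrasts (S0 vs S1 for inbreeding depression, S0 vs F1 for
average heterosis, S1 vs F1) are differences of adjusted group means,
tested against the check-derived error MS on the check df. Each
unreplicated test entry contributes variance `MSE`; a check entry — a mean
over `r` blocks — contributes `MSE / r`. Covariances induced by the shared
block correction are ignored; they cancel exactly for test groups balanced
over blocks, and a 200-replicate null simulation in the test suite shows
type-I error within the nominal band for all three contrasts. Proportional
inbreeding depression is reported as `1 - mean(S1) / mean(S0)` on group
means, plus per-family mid-parent and best-parent heterosis and the
fraction of F1 entries above the best parent. Which S1 families enter the
contrast is configurable (`s1_families`), since a program may exclude a
family whose parent could not be scored; default is all.

## 3. The tetraploid relationship matrix

`full_tetraploid` (default): centred scores `w_ij = dosage_ij - 4 p_j`,
`G = W W' / sum_j 4 p_j (1 - p_j)`. Under tetrasomic segregation
`Var(dosage) = 4pq(1 + 3F)`, so the expected diagonal is `1 + 3F` — 1.0 for
non-inbred individuals, 1.5 after one selfing — and an off-diagonal entry
estimates four times the co-ancestry (parent–selfed-offspring 1.0,
parent–outcross-offspring 0.5). `pseudodiploid` halves dosages onto the
0–2 scale and applies the diploid VanRaden form (`denominator
sum 2 p (1 - p)`); it is retained as the contrast method.

Frequencies default to the sample estimate `mean(dosage)/4`; in simulation
studies the true generating frequencies can be passed (`freq`), avoiding
the small-sample centring bias that sample frequencies introduce when only
a handful of founders and their families are genotyped. The MAF filter
(default 0.01) is applied on whichever frequencies are used. `repair =
TRUE` clamps negative eigenvalues at zero and blends
`G* = 0.99 G + 0.01 I`; it is off by default and recorded in the object,
because repairing changes entries slightly and should be a visible choice.
Missing dosages must be imputed first (`impute_missing()`, locus mean) —
standard GBLUP practice.

## 4. GBLUP: REML and Gibbs

The model is `y = mu 1 + u + e`, `u ~ N(0, sigma2_g G)`,
`e ~ N(0, sigma2_e I)`.

**REML.** `G` is eigendecomposed once; in the spectral basis the restricted
profile log-likelihood of `lambda = sigma2_g / sigma2_e` is a cheap
one-dimensional function. It is evaluated on a 121-point log grid spanning
`[1e-4, 1e4]` and the bracketing interval is refined by golden-section
search to a relative tolerance of 1e-8. A maximum at the grid edge (a
variance component effectively zero or the ratio unbounded) is flagged
`boundary = TRUE` rather than hidden. The intercept is the GLS estimate and
BLUPs are `u = lambda G (lambda G + I)^{-1} (y - mu)`. The implementation
is cross-checked in the tests against a dense-algebra grid search that uses
determinants and solves instead of the spectral path, and against the ridge
closed form when `G = I`.

**Gibbs.** The sampler works in the same spectral basis, where the genetic
effects have independent normal full conditionals; the intercept is normal
and both variances are scaled-inverse-chi-square (conjugate throughout).
Default priors: df 5 for each variance, scales set to half the sample
variance of `y` — an even prior split of total variance, weakly
informative. Default run length is 15,000 burn-in + 15,000 kept samples, a
conservative production setting; the tests use 500 + 1,500 and check the
posterior-mean GEBVs against the closed-form BLUP evaluated at the
posterior-mean variances (RMS below 0.05 on unit-variance phenotypes).
Chains are seed-reproducible; non-finite variance draws abort with
diagnostics rather than propagating.

**Prediction.** Unphenotyped individuals get
`u_test = G_test,train (G_train,train + (sigma2_e/sigma2_g) I)^{-1}
(y_train - mu)`; the masked-phenotype joint mixed-model route is also
implemented and the two are asserted to agree to 1e-8. The response
throughout the pipeline is the block-adjusted phenotype `Y'`, because the
augmented design leaves test entries unreplicated and the raw values carry
block effects that would otherwise be absorbed into GEBVs.

## 5. Cross-validation

`random_cv()` follows the standard protocol: 50 random partitions (default),
70% training, Pearson correlation between observed and predicted phenotypes
in the held-out 30%. Replicates whose test set has no variance are recorded
missing with a warning — never dropped silently.

`scheme_cv()` builds the family-structured accuracy matrix. Diagonal cells
(a family predicting itself) run `random_cv()` within the family;
off-diagonal cells are single fits training on the whole of family A and
predicting the whole of family B, matching the fixed train/test identities
of a published scheme table. Each cell carries a pedigree relatedness class
(full-sib on the diagonal; half-sib when the two families share a parent;
unrelated otherwise).

Two facts about this matrix, learned from the simulator and worth keeping
in mind when reading real-data analogues: (i) with families of a few dozen,
individual cells are extremely noisy and negative accuracies are common;
(ii) when the trait is generated from the same markers used in `G`, even
"unrelated" families share genuine marker-based covariance, so the
half-sib-over-unrelated advantage is a modest average effect, not a
cell-by-cell guarantee. The acceptance study therefore compares half-sib vs
unrelated *means* over dozens of replicate simulations (families of 60,
`h2 = 0.9`, 400 loci — sizes chosen so the ordering has statistical power
at a runtime of seconds per replicate).

## 6. Numerical and design choices

* Dosage validation is total: any out-of-range or non-integer cell aborts a
  read with the individual and SNP named; nothing partially loads.
* VCF input is v4.2, single ALT per record, unphased tetraploid GT
  (order-insensitive ALT count); a `DS` field overrides GT when present;
  GT ploidy other than 4 is an error, as are multi-allelic records.
* Eigenvalues below `1e-10 * max` are treated as null space in the Gibbs
  sampler; REML clamps tiny negatives at zero but refuses matrices with
  materially negative eigenvalues, pointing at `repair = TRUE`.
* The effective sample size reported for MCMC traces uses the initial
  positive autocorrelation sequence.
* `run_pipeline()` enforces file-based handoff so every stage is
  independently inspectable; unknown config keys are rejected, and a
  manifest (package version, seed, MD5 per artifact) makes reruns
  checkable byte-for-byte.
* Test and acceptance problem sizes (e.g. heritability recovery with 12–20
  replicates at n = 300 and 1,000 loci; 30–40 replicate simulations for the
  relatedness comparison; Gibbs checks at 500 + 1,500 iterations) were
  chosen so the whole suite runs in about a minute while leaving the
  statistical bands — 3 empirical standard errors, chi-square p > 0.001 —
  meaningful.

## 7. What the simulator does not emulate

* **No linkage, no LD.** Loci segregate independently; there are no
  chromosomes, no recombination map, no preferential pairing, and no mixed
  bivalent/quadrivalent configurations. Consequently marker–QTL LD decay
  across families — a major driver of real across-population prediction
  accuracy — is absent: a trait generated from loci disjoint from the
  marker panel is unpredictable across families here, whereas real genomes
  give partial transfer through linked markers.
* **Gaussian plot residuals.** Small weight classes can go slightly
  negative; score traits are continuous rather than ordinal 1–9.
* **No genotype-by-environment structure, single site, single year.**
* **No genotyping error or allele-dosage miscalls;** missingness exists
  only through the I/O layer.

Passing tests therefore demonstrate internal correctness of the algebra and
the claimed statistical behaviour under tetrasomic inheritance — not that
any particular field program will realize the same accuracies.
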