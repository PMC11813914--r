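---
title: "Methods: feed-efficiency traits, windowed GBLUP scans, and rumen community comparison"
author: "goatfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feed-efficiency traits, windowed GBLUP scans, and rumen community comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goatfe)
```

goatfe links three analyses that in feed-efficiency studies of small dairy
ruminants are usually run by separate tools: trait derivation from raw
records, a GBLUP-based genome scan that partitions additive variance into
5-SNP windows, and a two-group comparison of rumen amplicon communities.
This vignette is the package's account of the underlying models, the
choices that were genuinely open, and what the synthetic-data generator
does and does not emulate.

## Feed-efficiency traits

All traits derive from per-animal records of body weight, feed intake,
milk yield and composition, and (optionally) rumen propionate:

* metabolic weight $W^{0.75}$ (kg$^{0.75}$), the scale on which intake is
  expressed;
* dry-matter intake in kg/day, reconstructed as
  $\mathrm{DMI} = \mathrm{DMI}_{g/kg^{0.75}} \cdot W^{0.75} / 1000$ when
  only intake per metabolic weight is recorded (an explicit kg/day field
  always wins);
* 3.5 % fat-corrected milk, the Gaines-type standardization
  $\mathrm{FCM} = (0.432 + 0.1625\,\mathrm{fat\%}) \cdot \mathrm{MY}$;
* milk net energy (NRC),
  $\mathrm{NE} = \mathrm{MY}\,(0.0929\,\mathrm{fat\%} +
  0.0563\,\mathrm{protein\%} + 0.0395\,\mathrm{lactose\%})$ in Mcal/day;
* the efficiency ratios gross FE ($\mathrm{MY}/\mathrm{DMI}$), adjusted
  FE ($\mathrm{FCM}/\mathrm{DMI}$), and FE for lactation
  ($\mathrm{NE}/\mathrm{DMI}$);
* predicted enteric methane from rumen propionate (mM),
  $316/\mathrm{propionate} + 4.4$ g per kg DMI.

Milk recorded in ml/day is converted to mass at density 1.0 g/ml; the
published group values are consistent with that convention, and every
ratio is invariant to the volume unit once the density handling is fixed.
The methane curve is convex, so the mean of per-animal predictions
exceeds the prediction at the mean propionate — group summaries are
therefore always computed per animal first and averaged afterwards.
Two-group trait comparisons use Student's pooled-variance unpaired t-test
by default (the generic "unpaired t-test" of this literature); Welch's
test is available by flag. Groups with zero within-group variance are
flagged rather than given infinite statistics.

```{r traits}
rec <- data.frame(animal_id = "sh", breed = "SH", bw_kg = 40.6,
                  dmi_g_per_mbw = 110.3, milk_ml_day = 1241,
                  fat_pct = 2.62, protein_pct = 2.29, lactose_pct = 4.16,
                  propionate_mM = 13.41)
round(derive_traits(rec)[, -(1:2)], 4)
```

## Genotype quality control

`apply_qc()` applies the standard array-QC battery: SNPs at unknown or
duplicated map positions, animals with call rate below 90 %, SNPs with
call rate below 99 %, minor allele frequency at or below 0.01
(inclusive), and exact Hardy–Weinberg p-values below $10^{-6}$. The
filter **order** is fixed and documented — duplicates, then animals, then
SNP call rate, MAF, HWE — because removal counts depend on it and the
convention is otherwise ambiguous; the report reconciles exactly
(removals + survivors = input) under this order. The HWE test is the
standard conditional-enumeration exact test: given the allele counts, the
p-value sums the probabilities of all heterozygote counts at most as
probable as the observed one (no mid-p). Ties in probability mass are
resolved with a $10^{-9}$ relative tolerance so independent
implementations agree. HWE is tested across all animals by default; at
20 animals a within-breed test would have almost no resolution.
Surviving missing calls are imputed to twice the allele frequency (the
column mean dose) so that downstream algebra sees a complete matrix.

## GBLUP, EM-REML, and the window scan

The genomic relationship matrix follows VanRaden's scaling:
$Z = M - 2p$ column-centered doses, $G = ZZ^\top / (2\sum_j p_j(1-p_j))$,
blended as $(1-\varepsilon)G + \varepsilon I$ with $\varepsilon = 0.01$
for invertibility. With every phenotyped animal genotyped and no
pedigree, the single-step H-matrix reduces to this G — the case this
package implements; no H-matrix is built.

Variance components of $y = Xb + a + e$, $a \sim N(0, G\sigma^2_a)$, are
estimated by EM-REML. The model is rotated into the eigenbasis of $G$
once, making each EM update O(n); the restricted likelihood is tracked
and is non-decreasing per iteration (asserted in the tests). EM's
well-known slow crawl near the $\sigma^2_a = 0$ boundary means
non-convergence warnings are common on null-ish data; the fit is
returned with `converged = FALSE` rather than hidden. Components may
also be supplied directly to `solve_gblup()`, which solves Henderson's
mixed-model equations and verifies the solution residual is below
$10^{-8}$.

Fixed effects default to an overall mean; `~breed` is supported and is
the model the package's own validation experiments use, because the
generator plants a genuine between-breed shift: left unmodeled, that
contrast leaks through the back-solve and can outrank a modest QTL
window. For a two-group design this is the model a practitioner should
fit.

SNP effects are recovered from GEBVs by the standard back-solve
$\hat u = D Z^\top (Z D Z^\top)^{-1} \hat a_g$ with $D = I$ by default
(a hook accepts user weights). Because the columns of $Z$ are centered,
$ZZ^\top$ is always singular in the direction of ones; a Moore–Penrose
pseudo-inverse is used with a warning, and with an intercept (or breed)
in the model the GEBVs are orthogonal to that null direction, so
$Z\hat u = \hat a_g$ still holds to machine precision. The back-solve is
algebraically identical to SNP-BLUP/ridge with matched shrinkage, which
the tests verify against an independent ridge solver.

Per-SNP variance is $\hat u^2\, 2p(1-p)$. The window statistic for 5
adjacent SNPs is the **empirical variance across animals** of the window
genomic value $a_w = Z_{\cdot w}\hat u_w$, expressed as
$100 \cdot \mathrm{Var}(a_w)/\sigma^2_a$; the within-window sum of
per-SNP variances is also reported but does not define significance.
Windows slide by one SNP by default (`scheme = "distinct"` gives
non-overlapping windows); trailing SNPs that cannot fill a window are
dropped and short chromosomes are skipped with a warning. Windows above
0.1 % of total genetic variance are flagged. The Manhattan table plots
the variance percentage itself — the scan statistic has no p-value, and
none is invented.

## Community analysis

Alpha diversity (observed richness, Chao1, Shannon in natural log,
inverse Simpson), Bray–Curtis dissimilarity
$\sum|x-y| / \sum(x+y)$ on per-sample proportions, and classical PCoA
(Gower double-centering, eigendecomposition, coordinates scaled by root
eigenvalues) are implemented from first principles — they are part of
the package's contract — and cross-checked in the tests against vegan
and `cmdscale`. Chao1 uses the bias-corrected form
$S + F_1(F_1-1)/(2(F_2+1))$, defined even without doubletons; the
classic form is available by flag. With no singletons Chao1 equals
observed richness, the signature of deeply sequenced, denoised ASV
tables. Negative PCoA eigenvalues (Bray–Curtis is non-Euclidean) are
reported, not corrected, and proportions explained are relative to the
positive spectrum. Taxon comparisons aggregate counts to a requested
rank as percentages (taxa unresolved at that rank fall into a
`*_unclass` bucket), run unpaired t-tests (untransformed by default;
arcsine-square-root and log transforms by flag, since the field is split
on this), and control FDR by Benjamini–Hochberg.

## The synthetic-data generator

The generator exists so the full chain is testable offline, and its
defaults are the study conditions: two breeds of 10 goats, phenotypes
drawn around the published group means and standard errors (body weight
40.6/25.3 kg, DMI 110.3/136.1 g/kg$^{0.75}$, milk 1241/1428 ml/day,
propionate 13.4/17.5 mM for the two groups), a marker panel scaled down
from ~60K to a configurable desk-scale size, and ASV tables whose effect
taxa shift by stated log2 fold changes.

Design choices, made once:

* **LD** is a first-order Markov chain on haplotypes, realized by
  thresholding a latent AR(1) Gaussian at the drawn allele frequency;
  the study provides no LD information, and a single adjacent-dependence
  parameter is the simplest structure the scan can exercise.
* **QTL placement**: whole 5-SNP windows carry N(0, `qtl_effect_sd`²)
  effects so window recovery is well-posed. Residual variance is scaled
  to the *realized* genetic variance so the target h² is hit exactly in
  expectation. The published work reports no variance components, so the
  default `h2_target = 0.3` is a conventional moderate value and is
  config-exposed; the package's window-recovery experiment plants a
  single window at `h2_target = 0.6` as its "large-effect" case.
* **Breed effects** enter the focal trait additively
  (`breed_effect`, default 185 ml/day — the published between-group milk
  difference) on top of group-specific means; daily milk yield carries
  the same breeding values so derived efficiency traits inherit the
  architecture.
* **ASV tables** are Dirichlet-multinomial: a lognormal rank-abundance
  base composition, per-sample Dirichlet draws at concentration 50
  (strong overdispersion, typical of rumen data), Poisson library sizes.
  Fold changes are applied to the base composition and renormalized, so
  a planted 4-fold taxon realizes slightly less than 4-fold after
  closure — the tests check against the generator's own definition.
* **Missingness** is off by default (the study reports thresholds, not
  rates) and injectable to exercise QC.
* Each generator seeds its own substream derived from the single config
  seed (`seed`, `seed + 1`, `seed + 2`, `seed + 3` for genotypes,
  phenotypes, ASV tables, and gene intervals), so outputs are
  reproducible regardless of call order; draw order within each stream
  is documented in the function help.

What the generator does **not** emulate: coalescent-realistic LD decay,
population structure within breed, pedigree, selection, genotyping
error, compositional interactions between taxa, or any phenotype-
microbiome coupling. Passing tests therefore demonstrate that the
estimators recover what this generative model plants — not that the
pipeline would have equal power against real goat data, where LD
structure and polygenicity differ.

## Numerical choices and problem sizes

Tolerances: GRM symmetry within 1e-10; MME residual below 1e-8; EM-REML
stops on a 1e-6 relative change of both components (cap 1000
iterations); HWE tie tolerance 1e-9 relative; PCoA treats eigenvalues
below `max(eig) * 1e-12` as zero. Degenerate inputs error loudly:
all-monomorphic panels (zero GRM scale), zero DMI, non-positive
propionate, all-zero ASV samples, QC that removes every SNP.

The validation experiments use desk-scale sizes chosen to make each
statistical claim testable with comfortable Monte-Carlo margins:
heritability recovery at n = 200 animals, m = 1,000 markers over 50
replicates; window recovery at n = 100, m = 1,000 over 20 replicates;
HWE against brute-force enumeration for every genotype configuration up
to n = 50; FDR calibration over 500 null community simulations. One
finding worth recording: with n = 200 unrelated animals and 1,000
near-independent markers the GRM is nearly isotropic and null
heritability estimates are heavy-tailed; the null-recovery check uses
m = 100 markers, where realized-relationship contrast identifies h²
sharply. Equally, REML at the study's own n = 20 is volatile — the
pipeline reports those fits with convergence flags rather than
pretending stability.

## Known limitations

* Only single-trait, single-record models; no pedigree (A or H) matrix.
* The window scan reports variance shares, not p-values; thresholding at
  0.1 % is a convention, not a test.
* The exact HWE implementation enumerates per SNP; it is meant for
  array-scale panels, not sequence data.
* Gene annotation is any-overlap interval assignment; no LD-aware window
  merging or enrichment analysis.
* At n = 20 the sliding-window count (and hence which windows cross
  0.1 %) depends on the `sliding`/`distinct` choice; both schemes are
  emitted in the table metadata so results are always labeled.
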