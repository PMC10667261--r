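---
title: "From plasma proteome to causal candidates: methods and design"
author: "proteoMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plasma proteome to causal candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoMR)
```

## The scientific problem

Circulating proteins are attractive breast-cancer biomarkers and drug-target
candidates, but observational protein-disease associations are confounded by
lifestyle, adiposity and reverse causation. Mendelian randomisation (MR)
sidesteps this by using genetic variants that regulate a protein's plasma
level — cis protein quantitative trait loci (cis-pQTL) — as instrumental
variables: because alleles are fixed at conception, an association between a
protein-raising allele and disease risk supports a causal role for the
protein itself, under the usual instrumental-variable assumptions (the
variant affects disease only through the protein, and shares no confounder
with it).

`proteoMR` implements the full analysis chain for affinity-proteomics (NPX)
data: quality control against the limit of detection (LOD), per-protein
association with clinical characteristics, cis-window pQTL discovery with a
multiple-testing correction based on the number of *independent* variants
per region, instrument selection by LD clumping, two-sample MR against
case-control GWAS summary statistics with a discovery/replication design,
and regional "mirror-plot" concordance diagnostics that guard against an
MR hit being driven by a distinct causal variant in linkage disequilibrium
(LD) with the pQTL.

## The statistical core

**Cis-pQTL scan.** For each protein, variants within 1 Mbp of the encoding
gene (1-based inclusive window, clipped at position 1) are tested with an
additive OLS model of NPX on dosage, adjusted for age, BMI and 10 genetic
principal components. The implementation residualises both NPX and dosage
on the covariates (Frisch–Waugh), which is algebraically identical to the
joint model and vectorises over variants. NPX is z-scaled per protein by
default so betas are in SD units per effect-allele copy; values below LOD
are retained in the regression. Variants with minor allele frequency below
0.01 are removed first.

**Independent-variant correction.** The test burden per region is the
number of variants that survive greedy pruning at pairwise \(r^2 < 0.1\),
iterated in *position* order — deliberately independent of any association
result, since the count defines the threshold. The global significance
threshold is \(\alpha / \bar{k}\) with \(\bar{k}\) the mean independent
count across regions (0.05/180 = 2.77e-4 in the motivating study's setting);
a per-region mode is available behind a flag. Greedy \(r^2<0.1\) pruning
somewhat undercounts effectively independent tests in strongly
autocorrelated regions, so the derived threshold is mildly anticonservative
per region; the fixed-threshold mode reproduces the conventional behaviour
and is what the calibration tests assert.

**Hit selection and instruments.** Significant variants are clumped
greedily by ascending p (ties broken by lower SE, then position), discarding
anything at \(r^2 \ge 0.1\) with a kept variant; the same rule at
\(r^2 < 0.001\) collapses each protein's hits into approximately independent
instruments.

**Harmonisation.** Instruments are matched to the outcome by chromosome,
position and the unordered allele pair (id as fallback). Swapped alleles
negate the outcome beta and complement its frequency. Palindromic (A/T,
C/G) variants cannot be strand-resolved from alleles alone: they are
EAF-aligned when both frequencies fall on the same side of a 0.42 band,
flipped when on opposite sides, and dropped otherwise — the common
two-sample MR practice; the band is configurable.

**Estimation.** With one instrument the Wald ratio is used:
\(\hat\beta = \beta_{out}/\beta_{exp}\),
\(\mathrm{se} = \mathrm{se}_{out}/|\beta_{exp}|\), z from their ratio and a
two-sided standard-normal p. (The absolute value keeps the SE positive for
negative exposure betas without changing \(|z|\).) With several
instruments, the fixed-effect inverse-variance-weighted (IVW) combination
of per-instrument ratios is reported; a singleton reduces exactly to the
Wald ratio. This first-order SE ignores exposure-side uncertainty, so it
understates uncertainty for weak instruments — calibration properties are
therefore asserted at \(h^2_{cis} \ge 0.05\) and outcome samples of at
least 20k, where the approximation is good. Cochran's Q is attached as a
diagnostic only. Discovery significance uses 7.5e-5 (adopted as given — its
denominator is not derivable from the stated test count); replication of
discovery hits against an independent outcome requires nominal p < 0.05
*and* a concordant effect direction.

**Concordance verdicts.** The motivating analysis inspected mirror plots
visually. `leadConcordance()` is an explicit quantitative stand-in, labelled
as such: `concordant_lead` when the exposure and outcome lead variants
coincide or have \(r^2 \ge 0.8\), `same_limited_region` at
\(r^2 \ge 0.1\), `discordant` otherwise. The tiers are configurable and
reported with every verdict; they are not claimed to reproduce anyone's
visual judgement.

## What the generator emulates — and what it does not

The synthetic-data module exists so that every downstream stage is testable
without any external download, and its defaults define the study conditions
used throughout the tests.

*LD model.* A latent Gaussian AR(1) process (correlation `ldRho = 0.9`
between adjacent variants) is thresholded at the MAF quantile to give one
haplotype; two independent haplotypes sum to the dosage. This Gaussian
copula yields tunable, geometrically decaying \(r^2\) — sufficient for
pruning/clumping correctness — but not the block structure, allele-frequency
spectrum or long-range LD of real human genomes. Variant MAFs are uniform
on `mafRange = (0.05, 0.5)`.

*NPX model.* Per protein, NPX = lead-variant effect + covariate effects +
Gaussian noise, scaled to unit total variance with the lead variant
explaining `cisH2` of it. The default `cisH2 = 0.2` represents the strong
cis effects that dominate detected pQTL at a few hundred samples; the
motivating study does not report its cis variance explained, so recovery
experiments span 0.1–0.2. The per-assay LOD is placed at the
`lodQuantile` (default 0.25) of the simulated values; below-LOD values are
flagged but retained. Allele pairs are drawn non-complementary by default
(a strand-resolved simulation); `palindromeFraction` injects A/T-C/G pairs
when harmonisation stress-testing is wanted.

*Outcome model.* Case-control status is simulated at the individual level —
a logistic model on the causal protein's liability (`theta` log-odds per
NPX SD; default 0.4 under the causal scenario), on a direct variant effect
in LD (\(r^2 \approx 0.3\)) with the lead pQTL in the `ld_confounded`
scenario, or on the intercept alone under the null — and then reduced to
per-variant summary statistics with a vectorised one-step logistic score
test (beta = score/information), the approximation large-scale GWAS
software effectively computes; exact per-variant logistic regression is
available and cross-checked in the tests. Simulating individuals rather
than fabricating summary statistics preserves the realistic coupling
between effect sizes, standard errors and allele frequencies. Default
outcome studies have 10,000 cases and 10,000 controls; each exposure cohort
has 598 samples, the size of the motivating cohort.

*Seeds.* A single master seed; every stage, outcome draw and protein uses a
sub-stream derived by stable hashing of (stage, which-study, index), so the
whole study is a pure function of the configuration and discovery and
replication are independent draws.

Passing tests on these simulations demonstrate the statistical machinery —
calibration, recovery, selection, harmonisation, funnel logic — not
robustness to real-data pathologies (batch effects, population structure,
relatedness, imputation error, assay cross-reactivity), which are out of
scope.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `minDetect` | 0.25 | detectability needed to keep an assay (strict >) |
| `window` | 1e6 | cis flank in bp on each side of the gene |
| `mafMin` | 0.01 | minor-allele-frequency filter before testing |
| `r2Independent` | 0.1 | pruning/clumping threshold for counting and hits |
| `r2Clump` | 0.001 | instrument-selection clumping threshold |
| `alphaMR` | 7.5e-5 | MR discovery threshold |
| `alphaRep` | 0.05 | nominal replication threshold (plus sign agreement) |
| `palindromeEafBand` | 0.42 | EAF ambiguity band for palindromic variants |
| `zCut` | 5 | PCA outlier exclusion, SD units on leading components |

The detectability rule is strict (`> minDetect`): keeping assays with more
than 25% of values above LOD is the only reading consistent with filtering
those with at least 75% below it. The PCA criterion (±5 SD on the first two
components) is a documented stand-in — the motivating QC names PCA but no
numeric rule — chosen conservatively so that homogeneous data yield no
exclusions.

## Numerical choices and degenerate inputs

- OLS uses QR decompositions; rank-deficient clinical designs abort with
  the collinear terms named. A constant NPX vector is flagged degenerate
  (betas 0, p `NA`) rather than reported as significant.
- Benjamini–Hochberg is implemented step-up with an explicit family size
  `m`; the clinical module corrects its 8 per-protein terms against
  `m = 7 x` proteins, following the convention that the two menopause
  contrasts form one characteristic family (set `mPerProtein = 8` for the
  exact per-term count).
- Monomorphic variants: skipped with a reason in the exposure scan, omitted
  from simulated outcome summaries (as a GWAS would), and treated as
  \(r^2 = 0\) in greedy pruning so they can never block selection.
- Clumping ties in p are broken by (lower SE, then position) for exact
  determinism.
- Wald ratio with a zero exposure beta is an error (undefined ratio); a
  zero outcome beta gives estimate 0 and p = 1.

## Problem sizes used in the shipped experiments

The packaged calibration experiments run at: 1000 null replicates (5k/5k
outcome) for type-I error; 200 causal replicates (theta 0.3, cis h² 0.1,
598 exposure samples, 50k/50k outcome) for recovery; 50 end-to-end funnel
runs of 50 proteins (one causal) each; 100 LD-confounded replicates for
discordance detection; and 500/1000 random fixtures for the greedy and BH
oracle equivalences. The acceptance script uses the same experiments at
600/200/30/100 replicates. These sizes give Monte-Carlo standard errors
small enough for the stated acceptance bands (e.g. ±3 MC SE on the mean
causal estimate) while remaining desk-scale.

A note on the recovery experiment: instruments are selected in the same
exposure sample in which their effects are estimated, exactly as the
motivating design does, so the Wald denominator carries winner's-curse
inflation; at the asserted settings this deflation and the Jensen (1/x)
inflation nearly cancel, and the mean estimate stays within the Monte-Carlo
band of the generating effect. At weaker instruments or smaller outcome
studies neither approximation holds — which is why the recovery property is
bounded below in instrument strength.

## Known limitations

- Fixed-effect IVW only; no MR-Egger, weighted median, Steiger filtering or
  formal Bayesian colocalisation (all deliberately out of scope).
- The LD model has no block structure or realistic recombination map; proxy
  lookup and clumping behaviour on real panels will differ quantitatively.
- The score-test outcome summaries assume small per-variant effects; very
  large direct effects would need the exact glm path.
- Trans-pQTL, mixed-model association, relatedness and X-chromosome dosage
  are not modelled.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipelineConfig(sim = simulationConfig(nProteins = 10,
                                             scenario = "causal",
                                             seed = 1))
man <- runPipeline(cfg, "run1")
man$funnel
man$tables$replication
```
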