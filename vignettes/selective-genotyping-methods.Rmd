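---
title: "Methods: simulating selective genotyping in a sib-testing trout breeding program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating selective genotyping in a sib-testing trout breeding program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A rainbow trout breeding program keeps its selection candidates in the
nucleus (breeding) environment B while their full and half sibs are
performance-tested in the commercial environment C. Because of
genotype-by-environment interaction, the trait expressed in B and the trait
expressed in C are modelled as two genetically correlated traits (genetic
correlation $r_g$, the strength of re-ranking); the breeding goal puts all
weight on performance in C, so the C-tested sibs form the reference
population that ties the candidates' genotypes to the goal trait.
Genotyping is budgeted (1,000 fish per year at full scale) and the pedigrees
and phenotypes of non-genotyped fish are never registered, so *which* fish
enter the dataset is decided by phenotype-based screening rules — and that
choice distorts both genomic predictions and variance-component estimates.
`sibGenoSim` simulates this program forward in time so the screening rules
can be compared on the outcomes that matter: rate of genetic gain, rate of
inbreeding, prediction accuracy and dispersion bias.

# Simulation model

## Genome and trait

The genome is 29 chromosome pairs totalling 2,927.1 cM; loci are allocated
to chromosomes in near-equal numbers with uniform positions. Meiosis follows
the Haldane model: per chromosome, a Poisson(length/100) crossover count, no
interference, uniform crossover positions, random starting strand. No
mutation is applied — seven overlapping generations are too few for it to
matter.

A random subset of loci (3,742 of 36,451 at full scale) act as QTL; the rest
are evaluation markers. Each QTL carries an additive effect pair (B trait, C
trait). Raw effects are drawn as independent normals and linearly recombined
so that, in the realized founder population, each trait has genetic variance
exactly 1 and the founder TBV correlation is exactly $r_g$ — the factor
levels are therefore realized, not approximated, in every replicate. The
residual variance per environment is $(1-h^2)/h^2$ (2.333 at $h^2 = 0.3$), so
founder heritability is $h^2$ in both environments. Phenotype = TBV of the
placement environment + normal residual; simulated year effects are zero but
the evaluation model always fits year classes, so this is a modelling
convention, not a simplification of the estimator's task.

## Synthetic founders and linkage disequilibrium

The real founder panel (958 genotyped fish, imputed to 36,451 SNPs) is
proprietary, so a generator stands in for it. Allele-1 frequencies are drawn
uniformly on [0.05, 0.5]; haplotypes are initialized independently per locus
in a mixing pool of 50 individuals; 30 generations of random mating with
recombination let drift build linkage disequilibrium; one final random-mating
generation expands the pool to the founder count. The pool size and duration
emulate the long, narrow bottleneck of a closed hatchery strain and were
chosen to reproduce the short-range LD reported for dense SNP panels in
farmed trout — mean $r^2 \approx 0.2$ between loci less than 1 cM apart,
decaying to near baseline beyond ~20 cM (the genome test suite measures the
adjacent-versus-distant contrast). Loci that drift to fixation (~15%) are
redrawn independently at their original frequency; they segregate but carry
no LD, which mildly dilutes marker information. What the generator does
*not* emulate: a real site-frequency spectrum, imputation error, variable
marker density along chromosomes, and selection footprints from the strain's
own history. Passing tests therefore show that the *screening-induced*
distortions are reproduced, not that the genome is a replica of any real
panel.

## The yearly cycle

Each year (full scale in parentheses): 50 three-year-old sires and 50 dams
drawn from a 400-female pool mate in a partly factorial design — every sire
with two dams, every dam with two sires — giving 100 full-sib families of
200, i.e. 20,000 offspring. A configured share (0/20/40/60%) is placed in C
at birth, the rest in B. Fish are phenotyped, genotyped and selected at age
3; years 1–3 are seeded from founder parents. Sires (neo-males) spawn once;
females can serve two consecutive years: under 100% retention 200 new
females join and all are kept one further year, under 11% retention 360 join
and 40 are kept. At year 4 no previously selected females exist, so the
retained slots are filled at random from the same cohort's B females and
dropped the next year like 4-year-olds.

Genotyping strategies screen disjoint random groups of 20 (each fish has one
chance): `Top1_1` keeps the best of each group; `T1_1B1_1` the best and
worst; `T1_2B1_2` additionally thins tops and bottoms through random pairs;
`T3_4B1_4` keeps three of four tops and one of four bottoms; `Random`
ignores phenotypes. Ties (measure-zero) break to the lowest id for
determinism. Fish left over after forming the required groups are not
screened; a scenario whose cohort cannot supply the groups is rejected, not
silently degraded.

## Sex structure of the B budget

The group screening ties the budget to the cohort: budget × 20 equals the B
cohort size exactly, so male and female screening must tile the cohort.
When fish in B are genotyped at random, no females are genotyped (the whole
B budget goes to males) and females are selected phenotypically — best of
each random group of 20 by B phenotype. With group-based strategies that is
arithmetically impossible, so the yearly female intake is genotyped (same
screening strategy as the males), the male budget is the remainder and the
offspring sex ratio in B equals the male budget share. If that would leave
fewer genotyped males than sires are needed, the config falls back to
phenotypic female selection; cells feasible under neither rule (e.g. 60% of
genotyping in C combined with 11% retention) are flagged infeasible in the
scenario grid. The original study tuned per-scenario sex ratios with a
procedure whose details are not public; `optimize_sex_ratio()` offers a
plain pilot-run grid search instead, and the derived defaults above are used
everywhere else.

# Evaluation and estimation

GEBVs come from GBLUP with a VanRaden method-1 genomic relationship matrix
(centering and scaling frequencies fixed at the founder generation, loci
with boundary frequencies dropped) over all genotyped fish and all records
accumulated to date, with fixed year effects per environment and the *true*
variance components, exactly as the breeding program being modelled would
run it. With C records the model is the bivariate animal model
$y = Xb + Zg + e$, $\mathrm{var}(g) = G \otimes S$ with
$S = \begin{pmatrix} \sigma^2_{gB} & \sigma_{gBC} \\ \sigma_{gBC} &
\sigma^2_{gC}\end{pmatrix}$ and heterogeneous diagonal residuals; without C
records the univariate B model is used and selection falls back to the
B-trait GEBV.

Because every genotyped fish carries exactly one record, the package solves
the model in observation space: $V = S[e_i,e_j] \odot G[a_i,a_j] + R$ is
$n \times n$, fixed effects come from GLS and
$\hat g = \mathrm{Cov}(g, y) V^{-1}(y - X\hat b)$. This is algebraically the
mixed-model-equation solution — the test suite asserts equality with an
independently coded dense MME oracle to 1e-8 — and avoids inverting G every
year. A ridge of 1e-6 × mean diagonal is added only if the Cholesky of V
fails.

Variance components are estimated (at the year-10 snapshot only; estimates
never feed back into selection) by AI-REML in the same observation-space
parameterization: score and average-information matrix from $P$, the REML
projection of $V^{-1}$. Updates are guarded — steps capped at a five-fold
relative change, step-halving when the restricted likelihood would fall, a
scaled-gradient fallback direction before declaring an optimum, bending of
the 2×2 genetic matrix to the nearest positive semi-definite matrix, and
positive floors on residuals. Convergence is a relative parameter change
below 1e-6 within 200 iterations; non-convergence is reported, not raised.
Parameter recovery under random genotyping is certified by simulation tests
(within two Monte-Carlo standard errors); equivalence with any particular
REML software is asserted through those recovery tests, not by imitating its
implementation.

# Outcome measures

* **Rate of gain** $\Delta G$: mean C-trait TBV of the fish born each year,
  contrasted between years 19–21 and 5–7 (divisor 42) at the full horizon.
* **Rate of inbreeding** $\Delta F$: Wright's coefficients from the complete
  true pedigree (Meuwissen–Luo algorithm, compiled; verified exactly against
  a recursive kinship oracle), then
  $\Delta F = (1-e^\beta) \times 100$ with $\beta$ the slope of
  $\ln(1-F_t)$ on generation number over years 5–21. The year-to-generation
  mapping uses the fixed 3-year candidate age; the small 4-year-old dam
  share perturbs the true interval negligibly and a fixed mapping keeps the
  rate comparable across scenarios.
* **Accuracy and dispersion bias**: per evaluation year (10–12), the
  correlation of GEBV with C-trait TBV, and the slope of TBV on GEBV, over
  the 3-year-old genotyped B fish, averaged over the three years. Without C
  records the B-trait GEBV substitutes, with expectations $r_g$ (accuracy)
  and $r_g\sqrt{\sigma^2_{gC}/\sigma^2_{gB}}$ (slope).

Each scenario runs as independent replicates (100 in the original study)
with per-replicate substream seeds; scenarios sharing a replicate index
share founder genomes, so strategy contrasts are paired.

# Scale profiles and problem sizes

The `full` profile reproduces the study scale. The `desk` profile is the
package's reduced scale for testing and the acceptance computations: 2,000
offspring/year from 10 sires × 10 dams (20 families of 100), 100 genotyped
per year (80 B / 20 C at the 20% allocation), an 80-female pool, 3,000
markers + 400 QTL on the full 29-chromosome map, 20 replicates. It preserves
every ratio the distortions depend on — groups of 20, one genotyping slot
per 20 offspring, degree-2 factorial mating, the 3-year lag and the
evaluation windows — while the absolute numbers of parents and records
shrink. Consequences to keep in mind: inbreeding accumulates faster (fewer
parents), desk sire-selection intensity differs from full scale, and with
~1 marker/cM some QTL variance is untagged, which shifts REML levels and
dispersion slopes a little relative to the full-scale values even though
every qualitative contrast between strategies is preserved. The bias checks
run 12-year horizons (their years-10–12 window cannot be affected by later
years) and the strategy-ordering checks use a 14-year horizon with the late
gain window at years 12–14. The `micro` profile (400 offspring/year) is for
smoke tests only.

# Known limitations

* No mortality, no variable family sizes, no multi-trait index, females
  never spawn beyond two ages, no dominance or epistasis, no mutation.
* The founder generator is a stand-in: conclusions about absolute LD-driven
  quantities transfer to real panels only qualitatively.
* Single-step GBLUP and Bayesian marker models are out of scope; only
  genotyped fish ever enter the evaluation, mirroring the unregistered-
  pedigree premise.
* The full profile at 36k markers and 18k genotyped fish is memory- and
  CPU-hungry (a dense G across all genotyped fish); it is supported but
  intended for cluster use, not laptops.
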