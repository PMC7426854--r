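---
title: "Predicting offspring mortality risk from polygenic and recessive lethal components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting offspring mortality risk from polygenic and recessive lethal components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lethalrisk)
```

## The problem

Calf mortality in dairy cattle has two genetic components that act on
different scales. Part of the risk is polygenic: many loci of small effect
shift an underlying liability, and an animal dies when its liability
exceeds a threshold. Part is monogenic: recessive lethal alleles segregate
at appreciable frequencies in intensively selected populations, and an
offspring that inherits two copies dies with some penetrance. A carrier
sire is itself healthy, so its own phenotype carries no signal about the
lethal component — but its *offspring* are at risk whenever the dam
population also carries the allele. Fitting both components in one mixed
model is awkward because the modes of gene action differ.

`lethalrisk` implements the separated strategy: predict a polygenic risk
probability from genomic breeding values, predict a lethal risk probability
from sire carrier status, allele frequency and penetrance, and blend the
two into a single transmitted risk probability per sire that can be used
for selection.

## The risk model

For lethal locus $i$ with dam-population allele frequency $p_a$ and
penetrance $\rho_i$, the probability that a random offspring of the sire
dies of that locus is

$$p(\mathrm{leth}_i) = p(\text{a from sire} \mid \text{sire genotype})
  \times p_a \times \rho_i,$$

which is $0$, $0.5\,p_a\rho_i$ or $p_a\rho_i$ for sire genotypes AA, Aa and
aa (`lethal_risk_locus()`). Loci sit on different chromosomes and are
treated as independent, so the combined lethal risk is the union
probability $p_\mathrm{leth} = 1 - \prod_i (1 - p(\mathrm{leth}_i))$
(`lethal_risk_total()`).

The polygenic side starts from a genomic breeding value $\hat a_i$ and the
fitted mean $\hat\mu$ of one of three model families, each fitted by GBLUP
with a VanRaden method-1 genomic relationship matrix:

* **probit** (threshold model, residual scale 1, threshold 0):
  $\hat\pi_i = 1 - \Phi(-(\hat\mu + \hat a_i))$;
* **logit**: $\hat\pi_i = \mathrm{logit}^{-1}(\hat\mu + \hat a_i)$;
* **linear**: binary observations are treated as
  $N(\pi, \pi(1-\pi))$, so the threshold must be estimated:
  $\tau = \pi + \sqrt{\pi(1-\pi)}\,\Phi^{-1}(1-\pi)$ with $\pi$ the
  training incidence, and
  $\hat\pi_i = 1 - \Phi\!\big((\tau - (\hat\mu + \hat a_i))/s\big)$.

A sire transmits half its breeding value, so the transmitted polygenic risk
is $p_\mathrm{poly,offspring} = 0.5\, p_\mathrm{poly,sire}$
(`transmitted_poly_risk()`), and the components blend under independent
survival:

$$p_\mathrm{total} = 1 - (1 - p_\mathrm{leth})(1 - p_\mathrm{poly}).$$

The residual scale $s$ of the linear transform is the one genuinely open
choice in the method core: the $N(\pi, \pi(1-\pi))$ assumption is stated
only for deriving $\tau$. We use $s = \sqrt{\pi(1-\pi)}$ for internal
consistency with that distribution; `poly_risk_linear(sigma_e=)` switches
to a model-estimated residual scale.

Two named analysis routes use these pieces. The **separated** ("novel")
approach trains the polygenic model on `Data_poly` — reference records with
deaths caused by lethal alleles removed — and blends with the lethal
component; the **non-separated** ("conventional") approach trains on
`Data_all` and uses the transmitted polygenic risk alone. Model variants 2
(fixed regression on a lethal-homozygosity indicator) and 3 (lethal loci
included in the GRM, $G^*$) exist to measure how much of the lethal signal
a single mixed model can absorb; they are never part of the separated
pipeline.

## The simulator

The validation study is fully simulated, so the package ships the
generator as first-class code.

**Population.** Founders (year 0) are followed by `years` rounds of
matings with overlapping generations: each year `sires_per_year` males are
drawn from the alive males born earlier and each is mated to an equal
share of `dams_per_year` dams (one offspring per dam per year; dams are
reusable across years). Offspring sex is Bernoulli(0.5) and there is no
selection on any trait. Calf death feeds back into eligibility: a dead
individual is never sampled as a parent, so under complete penetrance no
lethal homozygote ever breeds while under partial penetrance surviving
homozygotes may. The full-scale design is 4 years of 50 sires × 10,000
dams (40,000 offspring); years 1..Y−1 form the reference population, the
final year is the test set whose phenotypes are masked, and the sires of
test-year offspring are the validation sires.

**Genome.** Loci are laid out equidistantly on `n_chr` chromosomes of 100
cM. Roles: neutral markers (frequency U(0.05, 0.5)), 66 QTLs per
chromosome, and 20 recessive lethal loci whose frequencies are drawn
directly from U(0.04, 0.05) — setting them directly (rather than
rediscovering them by MAF filtering) guarantees the intended band at any
panel size. Lethal loci go on distinct chromosomes whenever there are
enough chromosomes, otherwise they are spread evenly and maximally
separated.

**Founder haplotypes.** Each haplotype is a thresholded latent Gaussian
AR(1) process along the chromosome: the allele at a locus is 1 exactly
with its base frequency, and the latent autocorrelation decays as
$\exp(-d/\texttt{ld\_decay\_cm})$. This preserves every marginal frequency
exactly — which the narrow lethal band and the founder Hardy–Weinberg
checks rely on — while giving tunable, distance-decaying LD;
`ld_decay_cm = 0` is linkage equilibrium, used by several unit tests.

**Gene drop.** Non-founders receive one recombinant gamete per parent;
crossover counts are Poisson with mean equal to the map length in Morgans
(Haldane, no interference) with uniform positions. The kernel is compiled
and uses R's RNG, so whole populations are reproducible from one seed. A
phased Mendelian audit (`mendelian_violations()`) checks every transmitted
allele against its parent.

**Trait.** QTL effects are standard normal; TBVs are dosage-weighted sums,
centred on the founder mean and scaled by the founder standard deviation so
the base population has mean 0 and additive variance exactly 1 (the
liability threshold is defined for that base scale). The observed-scale
heritability 0.02 and incidence 0.068 are mapped to the liability scale
with the classical transform $h_l^2 = h_x^2\,\pi(1-\pi)/z^2$
(`liability_heritability()`); exact evaluation gives 0.0735. Note the
widely quoted 0.075 for these inputs corresponds to rounding $z$ to 0.13 —
the simulator uses the exact value, which moves $\sigma_e^2$ from 12.33 to
12.60 and is immaterial for incidence because the threshold is recomputed
from $\pi$ either way. Phenotypes are assigned stepwise: polygenic death
if liability exceeds the threshold, then an independent Bernoulli
penetrance draw per lethal locus at which the animal is homozygous; the
cause label (`none`/`polygenic`/`lethal`/`both`) drives the `Data_poly`
filter, which removes lethal-involved records entirely (including
`both`-cause records) rather than recoding them.

The penetrance scenarios are all-60%, all-80%, all-100% and a mixture with
four equal groups of five loci at 60/70/80/100% (the locus-group
definition, whose mean is 77.5%). Scenarios of one replicate share the
locus map, founder haplotypes and QTL effects; the pedigree and phenotypes
are realized per scenario because survival feeds back into parenthood.

## Model fitting

All nine models (three families × three variants) share the linear
predictor $\eta = 1\mu\,[{} + xd] + Zg$, $g \sim N(0, G\sigma_a^2)$, with
candidates (validation sires) carried unphenotyped in the GRM and solved
jointly.

* The **linear** family uses exact REML: after one spectral decomposition
  of the training GRM block the restricted likelihood is profiled to a
  one-dimensional search over $\sigma_e^2/\sigma_a^2$, which is solved by
  deterministic golden-section/parabolic optimization. Fixed variance
  components are supported (`varcomp=`), which is also how the tests pin
  the solver against an explicit mixed-model-equation oracle.
* The **probit/logit** families use penalized quasi-likelihood Newton
  iterations with the residual scale fixed by convention (1, respectively
  $\pi^2/3$) and the link-scale genetic variance fixed at the value
  implied by the linear-REML heritability passed through the
  observed-to-liability transform. PQL's own variance re-estimation is
  known to be badly biased for rare binary traits, while the transform
  route is deterministic and keeps all three families on one variance
  scale; `sigma2_a=` overrides it.

Every solver is deterministic, so refits are bit-for-bit identical —
stochastic seeds exist in the simulation layer only. Degenerate inputs
(zero outcome variance, complete separation pressure) yield flagged
boundary fits rather than silent failures; a small configurable ridge
(default $10^{-6}$) stabilizes the training GRM block.

## The validation workbench

`run_replicate()` chains simulate → fit → risk → evaluate for one
population; `run_study()` repeats it over hierarchically seeded replicates
and aggregates means, standard errors and paired t-tests
(`paired_replicate_test()`). Accuracy is the Pearson correlation between
predicted total risk and the observed proportion of deaths among each
validation sire's test-year offspring (simple proportions, no shrinkage);
calibration is the regression slope of observed on predicted.

Two presets bundle the study conditions:

* `study_config("paper")` — the published dimensions (40,000 animals,
  ~40K markers, 1,980 QTLs, 20 lethals, 4 scenarios, 15 replicates).
  Mortality-partition runs use it directly with `markers_per_chr = 0`,
  since only trait loci drive mortality; at roughly 4 s per population
  this takes a few minutes for 60 scenario × replicate cells.
* `study_config("desk")` — a reduced design used by the replicated
  validation checks: 2 offspring years of 40 sires × 3,200 dams (3,200
  reference records in 40 paternal half-sib families; 3,200 test offspring
  giving 80 per validation sire), 10 chromosomes with 4,000 markers, 660
  QTLs and the full 20 lethal loci, 10 replicates, Pen100.

The desk preset was sized from an information-content argument, not by
shrinking everything proportionally. Two quantities control whether the
reduced study can show the published contrasts at all. First, REML power
for a trait with $h_x^2 = 0.02$ is driven by the number of paternal
families: with too few, the restricted likelihood frequently hits the
$\sigma_a^2 = 0$ boundary and the non-separated approach collapses for the
wrong reason. Forty families at $n = 3200$ keep the sire intraclass signal
(~0.005 polygenic, roughly doubled by lethal clustering in `Data_all`)
estimable. Second, the precision of each sire's observed offspring
mortality sets an attenuation floor on every accuracy: with 80 offspring
the binomial noise (sd ≈ 0.033) is comparable to the true between-sire
spread (sd ≈ 0.033), close to the published 200-offspring design's ratio.
The desk genome also uses a longer founder-LD range (`ld_decay_cm = 5` vs
1 at full scale) because its markers sit 1.25 cM apart where the published
40K panel sits at 0.075 cM: without that compensation the desk panel
cannot tag lethal loci, the `Data_all` models lose the lethal family
signal they demonstrably have at full scale, and the conventional approach
is artificially crushed. The lethal-locus count and frequency band are
never scaled — the headline contrast is proportional to the lethal-caused
mortality share, which depends directly on them.

## What the simulation does and does not emulate

The generator reproduces the study conditions: overlapping generations
without selection, the mixed polygenic/monogenic architecture, stepwise
phenotypes with per-locus penetrance, and survivor-only parenthood. It
does not emulate several features of real cattle data: realistic
chromosome-specific LD profiles (the AR(1) founder model gives smooth
distance-decay only), mutation, genotyping error, fixed effects beyond an
overall mean (herd, parity, season), maternal effects, or epistasis
between lethal and polygenic loci. Passing validation therefore shows that
the separated risk computation behaves as designed under its own
assumptions — not that the same accuracies would be observed in field
data. Results at desk scale reproduce orderings and calibration patterns;
absolute GEBV accuracies (published 0.319–0.323, with a 4–9.3-point
spread between variants 2 and 3) require the full 40K-marker,
30,000-record design and are deliberately not asserted at desk scale.

## Numerical choices and degenerate inputs

* Probabilities are validated at interface boundaries; the logit transform
  saturates cleanly for $|\eta| \to \infty$.
* Monomorphic loci are dropped from GRMs with a warning; an all-monomorphic
  panel is an error (zero VanRaden denominator).
* REML profiles $\log\delta$ over $[\log 10^{-4}, \log 10^6]$; hitting an
  end is reported as a boundary fit. PQL clamps the linear predictor (±7
  probit, ±25 logit) and flags clamping.
* Zero-variance outcomes return flagged fits with $\hat a = 0$; undefined
  correlations (zero-variance predictions) propagate as `NA` with a
  warning, and paired tests drop undefined pairs with a warning.
* Replicate seeds are drawn hierarchically from one master seed; every
  simulated object records the seed that produced it.

## Session

```{r}
sessionInfo()
```
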