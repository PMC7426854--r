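# lethalrisk

Genomic prediction of offspring mortality risk when the trait mixes a
polygenic liability with segregating recessive lethal alleles — the
situation of calf mortality in dairy cattle, where a healthy carrier sire
transmits a risk its own phenotype never shows.

The package implements the *separated* prediction strategy: the polygenic
and recessive-lethal components are predicted as probabilities on the same
scale and then blended, instead of being forced into one mixed model with
incompatible modes of gene action.

For lethal locus *i* (dam-population allele frequency *p<sub>a</sub>*,
penetrance *ρ<sub>i</sub>*), an offspring of a sire with genotype AA / Aa /
aa dies of that locus with probability 0, 0.5 *p<sub>a</sub>ρ<sub>i</sub>*,
or *p<sub>a</sub>ρ<sub>i</sub>*; across independent loci

> p(leth) = 1 − Π<sub>i</sub> (1 − p(leth<sub>i</sub>)).

The polygenic risk comes from a GBLUP breeding value *â* and fitted mean
*μ̂* under a probit (1 − Φ(−(μ̂+â))), logit (logit⁻¹(μ̂+â)) or linear model
(threshold τ = π + √(π(1−π)) Φ⁻¹(1−π) estimated from the training
incidence π). A sire transmits half its breeding value, so
p(poly, offspring) = 0.5 p(poly, sire), and the total transmitted risk is

> p(total) = 1 − (1 − p(leth)) (1 − p(poly)).

Around that core the package provides the full validation machinery: a
stochastic breeding-population simulator (overlapping generations, Haldane
gene drop through a compiled kernel, liability-threshold phenotypes with
per-locus lethal penetrance and cause-of-death labels), VanRaden method-1
genomic relationship matrices, the nine genomic mixed models (linear /
probit / logit × plain GRM / lethal-covariate / lethal-in-GRM), and a
replicated study workbench measuring prediction accuracy and calibration
against observed offspring mortality.

## A worked example

Simulate a reduced-scale population, fit the probit model on `Data_poly`
(records of lethal-caused deaths removed), and blend the per-sire risks:

```r
library(lethalrisk)

cfg <- study_config("desk")
pop <- sim_population(cfg, "pen100", seed = 42)
pop
#> <sim_population> pen100: 9700 individuals (6400 phenotyped), mortality 10.45%

ph  <- pop$phenotypes
obs <- observed_sire_mortality(ph, pop$pedigree)
ids <- union(ph$id[ph$in_data_all], obs$sire_id)
G   <- build_grm(pop$panel, ids = ids, loci = "markers")

dat <- dplyr::left_join(tibble::tibble(id = ids),
                        ph[c("id", "y", "in_data_poly")], by = "id")
fit <- fit_probit(dat, G, train = dplyr::coalesce(dat$in_data_poly, FALSE))
glance(fit)[c("mu", "sigma2_a", "incidence", "converged")]
#>      mu sigma2_a incidence converged
#>   -1.55   0.0444    0.0623      TRUE

arch  <- pop$architecture
dams  <- unique(pop$pedigree$dam[pop$pedigree$year == 2])
p_a   <- allele_freq(pop$panel, arch$lethal_locus, dams)
sdos  <- dosages(pop$panel, arch$lethal_locus, obs$sire_id)
risk  <- sire_risk_pipeline(fit, obs$sire_id, sdos, p_a, arch$penetrance)
head(risk, 3)
#>   sire_id p_poly_sire p_poly_offspring p_leth p_total family variant
#> 1      30      0.0531           0.0266 0.0715  0.0962 probit       1
#> 2      88      0.0773           0.0387 0.0000  0.0387 probit       1
#> 3      99      0.0651           0.0326 0.0194  0.0513 probit       1

risk_accuracy(risk$p_total, obs$observed_mortality)
#> [1] 0.366
bias_slope(risk$p_total, obs$observed_mortality)
#> [1] 0.568
```

The fitted mean sits near Φ⁻¹ of the training incidence (−1.54), and each
sire's total risk combines its carrier load (sire 30 carries at least one
lethal allele, sire 88 none) with its transmitted polygenic risk. A single
replicate's accuracy is noisy — this one correlates 0.37 with realized
offspring mortality; across the 10-replicate desk study the separated
approach averages about 0.56 against about 0.23 for the non-separated one
(training on `Data_all` with no lethal blending). The replicated
comparison is one call:

```r
study <- run_study(study_config("desk"), seed = 1)
study$comparison   # paired tests: separated vs non-separated accuracy
```

`autoplot(study, "risk_accuracy")`, `"gebv_accuracy"` and `"bias"` draw
the standard result panels; `tidy()`/`glance()` expose fits and studies as
tibbles. A thin command-line wrapper for the two end-to-end entry points
lives at `inst/cli/lethalrisk.R` (`simulate`, `study`).

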