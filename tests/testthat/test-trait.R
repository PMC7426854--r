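# Trait architecture: heritability transform, penetrance scenarios, TBV
# scaling and the stepwise phenotype model.

test_that("observed-to-liability heritability transform is exact", {
  # independently computed: z = 0.1313013 at pi = 0.068 (frozen from a
  # high-precision normal-density evaluation)
  expect_equal(liability_heritability(0.02, 0.068), 0.07352188,
               tolerance = 1e-6)
  # the commonly quoted 0.075 comes from rounding z to 0.13
  expect_equal(0.02 * 0.068 * 0.932 / 0.13^2, 0.0750, tolerance = 1e-3)
  # closed form at pi = 0.5: h * 0.25 / dnorm(0)^2 = h * pi/2
  expect_equal(liability_heritability(0.1, 0.5), 0.1570796, tolerance = 1e-6)
  expect_error(liability_heritability(0, 0.1), "h2_obs")
  expect_error(liability_heritability(0.02, 1), "incidence")
})

test_that("penetrance scenarios expand to per-locus vectors", {
  expect_equal(penetrance_scenario("pen60", 4), rep(0.6, 4))
  expect_equal(penetrance_scenario("pen100", 20), rep(1, 20))
  expect_equal(penetrance_scenario("penGRP", 20),
               rep(c(0.6, 0.7, 0.8, 1.0), each = 5))
  expect_error(penetrance_scenario("penGRP", 10), "divisible")
  expect_error(penetrance_scenario("pen50", 4), "scenario")
})

test_that("architecture reproduces the published dimensions and is seed-stable", {
  map <- make_locus_map(30, 5, 66, 20, seed = 3)
  arch <- assign_architecture(map, "pen100", seed = 4)
  expect_length(arch$qtl_locus, 1980)
  expect_length(arch$lethal_locus, 20)
  expect_equal(length(unique(map$chr[arch$lethal_locus])), 20)
  expect_true(all(arch$lethal_freq >= 0.04 & arch$lethal_freq <= 0.05))
  # role sets are disjoint
  expect_length(intersect(arch$qtl_locus, arch$lethal_locus), 0)
  arch2 <- assign_architecture(map, "pen100", seed = 4)
  expect_identical(arch$qtl_effect, arch2$qtl_effect)

  # sampling roles on a bare map errors when a chromosome lacks candidates
  bare <- make_locus_map(2, 10, 0, 0, seed = 5,
                         marker_freq = c(0.3, 0.5))
  bare$role <- "marker"
  expect_error(
    assign_architecture(bare, "pen100", qtl_per_chr = 2, n_lethal = 2),
    "eligible lethal candidate")
})

test_that("TBVs are centred and scaled to unit variance in the founder population", {
  # single QTL with effect 1 and founder dosages 0/1/2 equally frequent
  map <- tibble::tibble(locus = 1L, chr = 1L, pos_cm = 0, freq = 0.5,
                        role = "qtl")
  ped <- tibble::tibble(id = 1:6, sire = NA_integer_, dam = NA_integer_,
                        sex = rep(c("male", "female"), 3),
                        year = 0L, alive = TRUE)
  H1 <- matrix(as.raw(c(0, 0, 0, 1, 1, 1)), 1, 6)
  H2 <- matrix(as.raw(c(0, 0, 1, 0, 1, 1)), 1, 6)
  panel <- manual_panel(H1, H2, map, ped)
  arch <- structure(list(qtl_locus = 1L, qtl_effect = 1,
                         lethal_locus = integer(0)), class = "trait_architecture")
  out <- compute_tbv(panel, arch)
  v <- mean((out$tbv$tbv - mean(out$tbv$tbv))^2)
  expect_equal(v, 1, tolerance = 1e-12)
  expect_equal(mean(out$tbv$tbv), 0, tolerance = 1e-12)

  arch0 <- arch; arch0$qtl_effect <- 0
  expect_error(compute_tbv(panel, arch0), "zero additive variance")
})

test_that("liability threshold matches the stated total-variance quantile", {
  map <- make_locus_map(4, 5, 10, 4, seed = 6)
  arch <- assign_architecture(map, "pen100", seed = 7)
  expect_equal(arch$sigma2_e, (1 - arch$h2_liab) / arch$h2_liab)
  expect_equal(arch$threshold,
               qnorm(1 - 0.068, 0, sqrt(1 + arch$sigma2_e)))
  # at the rounded liability heritability 0.075 the threshold is 5.444
  expect_equal(qnorm(1 - 0.068, 0, sqrt(1 + (1 - 0.075) / 0.075)),
               5.4438, tolerance = 1e-4)
})

test_that("stepwise phenotypes assign causes and honour penetrance", {
  cfg <- tiny_config()
  pop <- sim_population(cfg, "pen100", seed = 12)
  ph <- dplyr::filter(pop$phenotypes, !is.na(y))
  expect_true(all((ph$y == 1) == (ph$cause != "none")))

  # under 100% penetrance every lethal homozygote is dead with lethal cause
  hom <- rowSums(dosages(pop$panel, pop$architecture$lethal_locus,
                         ph$id) == 2L) > 0
  expect_true(all(ph$y[hom] == 1))
  expect_true(all(ph$cause[hom] %in% c("lethal", "both")))
  expect_true(all(ph$cause[!hom] %in% c("none", "polygenic")))

  # liability is TBV plus residual, compared against the threshold
  expect_equal(ph$y[!hom],
               as.integer(ph$liability[!hom] > pop$architecture$threshold))
})

test_that("incidence among non-lethal deaths matches the target", {
  cfg <- study_config("desk",
    population = list(years = 1, sires_per_year = 50, dams_per_year = 10000,
                      founder_males = 100, founder_females = 10000),
    genome = list(n_chr = 2, markers_per_chr = 0, qtl_per_chr = 30,
                  n_lethal = 2),
    analysis = list(fit_models = FALSE))
  pop <- sim_population(cfg, "pen100", seed = 31)
  ph <- dplyr::filter(pop$phenotypes, !is.na(y),
                      cause %in% c("none", "polygenic"))
  inc <- mean(ph$cause == "polygenic")
  # the binomial error is inflated by sire sampling: 50 sires contribute a
  # shared half-TBV with variance 0.25/50 that shifts the realized incidence
  se_bin <- sqrt(0.068 * 0.932 / nrow(ph))
  se_sire <- dnorm(qnorm(1 - 0.068)) *
    sqrt(0.25 / 50) / sqrt(1 + pop$architecture$sigma2_e)
  expect_lt(abs(inc - 0.068), 4 * sqrt(se_bin^2 + se_sire^2))

  # empirical liability-scale heritability near its target
  off <- dplyr::filter(pop$phenotypes, !is.na(y))
  h2_emp <- var(off$tbv) / var(off$liability)
  expect_lt(abs(h2_emp - pop$architecture$h2_liab), 0.02)
})

test_that("dataset construction masks test phenotypes and filters lethal deaths", {
  cfg <- tiny_config()
  pop <- sim_population(cfg, "pen80", seed = 21)
  ph <- pop$phenotypes
  last <- max(pop$pedigree$year)
  expect_true(all(ph$role[pop$pedigree$year == last] == "test"))
  expect_true(all(ph$role[pop$pedigree$year == 0] == "founder"))
  expect_false(any(ph$in_data_all[ph$role != "reference"]))
  expect_true(all(ph$cause[ph$in_data_poly] %in% c("none", "polygenic")))
  # records with lethal involvement are excluded from Data_poly entirely
  expect_false(any(ph$in_data_poly[ph$cause %in% c("lethal", "both")]))
  # validation sires are the sires of test-year offspring
  sires <- unique(pop$pedigree$sire[pop$pedigree$year == last])
  expect_setequal(ph$id[ph$validation_sire], sires)

  # with no lethal deaths the two datasets coincide
  ph2 <- ph
  ph2$cause[ph2$cause %in% c("lethal", "both")] <- "polygenic"
  ph2$in_data_poly <- NULL; ph2$in_data_all <- NULL; ph2$role <- NULL
  ph2$validation_sire <- NULL
  d2 <- make_datasets(ph2, pop$pedigree)
  expect_equal(d2$in_data_poly, d2$in_data_all)
})

test_that("cause shares partition the deaths exactly", {
  cfg <- tiny_config()
  pop <- sim_population(cfg, "penGRP", seed = 44)
  part <- mortality_partition(pop$phenotypes)
  if (part$total_mortality_pct > 0) {
    expect_equal(part$share_lethal_pct + part$share_polygenic_pct +
                   part$share_both_pct, 100)
  }
})
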