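#' Configuration for a replicated simulation study
#'
#' Bundles the population, genome, trait, analysis and study blocks with
#' defaults at one of two scales:
#'
#' * `"paper"` — the full published dimensions: 4 offspring years of
#'   50 sires x 10,000 dams (40,000 animals), 30 chromosomes of 100 cM with
#'   ~40K markers, 66 QTLs per chromosome (1,980), 20 lethal loci at
#'   frequency 0.04-0.05, all four penetrance scenarios, 15 replicates.
#' * `"desk"` — a reduced design for interactive work and testing:
#'   2 offspring years of 40 sires x 3,200 dams (3,200 reference records in
#'   40 paternal half-sib families, 3,200 test offspring, 80 offspring per
#'   validation sire), 10 chromosomes with 4,000 markers and 660 QTLs, the
#'   full 20 lethal loci (the lethal count and frequency band drive the
#'   headline contrast and are never scaled), Pen100 scenario, 10
#'   replicates. The founder LD range is longer than in the paper preset
#'   (`ld_decay_cm = 5` vs 1) so that the 16x sparser marker panel tags
#'   QTLs and lethal loci about as well as the published 40K panel does.
#'
#' @param scale `"desk"` or `"paper"`.
#' @param population,genome,trait,analysis,study named lists overriding
#'   individual defaults.
#' @return A `study_config` list.
#' @examples
#' cfg <- study_config("desk", study = list(replicates = 2))
#' cfg$population$dams_per_year
#' @export
study_config <- function(scale = c("desk", "paper"),
                         population = list(), genome = list(),
                         trait = list(), analysis = list(), study = list()) {
  scale <- match.arg(scale)
  base <- if (scale == "paper") {
    list(
      population = list(years = 4, sires_per_year = 50, dams_per_year = 10000,
                        founder_males = 200, founder_females = 10000),
      genome = list(n_chr = 30, chr_length_cm = 100, markers_per_chr = 1333,
                    qtl_per_chr = 66, n_lethal = 20,
                    lethal_freq = c(0.04, 0.05), marker_freq = c(0.05, 0.5),
                    ld_decay_cm = 1),
      trait = list(h2_obs = 0.02, incidence = 0.068,
                   scenarios = c("pen100", "penGRP", "pen80", "pen60")),
      analysis = list(families = c("linear", "probit", "logit"),
                      variants = list(linear = 1L, probit = 1L, logit = 1L),
                      fit_models = TRUE, ridge = 1e-6,
                      pql_maxit = 50, pql_tol = 1e-7, p_a_source = "dams"),
      study = list(replicates = 15)
    )
  } else {
    list(
      population = list(years = 2, sires_per_year = 40, dams_per_year = 3200,
                        founder_males = 100, founder_females = 3200),
      genome = list(n_chr = 10, chr_length_cm = 100, markers_per_chr = 400,
                    qtl_per_chr = 66, n_lethal = 20,
                    lethal_freq = c(0.04, 0.05), marker_freq = c(0.05, 0.5),
                    ld_decay_cm = 5),
      trait = list(h2_obs = 0.02, incidence = 0.068, scenarios = "pen100"),
      analysis = list(families = c("linear", "probit", "logit"),
                      variants = list(linear = 1L, probit = 1L, logit = 1L),
                      fit_models = TRUE, ridge = 1e-6,
                      pql_maxit = 50, pql_tol = 1e-7, p_a_source = "dams"),
      study = list(replicates = 10)
    )
  }
  cfg <- list(
    scale = scale,
    population = utils::modifyList(base$population, population),
    genome = utils::modifyList(base$genome, genome),
    trait = utils::modifyList(base$trait, trait),
    analysis = utils::modifyList(base$analysis, analysis),
    study = utils::modifyList(base$study, study)
  )
  # variants may be given as a plain vector applying to every family
  if (!is.list(cfg$analysis$variants))
    cfg$analysis$variants <- setNames(
      rep(list(as.integer(cfg$analysis$variants)),
          length(cfg$analysis$families)),
      cfg$analysis$families)
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> %s: %d yr x %d sires x %d dams; %d chr, %d markers, %d QTLs, %d lethals; scenarios %s; %d replicates\n",
    x$scale, x$population$years, x$population$sires_per_year,
    x$population$dams_per_year, x$genome$n_chr,
    x$genome$n_chr * x$genome$markers_per_chr,
    x$genome$n_chr * x$genome$qtl_per_chr, x$genome$n_lethal,
    paste(x$trait$scenarios, collapse = "/"), x$study$replicates))
  invisible(x)
}

#' Run one simulation replicate: simulate, fit, predict risk, evaluate
#'
#' Shares one genome (map, founder haplotypes, QTL effects, lethal loci)
#' across the configured penetrance scenarios, realizes the population for
#' each scenario, and — when model fitting is enabled — fits the configured
#' model families and variants, predicts per-sire transmitted risk with the
#' separated (novel, `Data_poly` + lethal blending) and non-separated
#' (conventional, `Data_all` only) approaches, and computes the validation
#' metrics against observed offspring mortality.
#'
#' @param config a [study_config()].
#' @param seed integer replicate seed.
#' @return Tibble of metric rows: `scenario`, `family`, `variant`,
#'   `dataset`, `approach`, `metric`, `value` (plus `seed`). Partition rows
#'   carry `metric` values `total_mortality_pct`, `share_*_pct` with `family
#'   = NA`.
#' @export
run_replicate <- function(config, seed) {
  scen <- config$trait$scenarios
  seeds <- child_seeds(seed, 1 + length(scen))
  genome <- sim_genome(config, seeds[1])
  rows <- purrr::map(seq_along(scen), function(i) {
    pop <- sim_population(config, scen[i], seed = seeds[1 + i],
                          genome = genome)
    part <- mortality_partition(pop$phenotypes)
    out <- tibble::tibble(
      scenario = scen[i], family = NA_character_, variant = NA_integer_,
      dataset = NA_character_, approach = NA_character_,
      metric = c("total_mortality_pct", "share_lethal_pct",
                 "share_polygenic_pct", "share_both_pct"),
      value = c(part$total_mortality_pct, part$share_lethal_pct,
                part$share_polygenic_pct, part$share_both_pct))
    if (isTRUE(config$analysis$fit_models))
      out <- dplyr::bind_rows(out, analyze_scenario(pop, config))
    out
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(seed = seed, .before = 1)
}

# Fit the requested models on one realized population and measure accuracy,
# calibration and GEBV accuracy over the validation sires.
analyze_scenario <- function(pop, config) {
  an <- config$analysis
  ph <- pop$phenotypes
  ped <- pop$pedigree
  arch <- pop$architecture

  obs <- observed_sire_mortality(ph, ped)
  sires <- obs$sire_id
  ref_ids <- ph$id[ph$in_data_all]
  grm_ids <- union(ref_ids, sires)
  G <- build_grm(pop$panel, ids = grm_ids, loci = "markers")
  need_gstar <- any(vapply(an$variants, function(v) 3L %in% v, TRUE))
  Gstar <- if (need_gstar)
    build_grm(pop$panel, ids = grm_ids, loci = "markers+lethal") else NULL

  # masked-outcome data frame over the GRM individuals
  dat <- tibble::tibble(id = grm_ids) |>
    dplyr::left_join(ph[, c("id", "y", "in_data_all", "in_data_poly")],
                     by = "id")
  leth_dos <- dosages(pop$panel, arch$lethal_locus, grm_ids)
  dat$x_lethal <- as.numeric(rowSums(leth_dos == 2L) > 0)

  # dam-population lethal-allele frequencies for the transmitted risk
  test_year <- max(ped$year)
  dam_ids <- if (identical(an$p_a_source, "dams"))
    unique(ped$dam[ped$year == test_year]) else grm_ids
  p_a <- allele_freq(pop$panel, arch$lethal_locus, dam_ids)
  sire_dos <- leth_dos[match(sires, grm_ids), , drop = FALSE]
  rownames(sire_dos) <- sires

  tbv_sires <- ph$tbv[match(sires, ph$id)]

  eig_cache <- new.env(parent = emptyenv())
  eig_of <- function(grm, train_rows_key, rows) {
    key <- paste0(grm$locus_set, ":", train_rows_key)
    if (is.null(eig_cache[[key]])) {
      Gtt <- grm$mat[rows, rows, drop = FALSE]
      diag(Gtt) <- diag(Gtt) + an$ridge
      eig_cache[[key]] <- eigen(Gtt, symmetric = TRUE)
    }
    eig_cache[[key]]
  }

  fit_one <- function(family, variant, dataset) {
    train <- if (dataset == "poly") dat$in_data_poly else dat$in_data_all
    train[is.na(train)] <- FALSE
    grm <- if (variant == 3L) Gstar else G
    rows <- match(dat$id[train], grm$ids)
    eg <- eig_of(grm, dataset, rows)
    covar <- if (variant == 2L) "x_lethal" else NULL
    if (family == "linear") {
      fit_gblup(dat, grm, family = "linear", covariate = covar,
                train = train, ridge = an$ridge, eigen_G = eg)
    } else {
      fit_gblup(dat, grm, family = family, covariate = covar,
                train = train, ridge = an$ridge,
                maxit = an$pql_maxit, tol = an$pql_tol, eigen_G = eg)
    }
  }

  out <- list()
  for (family in an$families) {
    variants <- an$variants[[family]]
    fit_poly <- fit_one(family, 1L, "poly")
    fit_all <- fit_one(family, 1L, "all")

    novel <- sire_risk_pipeline(fit_poly, sires, sire_dos, p_a,
                                arch$penetrance)
    conv <- sire_risk_pipeline(fit_all, sires)
    met <- function(family, variant, dataset, approach, metric, value)
      tibble::tibble(scenario = pop$scenario, family = family,
                     variant = variant, dataset = dataset,
                     approach = approach, metric = metric, value = value)
    out[[length(out) + 1]] <- dplyr::bind_rows(
      met(family, 1L, "poly", "novel", "risk_accuracy",
          risk_accuracy(novel$p_total, obs$observed_mortality)),
      met(family, 1L, "poly", "novel", "bias_slope",
          bias_slope(novel$p_total, obs$observed_mortality)),
      met(family, 1L, "all", "conventional", "risk_accuracy",
          risk_accuracy(conv$p_total, obs$observed_mortality)),
      met(family, 1L, "all", "conventional", "bias_slope",
          bias_slope(conv$p_total, obs$observed_mortality)),
      met(family, 1L, "poly", "novel", "gebv_accuracy",
          gebv_accuracy(sire_gebv(fit_poly, sires), tbv_sires)),
      met(family, 1L, "all", "conventional", "gebv_accuracy",
          gebv_accuracy(sire_gebv(fit_all, sires), tbv_sires))
    )
    for (v in setdiff(variants, 1L)) {
      f <- fit_one(family, v, "all")
      out[[length(out) + 1]] <- met(
        family, v, "all", "conventional", "gebv_accuracy",
        gebv_accuracy(sire_gebv(f, sires), tbv_sires))
    }
  }
  dplyr::bind_rows(out)
}

sire_gebv <- function(fit, sires) {
  fit$gebv$gebv[match(sires, fit$gebv$id)]
}

#' Run a replicated study and aggregate its validation metrics
#'
#' Executes [run_replicate()] for each of `replicates` hierarchically
#' seeded replicates and aggregates means, standard errors and paired
#' t-tests of the separated-vs-non-separated risk-prediction accuracy.
#'
#' @param config a [study_config()].
#' @param seed master seed; replicate seeds are derived from it.
#' @param replicates optional override of `config$study$replicates`.
#' @return A `risk_study` object: `metrics` (long tibble of all per-replicate
#'   values), `summary` (means/SE per cell), `comparison` (paired tests per
#'   scenario x family), `partition` (mortality partition summary), plus the
#'   config and seeds.
#' @export
run_study <- function(config, seed = 1, replicates = NULL) {
  n_rep <- replicates %||% config$study$replicates
  if (n_rep < 1) stop_bad_arg("replicates", "must be >= 1")
  rep_seeds <- child_seeds(seed, n_rep)
  metrics <- purrr::map(seq_len(n_rep), function(i) {
    run_replicate(config, rep_seeds[i]) |>
      dplyr::mutate(replicate = i, .before = 1)
  }) |> dplyr::bind_rows()

  summary <- metrics |>
    dplyr::group_by(.data$scenario, .data$family, .data$variant,
                    .data$dataset, .data$approach, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(), .groups = "drop")

  acc <- metrics |>
    dplyr::filter(.data$metric == "risk_accuracy") |>
    tidyr::pivot_wider(id_cols = c("replicate", "scenario", "family"),
                       names_from = "approach", values_from = "value")
  comparison <- if (n_rep >= 2 && nrow(acc) > 0) {
    acc |>
      dplyr::group_by(.data$scenario, .data$family) |>
      dplyr::group_modify(~ paired_replicate_test(.x$novel, .x$conventional)) |>
      dplyr::ungroup()
  } else tibble::tibble()

  partition <- metrics |>
    dplyr::filter(is.na(.data$family)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")

  structure(list(metrics = metrics, summary = summary,
                 comparison = comparison, partition = partition,
                 config = config, seed = seed, replicate_seeds = rep_seeds),
            class = "risk_study")
}

#' @export
print.risk_study <- function(x, ...) {
  cat(sprintf("<risk_study> %s scale, %d replicate(s), scenarios %s\n",
              x$config$scale, length(x$replicate_seeds),
              paste(x$config$trait$scenarios, collapse = "/")))
  print(x$partition)
  if (nrow(x$comparison) > 0) {
    cat("separated vs non-separated risk accuracy (paired):\n")
    print(x$comparison)
  }
  invisible(x)
}

#' @method tidy risk_study
#' @export
tidy.risk_study <- function(x, ...) x$metrics

#' @method glance risk_study
#' @export
glance.risk_study <- function(x, ...) {
  tibble::tibble(
    scale = x$config$scale,
    replicates = length(x$replicate_seeds),
    scenarios = paste(x$config$trait$scenarios, collapse = "/"),
    seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
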