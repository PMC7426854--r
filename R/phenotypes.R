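#' Simulate liability-threshold phenotypes with recessive lethal deaths
#'
#' Phenotypes are assigned stepwise. First, the liability `l = TBV + e`,
#' `e ~ N(0, sigma_e^2)`, is compared with the threshold (the upper
#' `incidence` quantile of `N(0, sigma_a^2 + sigma_e^2)`); individuals above
#' it die of the polygenic component. Second, an individual homozygous for
#' the lethal allele at a locus dies with probability equal to that locus's
#' penetrance (independent Bernoulli draw per locus), regardless of the
#' polygenic outcome. The cause label records which steps fired.
#'
#' Founders carry no phenotype (all columns `NA`).
#'
#' @param panel genotype panel.
#' @param architecture `trait_architecture` with `tbv_scale` set (see
#'   [compute_tbv()]).
#' @param tbv tibble (`id`, `tbv`) from [compute_tbv()]; recomputed when
#'   omitted.
#' @param seed optional integer seed.
#' @return Tibble with `id`, `tbv`, `liability`, `y` (0/1), `cause`
#'   (`"none"`, `"polygenic"`, `"lethal"`, `"both"`).
#' @export
simulate_phenotypes <- function(panel, architecture, tbv = NULL, seed = NULL) {
  if (is.null(tbv)) tbv <- compute_tbv(panel, architecture)$tbv
  ped <- panel$pedigree
  with_seed_(seed, {
    out <- phenotype_rows(panel, architecture, tbv$tbv,
                          rows = which(ped$year > 0))
    res <- tibble::tibble(
      id = ped$id, tbv = tbv$tbv,
      liability = NA_real_, y = NA_integer_, cause = NA_character_
    )
    res$liability[out$rows] <- out$liability
    res$y[out$rows] <- out$y
    res$cause[out$rows] <- out$cause
    res
  })
}

# Stepwise phenotype for a set of pedigree rows; used both by the standalone
# op (all rows at once) and the year-by-year integrated simulator.
phenotype_rows <- function(panel, architecture, tbv_all, rows) {
  n <- length(rows)
  liability <- tbv_all[rows] + rnorm(n, 0, sqrt(architecture$sigma2_e))
  poly_death <- liability > architecture$threshold
  lethal_death <- rep(FALSE, n)
  for (k in seq_along(architecture$lethal_locus)) {
    loc <- architecture$lethal_locus[k]
    hom <- (as.integer(panel$H1[loc, rows]) +
            as.integer(panel$H2[loc, rows])) == 2L
    if (any(hom)) {
      expressed <- hom
      expressed[hom] <- runif(sum(hom)) < architecture$penetrance[k]
      lethal_death <- lethal_death | expressed
    }
  }
  cause <- dplyr::case_when(
    poly_death & lethal_death ~ "both",
    lethal_death ~ "lethal",
    poly_death ~ "polygenic",
    TRUE ~ "none"
  )
  list(rows = rows, liability = liability,
       y = as.integer(poly_death | lethal_death), cause = cause)
}

#' Split phenotype records into training datasets and population roles
#'
#' Reference animals are those born in years `1 .. Y-1`; test animals are the
#' final-year offspring, whose phenotypes are masked from all training sets.
#' `Data_all` contains every reference record; `Data_poly` additionally
#' excludes records whose death involved a recessive lethal allele (cause
#' `"lethal"` or `"both"`), the set used to train the polygenic component of
#' the separated approach. Validation sires are the sires of test-year
#' offspring.
#'
#' @param phenotypes tibble from [simulate_phenotypes()].
#' @param pedigree matching pedigree tibble.
#' @return The phenotype tibble with columns `role` (`"founder"`,
#'   `"reference"`, `"test"`), `in_data_all`, `in_data_poly`,
#'   `validation_sire` added.
#' @export
make_datasets <- function(phenotypes, pedigree) {
  stopifnot(nrow(phenotypes) == nrow(pedigree),
            all(phenotypes$id == pedigree$id))
  last_year <- max(pedigree$year)
  role <- dplyr::case_when(
    pedigree$year == 0 ~ "founder",
    pedigree$year == last_year ~ "test",
    TRUE ~ "reference"
  )
  test_sires <- unique(pedigree$sire[pedigree$year == last_year])
  phenotypes |>
    dplyr::mutate(
      role = role,
      in_data_all = role == "reference",
      in_data_poly = role == "reference" & .data$cause %in% c("none", "polygenic"),
      validation_sire = .data$id %in% test_sires
    )
}

#' Mortality totals and cause partition of a phenotype table
#'
#' @param phenotypes phenotype tibble (optionally restricted upstream).
#' @return One-row tibble: `n`, `total_mortality_pct` and the percentage of
#'   deaths attributed to each cause (`share_lethal_pct`,
#'   `share_polygenic_pct`, `share_both_pct`; they sum to 100 when any death
#'   occurred).
#' @export
mortality_partition <- function(phenotypes) {
  ph <- dplyr::filter(phenotypes, !is.na(.data$y))
  deaths <- sum(ph$y)
  tibble::tibble(
    n = nrow(ph),
    total_mortality_pct = 100 * deaths / nrow(ph),
    share_lethal_pct = 100 * sum(ph$cause == "lethal") / max(deaths, 1),
    share_polygenic_pct = 100 * sum(ph$cause == "polygenic") / max(deaths, 1),
    share_both_pct = 100 * sum(ph$cause == "both") / max(deaths, 1)
  )
}
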