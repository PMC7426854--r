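#' Simulate a complete breeding population for one penetrance scenario
#'
#' Runs the integrated generator: founder haplotypes, year-by-year matings,
#' gene drop, true breeding values, liabilities and stepwise phenotypes.
#' Calf deaths feed back into the pedigree: an individual with `y = 1` is
#' never sampled as a parent in later years (under complete penetrance no
#' lethal homozygote ever breeds; under partial penetrance surviving
#' homozygotes may).
#'
#' A `sim_genome` (map + founder haplotypes + architecture) can be shared
#' across scenarios so that scenario comparisons differ only in penetrance
#' and the downstream stochastic draws.
#'
#' @param config a [study_config()].
#' @param scenario penetrance scenario name (see [penetrance_scenario()]).
#' @param seed integer seed for this realization.
#' @param genome optional [sim_genome()] result to reuse.
#' @return A `sim_population`: list with `pedigree`, `phenotypes` (with
#'   dataset flags from [make_datasets()]), `panel`, `architecture`,
#'   `scenario`, `seed`.
#' @export
sim_population <- function(config, scenario = config$trait$scenarios[1],
                           seed = NULL, genome = NULL) {
  if (is.null(genome)) genome <- sim_genome(config, seed = seed)
  pop <- config$population
  check_pedigree_config(pop$years, pop$sires_per_year, pop$dams_per_year,
                        pop$founder_males, pop$founder_females)
  arch <- genome$architecture
  arch$penetrance <- penetrance_scenario(scenario, length(arch$lethal_locus))
  arch$scenario <- if (is.character(scenario)) scenario else "custom"

  with_seed_(seed, {
    st <- pedigree_init(pop$founder_males, pop$founder_females,
                        pop$years * pop$dams_per_year)
    N <- length(st$id)
    L <- nrow(genome$map)
    nf <- st$n_founders
    H1 <- matrix(raw(1), L, N)
    H2 <- matrix(raw(1), L, N)
    H1[, seq_len(nf)] <- genome$founders$H1[, seq_len(nf)]
    H2[, seq_len(nf)] <- genome$founders$H2[, seq_len(nf)]
    panel_env <- list(H1 = H1, H2 = H2, map = genome$map)

    # founder TBVs fix the base-population centring and scaling constants
    tbv <- numeric(N)
    raw_f <- tbv_raw(panel_env, arch, seq_len(nf))
    s <- sd(raw_f) * sqrt((nf - 1) / nf)
    if (!is.finite(s) || s == 0)
      stop("degenerate architecture: zero additive variance among founders",
           call. = FALSE)
    ctr <- mean(raw_f)
    arch$tbv_scale <- s
    arch$tbv_center <- ctr
    tbv[seq_len(nf)] <- (raw_f - ctr) / s

    liability <- rep(NA_real_, N)
    y <- rep(NA_integer_, N)
    cause <- rep(NA_character_, N)

    for (yr in seq_len(pop$years)) {
      st <- pedigree_year(st, yr, pop$sires_per_year, pop$dams_per_year)
      rows <- (st$filled - pop$dams_per_year + 1L):st$filled
      cpp_gene_drop(H1, H2, st$sire |> na_zero(), st$dam |> na_zero(),
                    rows[1], rows[length(rows)],
                    genome$chr_first, genome$chr_last,
                    genome$map$pos_cm / 100)
      tbv[rows] <- (tbv_raw(panel_env, arch, rows) - ctr) / s
      out <- phenotype_rows(panel_env, arch, tbv, rows)
      liability[rows] <- out$liability
      y[rows] <- out$y
      cause[rows] <- out$cause
      st$alive[rows] <- out$y == 0L
    }

    pedigree <- pedigree_tibble(st)
    panel <- new_genotype_panel(H1, H2, genome$map, pedigree)
    phenotypes <- tibble::tibble(
      id = pedigree$id, tbv = tbv, liability = liability,
      y = y, cause = cause)
    phenotypes <- make_datasets(phenotypes, pedigree)
    structure(list(pedigree = pedigree, phenotypes = phenotypes,
                   panel = panel, architecture = arch,
                   scenario = arch$scenario, seed = seed),
              class = "sim_population")
  })
}

na_zero <- function(x) { x[is.na(x)] <- 0L; as.integer(x) }

#' @export
print.sim_population <- function(x, ...) {
  part <- mortality_partition(x$phenotypes)
  cat(sprintf(
    "<sim_population> %s: %d individuals (%d phenotyped), mortality %.2f%%\n",
    x$scenario, nrow(x$pedigree), part$n, part$total_mortality_pct))
  invisible(x)
}

#' Shared genome for a replicate: map, founder haplotypes, architecture
#'
#' Generates the locus map, the founder haplotype pool and the trait
#' architecture once, so that several penetrance scenarios of the same
#' replicate share QTL effects, lethal loci and founder genomes.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return A `sim_genome` list: `map`, `founders`, `architecture` (with the
#'   first configured scenario's penetrance; [sim_population()] overrides it
#'   per scenario), plus chromosome index bounds used by the gene dropper.
#' @export
sim_genome <- function(config, seed = NULL) {
  gen <- config$genome
  pop <- config$population
  seeds <- child_seeds(seed, 3)
  map <- make_locus_map(gen$n_chr, gen$markers_per_chr, gen$qtl_per_chr,
                        gen$n_lethal, gen$chr_length_cm,
                        gen$lethal_freq, gen$marker_freq, seed = seeds[1])
  founders <- simulate_founder_haplotypes(
    map, pop$founder_males + pop$founder_females,
    ld_decay_cm = gen$ld_decay_cm, seed = seeds[2])
  architecture <- assign_architecture(
    map, scenario = config$trait$scenarios[1],
    h2_obs = config$trait$h2_obs, incidence = config$trait$incidence,
    seed = seeds[3])
  structure(list(
    map = map, founders = founders, architecture = architecture,
    chr_first = as.integer(vapply(split(map$locus, map$chr), min, 1)),
    chr_last = as.integer(vapply(split(map$locus, map$chr), max, 1))
  ), class = "sim_genome")
}
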