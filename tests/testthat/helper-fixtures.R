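# Shared fixtures. Everything is generated in code under fixed seeds; the two
# replicated studies are memoised because several acceptance checks read
# different statistics from the same runs.

# A grm object from an explicit relationship matrix (for solver tests).
manual_grm <- function(G, ids = seq_len(nrow(G)), locus_set = "markers") {
  structure(list(mat = G, ids = ids, locus_set = locus_set,
                 loci = seq_len(nrow(G)), freq = rep(0.5, nrow(G))),
            class = "grm")
}

# A random positive-definite GRM with half-sib family structure.
family_grm <- function(n_fam, fam_size, seed = 1) {
  withr::with_seed(seed, {
    n <- n_fam * fam_size
    fam <- rep(seq_len(n_fam), each = fam_size)
    G <- outer(fam, fam, function(a, b) 0.25 * (a == b))
    diag(G) <- 1
    manual_grm(G)
  })
}

# A genotype panel built directly from haplotype matrices (loci x individuals).
manual_panel <- function(H1, H2, map, pedigree) {
  lethalrisk:::new_genotype_panel(H1, H2, map, pedigree)
}

tiny_config <- function(...) {
  study_config("desk",
    population = list(years = 2, sires_per_year = 4, dams_per_year = 80,
                      founder_males = 10, founder_females = 80),
    genome = list(n_chr = 3, markers_per_chr = 30, qtl_per_chr = 10,
                  n_lethal = 4),
    study = list(replicates = 2), ...)
}

# Desk-scale replicated study shared by the acceptance checks (accuracy gain,
# calibration slopes, GEBV-accuracy ordering). ~10 minutes; computed once.
get_desk_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- study_config("desk",
        analysis = list(variants = list(linear = c(1L, 2L, 3L),
                                        probit = 1L, logit = 1L)))
      cache <<- run_study(cfg, seed = 1)
    }
    cache
  }
})

# Full-population mortality-partition study (15 replicates x 4 penetrance
# scenarios, no model fitting). ~4 minutes; computed once.
get_partition_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- study_config("paper", genome = list(markers_per_chr = 0),
                          analysis = list(fit_models = FALSE))
      cache <<- run_study(cfg, seed = 20)
    }
    cache
  }
})
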