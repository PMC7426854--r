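#' Observed-scale to liability-scale heritability
#'
#' Converts the heritability of a binary trait on the observed (0/1) scale to
#' the underlying liability scale, `h_l^2 = h_x^2 * pi * (1 - pi) / z^2`,
#' where `z` is the standard normal density at the liability threshold
#' `qnorm(1 - pi)`.
#'
#' With `h_x^2 = 0.02` and incidence `pi = 0.068` the exact value is 0.0734;
#' rounding `z` to two decimals (0.13) gives 0.075, a figure often quoted for
#' these inputs. This function always computes exactly.
#'
#' @param h2_obs observed-scale heritability, in (0,1).
#' @param incidence proportion of the outcome (`y = 1`), in (0,1).
#' @return Liability-scale heritability.
#' @examples
#' liability_heritability(0.02, 0.068)   # 0.07339
#' @export
liability_heritability <- function(h2_obs, incidence) {
  check_prob(h2_obs, "h2_obs")
  check_prob(incidence, "incidence")
  z <- dnorm(qnorm(1 - incidence))
  h2_obs * incidence * (1 - incidence) / z^2
}

#' Penetrance vector for a named scenario
#'
#' `"pen60"`, `"pen80"` and `"pen100"` give all loci equal penetrance;
#' `"penGRP"` splits the loci into four equal groups with penetrances
#' 60/70/80/100%.
#'
#' @param scenario scenario name or a numeric vector of per-locus penetrances.
#' @param n_lethal number of lethal loci.
#' @return Numeric vector of length `n_lethal` with values in (0,1].
#' @export
penetrance_scenario <- function(scenario, n_lethal) {
  if (is.numeric(scenario)) {
    check_prob(scenario, "scenario", open_left = TRUE, open_right = FALSE)
    return(rep_len(scenario, n_lethal))
  }
  switch(scenario,
    pen60 = rep(0.6, n_lethal),
    pen80 = rep(0.8, n_lethal),
    pen100 = rep(1.0, n_lethal),
    penGRP = {
      if (n_lethal %% 4 != 0)
        stop_bad_arg("n_lethal", "must be divisible by 4 for penGRP")
      rep(c(0.6, 0.7, 0.8, 1.0), each = n_lethal / 4)
    },
    stop_bad_arg("scenario", "must be pen60, pen80, pen100, penGRP or numeric")
  )
}

#' Assign the genetic architecture of the mortality trait
#'
#' Fixes the QTL set with standard-normal allele-substitution effects, the
#' lethal loci with per-locus penetrances, and the liability-scale variance
#' components. If the map already carries `qtl`/`lethal` roles those are
#' used; otherwise the requested numbers of QTLs (per chromosome) and lethal
#' loci (one per chromosome, drawn from loci inside the lethal frequency
#' band) are sampled here.
#'
#' The additive variance is 1 by construction (true breeding values are
#' scaled to unit variance in the founder population, see [compute_tbv()]),
#' so the residual liability variance is `(1 - h_l^2) / h_l^2` and the
#' liability threshold is the upper `incidence` quantile of
#' `N(0, sigma_a^2 + sigma_e^2)`.
#'
#' @param map locus map (with or without pre-assigned roles).
#' @param scenario penetrance scenario (see [penetrance_scenario()]).
#' @param h2_obs observed-scale heritability (default 0.02).
#' @param incidence target mortality incidence from the polygenic component
#'   (default 0.068).
#' @param qtl_per_chr,n_lethal only used when the map has no roles yet.
#' @param lethal_freq frequency band from which lethal loci are drawn when
#'   sampling roles.
#' @param seed optional integer seed.
#' @return A `trait_architecture` object.
#' @export
assign_architecture <- function(map, scenario = "pen100",
                                h2_obs = 0.02, incidence = 0.068,
                                qtl_per_chr = NULL, n_lethal = NULL,
                                lethal_freq = c(0.04, 0.05), seed = NULL) {
  check_locus_map(map)
  with_seed_(seed, {
    if (!any(map$role %in% c("qtl", "lethal"))) {
      if (is.null(qtl_per_chr) || is.null(n_lethal))
        stop("map has no roles; supply qtl_per_chr and n_lethal",
             call. = FALSE)
      map <- sample_roles(map, qtl_per_chr, n_lethal, lethal_freq)
    }
    qtl <- which(map$role == "qtl")
    lethal <- which(map$role == "lethal")
    pen <- penetrance_scenario(scenario, length(lethal))
    h2_liab <- liability_heritability(h2_obs, incidence)
    sigma2_e <- (1 - h2_liab) / h2_liab
    structure(list(
      qtl_locus = qtl,
      qtl_effect = rnorm(length(qtl)),
      lethal_locus = lethal,
      lethal_freq = map$freq[lethal],
      penetrance = pen,
      scenario = if (is.character(scenario)) scenario else "custom",
      h2_obs = h2_obs,
      incidence = incidence,
      h2_liab = h2_liab,
      sigma2_a = 1,
      sigma2_e = sigma2_e,
      threshold = qnorm(1 - incidence, 0, sqrt(1 + sigma2_e)),
      tbv_scale = NA_real_,   # set by compute_tbv() from founder variance
      map = map
    ), class = "trait_architecture")
  })
}

sample_roles <- function(map, qtl_per_chr, n_lethal, lethal_freq) {
  chrs <- sort(unique(map$chr))
  lethal_chrs <- rep_len(chrs, n_lethal)
  for (c in chrs) {
    k <- sum(lethal_chrs == c)
    if (k > 0) {
      cand <- which(map$chr == c & map$role == "marker" &
                    map$freq >= lethal_freq[1] & map$freq <= lethal_freq[2])
      if (length(cand) < k)
        stop(sprintf(
          "chromosome %d has no eligible lethal candidate in [%g, %g]",
          c, lethal_freq[1], lethal_freq[2]), call. = FALSE)
      map$role[sample(cand, k)] <- "lethal"
    }
    free <- which(map$chr == c & map$role == "marker")
    if (length(free) < qtl_per_chr)
      stop(sprintf("chromosome %d has too few loci for %d QTLs",
                   c, qtl_per_chr), call. = FALSE)
    map$role[sample(free, qtl_per_chr)] <- "qtl"
  }
  map
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf(
    "<trait_architecture> %d QTLs, %d lethal loci (%s), h2_obs=%.3g, pi=%.3g, h2_liab=%.4g\n",
    length(x$qtl_locus), length(x$lethal_locus), x$scenario,
    x$h2_obs, x$incidence, x$h2_liab))
  invisible(x)
}

#' True breeding values from QTL dosages
#'
#' `TBV_i = sum_j g_j Q_ij`, scaled by the standard deviation of the raw
#' values among founders so the founder (base-population) variance is exactly
#' 1, i.e. `sigma_a^2 = 1`, and expressed as a deviation from the founder
#' mean (the liability threshold is defined for a base population centred at
#' zero).
#'
#' @param panel genotype panel covering every individual.
#' @param architecture `trait_architecture`.
#' @return A list: `tbv` tibble (`id`, `tbv`) and the updated `architecture`
#'   whose `tbv_scale` records the founder scaling constant.
#' @export
compute_tbv <- function(panel, architecture) {
  g <- architecture$qtl_effect
  if (length(g) == 0 || all(g == 0))
    stop("degenerate architecture: zero additive variance", call. = FALSE)
  raw_tbv <- tbv_raw(panel, architecture, seq_len(nrow(panel$pedigree)))
  founder <- panel$pedigree$year == 0
  s <- sd(raw_tbv[founder]) * sqrt((sum(founder) - 1) / sum(founder))
  if (!is.finite(s) || s == 0)
    stop("degenerate architecture: zero additive variance among founders",
         call. = FALSE)
  ctr <- mean(raw_tbv[founder])
  architecture$tbv_scale <- s
  architecture$tbv_center <- ctr
  list(
    tbv = tibble::tibble(id = panel$pedigree$id, tbv = (raw_tbv - ctr) / s),
    architecture = architecture
  )
}

# Raw (unscaled) TBV for a set of pedigree rows, accumulated per chromosome
# to keep the dense dosage blocks small.
tbv_raw <- function(panel, architecture, rows) {
  out <- numeric(length(rows))
  qtl <- architecture$qtl_locus
  chr <- panel$map$chr[qtl]
  for (c in unique(chr)) {
    idx <- qtl[chr == c]
    D <- matrix(as.integer(panel$H1[idx, rows, drop = FALSE]) +
                as.integer(panel$H2[idx, rows, drop = FALSE]),
                nrow = length(idx))
    out <- out + drop(crossprod(D, architecture$qtl_effect[match(idx, qtl)]))
  }
  out
}
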