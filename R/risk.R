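#' Offspring mortality risk from one recessive lethal locus
#'
#' Probability that a future offspring of the sire dies from lethal locus
#' *i*: the probability of transmitting the lethal allele from the sire
#' (0, 0.5 or 1 for genotypes AA, Aa, aa), times the probability `p_a` of
#' receiving a second copy from a random dam, times the locus penetrance.
#'
#' @param sire_genotype `"AA"`, `"Aa"` or `"aa"` (or dosage 0/1/2 of the
#'   lethal allele); vectorized.
#' @param p_a lethal-allele frequency in the dam population, in `[0, 1]`.
#' @param penetrance probability that the homozygous genotype expresses
#'   death, in `(0, 1]`.
#' @return Per-locus risk probability.
#' @examples
#' lethal_risk_locus("Aa", 0.05, 1)    # 0.025
#' lethal_risk_locus("aa", 0.04, 0.6)  # 0.024
#' @export
lethal_risk_locus <- function(sire_genotype, p_a, penetrance = 1) {
  check_prob(p_a, "p_a", open_left = FALSE, open_right = FALSE)
  check_prob(penetrance, "penetrance", open_left = TRUE, open_right = FALSE)
  trans <- genotype_transmission(sire_genotype)
  trans * p_a * penetrance
}

genotype_transmission <- function(g) {
  if (is.numeric(g)) {
    if (any(!g %in% 0:2))
      stop_bad_arg("sire_genotype", "dosage must be 0, 1 or 2")
    return(g / 2)
  }
  out <- c(AA = 0, Aa = 0.5, aA = 0.5, aa = 1)[as.character(g)]
  if (anyNA(out))
    stop_bad_arg("sire_genotype", "must be AA, Aa or aa (or dosage 0/1/2)")
  unname(out)
}

#' Combined risk over all lethal loci
#'
#' Union probability under independence across loci:
#' `1 - prod(1 - p_i)`.
#'
#' @param p_locus vector of per-locus risk probabilities (may be empty).
#' @return Single probability.
#' @examples
#' lethal_risk_total(c(0.025, 0.025))  # 0.049375
#' @export
lethal_risk_total <- function(p_locus) {
  check_prob(p_locus, "p_locus", open_left = FALSE, open_right = FALSE)
  1 - prod(1 - p_locus)
}

#' Polygenic risk probability from a fitted model's linear predictor
#'
#' Transforms `mu + a` into the probability of the offspring-scale event
#' under each model family:
#' * probit: `1 - Phi(-(mu + a)) = Phi(mu + a)` (threshold 0, residual sd 1);
#' * logit: inverse-logit of `mu + a`, numerically saturating;
#' * linear: the threshold is estimated from the training incidence
#'   `pi` as the upper-`pi` quantile of `N(pi, pi (1 - pi))`, i.e.
#'   `tau = pi + sqrt(pi (1 - pi)) * qnorm(1 - pi)`, and the risk is
#'   `1 - Phi((tau - (mu + a)) / s)` with residual scale
#'   `s = sqrt(pi (1 - pi))` by default (`sigma_e` overrides).
#'
#' @param mu fitted overall mean.
#' @param a breeding value(s) on the model's link scale.
#' @param incidence training incidence `pi` in (0,1) (linear model only).
#' @param sigma_e optional residual scale for the linear transform.
#' @return Risk probabilities in `[0, 1]`.
#' @examples
#' poly_risk_probit(-1.4909, 0)    # ~0.068
#' poly_risk_logit(-2.618, 0)      # ~0.068
#' poly_risk_linear(0.068, 0, 0.068)  # ~0.068
#' @export
poly_risk_probit <- function(mu, a) {
  pnorm(mu + a)
}

#' @rdname poly_risk_probit
#' @export
poly_risk_logit <- function(mu, a) {
  plogis(mu + a)
}

#' @rdname poly_risk_probit
#' @export
poly_risk_linear <- function(mu, a, incidence, sigma_e = NULL) {
  check_prob(incidence, "incidence")
  s0 <- sqrt(incidence * (1 - incidence))
  tau <- incidence + s0 * qnorm(1 - incidence)
  s <- if (is.null(sigma_e)) s0 else sigma_e
  1 - pnorm((tau - (mu + a)) / s)
}

#' Risk transmitted to offspring from the sire's polygenic risk
#'
#' A breeding animal passes on average half its breeding value, so the
#' transmitted polygenic risk is half the sire's own risk probability.
#'
#' @param p_poly_sire sire risk probability in `[0, 1]`.
#' @return Offspring polygenic risk.
#' @export
transmitted_poly_risk <- function(p_poly_sire) {
  check_prob(p_poly_sire, "p_poly_sire", open_left = FALSE, open_right = FALSE)
  0.5 * p_poly_sire
}

#' Total transmitted risk from lethal and polygenic components
#'
#' Assuming independent survival of the two components:
#' `p_total = 1 - (1 - p_leth) (1 - p_poly)`.
#'
#' @param p_leth lethal-component risk in `[0, 1]`.
#' @param p_poly_offspring transmitted polygenic risk in `[0, 1]`.
#' @return Total risk probability.
#' @examples
#' total_risk(0.025, 0.034)  # 0.05815
#' @export
total_risk <- function(p_leth, p_poly_offspring) {
  check_prob(p_leth, "p_leth", open_left = FALSE, open_right = FALSE)
  check_prob(p_poly_offspring, "p_poly_offspring",
             open_left = FALSE, open_right = FALSE)
  1 - (1 - p_leth) * (1 - p_poly_offspring)
}

#' Predict per-sire transmitted risk probabilities from a fitted model
#'
#' Applies the family-appropriate polygenic transform to each sire's
#' `mu + a`, halves it (transmission), computes the per-locus and combined
#' lethal risks from the sire's genotypes at the lethal loci, the
#' dam-population lethal-allele frequencies and the penetrances, and blends
#' the two components into the total transmitted risk. Omitting the lethal
#' arguments gives the non-separated (polygenic-only) prediction, i.e.
#' `p_total = p_poly_offspring`.
#'
#' @param fit a `gp_fit` covering every sire.
#' @param sire_ids sires to predict.
#' @param lethal_genotypes optional sires x loci matrix of lethal-allele
#'   dosages (0/1/2), rownames = sire ids.
#' @param p_a per-locus lethal-allele frequencies in the dam population.
#' @param penetrance per-locus penetrances.
#' @return Tibble: `sire_id`, `p_poly_sire`, `p_poly_offspring`, `p_leth`,
#'   `p_total`, `family`, `variant`.
#' @export
sire_risk_pipeline <- function(fit, sire_ids, lethal_genotypes = NULL,
                               p_a = NULL, penetrance = NULL) {
  idx <- match(sire_ids, fit$gebv$id)
  if (anyNA(idx))
    stop("fit does not provide breeding values for all sires", call. = FALSE)
  a <- fit$gebv$gebv[idx]
  p_sire <- switch(fit$family,
    probit = poly_risk_probit(fit$mu, a),
    logit = poly_risk_logit(fit$mu, a),
    linear = poly_risk_linear(fit$mu, a, fit$incidence))
  p_sire <- pmin(pmax(p_sire, 0), 1)
  p_off <- transmitted_poly_risk(p_sire)
  if (is.null(lethal_genotypes)) {
    p_leth <- rep(0, length(sire_ids))
  } else {
    if (is.null(p_a) || is.null(penetrance))
      stop("supply p_a and penetrance with lethal_genotypes", call. = FALSE)
    rows <- match(as.character(sire_ids), rownames(lethal_genotypes))
    if (anyNA(rows))
      stop(sprintf("missing lethal genotypes for sire(s) %s",
                   paste(sire_ids[is.na(rows)], collapse = ", ")),
           call. = FALSE)
    if (ncol(lethal_genotypes) != length(p_a) ||
        length(p_a) != length(penetrance))
      stop("lethal_genotypes, p_a and penetrance disagree on locus count",
           call. = FALSE)
    if (anyNA(lethal_genotypes[rows, ])) {
      bad <- which(is.na(lethal_genotypes[rows, , drop = FALSE]),
                   arr.ind = TRUE)[1, ]
      stop(sprintf("missing genotype for sire %s at lethal locus %d",
                   sire_ids[bad[1]], bad[2]), call. = FALSE)
    }
    p_leth <- vapply(seq_along(rows), function(i) {
      lethal_risk_total(lethal_risk_locus(
        as.numeric(lethal_genotypes[rows[i], ]), p_a, penetrance))
    }, 1)
  }
  tibble::tibble(
    sire_id = sire_ids,
    p_poly_sire = p_sire,
    p_poly_offspring = p_off,
    p_leth = p_leth,
    p_total = total_risk(p_leth, p_off),
    family = fit$family,
    variant = fit$variant
  )
}
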