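# The risk transforms are the method core: per-locus lethal risk, multi-locus
# union, polygenic transforms per model family, transmission and blending.

test_that("per-locus lethal risk follows sire transmission x dam frequency x penetrance", {
  expect_equal(lethal_risk_locus("Aa", 0.05, 1.0), 0.025)
  expect_equal(lethal_risk_locus("AA", 0.05, 0.8), 0)
  expect_equal(lethal_risk_locus("aa", 0.04, 0.6), 0.024)
  # dosage coding is equivalent to genotype strings
  expect_equal(lethal_risk_locus(1, 0.05, 1.0), 0.025)
  expect_equal(lethal_risk_locus(c(0, 1, 2), 0.1, 0.5),
               c(0, 0.025, 0.05))
  expect_error(lethal_risk_locus("aA?", 0.05, 1), "sire_genotype")
  expect_error(lethal_risk_locus("Aa", 1.5, 1), "p_a")
  expect_error(lethal_risk_locus("Aa", 0.05, 0), "penetrance")
})

test_that("multi-locus lethal risk matches the exhaustive union oracle", {
  expect_equal(lethal_risk_total(numeric(0)), 0)
  expect_equal(lethal_risk_total(c(0.025, 0.025)), 1 - 0.975^2)

  # oracle: enumerate all 2^n death patterns and add up disjoint probabilities
  union_oracle <- function(p) {
    n <- length(p)
    total <- 0
    for (mask in 1:(2^n - 1)) {
      bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
      total <- total + prod(ifelse(bits, p, 1 - p))
    }
    total
  }
  withr::with_seed(42, {
    for (n in c(3, 7, 12)) {
      p <- runif(n, 0, 0.2)
      expect_equal(lethal_risk_total(p), union_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("polygenic risk transforms evaluate their closed forms", {
  expect_equal(poly_risk_probit(0, 0), 0.5)
  expect_equal(poly_risk_probit(-1.4909, 0), 0.068, tolerance = 1e-4)
  expect_equal(poly_risk_logit(0, 0), 0.5)
  expect_equal(poly_risk_logit(-2.618, 0), 0.068, tolerance = 1e-3)
  expect_equal(poly_risk_logit(700, 0), 1)   # saturates, no overflow
  expect_equal(poly_risk_logit(-700, 0), 0)

  # linear transform: threshold from N(pi, pi(1-pi)) and matching residual
  tau <- 0.068 + sqrt(0.068 * 0.932) * qnorm(1 - 0.068)
  expect_equal(tau, 0.4433, tolerance = 1e-3)
  expect_equal(poly_risk_linear(0.068, 0, 0.068), 0.068, tolerance = 1e-12)
  expect_error(poly_risk_linear(0.1, 0, 1), "incidence")

  # monotone in the breeding value (away from double-precision saturation)
  a <- seq(-1, 1, length.out = 41)
  expect_true(all(diff(poly_risk_probit(-1.5, a)) > 0))
  expect_true(all(diff(poly_risk_logit(-2.6, a)) > 0))
  expect_true(all(diff(poly_risk_linear(0.07, a, 0.068)) > 0))
})

test_that("transmission halves the sire risk and blending is an independent union", {
  expect_equal(transmitted_poly_risk(0.136), 0.068)
  expect_equal(transmitted_poly_risk(0), 0)
  expect_equal(transmitted_poly_risk(1), 0.5)
  expect_equal(total_risk(0, 0.05), 0.05)
  expect_equal(total_risk(0.025, 0.034), 1 - 0.975 * 0.966)
  expect_equal(total_risk(1, 0.3), 1)

  # commutative and associative when folded over components
  withr::with_seed(7, {
    p <- runif(6)
    fold <- function(v) Reduce(total_risk, v)
    expect_equal(fold(p), fold(rev(p)), tolerance = 1e-12)
    expect_equal(total_risk(fold(p[1:3]), fold(p[4:6])), fold(p),
                 tolerance = 1e-12)
  })
})

test_that("all risk outputs stay in [0,1] under fuzzing", {
  withr::with_seed(99, {
    for (i in 1:200) {
      mu <- rnorm(1, 0, 5)
      a <- rnorm(1, 0, 5)
      inc <- runif(1, 0.001, 0.999)
      vals <- c(poly_risk_probit(mu, a), poly_risk_logit(mu, a),
                poly_risk_linear(mu, a, inc),
                lethal_risk_total(runif(8)),
                total_risk(runif(1), runif(1)))
      expect_true(all(vals >= 0 & vals <= 1))
    }
  })
})

test_that("probit and logit risk rank sires identically for rare outcomes", {
  # both transforms are strictly increasing in mu + a, so orderings agree
  withr::with_seed(11, {
    agree <- vapply(1:100, function(i) {
      a <- rnorm(50, 0, 0.3)
      rp <- rank(poly_risk_probit(qnorm(0.07), a))
      rl <- rank(poly_risk_logit(qlogis(0.07), a))
      all(rp == rl)
    }, TRUE)
    expect_gte(mean(agree), 0.99)
  })
})

test_that("sire risk pipeline blends components and validates inputs", {
  fit <- lethalrisk:::new_gp_fit(
    family = "probit", variant = 1L, mu = -1.5, d = NULL,
    gebv = tibble::tibble(id = 1:3, gebv = c(-0.2, 0, 0.2)),
    sigma2_a = 0.08, sigma2_e = 1, incidence = 0.068, n_train = 100,
    convergence = list(converged = TRUE, boundary = FALSE, iterations = 5))

  # non-carrier: total risk equals the transmitted polygenic risk
  geno <- matrix(0L, 3, 2, dimnames = list(1:3, NULL))
  r0 <- sire_risk_pipeline(fit, 1:3, geno, p_a = c(0.05, 0.04),
                           penetrance = c(1, 1))
  expect_equal(r0$p_leth, rep(0, 3))
  expect_equal(r0$p_total, r0$p_poly_offspring)
  expect_equal(r0$p_poly_offspring, 0.5 * r0$p_poly_sire)

  # carrier at every locus: p_leth follows the product formula
  geno1 <- matrix(1L, 1, 20, dimnames = list("2", NULL))
  r1 <- sire_risk_pipeline(fit, 2, geno1, p_a = rep(0.05, 20),
                           penetrance = rep(1, 20))
  expect_equal(r1$p_leth, 1 - 0.975^20, tolerance = 1e-12)

  # equal breeding value and carrier status => identical prediction
  fit2 <- fit
  fit2$gebv <- tibble::tibble(id = 1:2, gebv = c(0.1, 0.1))
  g2 <- matrix(1L, 2, 2, dimnames = list(1:2, NULL))
  r2 <- sire_risk_pipeline(fit2, 1:2, g2, p_a = c(0.05, 0.04),
                           penetrance = c(0.8, 0.8))
  expect_equal(r2$p_total[1], r2$p_total[2])

  # omitting lethal information gives the non-separated prediction
  conv <- sire_risk_pipeline(fit, 1:3)
  expect_equal(conv$p_total, conv$p_poly_offspring)

  # missing genotype raises an error naming the sire
  geno_na <- geno; geno_na[2, 1] <- NA
  expect_error(
    sire_risk_pipeline(fit, 1:3, geno_na, p_a = c(0.05, 0.04),
                       penetrance = c(1, 1)), "sire 2")
  expect_error(sire_risk_pipeline(fit, 1:4), "breeding values")
})
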