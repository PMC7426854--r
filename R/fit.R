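#' Fit genomic mixed models for a binary mortality trait
#'
#' All three families share the linear predictor `eta = 1 mu [+ x d] + Z g`
#' with `g ~ N(0, G sigma_a^2)` over every individual in the GRM; training
#' individuals are the rows of `data` with non-missing `y` and `train =
#' TRUE`, and the remaining individuals in the GRM (e.g. unphenotyped
#' candidate sires) receive breeding values through the joint solve.
#'
#' * `fit_linear()` treats the 0/1 outcome as Gaussian and estimates
#'   `sigma_a^2`, `sigma_e^2` by exact restricted maximum likelihood,
#'   profiled over the variance ratio after a spectral decomposition of the
#'   training-block GRM. Supplying `varcomp` skips estimation.
#' * `fit_probit()` / `fit_logit()` fit the threshold (liability) and
#'   logistic mixed model by penalized quasi-likelihood Newton iterations
#'   with the residual scale fixed (1 for probit, with threshold 0; the
#'   standard logistic variance pi^2/3 for logit). The genetic variance on
#'   the link scale is fixed at the value implied by the linear-REML
#'   observed-scale heritability mapped through the observed-to-liability
#'   transform (see [liability_heritability()]), unless `sigma2_a` is given.
#'
#' All solvers are deterministic: refits reproduce breeding values
#' bit-for-bit. `seed` is accepted for interface uniformity and ignored.
#'
#' @param data tibble with columns `id`, `y` (0/1, `NA` for unphenotyped) and
#'   optionally the lethal-status covariate column named by `covariate`
#'   (1 if homozygous for the lethal allele at any locus).
#' @param grm a [build_grm()] object covering at least all training ids.
#' @param covariate optional name of the fixed lethal-regression column
#'   (model variant 2).
#' @param train optional logical vector marking training rows of `data`
#'   (default: rows with non-missing `y`).
#' @param varcomp optional list `list(sigma2_a =, sigma2_e =)` to fix the
#'   linear-model variance components.
#' @param sigma2_a optional fixed link-scale genetic variance
#'   (probit/logit).
#' @param ridge diagonal stabilizer added to the training GRM block.
#' @param maxit,tol iteration cap and convergence tolerance.
#' @param seed ignored (deterministic solvers); kept for call uniformity.
#' @return A `gp_fit` object; see [tidy.gp_fit()] and [glance.gp_fit()].
#' @examples
#' # two individuals, identity GRM, fixed variance ratio 1
#' g <- structure(list(mat = diag(2), ids = 1:2, locus_set = "markers",
#'                     loci = 1:2, freq = c(.5, .5)), class = "grm")
#' d <- tibble::tibble(id = 1:2, y = c(0, 1))
#' f <- fit_linear(d, g, varcomp = list(sigma2_a = 1, sigma2_e = 1))
#' glance(f)$mu           # 0.5
#' tidy(f)$gebv           # -0.25, 0.25
#' @export
fit_linear <- function(data, grm, covariate = NULL, train = NULL,
                       varcomp = NULL, ridge = 1e-6, maxit = 100,
                       tol = 1e-8, seed = NULL) {
  fit_gblup(data, grm, family = "linear", covariate = covariate,
            train = train, varcomp = varcomp, ridge = ridge,
            maxit = maxit, tol = tol)
}

#' @rdname fit_linear
#' @export
fit_probit <- function(data, grm, covariate = NULL, train = NULL,
                       sigma2_a = NULL, ridge = 1e-6, maxit = 50,
                       tol = 1e-7, seed = NULL) {
  fit_gblup(data, grm, family = "probit", covariate = covariate,
            train = train, sigma2_a = sigma2_a, ridge = ridge,
            maxit = maxit, tol = tol)
}

#' @rdname fit_linear
#' @export
fit_logit <- function(data, grm, covariate = NULL, train = NULL,
                      sigma2_a = NULL, ridge = 1e-6, maxit = 50,
                      tol = 1e-7, seed = NULL) {
  fit_gblup(data, grm, family = "logit", covariate = covariate,
            train = train, sigma2_a = sigma2_a, ridge = ridge,
            maxit = maxit, tol = tol)
}

# Shared engine. `eigen_G` lets callers that fit several models on the same
# training set reuse the spectral decomposition of the training GRM block.
fit_gblup <- function(data, grm, family, covariate = NULL, train = NULL,
                      varcomp = NULL, sigma2_a = NULL, ridge = 1e-6,
                      maxit = 50, tol = 1e-7, eigen_G = NULL) {
  if (is.null(train)) train <- !is.na(data$y)
  tr_ids <- data$id[train]
  y <- as.numeric(data$y[train])
  if (anyNA(y)) stop("training outcomes contain NA", call. = FALSE)
  rows <- match(tr_ids, grm$ids)
  if (anyNA(rows)) stop("GRM does not cover all training ids", call. = FALSE)
  X <- cbind(intercept = rep(1, length(y)))
  if (!is.null(covariate)) {
    xv <- data[[covariate]][train]
    if (is.null(xv) || anyNA(xv))
      stop(sprintf("covariate column `%s` missing or NA", covariate),
           call. = FALSE)
    X <- cbind(X, lethal = as.numeric(xv))
  }
  variant <- if (!is.null(covariate)) 2L
             else if (grm$locus_set == "markers+lethal") 3L else 1L
  n <- length(y)
  incidence <- mean(y)

  if (var(y) == 0) {
    return(new_gp_fit(
      family = family, variant = variant, mu = link_of(family, incidence),
      d = if (variant == 2L) 0 else NULL,
      gebv = tibble::tibble(id = grm$ids, gebv = 0),
      sigma2_a = 0, sigma2_e = if (family == "linear") 0 else 1,
      incidence = incidence, n_train = n,
      convergence = list(converged = FALSE, boundary = TRUE, iterations = 0,
                         note = "zero outcome variance")))
  }

  Gtt <- grm$mat[rows, rows, drop = FALSE]
  diag(Gtt) <- diag(Gtt) + ridge
  cand <- setdiff(seq_along(grm$ids), rows)
  Gct <- grm$mat[cand, rows, drop = FALSE]

  if (family == "linear") {
    if (is.null(eigen_G)) eigen_G <- eigen(Gtt, symmetric = TRUE)
    fit <- reml_linear(y, X, eigen_G, varcomp)
    a_tr <- fit$a_train
    Vinv_r <- fit$Vinv_r
    conv <- fit$convergence
    mu <- unname(fit$beta[1])
    d <- if (variant == 2L) unname(fit$beta[2]) else NULL
    s2a <- fit$sigma2_a; s2e <- fit$sigma2_e
  } else {
    if (is.null(sigma2_a))
      sigma2_a <- link_scale_variance(y, X, Gtt, family, eigen_G)
    fit <- pql_binary(y, X, Gtt, family, sigma2_a, maxit, tol)
    a_tr <- fit$a_train
    Vinv_r <- fit$Vinv_r
    conv <- fit$convergence
    mu <- unname(fit$beta[1])
    d <- if (variant == 2L) unname(fit$beta[2]) else NULL
    s2a <- sigma2_a
    s2e <- if (family == "probit") 1 else pi^2 / 3
  }

  gebv <- numeric(length(grm$ids))
  gebv[rows] <- a_tr
  if (length(cand) > 0) gebv[cand] <- drop(Gct %*% Vinv_r) * s2a
  new_gp_fit(
    family = family, variant = variant, mu = mu, d = d,
    gebv = tibble::tibble(id = grm$ids, gebv = gebv),
    sigma2_a = s2a, sigma2_e = s2e, incidence = incidence, n_train = n,
    convergence = conv)
}

# Exact REML for y = X beta + a + e, a ~ N(0, G s2a), via the spectral
# decomposition G = U diag(d) U'. The restricted likelihood is profiled to a
# one-dimensional search over delta = s2e / s2a.
reml_linear <- function(y, X, eg, varcomp = NULL) {
  U <- eg$vectors
  dvals <- pmax(eg$values, 0)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)
  n <- length(y)

  gls <- function(delta) {
    w <- dvals + delta
    XtW <- Xt / w
    A <- crossprod(XtW, Xt)
    beta <- solve(A, crossprod(XtW, yt))
    r <- yt - Xt %*% beta
    rss <- sum(r^2 / w)
    list(beta = beta, r = r, rss = rss, w = w, A = A)
  }
  neg_restricted_ll <- function(log_delta) {
    g <- gls(exp(log_delta))
    s2a <- g$rss / (n - p)
    0.5 * ((n - p) * log(s2a) + sum(log(g$w)) +
             determinant(g$A, logarithm = TRUE)$modulus)
  }

  if (is.null(varcomp)) {
    opt <- optimize(neg_restricted_ll, c(log(1e-4), log(1e6)), tol = 1e-10)
    delta <- exp(opt$minimum)
    g <- gls(delta)
    s2a <- g$rss / (n - p)
    s2e <- delta * s2a
    boundary <- opt$minimum < log(1e-4) + 1e-6 || opt$minimum > log(1e6) - 1e-6
    conv <- list(converged = TRUE, boundary = boundary, iterations = NA_integer_,
                 note = "REML profile optimum")
  } else {
    s2a <- varcomp$sigma2_a
    s2e <- varcomp$sigma2_e
    delta <- s2e / s2a
    g <- gls(delta)
    conv <- list(converged = TRUE, boundary = FALSE, iterations = 0,
                 note = "fixed variance components")
  }
  # BLUP: a = G V^{-1} (y - X beta) * s2a with V = s2a (G + delta I)
  r_rot <- g$r                                 # U' (y - X beta)
  Vinv_r <- drop(U %*% (r_rot / (s2a * g$w)))  # V^{-1} residual, original basis
  a_train <- drop(U %*% (dvals * r_rot / g$w))
  list(beta = drop(g$beta), sigma2_a = s2a, sigma2_e = s2e,
       a_train = a_train, Vinv_r = Vinv_r, convergence = conv)
}

# Link-scale genetic variance implied by the linear-model heritability and
# the observed-to-liability transform.
link_scale_variance <- function(y, X, Gtt, family, eigen_G = NULL) {
  if (is.null(eigen_G)) eigen_G <- eigen(Gtt, symmetric = TRUE)
  lf <- reml_linear(y, X, eigen_G)
  h2_obs <- lf$sigma2_a / (lf$sigma2_a + lf$sigma2_e)
  h2_obs <- min(max(h2_obs, 1e-5), 0.95)
  inc <- min(max(mean(y), 1e-4), 1 - 1e-4)
  h2_l <- min(liability_heritability(h2_obs, inc), 0.95)
  s2e <- if (family == "probit") 1 else pi^2 / 3
  h2_l * s2e / (1 - h2_l)
}

# Penalized quasi-likelihood for the binary mixed model with fixed genetic
# variance: iterate the weighted working model z = X beta + a + eps,
# eps ~ N(0, W^{-1}), solving V = s2a G + W^{-1} directly.
pql_binary <- function(y, X, Gtt, family, sigma2_a, maxit, tol) {
  n <- length(y)
  linkinv <- if (family == "probit") pnorm else plogis
  dmu <- if (family == "probit") dnorm else function(x) plogis(x) * plogis(-x)
  eta_cap <- if (family == "probit") 7 else 25

  inc <- min(max(mean(y), 1 / (2 * n)), 1 - 1 / (2 * n))
  eta <- rep(link_of(family, inc), n)
  a <- rep(0, n)
  converged <- FALSE
  clamped <- FALSE
  it <- 0
  beta <- NULL
  Vinv_r <- NULL
  for (it in seq_len(maxit)) {
    eta_c <- pmin(pmax(eta, -eta_cap), eta_cap)
    if (any(eta_c != eta)) clamped <- TRUE
    mu <- linkinv(eta_c)
    g1 <- dmu(eta_c)
    w <- pmax(g1^2 / (mu * (1 - mu)), 1e-10)
    z <- eta_c + (y - mu) / pmax(g1, 1e-10)
    V <- sigma2_a * Gtt
    diag(V) <- diag(V) + 1 / w
    R <- chol(V)
    Rt <- t(R)
    ViX <- backsolve(R, forwardsolve(Rt, X))
    Viz <- backsolve(R, forwardsolve(Rt, z))
    A <- crossprod(X, ViX)
    beta <- solve(A, crossprod(X, Viz))
    Vinv_r <- drop(Viz - ViX %*% beta)
    a_new <- sigma2_a * drop(Gtt %*% Vinv_r)
    eta_new <- drop(X %*% beta) + a_new
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    a <- a_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = drop(beta), a_train = a, Vinv_r = drop(Vinv_r),
       convergence = list(converged = converged, boundary = clamped,
                          iterations = it,
                          note = if (converged) "PQL converged"
                                 else "PQL iteration cap reached"))
}

link_of <- function(family, p) {
  p <- min(max(p, 1e-12), 1 - 1e-12)
  switch(family,
         linear = p,
         probit = qnorm(p),
         logit = qlogis(p))
}

new_gp_fit <- function(family, variant, mu, d, gebv, sigma2_a, sigma2_e,
                       incidence, n_train, convergence) {
  structure(list(family = family, variant = variant, mu = mu, d = d,
                 gebv = gebv, sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 incidence = incidence, n_train = n_train,
                 convergence = convergence),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "<gp_fit> %s (variant %d): mu=%.4f%s, sigma2_a=%.4g, sigma2_e=%.4g, n=%d%s\n",
    x$family, x$variant, x$mu,
    if (!is.null(x$d)) sprintf(", d=%.4f", x$d) else "",
    x$sigma2_a, x$sigma2_e, x$n_train,
    if (isTRUE(x$convergence$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Per-individual breeding values of a fitted model
#'
#' @param x a `gp_fit`.
#' @param ... unused.
#' @return Tibble with `id` and `gebv` (link/liability scale for
#'   probit/logit, observed scale for linear) for every individual in the
#'   GRM, training and candidates alike.
#' @method tidy gp_fit
#' @export
tidy.gp_fit <- function(x, ...) x$gebv

#' One-row model summary of a fitted genomic model
#'
#' @param x a `gp_fit`.
#' @param ... unused.
#' @return One-row tibble: family, variant, estimates, variance components,
#'   training incidence and convergence flags.
#' @method glance gp_fit
#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, variant = x$variant, mu = x$mu,
    d = if (is.null(x$d)) NA_real_ else x$d,
    sigma2_a = x$sigma2_a, sigma2_e = x$sigma2_e,
    incidence = x$incidence, n_train = x$n_train,
    iterations = x$convergence$iterations,
    converged = x$convergence$converged,
    boundary = x$convergence$boundary)
}
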