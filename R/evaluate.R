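#' Validation statistics for predicted risk probabilities
#'
#' `risk_accuracy()` is the Pearson correlation between predicted total risk
#' probabilities and the observed proportion of offspring mortality across
#' validation sires; `bias_slope()` is the ordinary least-squares regression
#' coefficient of observed on predicted (1 = calibrated); `gebv_accuracy()`
#' is the correlation between estimated and true breeding values.
#'
#' @param predicted,observed numeric vectors over the same sires (length
#'   >= 3 for the risk statistics).
#' @return A single number; `NA` with a warning when a vector has zero
#'   variance (undefined statistic).
#' @examples
#' risk_accuracy(c(0, .1, .2), c(.05, .05, .20))  # 0.866
#' bias_slope(c(0, .1, .2), c(.05, .05, .20))     # 0.75
#' @export
risk_accuracy <- function(predicted, observed) {
  check_eval_pair(predicted, observed)
  if (var(predicted) == 0 || var(observed) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(predicted, observed)
}

#' @rdname risk_accuracy
#' @export
bias_slope <- function(predicted, observed) {
  check_eval_pair(predicted, observed)
  if (var(predicted) == 0) {
    warning("zero variance in predictions: slope undefined", call. = FALSE)
    return(NA_real_)
  }
  cov(predicted, observed) / var(predicted)
}

#' @param estimated,true breeding values over the same individuals.
#' @rdname risk_accuracy
#' @export
gebv_accuracy <- function(estimated, true) {
  risk_accuracy(estimated, true)
}

check_eval_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 3)
    stop("need at least 3 paired values", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("missing values in evaluation vectors", call. = FALSE)
  invisible(TRUE)
}

#' Paired t-test of a metric across matched replicates
#'
#' Two-sided paired t-test on per-replicate differences of an accuracy (or
#' any other) metric, matched by replicate. Zero-variance differences are
#' degenerate: all-zero differences are reported as "no difference"
#' (`t = 0`, `p = 1`); a constant non-zero shift leaves the statistic
#' undefined and is flagged.
#'
#' @param a,b equal-length (>= 2) metric series from matched replicates.
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `p_value`, `df`, `n`, `degenerate`.
#' @export
paired_replicate_test <- function(a, b) {
  if (length(a) != length(b))
    stop("metric series must have equal length", call. = FALSE)
  if (length(a) < 2)
    stop("need at least 2 matched replicates", call. = FALSE)
  d <- a - b
  if (anyNA(d)) {
    warning("dropping replicate pairs with undefined metrics", call. = FALSE)
    d <- d[!is.na(d)]
    if (length(d) < 2)
      return(tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                            p_value = NA_real_, df = NA_real_,
                            n = length(d), degenerate = TRUE))
  }
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(estimate = 0, statistic = 0, p_value = 1,
                            df = length(d) - 1, n = length(d),
                            degenerate = TRUE))
    }
    return(tibble::tibble(estimate = mean(d), statistic = NA_real_,
                          p_value = NA_real_, df = length(d) - 1,
                          n = length(d), degenerate = TRUE))
  }
  tt <- t.test(d)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 n = length(d), degenerate = FALSE)
}

#' Observed offspring mortality proportion per sire
#'
#' @param phenotypes phenotype tibble with dataset flags
#'   (see [make_datasets()]).
#' @param pedigree matching pedigree.
#' @return Tibble `sire_id`, `n_offspring`, `observed_mortality` over sires
#'   of test-year offspring.
#' @export
observed_sire_mortality <- function(phenotypes, pedigree) {
  test_ids <- phenotypes$id[phenotypes$role == "test"]
  off <- pedigree[match(test_ids, pedigree$id), ]
  tibble::tibble(sire_id = off$sire,
                 y = phenotypes$y[match(test_ids, phenotypes$id)]) |>
    dplyr::group_by(.data$sire_id) |>
    dplyr::summarise(n_offspring = dplyr::n(),
                     observed_mortality = mean(.data$y)) |>
    dplyr::rename(sire_id = 1)
}
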