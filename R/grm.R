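#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M M' / (2 * sum_k p_k (1 - p_k))` where `M` is the dosage matrix
#' centred by twice the allele frequency at each locus. Frequencies are
#' computed from the supplied individuals by default (`freq_source =
#' "panel"`), or can be restricted to a subset of ids. Simulated QTLs are
#' never included; the `"markers"` locus set excludes the recessive lethal
#' loci (the matrix `G` of the models that separate the two components),
#' while `"markers+lethal"` includes them (`G*`).
#'
#' Monomorphic loci (zero variance in the observed individuals) contribute
#' nothing to relationships and are dropped with a warning.
#'
#' @param panel genotype panel.
#' @param ids individuals to include (default: all in the panel).
#' @param loci `"markers"` or `"markers+lethal"`.
#' @param freq_ids ids used to compute allele frequencies (default `ids`).
#' @return A `grm` object: the relationship matrix with attributes `ids`,
#'   `locus_set`, `loci` (map indices used) and `freq`.
#' @examples
#' map <- make_locus_map(2, 20, 2, 1, seed = 1)
#' ped <- make_pedigree(1, 2, 10, 4, 10, seed = 2)
#' panel <- gene_drop(ped, simulate_founder_haplotypes(map, 14, seed = 3), seed = 4)
#' G <- build_grm(panel)
#' mean(diag(G$mat))
#' @export
build_grm <- function(panel, ids = NULL,
                      loci = c("markers", "markers+lethal"),
                      freq_ids = NULL) {
  loci <- match.arg(loci)
  roles <- if (loci == "markers") "marker" else c("marker", "lethal")
  idx <- which(panel$map$role %in% roles)
  if (length(idx) < 1) stop("no loci in the requested set", call. = FALSE)
  if (is.null(ids)) ids <- panel$pedigree$id
  if (length(ids) < 2) stop("need at least 2 individuals", call. = FALSE)
  D <- dosages(panel, idx, ids)
  p <- if (is.null(freq_ids)) colMeans(D) / 2
       else colMeans(dosages(panel, idx, freq_ids)) / 2
  poly <- p > 0 & p < 1
  if (!any(poly))
    stop("all loci monomorphic: VanRaden denominator is zero", call. = FALSE)
  if (any(!poly)) {
    warning(sprintf("dropping %d monomorphic loci from the GRM", sum(!poly)),
            call. = FALSE)
    D <- D[, poly, drop = FALSE]
    p <- p[poly]
    idx <- idx[poly]
  }
  M <- sweep(matrix(as.numeric(D), nrow(D)), 2, 2 * p)
  G <- tcrossprod(M) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(ids, ids)
  structure(list(mat = G, ids = ids, locus_set = loci,
                 loci = idx, freq = p),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals, %d loci (%s), mean diagonal %.3f\n",
              nrow(x$mat), length(x$loci), x$locus_set, mean(diag(x$mat))))
  invisible(x)
}
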