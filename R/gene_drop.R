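#' Drop founder haplotypes through a pedigree
#'
#' Simulates transmission of whole chromosomes from parents to offspring.
#' Each non-founder receives one recombinant gamete from each parent; the
#' crossover count per chromosome is Poisson with mean equal to the map
#' length in Morgans (Haldane model, no interference) and crossover positions
#' are uniform along the chromosome.
#'
#' @param pedigree tibble from [make_pedigree()] (founders first, parents on
#'   earlier rows than offspring).
#' @param founders `founder_haplotypes` object covering every founder.
#' @param seed optional integer seed.
#'
#' @return A `genotype_panel`: phased haplotypes (`H1` paternal, `H2`
#'   maternal; raw 0/1 matrices stored loci x individuals), the locus `map`
#'   and the `pedigree`.
#' @examples
#' map <- make_locus_map(2, 5, 2, 1, seed = 1)
#' ped <- make_pedigree(1, 2, 10, 4, 10, seed = 2)
#' fh <- simulate_founder_haplotypes(map, 14, seed = 3)
#' panel <- gene_drop(ped, fh, seed = 4)
#' dim(dosages(panel))
#' @export
gene_drop <- function(pedigree, founders, seed = NULL) {
  check_pedigree(pedigree)
  map <- founders$map
  founder_rows <- which(is.na(pedigree$sire) & is.na(pedigree$dam))
  n_founders <- length(founder_rows)
  if (!all(founder_rows == seq_len(n_founders)))
    stop("pedigree must list all founders before any offspring", call. = FALSE)
  if (ncol(founders$H1) < n_founders)
    stop("founder haplotypes cover fewer individuals than pedigree founders",
         call. = FALSE)
  N <- nrow(pedigree)
  L <- nrow(map)
  H1 <- matrix(raw(1), L, N)
  H2 <- matrix(raw(1), L, N)
  H1[, seq_len(n_founders)] <- founders$H1[, seq_len(n_founders)]
  H2[, seq_len(n_founders)] <- founders$H2[, seq_len(n_founders)]
  if (N > n_founders) {
    with_seed_(seed,
      drop_rows(H1, H2, pedigree, map, n_founders + 1L, N))
  }
  new_genotype_panel(H1, H2, map, pedigree)
}

# Fill pedigree rows [from, to] of H1/H2 in place (raw matrices shared with
# the caller); parents must already be filled.
drop_rows <- function(H1, H2, pedigree, map, from, to) {
  sire_row <- match(pedigree$sire, pedigree$id)
  dam_row <- match(pedigree$dam, pedigree$id)
  sire_row[is.na(sire_row)] <- 0L
  dam_row[is.na(dam_row)] <- 0L
  chr_first <- vapply(split(map$locus, map$chr), min, 1)
  chr_last <- vapply(split(map$locus, map$chr), max, 1)
  cpp_gene_drop(H1, H2, sire_row, dam_row, as.integer(from), as.integer(to),
                as.integer(chr_first), as.integer(chr_last),
                map$pos_cm / 100)
  invisible(NULL)
}

new_genotype_panel <- function(H1, H2, map, pedigree) {
  structure(list(H1 = H1, H2 = H2, map = map, pedigree = pedigree),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d loci (%s)\n",
              ncol(x$H1), nrow(x$H1),
              paste(sprintf("%s: %d", names(table(x$map$role)),
                            table(x$map$role)), collapse = ", ")))
  invisible(x)
}

#' Allele dosages from a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param loci integer locus indices (default all).
#' @param ids individual ids (default all).
#' @return Integer matrix of 0/1/2 dosages of the counted allele,
#'   individuals x loci, with ids as rownames.
#' @export
dosages <- function(panel, loci = NULL, ids = NULL) {
  if (is.null(loci)) loci <- seq_len(nrow(panel$H1))
  cols <- if (is.null(ids)) seq_len(ncol(panel$H1))
          else match(ids, panel$pedigree$id)
  if (anyNA(cols)) stop("unknown individual ids", call. = FALSE)
  d <- t(matrix(as.integer(panel$H1[loci, cols, drop = FALSE]) +
                as.integer(panel$H2[loci, cols, drop = FALSE]),
                nrow = length(loci)))
  rownames(d) <- panel$pedigree$id[cols]
  d
}

#' Audit Mendelian consistency of a gene-dropped panel
#'
#' Checks, for every non-founder and locus, that the paternal haplotype
#' allele occurs in the sire and the maternal haplotype allele in the dam.
#'
#' @param panel a `genotype_panel` with phase (as produced by [gene_drop()]).
#' @return Number of violating (individual, locus) cells (0 when consistent).
#' @export
mendelian_violations <- function(panel) {
  ped <- panel$pedigree
  off <- which(!is.na(ped$sire))
  if (length(off) == 0) return(0L)
  sr <- match(ped$sire[off], ped$id)
  dr <- match(ped$dam[off], ped$id)
  bad_pat <- (panel$H1[, off, drop = FALSE] != panel$H1[, sr, drop = FALSE]) &
             (panel$H1[, off, drop = FALSE] != panel$H2[, sr, drop = FALSE])
  bad_mat <- (panel$H2[, off, drop = FALSE] != panel$H1[, dr, drop = FALSE]) &
             (panel$H2[, off, drop = FALSE] != panel$H2[, dr, drop = FALSE])
  sum(bad_pat) + sum(bad_mat)
}

#' Observed allele frequencies in a panel subset
#'
#' @inheritParams dosages
#' @return Numeric vector of counted-allele frequencies, one per locus.
#' @export
allele_freq <- function(panel, loci = NULL, ids = NULL) {
  colMeans(dosages(panel, loci, ids)) / 2
}
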