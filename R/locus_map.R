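#' Build a locus map with marker, QTL and lethal roles
#'
#' Lays out equidistant loci along each chromosome and assigns each locus a
#' role (`marker`, `qtl` or `lethal`) and a base allele frequency. Marker and
#' QTL frequencies are drawn uniformly from `marker_freq`; lethal-locus
#' frequencies from the narrow `lethal_freq` band typical of segregating
#' recessive lethal haplotypes in dairy cattle (0.04-0.05 by default).
#'
#' QTL positions are sampled at random within each chromosome. Lethal loci are
#' placed on distinct chromosomes whenever `n_chr >= n_lethal`; otherwise they
#' are spread round-robin and maximally separated within a chromosome so that
#' the independence assumption of the multi-locus risk formula remains
#' reasonable.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr neutral SNP markers per chromosome (may be 0 when
#'   only the trait architecture is needed, e.g. for mortality-partition runs).
#' @param qtl_per_chr QTLs per chromosome (66 by default, giving 1,980 on a
#'   30-chromosome genome).
#' @param n_lethal total number of recessive lethal loci.
#' @param chr_length_cm chromosome length in centimorgans.
#' @param lethal_freq,marker_freq length-2 numeric ranges for base allele
#'   frequencies.
#' @param seed optional integer seed.
#'
#' @return A tibble with one row per locus: `locus` (index), `chr`, `pos_cm`,
#'   `freq` (base frequency of the counted allele; for lethal loci the counted
#'   allele is the lethal one) and `role`.
#' @examples
#' map <- make_locus_map(n_chr = 3, markers_per_chr = 10, qtl_per_chr = 4,
#'                       n_lethal = 2, seed = 1)
#' dplyr::count(map, role)
#' @export
make_locus_map <- function(n_chr, markers_per_chr, qtl_per_chr, n_lethal,
                           chr_length_cm = 100,
                           lethal_freq = c(0.04, 0.05),
                           marker_freq = c(0.05, 0.5),
                           seed = NULL) {
  if (n_chr < 1) stop_bad_arg("n_chr", "must be >= 1")
  if (chr_length_cm < 0) stop_bad_arg("chr_length_cm", "must be >= 0")
  check_prob(lethal_freq, "lethal_freq")
  check_prob(marker_freq, "marker_freq")

  lethal_per_chr <- table(factor(((seq_len(n_lethal) - 1L) %% n_chr) + 1L,
                                 levels = seq_len(n_chr)))
  with_seed_(seed, {
    chrs <- purrr::map(seq_len(n_chr), function(c) {
      n_leth_c <- as.integer(lethal_per_chr[[c]])
      n_loci <- markers_per_chr + qtl_per_chr + n_leth_c
      if (n_loci < 1) return(NULL)
      pos <- seq(0, chr_length_cm, length.out = max(n_loci, 2))[seq_len(n_loci)]
      role <- rep("marker", n_loci)
      # lethal loci first, maximally separated; QTLs among the rest
      if (n_leth_c > 0) {
        leth_idx <- round(seq(1, n_loci, length.out = n_leth_c + 2))[-c(1, n_leth_c + 2)]
        if (n_leth_c == 1) leth_idx <- round(n_loci / 2)
        role[leth_idx] <- "lethal"
      }
      free <- which(role == "marker")
      role[sample(free, qtl_per_chr)] <- "qtl"
      freq <- runif(n_loci, marker_freq[1], marker_freq[2])
      freq[role == "lethal"] <- runif(sum(role == "lethal"),
                                      lethal_freq[1], lethal_freq[2])
      tibble::tibble(chr = c, pos_cm = pos, freq = freq, role = role)
    })
    map <- dplyr::bind_rows(chrs)
    map$locus <- seq_len(nrow(map))
    dplyr::relocate(map, "locus")
  })
}

check_locus_map <- function(map) {
  stopifnot(all(c("locus", "chr", "pos_cm", "freq", "role") %in% names(map)))
  check_prob(map$freq, "map$freq")
  bad <- map |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos_cm, strictly = FALSE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0)
    stop("locus map positions must be non-decreasing within a chromosome",
         call. = FALSE)
  invisible(map)
}
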