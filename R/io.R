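# Readers and writers for the plain-text exchange formats: pedigree CSV,
# dosage CSV, PLINK-style .ped/.map, phenotype and risk tables.

#' Read and write the exchange file formats
#'
#' Pedigree CSV uses columns `id,sire,dam,sex,year,alive` with `0` for an
#' unknown parent. The dosage CSV is individuals x loci with an `id` column.
#' The PLINK-style pair writes one `.ped` row per individual (family id,
#' id, sire, dam, sex 1/2, phenotype, two alleles per locus coded 1/2) and a
#' 4-column `.map` (`chr`, locus name, cM, position index).
#'
#' @param pedigree,panel,phenotypes,risk,map objects to write.
#' @param path,prefix file path (or path prefix for the `.ped`/`.map` pair).
#' @name lethalrisk-io
NULL

#' @rdname lethalrisk-io
#' @export
write_pedigree_csv <- function(pedigree, path) {
  out <- pedigree
  out$sire[is.na(out$sire)] <- 0L
  out$dam[is.na(out$dam)] <- 0L
  out$alive <- as.integer(out$alive)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lethalrisk-io
#' @export
read_pedigree_csv <- function(path) {
  d <- read.csv(path)
  tibble::tibble(
    id = as.integer(d$id),
    sire = ifelse(d$sire == 0, NA_integer_, as.integer(d$sire)),
    dam = ifelse(d$dam == 0, NA_integer_, as.integer(d$dam)),
    sex = d$sex,
    year = as.integer(d$year),
    alive = as.logical(d$alive)
  )
}

#' @rdname lethalrisk-io
#' @export
write_locus_map_csv <- function(map, path) {
  write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lethalrisk-io
#' @export
read_locus_map_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' @rdname lethalrisk-io
#' @export
write_dosage_csv <- function(panel, path) {
  D <- dosages(panel)
  out <- cbind(id = panel$pedigree$id, as.data.frame(D))
  names(out)[-1] <- paste0("L", seq_len(ncol(D)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lethalrisk-io
#' @export
read_dosage_csv <- function(path) {
  d <- read.csv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$id
  storage.mode(m) <- "integer"
  m
}

#' @rdname lethalrisk-io
#' @export
write_plink <- function(panel, prefix) {
  ped <- panel$pedigree
  map <- panel$map
  map_out <- data.frame(chr = map$chr,
                        name = paste0("L", map$locus),
                        cm = map$pos_cm,
                        pos = map$locus)
  utils::write.table(map_out, paste0(prefix, ".map"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = "\t")
  # alleles: 1 = reference, 2 = counted (lethal/minor) allele
  a1 <- t(matrix(as.integer(panel$H1) + 1L, nrow(panel$H1)))
  a2 <- t(matrix(as.integer(panel$H2) + 1L, nrow(panel$H2)))
  geno <- matrix(0L, nrow(a1), 2L * ncol(a1))
  geno[, seq(1, ncol(geno), 2)] <- a1
  geno[, seq(2, ncol(geno), 2)] <- a2
  lead <- data.frame(fam = 1L, id = ped$id,
                     sire = ifelse(is.na(ped$sire), 0L, ped$sire),
                     dam = ifelse(is.na(ped$dam), 0L, ped$dam),
                     sex = ifelse(ped$sex == "male", 1L, 2L),
                     pheno = -9L)
  utils::write.table(cbind(lead, geno), paste0(prefix, ".ped"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE,
                     sep = " ")
  invisible(prefix)
}

#' @rdname lethalrisk-io
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"),
                           col.names = c("chr", "name", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"))
  lead <- ped[, 1:6]
  geno <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- geno[, seq(1, ncol(geno), 2), drop = FALSE] - 1L
  a2 <- geno[, seq(2, ncol(geno), 2), drop = FALSE] - 1L
  d <- a1 + a2
  rownames(d) <- lead[[2]]
  list(map = tibble::as_tibble(map), dosage = d,
       pedigree = tibble::tibble(
         id = as.integer(lead[[2]]),
         sire = ifelse(lead[[3]] == 0, NA_integer_, as.integer(lead[[3]])),
         dam = ifelse(lead[[4]] == 0, NA_integer_, as.integer(lead[[4]])),
         sex = ifelse(lead[[5]] == 1, "male", "female")))
}

#' @rdname lethalrisk-io
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lethalrisk-io
#' @export
write_risk_csv <- function(risk, path) {
  write.csv(risk, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-row JSON report of a fitted model
#'
#' @param fit a `gp_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite required for JSON fit reports", call. = FALSE)
  jsonlite::write_json(
    c(as.list(glance(fit)), list(convergence = fit$convergence)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
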