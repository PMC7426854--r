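#' Simulate an overlapping-generation breeding pedigree
#'
#' Founders (birth year 0) are followed by `years` rounds of matings. Each
#' year, `sires_per_year` males are drawn at random from the alive males born
#' in earlier years and mated to `dams_per_year` females (each dam has at most
#' one offspring per year; dams may be reused across years, giving overlapping
#' generations). Every mating produces one offspring whose sex is assigned
#' with probability 0.5. There is no selection on any trait.
#'
#' @param years number of offspring birth years (>= 1).
#' @param sires_per_year sires sampled each year.
#' @param dams_per_year dams mated each year; must be divisible by
#'   `sires_per_year` so each sire serves an equal full-sib-free block of dams.
#' @param founder_males,founder_females founder pool sizes.
#' @param seed optional integer seed.
#'
#' @return A tibble with columns `id`, `sire`, `dam` (NA for founders), `sex`
#'   (`"male"`/`"female"`), `year` (0 for founders) and `alive` (all `TRUE`;
#'   the integrated simulator [sim_population()] flags calf deaths).
#' @examples
#' ped <- make_pedigree(years = 1, sires_per_year = 2, dams_per_year = 10,
#'                      founder_males = 4, founder_females = 10, seed = 1)
#' table(ped$year)
#' @export
make_pedigree <- function(years, sires_per_year, dams_per_year,
                          founder_males, founder_females, seed = NULL) {
  check_pedigree_config(years, sires_per_year, dams_per_year,
                        founder_males, founder_females)
  with_seed_(seed, {
    st <- pedigree_init(founder_males, founder_females,
                        years * dams_per_year)
    for (y in seq_len(years)) {
      st <- pedigree_year(st, y, sires_per_year, dams_per_year)
    }
    pedigree_tibble(st)
  })
}

check_pedigree_config <- function(years, sires_per_year, dams_per_year,
                                  founder_males, founder_females) {
  if (years < 1) stop_bad_arg("years", "must be >= 1")
  if (sires_per_year < 1) stop_bad_arg("sires_per_year", "must be >= 1")
  if (dams_per_year %% sires_per_year != 0)
    stop_bad_arg("dams_per_year", "must be divisible by sires_per_year")
  if (founder_males < sires_per_year)
    stop_bad_arg("founder_males", "must be >= sires_per_year")
  if (founder_females < dams_per_year)
    stop_bad_arg("founder_females", "must be >= dams_per_year")
  invisible(TRUE)
}

# Pedigree state kept in preallocated vectors: founders first, then all
# offspring rows in birth order. `alive` is updated by the caller when calf
# deaths occur, before the next year's parents are sampled.
pedigree_init <- function(founder_males, founder_females, n_offspring) {
  nf <- founder_males + founder_females
  n <- nf + n_offspring
  st <- list(
    id = seq_len(n),
    sire = rep(NA_integer_, n),
    dam = rep(NA_integer_, n),
    male = c(rep(TRUE, founder_males), rep(FALSE, founder_females),
             rep(NA, n_offspring)),
    year = c(rep(0L, nf), rep(NA_integer_, n_offspring)),
    alive = rep(TRUE, n),
    n_founders = nf,
    filled = nf
  )
  st
}

pedigree_year <- function(st, year, sires_per_year, dams_per_year) {
  born <- !is.na(st$year) & st$year < year
  males <- which(born & st$male & st$alive)
  females <- which(born & !st$male & st$alive)
  if (length(males) < sires_per_year)
    stop(sprintf(
      "year %d: only %d alive male candidates for %d sires",
      year, length(males), sires_per_year), call. = FALSE)
  if (length(females) < dams_per_year)
    stop(sprintf(
      "year %d: only %d alive female candidates for %d dams",
      year, length(females), dams_per_year), call. = FALSE)
  sires <- sample(males, sires_per_year)
  dams <- sample(females, dams_per_year)  # without replacement within a year
  per_sire <- dams_per_year / sires_per_year
  rows <- st$filled + seq_len(dams_per_year)
  st$sire[rows] <- rep(sires, each = per_sire)
  st$dam[rows] <- dams
  st$male[rows] <- runif(dams_per_year) < 0.5
  st$year[rows] <- year
  st$filled <- st$filled + dams_per_year
  st
}

pedigree_tibble <- function(st) {
  tibble::tibble(
    id = st$id,
    sire = st$sire,
    dam = st$dam,
    sex = ifelse(st$male, "male", "female"),
    year = st$year,
    alive = st$alive
  )
}

check_pedigree <- function(pedigree) {
  req <- c("id", "sire", "dam", "sex", "year", "alive")
  if (!all(req %in% names(pedigree)))
    stop("pedigree needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(pedigree$id)) stop("duplicate pedigree ids", call. = FALSE)
  for (p in c("sire", "dam")) {
    known <- !is.na(pedigree[[p]])
    r <- match(pedigree[[p]][known], pedigree$id)
    if (anyNA(r))
      stop(sprintf("%s ids missing from pedigree", p), call. = FALSE)
    if (any(pedigree$year[r] >= pedigree$year[known]))
      stop(sprintf("%s born in or after offspring's birth year", p),
           call. = FALSE)
    want <- if (p == "sire") "male" else "female"
    if (any(pedigree$sex[r] != want))
      stop(sprintf("%s of wrong sex in pedigree", p), call. = FALSE)
  }
  non_founder <- !is.na(pedigree$sire) | !is.na(pedigree$dam)
  if (any(non_founder & (is.na(pedigree$sire) | is.na(pedigree$dam))))
    stop("non-founders must have both parents known", call. = FALSE)
  invisible(pedigree)
}
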