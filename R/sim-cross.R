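#' @importFrom utils head tail
#' @importFrom stats rbinom rpois rexp runif setNames median wilcox.test
NULL

# Founder haplotype indices: 1,2 = father; 3 = mother's causal-bearing
# haplotype; 4 = mother's other haplotype; 5.. = unrelated founders.
FATHER_HAPS <- c(1L, 2L)
MOTHER_HAPS <- c(3L, 4L)

# One meiotic gamete: per scaffold, a sorted crossover-position vector and
# the haplotype (1 or 2, indexing into the parent's pair) at the left end.
make_gamete <- function(scaffold_lengths, recomb_rate) {
  breaks <- lapply(scaffold_lengths, function(L) {
    n <- rpois(1L, recomb_rate)
    sort(runif(n, min = 1, max = L))
  })
  start <- vapply(scaffold_lengths, function(L) sample(1:2, 1L), integer(1))
  list(breaks = breaks, start = start)
}

# Non-recombined gamete consisting of one founder haplotype.
pure_gamete <- function(scaffold_lengths, which_hap) {
  list(breaks = lapply(scaffold_lengths, function(L) numeric(0)),
       start = setNames(rep(which_hap, length(scaffold_lengths)),
                        names(scaffold_lengths)))
}

# Founder haplotype id transmitted by `gamete` at each of `pos` on `scaffold`.
gamete_haps <- function(gamete, hap_pair, scaffold, pos) {
  seg <- findInterval(pos, gamete$breaks[[scaffold]])
  s <- gamete$start[[scaffold]]
  hap_pair[ifelse(seg %% 2L == 0L, s, 3L - s)]
}

#' Simulate the mapping cross and the unrelated individuals
#'
#' Performs meioses for a homozygous affected father by a heterozygous
#' carrier mother until the two phenotype pools are full (crossover counts
#' are Poisson per scaffold, placement uniform, no interference), and adds
#' the configured unrelated individuals drawn from independent founder
#' haplotypes. An offspring's phenotype equals its genotype at the causal
#' site: affected iff the maternal gamete transmits the causal-bearing
#' haplotype there.
#'
#' @param config A [sim_config()].
#' @param reference A `sim_reference` from [build_reference()].
#' @param truth A `sim_truth` from [plant_causal_stop()].
#' @return A tibble with one row per individual: `individual_id`, `group`,
#'   `phenotype`, and `gamete1`/`gamete2` list-columns (each a crossover
#'   mosaic over founder haplotypes; see `hap_pair1`/`hap_pair2`).
#' @export
simulate_cross <- function(config, reference, truth) {
  withr::with_seed(config$seed + 1L, simulate_cross_impl(config, reference, truth))
}

simulate_cross_impl <- function(config, reference, truth) {
  lens <- config$scaffold_lengths
  n_pool <- config$n_offspring_per_pool
  aff <- list(); car <- list()
  max_tries <- 50L * n_pool
  tries <- 0L
  while ((length(aff) < n_pool || length(car) < n_pool) && tries < max_tries) {
    tries <- tries + 1L
    gp <- make_gamete(lens, config$recomb_rate)
    gm <- make_gamete(lens, config$recomb_rate)
    mat_hap <- gamete_haps(gm, MOTHER_HAPS, truth$causal_scaffold,
                           truth$causal_pos)
    affected <- mat_hap == 3L   # hap 3 carries the causal allele
    if (affected && length(aff) < n_pool) {
      aff[[length(aff) + 1L]] <- list(gp, gm)
    } else if (!affected && length(car) < n_pool) {
      car[[length(car) + 1L]] <- list(gp, gm)
    }
  }
  if (length(aff) < n_pool || length(car) < n_pool) {
    stop("failed to fill offspring pools", call. = FALSE)
  }

  offspring <- function(lst, grp, pheno, prefix) {
    tibble(
      individual_id = paste0(prefix, seq_along(lst)),
      group = grp, phenotype = pheno,
      gamete1 = purrr::map(lst, 1), gamete2 = purrr::map(lst, 2),
      hap_pair1 = list(FATHER_HAPS), hap_pair2 = list(MOTHER_HAPS)
    )
  }

  n_unrel <- config$n_unrelated_carrier + config$n_unrelated_wt
  unrel_ids <- c(
    if (config$n_unrelated_carrier > 0)
      paste0("unrel_carrier_", seq_len(config$n_unrelated_carrier)),
    if (config$n_unrelated_wt > 0)
      paste0("unrel_wt_", seq_len(config$n_unrelated_wt))
  )
  unrel <- tibble(
    individual_id = unrel_ids,
    group = rep(c("unrelated_carrier", "unrelated_wt"),
                c(config$n_unrelated_carrier, config$n_unrelated_wt)),
    phenotype = "wildtype",
    gamete1 = purrr::map(seq_len(n_unrel), ~ pure_gamete(lens, 1L)),
    gamete2 = purrr::map(seq_len(n_unrel), ~ pure_gamete(lens, 2L)),
    hap_pair1 = purrr::map(seq_len(n_unrel), ~ c(3L + 2L * .x, 4L + 2L * .x)),
    hap_pair2 = purrr::map(seq_len(n_unrel), ~ c(3L + 2L * .x, 4L + 2L * .x))
  )

  parents <- tibble(
    individual_id = c("father", "mother"),
    group = c("father", "mother"),
    phenotype = c("affected", "wildtype"),
    gamete1 = list(pure_gamete(lens, 1L), pure_gamete(lens, 1L)),
    gamete2 = list(pure_gamete(lens, 2L), pure_gamete(lens, 2L)),
    hap_pair1 = list(FATHER_HAPS, MOTHER_HAPS),
    hap_pair2 = list(FATHER_HAPS, MOTHER_HAPS)
  )

  bind_rows(
    parents,
    offspring(aff, "pool_affected", "affected", "aff_"),
    offspring(car, "pool_carrier", "wildtype", "car_"),
    unrel
  )
}

# Founder-haplotype ids carried by each individual at each site of one
# scaffold: returns an n_sites x (2 * n_individuals) integer matrix.
individual_haps_at <- function(individuals, scaffold, pos) {
  cols <- vector("list", 2L * nrow(individuals))
  for (i in seq_len(nrow(individuals))) {
    cols[[2L * i - 1L]] <- gamete_haps(individuals$gamete1[[i]],
                                       individuals$hap_pair1[[i]], scaffold, pos)
    cols[[2L * i]] <- gamete_haps(individuals$gamete2[[i]],
                                  individuals$hap_pair2[[i]], scaffold, pos)
  }
  do.call(cbind, cols)
}
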