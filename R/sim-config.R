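#' Configure a synthetic mapping-by-sequencing study
#'
#' Builds the configuration object consumed by [build_reference()],
#' [simulate_cross()] and [simulate_study()]. The defaults reproduce the
#' study design the pipeline was written for: a homozygous affected father
#' crossed to a heterozygous carrier mother, one pooled library of 20
#' affected offspring and one of 20 carrier offspring, plus one unrelated
#' carrier and four unrelated wild-type individuals, with a planted C-to-T
#' stop-gain in one gene and a fully linked haplotype block around it.
#'
#' @param seed Integer seed; together with the other fields it determines
#'   every output byte of the simulator.
#' @param scaffold_lengths Named or unnamed integer vector of scaffold
#'   lengths in bp. Unnamed vectors are named `scaffold_1`, `scaffold_2`, ...
#' @param variant_density Expected heterozygous-site rate per bp between two
#'   random founder haplotypes. Segregating sites are planted at twice this
#'   density with allele frequency 1/2, so the pairwise het rate matches.
#' @param causal_gene Identifier of the gene receiving the stop-gain, or
#'   `NULL` to let [build_reference()] pick the second gene on the first
#'   scaffold.
#' @param causal_cds_len Spliced CDS length (nt, incl. terminal stop) forced
#'   on the causal gene. The default encodes a 3,772-residue protein.
#' @param causal_cds_pos 1-based CDS coordinate of the planted substitution;
#'   must be the first base of a codon.
#' @param linked_block_bp Length of the haplotype block fully linked to the
#'   causal allele in the father.
#' @param n_offspring_per_pool Offspring count per phenotype pool.
#' @param n_unrelated_wt,n_unrelated_carrier Unrelated individuals sequenced
#'   for extended mapping.
#' @param recomb_rate Expected crossovers per scaffold per meiosis
#'   (Poisson count, uniform placement, no interference).
#' @param depth_mean Mean per-library read depth (Poisson).
#' @param indel_fraction Fraction of background variant sites simulated as
#'   1-3 bp indels.
#' @param mnp_fraction Fraction of background variant sites simulated as
#'   2-3 bp multi-nucleotide polymorphisms.
#' @param multiallelic_fraction Fraction of background SNP sites given a
#'   second ALT allele (exercises biallelic-only filtering).
#' @param repeat_fraction Fraction of each scaffold covered by the simulated
#'   repeat track.
#' @param genotype_error Probability that a sampled read carries the wrong
#'   allele.
#' @param decoy_fraction Low-quality decoy sites added per true site; decoys
#'   fail at least one of the site/genotype quality filters.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       scaffold_lengths = c(scaffold_1 = 2e6, scaffold_2 = 1.5e6,
                                            scaffold_3 = 3e5),
                       variant_density = 1.25e-3,
                       causal_gene = NULL,
                       causal_cds_len = 11319L,
                       causal_cds_pos = 9508L,
                       linked_block_bp = 5e5,
                       n_offspring_per_pool = 20L,
                       n_unrelated_wt = 4L,
                       n_unrelated_carrier = 1L,
                       recomb_rate = 1,
                       depth_mean = 30,
                       indel_fraction = 0.1,
                       mnp_fraction = 0.05,
                       multiallelic_fraction = 0.02,
                       repeat_fraction = 0.4,
                       genotype_error = 0.005,
                       decoy_fraction = 0.1) {
  if (is.null(names(scaffold_lengths))) {
    names(scaffold_lengths) <- paste0("scaffold_", seq_along(scaffold_lengths))
  }
  cfg <- list(
    seed = as.integer(seed),
    scaffold_lengths = round(scaffold_lengths),
    variant_density = variant_density,
    causal_gene = causal_gene,
    causal_cds_len = as.integer(causal_cds_len),
    causal_cds_pos = as.integer(causal_cds_pos),
    linked_block_bp = round(linked_block_bp),
    n_offspring_per_pool = as.integer(n_offspring_per_pool),
    n_unrelated_wt = as.integer(n_unrelated_wt),
    n_unrelated_carrier = as.integer(n_unrelated_carrier),
    recomb_rate = recomb_rate,
    depth_mean = depth_mean,
    indel_fraction = indel_fraction,
    mnp_fraction = mnp_fraction,
    multiallelic_fraction = multiallelic_fraction,
    repeat_fraction = repeat_fraction,
    genotype_error = genotype_error,
    decoy_fraction = decoy_fraction
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, is.finite(cfg$seed),
    length(cfg$scaffold_lengths) >= 1L, all(cfg$scaffold_lengths > 0)
  )
  fracs <- c(cfg$variant_density, cfg$indel_fraction, cfg$mnp_fraction,
             cfg$multiallelic_fraction, cfg$repeat_fraction,
             cfg$genotype_error)
  if (any(fracs < 0 | fracs > 1)) {
    stop("densities and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$decoy_fraction < 0) stop("decoy_fraction must be >= 0", call. = FALSE)
  if (any(c(cfg$linked_block_bp, cfg$n_offspring_per_pool, cfg$depth_mean,
            cfg$recomb_rate) < 0)) {
    stop("lengths, counts and rates must be non-negative", call. = FALSE)
  }
  if (cfg$causal_cds_len %% 3L != 0L) {
    stop("causal_cds_len must be a multiple of 3", call. = FALSE)
  }
  if (cfg$causal_cds_pos %% 3L != 1L) {
    stop("causal_cds_pos must be the first base of a codon", call. = FALSE)
  }
  if (cfg$causal_cds_pos < 4L || cfg$causal_cds_pos > cfg$causal_cds_len - 3L) {
    stop("causal_cds_pos must fall inside the coding portion of the causal gene",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  scaffolds:", length(x$scaffold_lengths), "totalling",
      sum(x$scaffold_lengths), "bp\n")
  cat("  pools: 2 x", x$n_offspring_per_pool, "offspring; unrelated:",
      x$n_unrelated_carrier, "carrier +", x$n_unrelated_wt, "wild type\n")
  cat("  causal CDS:", x$causal_cds_len, "nt, substitution at CDS pos",
      x$causal_cds_pos, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
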