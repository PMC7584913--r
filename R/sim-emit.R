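# Variant-site generation and the naive pooled genotype caller that stands
# between the simulated pedigree and the VCF consumed by the mapping
# pipeline. Pools are emitted as single diploid columns, mirroring how the
# pooled libraries are genotyped as one library each.

#' Call a diploid genotype from simulated reads
#'
#' Draws a Poisson read depth and binomial ALT reads from a library's true
#' ALT-allele fraction, then assigns hom-REF / het / hom-ALT by
#' allele-fraction cutoffs 0.1 and 0.9. Genotype quality is the
#' phred-scaled binomial likelihood ratio between the best and second-best
#' of the three genotype models, capped at 99. Zero-depth sites come back
#' as missing calls.
#'
#' @param p_alt Numeric vector of true ALT-allele fractions (one per site).
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param error Probability that a read carries the wrong allele.
#' @return A tibble with columns `gt` ("0/0", "0/1", "1/1" or `NA`),
#'   `gq` and `dp`.
#' @export
call_genotypes <- function(p_alt, depth_mean = 30, error = 0.005) {
  n <- length(p_alt)
  dp <- rpois(n, depth_mean)
  p_read <- p_alt * (1 - error) + (1 - p_alt) * error
  alt <- rbinom(n, dp, p_read)
  frac <- ifelse(dp > 0, alt / dp, NA_real_)
  gt <- dplyr::case_when(
    is.na(frac) ~ NA_character_,
    frac <= 0.1 ~ "0/0",
    frac >= 0.9 ~ "1/1",
    TRUE ~ "0/1"
  )
  ll <- cbind(dbinom(alt, dp, error, log = TRUE),
              dbinom(alt, dp, 0.5, log = TRUE),
              dbinom(alt, dp, 1 - error, log = TRUE)) / log(10)
  ord <- t(apply(ll, 1L, sort, decreasing = TRUE))
  gq <- as.integer(round(pmin(99, pmax(0, 10 * (ord[, 1L] - ord[, 2L])))))
  gq[is.na(gt)] <- 0L
  tibble(gt = gt, gq = gq, dp = dp)
}

# --- site generation ---------------------------------------------------------

# Splice-zone positions (the two intronic bases at each junction) and the
# CDS +/- 2 bp mask for one scaffold's gene models.
coding_masks <- function(genes_scf) {
  if (nrow(genes_scf) == 0L) {
    return(list(cds = IRanges::IRanges(), splice = integer(0)))
  }
  segs <- bind_rows(genes_scf$cds)
  cds <- IRanges::reduce(IRanges::IRanges(segs$start, segs$end))
  splice <- unlist(lapply(genes_scf$cds, function(s) {
    if (nrow(s) < 2L) return(integer(0))
    c(s$end[-nrow(s)] + 1L, s$end[-nrow(s)] + 2L,
      s$start[-1L] - 1L, s$start[-1L] - 2L)
  }))
  list(cds = cds, splice = unique(splice))
}

# ALT bases for a coding SNP that do not create a premature stop codon in
# the gene's reading frame. Background alleles creating nonsense changes are
# excluded: in a healthy breeding colony such alleles are purged by
# selection, and planting them would confound candidate-gene triage.
safe_snp_alts <- function(pos, ref_base, gene, cds_string) {
  cpos <- genomic_to_cds(gene, pos)
  if (is.na(cpos)) return(setdiff(DNA_BASES, ref_base))
  codon_i <- (cpos + 2L) %/% 3L
  in_codon <- cpos - 3L * (codon_i - 1L)
  codon <- substr(cds_string, 3L * codon_i - 2L, 3L * codon_i)
  ok <- character(0)
  for (b in setdiff(DNA_BASES, ref_base)) {
    cb <- if (gene$strand == "+") b else chartr("ACGT", "TGCA", b)
    mut <- codon
    substr(mut, in_codon, in_codon) <- cb
    if (!mut %in% STOP_CODONS) ok <- c(ok, b)
  }
  ok
}

# Generate the true segregating sites for one study. Sites are planted at
# twice the configured pairwise heterozygosity (alleles at frequency ~1/2),
# independently of the repeat track.
generate_sites <- function(config, reference, truth) {
  out <- vector("list", length(config$scaffold_lengths))
  for (i in seq_along(config$scaffold_lengths)) {
    scf <- names(config$scaffold_lengths)[i]
    L <- config$scaffold_lengths[[i]]
    n_target <- round(L * 2 * config$variant_density)
    if (n_target == 0L) { out[[i]] <- NULL; next }
    pos <- sort(sample(seq(10L, as.integer(L) - 10L), n_target))
    pos <- pos[c(TRUE, diff(pos) >= 6L)]
    if (identical(scf, truth$causal_scaffold)) {
      pos <- pos[abs(pos - truth$causal_pos) > 5L]
    }
    genes_scf <- reference$genes[reference$genes$scaffold == scf, ]
    masks <- coding_masks(genes_scf)
    cds_ext <- if (length(masks$cds)) {
      IRanges::IRanges(IRanges::start(masks$cds) - 2L,
                       IRanges::end(masks$cds) + 2L)
    } else IRanges::IRanges()

    u <- runif(length(pos))
    vclass <- ifelse(u < config$indel_fraction, "INDEL",
                     ifelse(u < config$indel_fraction + config$mnp_fraction,
                            "MNP", "SNP"))
    # indels and MNPs are kept out of CDS and splice zones
    near_cds <- IRanges::overlapsAny(
      IRanges::IRanges(pos, pos + 4L), cds_ext)
    vclass[vclass != "SNP" & near_cds] <- "SNP"
    keep <- !(vclass == "SNP" & pos %in% masks$splice)
    pos <- pos[keep]; vclass <- vclass[keep]

    seq_chr <- as.character(reference$sequences[[scf]])
    gene_at <- rep(NA_integer_, length(pos))
    for (g in seq_len(nrow(genes_scf))) {
      segs <- genes_scf$cds[[g]]
      hit <- IRanges::overlapsAny(IRanges::IRanges(pos, pos),
                                  IRanges::IRanges(segs$start, segs$end))
      gene_at[hit] <- g
    }
    cds_cache <- if (nrow(genes_scf)) {
      vapply(seq_len(nrow(genes_scf)),
             function(g) spliced_cds(genes_scf[g, ], reference$sequences),
             character(1))
    } else character(0)

    ref <- alt <- character(length(pos))
    drop <- logical(length(pos))
    for (k in seq_along(pos)) {
      p <- pos[k]
      if (vclass[k] == "SNP") {
        ref[k] <- substr(seq_chr, p, p)
        alts <- if (!is.na(gene_at[k])) {
          safe_snp_alts(p, ref[k], genes_scf[gene_at[k], ],
                        cds_cache[gene_at[k]])
        } else setdiff(DNA_BASES, ref[k])
        if (length(alts) == 0L) { drop[k] <- TRUE; next }
        alt[k] <- if (length(alts) == 1L) alts else sample(alts, 1L)
        if (is.na(gene_at[k]) &&
            runif(1) < config$multiallelic_fraction) {
          alt2 <- sample(setdiff(DNA_BASES, c(ref[k], alt[k])), 1L)
          alt[k] <- paste(alt[k], alt2, sep = ",")
        }
      } else if (vclass[k] == "MNP") {
        len <- sample(2:3, 1L)
        ref[k] <- substr(seq_chr, p, p + len - 1L)
        alt[k] <- paste(vapply(strsplit(ref[k], "")[[1]], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1)), collapse = "")
      } else {
        len <- sample(1:3, 1L)
        if (runif(1) < 0.5) {                       # deletion
          ref[k] <- substr(seq_chr, p, p + len)
          alt[k] <- substr(seq_chr, p, p)
        } else {                                    # insertion
          ref[k] <- substr(seq_chr, p, p)
          alt[k] <- paste0(ref[k], random_dna(len))
        }
      }
    }
    out[[i]] <- tibble(scaffold = scf, pos = pos, ref = ref, alt = alt,
                       vclass = vclass, is_causal = FALSE)[!drop, ]
  }
  sites <- bind_rows(out)
  causal <- tibble(scaffold = truth$causal_scaffold, pos = truth$causal_pos,
                   ref = truth$causal_ref, alt = truth$causal_alt,
                   vclass = "SNP", is_causal = TRUE)
  sites <- bind_rows(sites, causal) %>%
    mutate(scaffold = factor(.data$scaffold,
                             levels = names(config$scaffold_lengths))) %>%
    arrange(.data$scaffold, .data$pos) %>%
    mutate(scaffold = as.character(.data$scaffold),
           n_alt = stringr::str_count(.data$alt, ",") + 1L,
           vclass = if_else(.data$n_alt > 1L, "MULTI", .data$vclass))
  sites
}

# Founder allele matrix: one row per true site, one column per founder
# haplotype (0 = reference allele). Within the linked block the father's two
# haplotypes and the mother's causal-bearing haplotype share one mosaic-free
# pattern; the causal allele itself is carried only by those three
# haplotypes plus one haplotype of the unrelated carrier.
founder_alleles <- function(sites, config, truth) {
  n_unrel <- config$n_unrelated_carrier + config$n_unrelated_wt
  n_hap <- 4L + 2L * n_unrel
  n <- nrow(sites)
  H <- matrix(rbinom(n * n_hap, 1L, 0.5), nrow = n)
  multi <- sites$n_alt > 1L
  if (any(multi)) {
    H[multi, ] <- matrix(
      sample(0:2, sum(multi) * n_hap, replace = TRUE, prob = c(.5, .3, .2)),
      nrow = sum(multi))
  }
  in_block <- sites$scaffold == truth$causal_scaffold &
    sites$pos >= truth$linked_interval[1] &
    sites$pos <= truth$linked_interval[2]
  lav <- rbinom(sum(in_block), 1L, 0.5)
  H[in_block, 1L] <- H[in_block, 2L] <- H[in_block, 3L] <- lav
  ci <- which(sites$is_causal)
  H[ci, ] <- 0L
  H[ci, c(1L, 2L, 3L)] <- 1L
  if (config$n_unrelated_carrier > 0) H[ci, 5L] <- 1L
  H
}

# --- VCF-level emission ------------------------------------------------------

library_members <- function(individuals, config) {
  list(
    father = "father",
    mother = "mother",
    pool_affected = individuals$individual_id[individuals$group == "pool_affected"],
    pool_carrier = individuals$individual_id[individuals$group == "pool_carrier"]
  ) %>%
    c(setNames(
      as.list(individuals$individual_id[startsWith(individuals$individual_id, "unrel_")]),
      individuals$individual_id[startsWith(individuals$individual_id, "unrel_")]))
}

#' Emit variant calls and the sample-role sheet for a simulated study
#'
#' Resolves every individual's alleles at the simulated segregating sites,
#' collapses each library (parents, the two offspring pools, unrelated
#' individuals) to an ALT-allele fraction, pushes the fractions through the
#' read-based caller of [call_genotypes()], and appends low-quality decoy
#' sites that fail at least one downstream filter. The result has the same
#' shape as [read_variants()] output, so it can be analysed in memory or
#' round-tripped through a VCF on disk.
#'
#' @param individuals Tibble from [simulate_cross()].
#' @param config A [sim_config()].
#' @param reference A `sim_reference`.
#' @param truth A `sim_truth`.
#' @return A list with `variants` (tibble), `roles` (tibble) and `sites`
#'   (the ground-truth site table, decoys flagged).
#' @export
emit_vcf <- function(individuals, config, reference, truth) {
  withr::with_seed(config$seed + 2L,
                   emit_vcf_impl(individuals, config, reference, truth))
}

emit_vcf_impl <- function(individuals, config, reference, truth) {
  sites <- generate_sites(config, reference, truth)
  H <- founder_alleles(sites, config, truth)
  libs <- library_members(individuals, config)
  lib_ids <- names(libs)

  # per-site allele matrix for every individual haplotype, scaffold block-wise
  n <- nrow(sites)
  n_ind <- nrow(individuals)
  A <- matrix(NA_integer_, nrow = n, ncol = 2L * n_ind)
  for (scf in unique(sites$scaffold)) {
    rows <- which(sites$scaffold == scf)
    M <- individual_haps_at(individuals, scf, sites$pos[rows])
    A[rows, ] <- matrix(H[rows, ][cbind(rep(seq_along(rows), ncol(M)),
                                        as.vector(M))],
                        nrow = length(rows))
  }
  colnames(A) <- rep(individuals$individual_id, each = 2L)

  gt <- gq <- dp <- matrix(NA_integer_, nrow = n, ncol = length(libs),
                           dimnames = list(NULL, lib_ids))
  gt <- matrix(NA_character_, nrow = n, ncol = length(libs),
               dimnames = list(NULL, lib_ids))
  multi <- sites$n_alt > 1L
  for (j in seq_along(libs)) {
    cols <- which(colnames(A) %in% libs[[j]])
    sub <- A[, cols, drop = FALSE]
    p_alt <- rowMeans(sub == 1L)
    calls <- call_genotypes(p_alt, config$depth_mean, config$genotype_error)
    gt[, j] <- calls$gt; gq[, j] <- calls$gq; dp[, j] <- calls$dp
    if (any(multi)) {
      mi <- which(multi)
      naive <- t(vapply(mi, function(i) {
        cnt <- tabulate(sub[i, ] + 1L, nbins = 3L)
        f <- cnt / sum(cnt)
        top <- order(f, decreasing = TRUE)
        if (f[top[1]] >= 0.9) paste(top[1] - 1L, top[1] - 1L, sep = "/")
        else paste(sort(c(top[1], top[2]) - 1L), collapse = "/")
      }, character(1)))
      gt[mi, j] <- naive
      gq[mi, j] <- 60L
    }
  }

  variants <- sites %>%
    mutate(qual = round(runif(n, 150, 2000), 1),
           filter = "PASS", is_decoy = FALSE)

  # decoy sites: sequencing-noise records that fail the quality filters
  n_decoy <- round(config$decoy_fraction * n)
  if (n_decoy > 0) {
    dec <- decoy_sites(n_decoy, config, reference, sites)
    gt <- rbind(gt, dec$gt); gq <- rbind(gq, dec$gq); dp <- rbind(dp, dec$dp)
    variants <- bind_rows(variants, dec$variants)
  }

  for (j in seq_along(lib_ids)) {
    variants[[paste0("gt_", lib_ids[j])]] <- gt[, j]
    variants[[paste0("gq_", lib_ids[j])]] <- gq[, j]
    variants[[paste0("dp_", lib_ids[j])]] <- dp[, j]
  }
  variants <- variants %>%
    mutate(scaffold = factor(.data$scaffold,
                             levels = names(config$scaffold_lengths))) %>%
    arrange(.data$scaffold, .data$pos) %>%
    mutate(scaffold = as.character(.data$scaffold)) %>%
    mutate(in_repeat = flag_repeat_overlap(.data$scaffold, .data$pos,
                                           .data$ref, reference$repeats)) %>%
    relocate(all_of(c("scaffold", "pos", "ref", "alt", "n_alt", "vclass",
                      "qual", "filter", "in_repeat")))

  roles <- tibble(
    library_id = lib_ids,
    role = dplyr::case_when(
      lib_ids %in% c("father", "pool_affected") ~ "affected_hom",
      lib_ids %in% c("mother", "pool_carrier") |
        startsWith(lib_ids, "unrel_carrier") ~ "carrier_het",
      TRUE ~ "wildtype_hom"
    ),
    phenotype = if_else(lib_ids %in% c("father", "pool_affected"),
                        "affected", "wildtype"),
    origin = if_else(startsWith(lib_ids, "unrel_"), "unrelated", "family"),
    member = dplyr::case_when(
      lib_ids == "father" ~ "father",
      lib_ids == "mother" ~ "mother",
      startsWith(lib_ids, "pool_") ~ "offspring_pool",
      TRUE ~ "unrelated"
    )
  )

  truth$individual_haplotypes <- individuals %>%
    select(all_of(c("individual_id", "group", "phenotype",
                    "gamete1", "gamete2", "hap_pair1", "hap_pair2")))

  list(variants = variants,
       roles = roles,
       sites = select(variants, all_of(c("scaffold", "pos", "ref", "alt",
                                         "vclass", "is_causal", "is_decoy"))),
       truth = truth)
}

decoy_sites <- function(n_decoy, config, reference, sites) {
  lens <- config$scaffold_lengths
  scf <- sample(names(lens), n_decoy, replace = TRUE,
                prob = lens / sum(lens))
  pos <- unname(vapply(scf, function(s)
    sample(seq(10L, as.integer(lens[[s]]) - 10L), 1L), integer(1)))
  taken <- paste(sites$scaffold, sites$pos)
  keep <- !paste(scf, pos) %in% taken & !duplicated(paste(scf, pos))
  scf <- scf[keep]; pos <- pos[keep]
  m <- length(scf)
  ref <- vapply(seq_len(m), function(i)
    as.character(Biostrings::subseq(reference$sequences[[scf[i]]],
                                    pos[i], pos[i])), character(1))
  alt <- unname(vapply(ref, function(b)
    sample(setdiff(DNA_BASES, b), 1L), character(1)))
  mode <- sample(c("low_qual", "filter_fail", "low_depth", "low_gq"),
                 m, replace = TRUE)
  n_lib <- 4L + config$n_unrelated_wt + config$n_unrelated_carrier
  gt <- matrix(sample(c("0/0", "0/1", "1/1"), m * n_lib, replace = TRUE,
                      prob = c(.4, .4, .2)), nrow = m)
  gq <- matrix(sample(30:99, m * n_lib, replace = TRUE), nrow = m)
  dp <- matrix(rpois(m * n_lib, config$depth_mean), nrow = m)
  qual <- round(runif(m, 150, 2000), 1)
  filt <- rep("PASS", m)
  qual[mode == "low_qual"] <- round(runif(sum(mode == "low_qual"), 20, 100), 1)
  filt[mode == "filter_fail"] <- sample(c("badReads", "MQ", "strandBias"),
                                        sum(mode == "filter_fail"), replace = TRUE)
  # degrade a family library so the decoy fails family and extended
  # analyses alike (columns 1:4 are father, mother and the two pools)
  for (i in which(mode == "low_depth")) {
    dp[i, sample(4L, 1L)] <- sample(0:8, 1L)
  }
  for (i in which(mode == "low_gq")) {
    gq[i, sample(4L, 1L)] <- sample(0:19, 1L)
  }
  list(variants = tibble(scaffold = scf, pos = pos, ref = ref, alt = alt,
                         vclass = "SNP", is_causal = FALSE, n_alt = 1L,
                         qual = qual, filter = filt, is_decoy = TRUE),
       gt = gt, gq = gq, dp = dp)
}

# TRUE where a record's REF footprint overlaps any repeat interval.
flag_repeat_overlap <- function(scaffold, pos, ref, repeats) {
  out <- logical(length(pos))
  if (nrow(repeats) == 0L) return(out)
  for (scf in unique(scaffold)) {
    rows <- scaffold == scf
    rep_scf <- repeats[repeats$scaffold == scf, ]
    if (nrow(rep_scf) == 0L) next
    out[rows] <- IRanges::overlapsAny(
      IRanges::IRanges(pos[rows], pos[rows] + nchar(ref[rows]) - 1L),
      IRanges::IRanges(rep_scf$start, rep_scf$end))
  }
  out
}

#' Simulate a complete mapping-by-sequencing study
#'
#' Runs [build_reference()], [plant_causal_stop()], [simulate_cross()] and
#' [emit_vcf()] in sequence, optionally writing the study to disk as FASTA,
#' GFF3, BED, VCF and a tab-separated sample-role sheet. Identical
#' configurations produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory, or `NULL` to keep the study in memory.
#' @return A list of class `sim_study`: `reference`, `truth`, `individuals`,
#'   `variants`, `roles`, `sites`, and (when written) `paths`.
#' @export
simulate_study <- function(config, dir = NULL) {
  reference <- build_reference(config)
  truth <- plant_causal_stop(reference)
  individuals <- simulate_cross(config, reference, truth)
  emitted <- emit_vcf(individuals, config, reference, truth)
  study <- list(reference = reference, truth = emitted$truth,
                individuals = individuals, variants = emitted$variants,
                roles = emitted$roles, sites = emitted$sites)
  class(study) <- "sim_study"
  if (!is.null(dir)) {
    study$paths <- write_study(study, dir)
  }
  study
}
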