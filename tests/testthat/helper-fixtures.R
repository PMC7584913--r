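# Shared fixtures, all generated in code at test time.

# Down-scaled study configuration used by most unit tests (two scaffolds,
# full machinery, small enough to simulate in well under a second).
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             scaffold_lengths = c(tig_1 = 2e5, tig_2 = 1.2e5),
             causal_gene = "gene_tig_1_2",
             ...)
}

# One cached default tiny study per option set, to avoid re-simulating.
.study_cache <- new.env(parent = emptyenv())
cached_tiny_study <- function(seed = 1L, key = "default", ...) {
  id <- paste(key, seed, sep = "#")
  if (is.null(.study_cache[[id]])) {
    .study_cache[[id]] <- simulate_study(tiny_config(seed = seed, ...))
  }
  .study_cache[[id]]
}

# Hand-rolled variant tibble for filter/cosegregation unit tests. `gts` is
# a named list mapping library id -> genotype string vector.
make_variants <- function(pos, gts, scaffold = "tig_1", ref = "A", alt = "T",
                          qual = 500, filter = "PASS", in_repeat = FALSE,
                          gq = 99L, dp = 30L, n_alt = 1L) {
  n <- length(pos)
  out <- tibble::tibble(
    scaffold = rep_len(scaffold, n), pos = as.integer(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    n_alt = rep_len(as.integer(n_alt), n),
    vclass = ifelse(rep_len(n_alt, n) > 1L, "MULTI",
                    ifelse(nchar(rep_len(ref, n)) !=
                             nchar(rep_len(alt, n)), "INDEL",
                           ifelse(nchar(rep_len(ref, n)) > 1L, "MNP", "SNP"))),
    qual = rep_len(qual, n), filter = rep_len(filter, n),
    in_repeat = rep_len(in_repeat, n)
  )
  for (lib in names(gts)) {
    out[[paste0("gt_", lib)]] <- as.character(rep_len(gts[[lib]], n))
    out[[paste0("gq_", lib)]] <- rep_len(as.integer(gq), n)
    out[[paste0("dp_", lib)]] <- rep_len(as.integer(dp), n)
  }
  out
}

family_roles <- function() {
  tibble::tibble(
    library_id = c("father", "mother", "pool_affected", "pool_carrier"),
    role = c("affected_hom", "carrier_het", "affected_hom", "carrier_het"),
    phenotype = c("affected", "wildtype", "affected", "wildtype"),
    origin = "family"
  )
}

extended_roles <- function(n_wt = 2L) {
  dplyr::bind_rows(
    family_roles(),
    tibble::tibble(
      library_id = c("unrel_carrier_1", paste0("unrel_wt_", seq_len(n_wt))),
      role = c("carrier_het", rep("wildtype_hom", n_wt)),
      phenotype = "wildtype", origin = "unrelated"
    )
  )
}

# A single-gene toy scenario: place a given CDS (split into exons) on a
# short scaffold, with `intron_len`-bp introns, at `offset`. Returns the
# sequences and the one-row gene tibble.
toy_gene <- function(cds, n_exons = 1L, strand = "+", intron_len = 20L,
                     offset = 100L, pad = 150L, scaffold = "toy",
                     gene_id = "g1", seed = 42L) {
  withr::with_seed(seed, {
    cds_len <- nchar(cds)
    cuts <- if (n_exons > 1L) sort(sample(cds_len - 1L, n_exons - 1L)) else
      integer(0)
    seg_len <- diff(c(0L, cuts, cds_len))           # transcription order
    if (strand == "-") seg_len <- rev(seg_len)      # genomic order
    starts <- offset + cumsum(c(0L, head(seg_len, -1L) + intron_len))
    ends <- starts + seg_len - 1L
    total <- max(ends) + pad
    filler <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                    collapse = "")
    genome_cds <- if (strand == "+") cds else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    offs <- cumsum(c(0L, head(seg_len, -1L)))
    seqs <- Biostrings::DNAStringSet(stats::setNames(filler, scaffold))
    seqs[[1]] <- Biostrings::replaceAt(
      seqs[[1]], IRanges::IRanges(starts, ends),
      Biostrings::DNAStringSet(substring(genome_cds, offs + 1L,
                                         offs + seg_len)))
    tx_len <- if (strand == "+") seg_len else rev(seg_len)
    phase_tx <- (3L - cumsum(c(0L, head(tx_len, -1L))) %% 3L) %% 3L
    gene <- tibble::tibble(
      gene_id = gene_id, scaffold = scaffold, strand = strand,
      start = min(starts), end = max(ends), cds_len = cds_len,
      exons = list(tibble::tibble(start = starts, end = ends)),
      cds = list(tibble::tibble(
        start = starts, end = ends,
        phase = if (strand == "+") phase_tx else rev(phase_tx)))
    )
    list(sequences = seqs, genes = gene)
  })
}

# CDS of n_codons residues plus terminal stop, no internal stop, with
# optional overridden codons (named by codon index).
toy_cds <- function(n_codons, override = NULL, seed = 7L) {
  withr::with_seed(seed, {
    pool <- setdiff(
      as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0), c("A", "C", "G", "T"), paste0)),
      c("TAA", "TAG", "TGA"))
    codons <- c("ATG", sample(pool, n_codons - 1L, replace = TRUE), "TAA")
    for (i in names(override)) codons[as.integer(i)] <- override[[i]]
    paste(codons, collapse = "")
  })
}

# Single biallelic variant row for annotation tests.
one_variant <- function(scaffold, pos, ref, alt) {
  tibble::tibble(scaffold = scaffold, pos = as.integer(pos), ref = ref,
                 alt = alt, n_alt = 1L,
                 vclass = ifelse(nchar(ref) != nchar(alt), "INDEL",
                                 ifelse(nchar(ref) > 1L, "MNP", "SNP")),
                 qual = 500, filter = "PASS", in_repeat = FALSE)
}
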