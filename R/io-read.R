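# Readers for the study inputs: multi-sample VCF (vcfR), repeat BED,
# sample-role sheet, gene models (rtracklayer) and reference FASTA
# (Biostrings).

#' Read a multi-sample VCF into the package's variant tibble
#'
#' Materializes every record with its site fields, variant class, and
#' per-library GT/GQ/DP columns (`gt_<lib>`, `gq_<lib>`, `dp_<lib>`).
#' Missing genotypes come back as `NA` with GQ/DP 0. When a repeat BED is
#' supplied, `in_repeat` is `TRUE` iff any reference base of the record
#' overlaps a repeat interval (BED half-open intervals converted to
#' 1-based inclusive).
#'
#' @param vcf_path Path to a sorted VCF (plain text or bgzipped).
#' @param repeat_bed_path Optional repeat-track BED path.
#' @return A tibble with one row per record, carrying scaffold lengths seen
#'   in the header as the `scaffold_lengths` attribute.
#' @export
read_variants <- function(vcf_path, repeat_bed_path = NULL) {
  if (!file.exists(vcf_path)) stop("no such VCF: ", vcf_path, call. = FALSE)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)          # single-record VCF
  fix <- tibble::as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  out <- tibble(
    scaffold = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    qual = as.numeric(fix$QUAL),
    filter = fix$FILTER
  ) %>%
    mutate(n_alt = stringr::str_count(.data$alt, ",") + 1L,
           vclass = classify_variant(.data$ref, .data$alt, .data$n_alt))

  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gt[gt %in% c("./.", ".", ".|.")] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)
  for (lib in colnames(gt)) {
    out[[paste0("gt_", lib)]] <- unname(gt[, lib])
    out[[paste0("gq_", lib)]] <- ifelse(is.na(gq[, lib]), 0, unname(gq[, lib]))
    out[[paste0("dp_", lib)]] <- ifelse(is.na(dp[, lib]), 0, unname(dp[, lib]))
  }

  repeats <- if (is.null(repeat_bed_path)) {
    tibble(scaffold = character(), start = integer(), end = integer())
  } else {
    read_repeats(repeat_bed_path)
  }
  out <- out %>%
    mutate(in_repeat = flag_repeat_overlap(.data$scaffold, .data$pos,
                                           .data$ref, repeats)) %>%
    relocate(all_of(c("scaffold", "pos", "ref", "alt", "n_alt", "vclass",
                      "qual", "filter", "in_repeat")))

  contig <- grep("^##contig", v@meta, value = TRUE)
  if (length(contig)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)))
    attr(out, "scaffold_lengths") <- setNames(lens, ids)
  }
  out
}

# SNP: equal single-base ref/alt; MNP: equal multi-base; INDEL: unequal
# lengths. Multiallelic records are labelled MULTI and judged only when
# decomposed (the pipeline drops them under biallelic-only analysis).
classify_variant <- function(ref, alt, n_alt) {
  dplyr::case_when(
    n_alt > 1L ~ "MULTI",
    nchar(ref) == nchar(alt) & nchar(ref) == 1L ~ "SNP",
    nchar(ref) == nchar(alt) ~ "MNP",
    TRUE ~ "INDEL"
  )
}

#' Read a repeat-track BED file (0-based half-open) as 1-based intervals
#'
#' @param path BED path (first three columns used).
#' @return Tibble with `scaffold`, `start`, `end` (1-based inclusive).
#' @export
read_repeats <- function(path) {
  if (!file.exists(path)) stop("no such BED: ", path, call. = FALSE)
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE)
  if (nrow(bed) == 0L) {
    return(tibble(scaffold = character(), start = integer(), end = integer()))
  }
  if (any(bed[[3]] <= bed[[2]])) {
    stop("BED interval with end <= start", call. = FALSE)
  }
  tibble(scaffold = as.character(bed[[1]]),
         start = as.integer(bed[[2]]) + 1L,
         end = as.integer(bed[[3]]))
}

#' Read the sample-role sheet
#'
#' @param path Tab-separated sheet with columns `library_id`, `role`,
#'   `phenotype` and optionally `origin` and `member`.
#' @return Tibble; `origin` defaults to `"family"` when absent.
#' @export
read_roles <- function(path) {
  roles <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("library_id", "role", "phenotype")
  if (!all(need %in% names(roles))) {
    stop("role sheet must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok_roles <- c("affected_hom", "carrier_het", "wildtype_hom")
  if (!all(roles$role %in% ok_roles)) {
    stop("unknown role value; expected one of ",
         paste(ok_roles, collapse = ", "), call. = FALSE)
  }
  if (!"origin" %in% names(roles)) roles$origin <- "family"
  roles
}

#' Read gene models from a GFF3 file
#'
#' Collapses CDS and exon features to one row per gene with `exons` and
#' `cds` list-columns ordered by genomic coordinate, the representation
#' used by [spliced_cds()] and [annotate_consequences()].
#'
#' @param path GFF3 path.
#' @return Tibble with `gene_id`, `scaffold`, `strand`, `start`, `end`,
#'   `cds_len`, `exons`, `cds`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such GFF3: ", path, call. = FALSE)
  gr <- rtracklayer::import(path)
  df <- tibble::as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  tx2gene <- df %>%
    filter(.data$type %in% c("mRNA", "transcript")) %>%
    mutate(gene_id = vapply(.data$Parent, function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))) %>%
    select(tx_id = "ID", "gene_id")
  feat <- df %>%
    filter(.data$type %in% c("CDS", "exon")) %>%
    mutate(tx_id = vapply(.data$Parent, function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))) %>%
    left_join(tx2gene, by = "tx_id")
  if (any(is.na(feat$gene_id))) {
    feat$gene_id[is.na(feat$gene_id)] <- feat$tx_id[is.na(feat$gene_id)]
  }
  feat %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(function(d, key) {
      cds <- d %>% filter(.data$type == "CDS") %>% arrange(.data$start)
      ex <- d %>% filter(.data$type == "exon") %>% arrange(.data$start)
      if (nrow(ex) == 0L) ex <- cds
      phase <- suppressWarnings(as.integer(as.character(cds$phase)))
      tibble(
        scaffold = as.character(d$seqnames[1]),
        strand = as.character(d$strand[1]),
        start = min(d$start), end = max(d$end),
        cds_len = sum(cds$end - cds$start + 1L),
        exons = list(tibble(start = ex$start, end = ex$end)),
        cds = list(tibble(start = cds$start, end = cds$end,
                          phase = ifelse(is.na(phase), 0L, phase)))
      )
    }) %>%
    ungroup() %>%
    arrange(.data$scaffold, .data$start)
}

#' Read a reference FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] named by scaffold.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("no such FASTA: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  seqs
}
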