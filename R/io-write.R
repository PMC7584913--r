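# Plain-text writers for the study formats. Reading goes through the
# established parsers (vcfR, rtracklayer, Biostrings); writing is simple
# line formatting of the package's own tibbles.

#' Write a simulated study to disk
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly usable for
#'   [run_config()].
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "reference.fa"),
    gff = file.path(dir, "genes.gff3"),
    bed = file.path(dir, "repeats.bed"),
    vcf = file.path(dir, "calls.vcf"),
    roles = file.path(dir, "roles.tsv")
  )
  Biostrings::writeXStringSet(study$reference$sequences, paths[["fasta"]])
  write_gene_models_gff3(study$reference$genes, paths[["gff"]])
  write_repeats_bed(study$reference$repeats, paths[["bed"]])
  write_variants_vcf(study$variants, paths[["vcf"]],
                     study$reference$scaffold_lengths)
  readr::write_tsv(study$roles, paths[["roles"]])
  paths
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based inclusive, CDS phase
#' column populated) for the `genes` tibble of a reference bundle.
#'
#' @param genes Tibble with `gene_id`, `scaffold`, `strand` and `exons`/
#'   `cds` list-columns.
#' @param path Output file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      paste(g$scaffold, "cosegmap", "gene", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$scaffold, "cosegmap", "mRNA", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", tid, ";Parent=", g$gene_id), sep = "\t"))
    ex <- g$exons[[1]]
    lines <- c(lines, paste(g$scaffold, "cosegmap", "exon", ex$start, ex$end,
                            ".", g$strand, ".", paste0("Parent=", tid),
                            sep = "\t"))
    cds <- g$cds[[1]]
    lines <- c(lines, paste(g$scaffold, "cosegmap", "CDS", cds$start, cds$end,
                            ".", g$strand, cds$phase,
                            paste0("ID=", tid, ".cds;Parent=", tid),
                            sep = "\t"))
  }
  readr::write_lines(lines, path)
}

#' Write repeat intervals as BED (0-based half-open)
#'
#' @param repeats Tibble with `scaffold`, `start`, `end` (1-based inclusive).
#' @param path Output file.
#' @export
write_repeats_bed <- function(repeats, path) {
  readr::write_lines(
    paste(repeats$scaffold, repeats$start - 1L, repeats$end, sep = "\t"),
    path)
}

#' Write a variant tibble as a multi-sample VCF v4.2
#'
#' Per-sample fields are emitted as GT:GQ:DP. Missing genotypes become
#' `./.`. Records must already be sorted by scaffold then position.
#'
#' @param variants Variant tibble in [read_variants()] shape.
#' @param path Output file.
#' @param scaffold_lengths Named vector used for `##contig` header lines.
#' @export
write_variants_vcf <- function(variants, path, scaffold_lengths = NULL) {
  libs <- variant_libraries(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(scaffold_lengths)) {
      paste0("##contig=<ID=", names(scaffold_lengths), ",length=",
             format(scaffold_lengths, scientific = FALSE, trim = TRUE), ">")
    },
    "##FILTER=<ID=badReads,Description=\"Low quality read evidence\">",
    "##FILTER=<ID=MQ,Description=\"Low mapping quality\">",
    "##FILTER=<ID=strandBias,Description=\"Strand bias\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", libs), collapse = "\t")
  )
  fmt <- vapply(libs, function(lib) {
    gt <- variants[[paste0("gt_", lib)]]
    gq <- variants[[paste0("gq_", lib)]]
    dp <- variants[[paste0("dp_", lib)]]
    paste(ifelse(is.na(gt), "./.", gt),
          ifelse(is.na(gq), 0L, gq),
          ifelse(is.na(dp), 0L, dp), sep = ":")
  }, character(nrow(variants)))
  if (nrow(variants) == 1L) fmt <- matrix(fmt, nrow = 1L)
  body <- paste(variants$scaffold, variants$pos, ".", variants$ref,
                variants$alt, sprintf("%.1f", variants$qual),
                variants$filter, ".", "GT:GQ:DP",
                apply(fmt, 1L, paste, collapse = "\t"), sep = "\t")
  readr::write_lines(c(header, body), path)
}

#' Library identifiers present in a variant tibble
#'
#' @param variants Variant tibble with `gt_<library>` columns.
#' @return Character vector of library ids.
#' @export
variant_libraries <- function(variants) {
  sub("^gt_", "", grep("^gt_", names(variants), value = TRUE))
}
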