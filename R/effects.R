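# Coding-consequence annotation: map variants onto gene models, splice and
# translate wild-type and mutant CDS, and classify the change (synonymous,
# missense, stop_gain, frameshift, splice_site, ...). The premature-stop
# truncation arithmetic used for candidate triage lives here.

CONSEQUENCE_SEVERITY <- c(
  stop_gain = 1, frameshift = 2, splice_site = 3, start_lost = 4,
  stop_loss = 5, missense = 6, inframe_indel = 7, synonymous = 8,
  intron = 9, flank_upstream = 10, flank_downstream = 10, intergenic = 11
)
FLAGGED_CATEGORIES <- c("stop_gain", "frameshift", "splice_site")

#' Spliced coding sequence of a gene model
#'
#' Concatenates the CDS segments in genomic order and reverse-complements
#' the result for minus-strand genes. Models whose CDS does not start with
#' ATG, is not a multiple of 3, or contains an internal stop trigger a
#' model-integrity warning.
#'
#' @param gene One row of a gene-model tibble ([read_gene_models()] shape).
#' @param sequences Reference [Biostrings::DNAStringSet].
#' @return The spliced CDS as an uppercase character string.
#' @export
spliced_cds <- function(gene, sequences) {
  segs <- gene$cds[[1]]
  scaffold <- sequences[[gene$scaffold]]
  pieces <- vapply(seq_len(nrow(segs)), function(i)
    as.character(Biostrings::subseq(scaffold, segs$start[i], segs$end[i])),
    character(1))
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  check_cds_integrity(s, gene$gene_id)
  s
}

check_cds_integrity <- function(s, gene_id) {
  bad <- character(0)
  if (substr(s, 1L, 3L) != "ATG") bad <- c(bad, "does not start with ATG")
  if (nchar(s) %% 3L != 0L) bad <- c(bad, "length not a multiple of 3")
  aa <- translate_cds(s)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L && stop_at < nchar(aa)) bad <- c(bad, "internal stop codon")
  if (length(bad)) {
    warning("gene model '", gene_id, "' flagged: ",
            paste(bad, collapse = "; "), call. = FALSE)
  }
  invisible(length(bad) == 0L)
}

# Translate a CDS string (standard nuclear code), truncating a trailing
# partial codon; "*" marks stops.
translate_cds <- function(s) {
  usable <- nchar(s) - nchar(s) %% 3L
  if (usable < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, usable)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

# Residues before the first stop.
protein_len <- function(aa) {
  stop_at <- as.vector(regexpr("*", aa, fixed = TRUE))
  if (stop_at < 0L) nchar(aa) else stop_at - 1L
}

#' Locate variants relative to gene models
#'
#' Reports every gene whose body or `flank`-bp flank overlaps the variant's
#' REF footprint, labelling the region `body`, `upstream` or `downstream`
#' relative to the gene's strand; variants touching no gene are
#' `intergenic`.
#'
#' @param variants Variant tibble.
#' @param genes Gene-model tibble.
#' @param flank Flank width in bp (strict cutoff: a variant `flank + 1` bp
#'   away is intergenic).
#' @return Tibble with one row per variant-gene context: variant columns
#'   `scaffold`, `pos`, `ref`, `alt` plus `gene_id` and `region`.
#' @export
locate_variants <- function(variants, genes, flank = 3000L) {
  v <- variants %>%
    mutate(.vidx = row_number(),
           fp_end = .data$pos + nchar(.data$ref) - 1L)
  out <- list()
  for (scf in unique(v$scaffold)) {
    vs <- v[v$scaffold == scf, ]
    gs <- genes[genes$scaffold == scf, ]
    if (nrow(gs) == 0L) {
      out[[scf]] <- mutate(vs, gene_id = NA_character_,
                           region = "intergenic")
      next
    }
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(vs$pos, vs$fp_end),
      IRanges::IRanges(gs$start - flank, gs$end + flank))
    hit_tbl <- tibble(
      vrow = S4Vectors::queryHits(hits),
      grow = S4Vectors::subjectHits(hits)
    ) %>%
      mutate(
        gene_id = gs$gene_id[.data$grow],
        region = purrr::map2_chr(.data$vrow, .data$grow, function(a, b) {
          if (vs$fp_end[a] < gs$start[b]) {
            if (gs$strand[b] == "+") "upstream" else "downstream"
          } else if (vs$pos[a] > gs$end[b]) {
            if (gs$strand[b] == "+") "downstream" else "upstream"
          } else "body"
        })
      )
    located <- vs %>%
      mutate(vrow = row_number()) %>%
      left_join(hit_tbl, by = "vrow") %>%
      mutate(region = if_else(is.na(.data$region), "intergenic",
                              .data$region))
    out[[scf]] <- located
  }
  bind_rows(out) %>%
    arrange(.data$.vidx) %>%
    select(-any_of(c(".vidx", "vrow", "grow", "fp_end")))
}

# Map genomic footprint bases of a record onto spliced-CDS coordinates;
# NA for bases outside the CDS.
footprint_cds_pos <- function(gene, gpos) {
  vapply(gpos, function(p) genomic_to_cds(gene, p), integer(1))
}

# Distance from an intronic position to the nearest exon boundary; the two
# canonical intronic bases at each junction count as splice sites.
is_splice_site <- function(gene, gpos) {
  segs <- gene$cds[[1]]
  if (nrow(segs) < 2L) return(rep(FALSE, length(gpos)))
  donors <- c(segs$end[-nrow(segs)] + 1L, segs$end[-nrow(segs)] + 2L)
  acceptors <- c(segs$start[-1L] - 1L, segs$start[-1L] - 2L)
  gpos %in% c(donors, acceptors)
}

# Consequence of one biallelic variant on one gene. `region` comes from
# locate_variants(); `cds_cache` maps gene_id -> spliced CDS string.
consequence_one <- function(variant, gene, region, sequences, cds_cache) {
  base <- tibble(
    scaffold = variant$scaffold, pos = variant$pos,
    ref = variant$ref, alt = variant$alt, gene_id = gene$gene_id,
    category = NA_character_, cds_pos = NA_integer_,
    codon_index = NA_integer_, ref_aa = NA_character_,
    alt_aa = NA_character_, wt_protein_len = NA_integer_,
    mut_protein_len = NA_integer_
  )
  if (region == "upstream") { base$category <- "flank_upstream"; return(base) }
  if (region == "downstream") { base$category <- "flank_downstream"; return(base) }

  ref_len <- nchar(variant$ref)
  fp <- variant$pos:(variant$pos + ref_len - 1L)
  genome_ref <- as.character(Biostrings::subseq(
    sequences[[variant$scaffold]], variant$pos, variant$pos + ref_len - 1L))
  if (!identical(genome_ref, variant$ref)) {
    stop("variant REF '", variant$ref, "' at ", variant$scaffold, ":",
         variant$pos, " does not match the reference sequence ('",
         genome_ref, "')", call. = FALSE)
  }

  wt_cds <- cds_cache[[gene$gene_id]]
  wt_aa <- translate_cds(wt_cds)
  wt_len <- protein_len(wt_aa)
  base$wt_protein_len <- wt_len

  is_indel <- nchar(variant$ref) != nchar(variant$alt)
  cds_idx <- footprint_cds_pos(gene, fp)
  changed_fp <- if (is_indel && nchar(variant$ref) > 1L) fp[-1L] else fp
  changed_idx <- if (is_indel && nchar(variant$ref) > 1L) cds_idx[-1L] else cds_idx

  in_cds <- any(!is.na(changed_idx))
  splice <- any(is_splice_site(gene, changed_fp))
  if (is_indel && !in_cds) {
    # an insertion point inside the CDS still disrupts it
    anchor_in <- !is.na(genomic_to_cds(gene, variant$pos))
    if (nchar(variant$alt) > nchar(variant$ref) && anchor_in) in_cds <- TRUE
  }

  # splice zones are intronic, so any footprint touching them wins on
  # severity; a substitution straddling a junction necessarily touches one
  if (splice || (!is_indel && in_cds && any(is.na(changed_idx)))) {
    base$category <- "splice_site"
    return(base)
  }
  if (!in_cds) {
    base$category <- "intron"
    return(base)
  }

  if (!is_indel) {
    cp <- changed_idx
    cds_alt <- if (gene$strand == "+") variant$alt else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(variant$alt)))
    alt_bases <- strsplit(cds_alt, "")[[1]]
    mut_cds <- wt_cds
    if (gene$strand == "+") {
      for (i in seq_along(cp)) substr(mut_cds, cp[i], cp[i]) <- alt_bases[i]
    } else {
      # reverse complemented alt aligns to descending genomic = ascending CDS
      cp_asc <- sort(cp)
      for (i in seq_along(cp_asc)) {
        substr(mut_cds, cp_asc[i], cp_asc[i]) <- alt_bases[i]
      }
    }
    mut_aa <- translate_cds(mut_cds)
    mut_len <- protein_len(mut_aa)
    first_cds <- min(cp)
    codon_i <- (first_cds + 2L) %/% 3L
    base$cds_pos <- first_cds
    base$codon_index <- codon_i
    last_codon <- (max(cp) + 2L) %/% 3L
    base$ref_aa <- substr(wt_aa, codon_i, last_codon)
    base$alt_aa <- substr(mut_aa, codon_i, last_codon)
    base$mut_protein_len <- mut_len
    base$category <- if (identical(wt_aa, mut_aa)) "synonymous"
      else if (codon_i == 1L && substr(mut_cds, 1L, 3L) != "ATG") "start_lost"
      else if (mut_len < wt_len) "stop_gain"
      else if (mut_len > wt_len) "stop_loss"
      else "missense"
    return(base)
  }

  # coding indel
  len_change <- nchar(variant$alt) - nchar(variant$ref)
  ins_point <- genomic_to_cds(gene, variant$pos)
  first_cds <- if (len_change < 0L) min(changed_idx, na.rm = TRUE) else
    ins_point + if (gene$strand == "+") 1L else 0L
  base$cds_pos <- first_cds
  base$codon_index <- (first_cds + 2L) %/% 3L
  mut_cds <- mutate_cds_indel(wt_cds, gene, variant, changed_idx, len_change)
  mut_aa <- translate_cds(mut_cds)
  mut_len <- protein_len(mut_aa)
  base$mut_protein_len <- mut_len
  if (abs(len_change) %% 3L != 0L) {
    base$category <- "frameshift"
  } else if (mut_len < wt_len) {
    base$category <- "stop_gain"          # in-frame indel exposing a stop
  } else {
    base$category <- "inframe_indel"
  }
  base
}

# Apply a deletion/insertion to the spliced CDS. Deleted bases are those of
# the footprint that lie in the CDS; inserted bases go in at the anchor's
# CDS position (reverse-complemented for minus-strand genes).
mutate_cds_indel <- function(wt_cds, gene, variant, changed_idx, len_change) {
  if (len_change < 0L) {
    del <- sort(changed_idx[!is.na(changed_idx)])
    keep <- setdiff(seq_len(nchar(wt_cds)), del)
    paste(strsplit(wt_cds, "")[[1]][keep], collapse = "")
  } else {
    ins <- substr(variant$alt, 2L, nchar(variant$alt))
    anchor <- genomic_to_cds(gene, variant$pos)
    if (gene$strand == "+") {
      paste0(substr(wt_cds, 1L, anchor), ins,
             substr(wt_cds, anchor + 1L, nchar(wt_cds)))
    } else {
      ins_rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ins)))
      paste0(substr(wt_cds, 1L, anchor - 1L), ins_rc,
             substr(wt_cds, anchor, nchar(wt_cds)))
    }
  }
}

#' Annotate variants with their coding consequences
#'
#' For every variant-gene context from [locate_variants()], splices and
#' translates the wild-type and mutant CDS and classifies the change.
#' Intronic variants within the two canonical bases of a junction are
#' `splice_site`; substitutions are compared codon-by-codon (`synonymous`,
#' `missense`, `stop_gain`, `stop_loss`, `start_lost`); coding indels are
#' `frameshift` when their length change is not a multiple of 3, otherwise
#' `inframe_indel` (re-translated, so an in-frame indel exposing a
#' premature stop is reported as `stop_gain`). Flank variants get no
#' coding consequence.
#'
#' @param variants Biallelic variant tibble.
#' @param genes Gene-model tibble.
#' @param sequences Reference [Biostrings::DNAStringSet].
#' @param flank Flank width in bp.
#' @return Tibble with one row per variant-gene context (`intergenic` rows
#'   keep `gene_id = NA`): category, CDS/codon coordinates, wild-type and
#'   mutant protein lengths (residues, stop excluded).
#' @export
annotate_consequences <- function(variants, genes, sequences, flank = 3000L) {
  if (any(variants$n_alt > 1L)) {
    stop("annotate_consequences expects biallelic records; drop multiallelic ones first",
         call. = FALSE)
  }
  ctx <- locate_variants(variants, genes, flank)
  cds_cache <- list()
  rows <- vector("list", nrow(ctx))
  for (i in seq_len(nrow(ctx))) {
    r <- ctx[i, ]
    if (is.na(r$gene_id)) {
      rows[[i]] <- tibble(scaffold = r$scaffold, pos = r$pos, ref = r$ref,
                          alt = r$alt, gene_id = NA_character_,
                          category = "intergenic", cds_pos = NA_integer_,
                          codon_index = NA_integer_, ref_aa = NA_character_,
                          alt_aa = NA_character_,
                          wt_protein_len = NA_integer_,
                          mut_protein_len = NA_integer_)
      next
    }
    gene <- genes[genes$gene_id == r$gene_id, ]
    if (is.null(cds_cache[[r$gene_id]])) {
      cds_cache[[r$gene_id]] <- spliced_cds(gene, sequences)
    }
    rows[[i]] <- consequence_one(r, gene, r$region, sequences, cds_cache)
  }
  bind_rows(rows)
}

#' Rank candidate genes by consequence severity
#'
#' Summarizes consequences per gene and flags genes carrying a stop-gain,
#' frameshift or splice-site change among the (typically cosegregating)
#' input variants as top candidates. Ordering is deterministic: flagged
#' genes first, then by the severity of their most severe consequence,
#' then genomic coordinate.
#'
#' @param consequences Output of [annotate_consequences()].
#' @param genes Gene-model tibble (for coordinates).
#' @return Tibble of class `candidate_report`: one row per gene with
#'   per-category counts, `top_category` and `flagged`.
#' @export
candidate_report <- function(consequences, genes) {
  per_gene <- consequences %>%
    filter(!is.na(.data$gene_id)) %>%
    count(.data$gene_id, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  if (nrow(per_gene) == 0L) {
    res <- tibble(gene_id = character(), scaffold = character(),
                  start = integer(), top_category = character(),
                  flagged = logical(), n_variants = integer())
    class(res) <- c("candidate_report", class(res))
    return(res)
  }
  cat_cols <- intersect(names(CONSEQUENCE_SEVERITY), names(per_gene))
  res <- per_gene %>%
    mutate(
      n_variants = rowSums(across(all_of(cat_cols))),
      top_category = purrr::pmap_chr(across(all_of(cat_cols)), function(...) {
        counts <- c(...)
        present <- names(counts)[counts > 0]
        present[which.min(CONSEQUENCE_SEVERITY[present])]
      }),
      flagged = purrr::pmap_lgl(across(all_of(FLAGGED_CATEGORIES[
        FLAGGED_CATEGORIES %in% cat_cols])), function(...) sum(...) > 0)
    ) %>%
    left_join(genes %>% select(all_of(c("gene_id", "scaffold", "start"))),
              by = "gene_id") %>%
    arrange(desc(.data$flagged), CONSEQUENCE_SEVERITY[.data$top_category],
            .data$scaffold, .data$start) %>%
    relocate(all_of(c("gene_id", "scaffold", "start", "n_variants",
                      "top_category", "flagged")))
  class(res) <- c("candidate_report", class(res))
  res
}
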