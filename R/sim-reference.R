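#' @import tibble
#' @importFrom dplyr %>% mutate filter arrange select bind_rows group_by
#'   ungroup summarise across left_join row_number n desc all_of any_of
#'   if_else first last rename relocate distinct pull slice count
#' @importFrom rlang .data
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
}

random_dna <- function(n) {
  intToUtf8(sample(utf8ToInt("ACGT"), n, replace = TRUE))
}

# CDS string of cds_len nt: ATG start, one terminal stop, no internal stop.
# force_codon: optional list(index=, codon=) overriding one internal codon.
make_cds <- function(cds_len, force_codon = NULL) {
  n_codon <- cds_len %/% 3L
  stopifnot(cds_len %% 3L == 0L, n_codon >= 3L)
  internal <- setdiff(all_codons(), STOP_CODONS)
  codons <- c("ATG",
              sample(internal, n_codon - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
  if (!is.null(force_codon)) {
    stopifnot(force_codon$index > 1L, force_codon$index < n_codon)
    codons[force_codon$index] <- force_codon$codon
  }
  paste(codons, collapse = "")
}

# Partition cds_len into n_exons positive chunk lengths (transcription order).
split_exon_lengths <- function(cds_len, n_exons) {
  if (n_exons == 1L) return(cds_len)
  cuts <- sort(sample.int(cds_len - 1L, n_exons - 1L))
  diff(c(0L, cuts, cds_len))
}

# Lay out one gene starting at `start` on the genomic strand. Returns a
# one-row tibble with list-columns for exon and CDS segments. Exons equal
# CDS segments (the simulator emits UTR-less models).
layout_gene <- function(gene_id, scaffold, strand, start, cds_len, n_exons,
                        intron_range = c(200L, 1500L)) {
  seg_len <- split_exon_lengths(cds_len, n_exons)           # transcription order
  introns <- if (n_exons > 1L) {
    sample(seq(intron_range[1], intron_range[2]), n_exons - 1L, replace = TRUE)
  } else integer(0)
  if (strand == "-") seg_len <- rev(seg_len)                # genomic order
  seg_start <- start + cumsum(c(0L, head(seg_len, -1L) + introns))
  seg_end <- seg_start + seg_len - 1L
  # phase of each segment in transcription order
  tx_len <- if (strand == "+") seg_len else rev(seg_len)
  phase_tx <- (3L - cumsum(c(0L, head(tx_len, -1L))) %% 3L) %% 3L
  phase <- if (strand == "+") phase_tx else rev(phase_tx)
  segs <- tibble(start = seg_start, end = seg_end, phase = phase)
  tibble(
    gene_id = gene_id, scaffold = scaffold, strand = strand,
    start = min(seg_start), end = max(seg_end),
    cds_len = cds_len,
    exons = list(segs[, c("start", "end")]),
    cds = list(segs)
  )
}

#' Build a synthetic reference bundle
#'
#' Generates random scaffold sequences, multi-exon protein-coding gene
#' models on both strands (every spliced CDS starts with ATG, ends with a
#' single stop codon and contains no internal stop), and a repeat track
#' covering approximately `repeat_fraction` of each scaffold while never
#' overlapping the causal gene's CDS. All output is a deterministic
#' function of the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_reference` with elements `sequences`
#'   (a [Biostrings::DNAStringSet]), `genes` (tibble with `exons`/`cds`
#'   list-columns), `repeats` (tibble, 1-based inclusive), `causal_gene`,
#'   `scaffold_lengths` and `config`.
#' @export
build_reference <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, build_reference_impl(config))
}

build_reference_impl <- function(config) {
  lens <- config$scaffold_lengths
  seqs <- Biostrings::DNAStringSet(vapply(lens, random_dna, character(1)))
  names(seqs) <- names(lens)

  causal_id <- config$causal_gene
  if (is.null(causal_id)) causal_id <- paste0("gene_", names(lens)[1], "_2")
  causal_codon_idx <- (config$causal_cds_pos + 2L) %/% 3L

  genes <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    L <- lens[i]
    n_genes <- max(3L, as.integer(round(L / 4e5)))
    rows <- vector("list", n_genes)
    cursor <- 5000L
    for (j in seq_len(n_genes)) {
      gid <- paste0("gene_", names(lens)[i], "_", j)
      is_causal <- identical(gid, causal_id)
      cds_len <- if (is_causal) config$causal_cds_len else
        3L * sample(100:800, 1L)
      n_exons <- if (is_causal) sample(8:12, 1L) else sample(2:5, 1L)
      # keep the causal gene interior so its linked block fits the scaffold
      if (is_causal) cursor <- max(cursor, as.integer(0.3 * L))
      gap <- sample(8000:20000, 1L)
      row <- layout_gene(gid, names(lens)[i],
                         strand = if (j %% 2L == 1L) "+" else "-",
                         start = cursor + gap, cds_len = cds_len,
                         n_exons = n_exons)
      if (row$end > L - 5000L) {
        stop("scaffold '", names(lens)[i], "' too short for ", n_genes,
             " gene models", call. = FALSE)
      }
      cursor <- row$end
      # write the coding sequence into the scaffold
      cds_seq <- make_cds(cds_len, force_codon = if (is_causal)
        list(index = causal_codon_idx, codon = sample(c("CAG", "CAA"), 1L)))
      segs <- row$cds[[1]]
      genome_seq <- if (row$strand == "+") cds_seq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
      offs <- cumsum(c(0L, head(segs$end - segs$start + 1L, -1L)))
      pieces <- substring(genome_seq, offs + 1L,
                          offs + (segs$end - segs$start + 1L))
      seqs[[i]] <- Biostrings::replaceAt(
        seqs[[i]], IRanges::IRanges(segs$start, segs$end),
        Biostrings::DNAStringSet(pieces))
      rows[[j]] <- row
    }
    genes[[i]] <- bind_rows(rows)
  }
  genes <- bind_rows(genes)
  if (!causal_id %in% genes$gene_id) {
    stop("configured causal gene '", causal_id, "' was not built",
         call. = FALSE)
  }
  if (config$causal_cds_pos > genes$cds_len[genes$gene_id == causal_id] - 3L) {
    stop("causal gene is shorter than causal_cds_pos", call. = FALSE)
  }

  repeats <- simulate_repeats(config, genes, causal_id)

  structure(
    list(sequences = seqs, scaffold_lengths = lens, genes = genes,
         repeats = repeats, causal_gene = causal_id, config = config),
    class = "sim_reference")
}

# Random non-overlapping repeat intervals covering ~ repeat_fraction of each
# scaffold, clipped away from the causal gene's CDS.
simulate_repeats <- function(config, genes, causal_id) {
  f <- config$repeat_fraction
  if (f <= 0) {
    return(tibble(scaffold = character(), start = integer(), end = integer()))
  }
  causal_cds <- genes$cds[[match(causal_id, genes$gene_id)]]
  causal_scaffold <- genes$scaffold[genes$gene_id == causal_id]
  out <- vector("list", length(config$scaffold_lengths))
  for (i in seq_along(config$scaffold_lengths)) {
    L <- config$scaffold_lengths[i]
    scf <- names(config$scaffold_lengths)[i]
    target <- f * L
    lens <- integer(0)
    while (sum(lens) < target) {
      lens <- c(lens, 200L + as.integer(rexp(50, 1 / 1800)))
    }
    lens <- lens[cumsum(lens) <= target]
    if (length(lens) == 0L) lens <- as.integer(target)
    slack <- L - sum(lens)
    gaps <- rexp(length(lens) + 1L)
    gaps <- floor(gaps / sum(gaps) * slack)
    starts <- cumsum(gaps[seq_along(lens)] + c(1L, head(lens, -1L)))
    ir <- IRanges::IRanges(starts, width = lens)
    ir <- IRanges::restrict(ir, start = 1L, end = as.integer(L))
    if (identical(scf, causal_scaffold)) {
      ir <- IRanges::setdiff(ir, IRanges::IRanges(causal_cds$start,
                                                  causal_cds$end))
    }
    out[[i]] <- tibble(scaffold = scf, start = IRanges::start(ir),
                       end = IRanges::end(ir))
  }
  bind_rows(out)
}

#' Map a spliced-CDS coordinate to its genomic base
#'
#' @param gene One row of the `genes` tibble of a reference bundle.
#' @param cds_pos 1-based position in the spliced CDS.
#' @return 1-based genomic position on the gene's scaffold.
#' @export
cds_to_genomic <- function(gene, cds_pos) {
  segs <- gene$cds[[1]]
  widths <- segs$end - segs$start + 1L
  if (cds_pos < 1L || cds_pos > sum(widths)) {
    stop("cds_pos outside CDS", call. = FALSE)
  }
  if (gene$strand == "+") {
    ends <- cumsum(widths)
    k <- which(cds_pos <= ends)[1]
    segs$start[k] + (cds_pos - c(0L, ends)[k] - 1L)
  } else {
    widths_tx <- rev(widths)                      # transcription order
    ends <- cumsum(widths_tx)
    k <- which(cds_pos <= ends)[1]
    seg <- segs[nrow(segs) - k + 1L, ]
    seg$end - (cds_pos - c(0L, ends)[k] - 1L)
  }
}

#' Map a genomic base to its spliced-CDS coordinate
#'
#' Inverse of [cds_to_genomic()]; returns `NA` for positions outside the CDS.
#' @inheritParams cds_to_genomic
#' @param genomic_pos 1-based genomic position.
#' @export
genomic_to_cds <- function(gene, genomic_pos) {
  segs <- gene$cds[[1]]
  widths <- segs$end - segs$start + 1L
  k <- which(genomic_pos >= segs$start & genomic_pos <= segs$end)
  if (length(k) == 0L) return(NA_integer_)
  if (gene$strand == "+") {
    sum(widths[seq_len(k - 1L)]) + (genomic_pos - segs$start[k] + 1L)
  } else {
    after <- if (k < nrow(segs)) sum(widths[(k + 1L):nrow(segs)]) else 0L
    after + (segs$end[k] - genomic_pos + 1L)
  }
}

#' Plant the causal stop-gain substitution
#'
#' Records a C-to-T substitution (on the coding strand) at the genomic base
#' corresponding to a spliced-CDS coordinate. The target codon must be a
#' glutamine codon (CAG or CAA) with `cds_pos` at its first base, so the
#' substitution converts it to a premature stop (TAG/TAA) and truncates
#' the protein.
#'
#' @param reference A `sim_reference` bundle.
#' @param gene_id Gene receiving the substitution; defaults to the bundle's
#'   causal gene.
#' @param cds_pos 1-based spliced-CDS coordinate of the substitution.
#' @return A list of class `sim_truth`: causal scaffold/position, REF and
#'   ALT bases as they appear in the (plus-strand) reference, the linked
#'   interval, and the identity of the causal gene.
#' @export
plant_causal_stop <- function(reference,
                              gene_id = reference$causal_gene,
                              cds_pos = reference$config$causal_cds_pos) {
  gene <- reference$genes[reference$genes$gene_id == gene_id, ]
  if (nrow(gene) != 1L) stop("unknown gene '", gene_id, "'", call. = FALSE)
  if (cds_pos %% 3L != 1L) {
    stop("cds_pos must be the first base of a codon", call. = FALSE)
  }
  cds <- spliced_cds(gene, reference$sequences)
  codon <- substr(cds, cds_pos, cds_pos + 2L)
  if (!codon %in% c("CAG", "CAA")) {
    stop("target codon is ", codon, ", not a glutamine codon (CAG/CAA)",
         call. = FALSE)
  }
  gpos <- cds_to_genomic(gene, cds_pos)
  plus_ref <- if (gene$strand == "+") "C" else "G"
  plus_alt <- if (gene$strand == "+") "T" else "A"
  L <- reference$scaffold_lengths[[gene$scaffold]]
  half <- reference$config$linked_block_bp %/% 2L
  linked <- c(max(1L, gpos - half), min(as.integer(L), gpos + half))
  structure(
    list(causal_scaffold = gene$scaffold, causal_pos = gpos,
         causal_ref = plus_ref, causal_alt = plus_alt,
         causal_gene = gene_id, causal_cds_pos = cds_pos,
         linked_interval = linked),
    class = "sim_truth")
}
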