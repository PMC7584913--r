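test_that("spliced CDS assembly matches a manual splice on a toy gene", {
  # 30-bp CDS split over two exons on the minus strand
  cds <- "ATGGCTACCGATTGGAAACCCGGGTTTTAA"
  tg <- toy_gene(cds, n_exons = 2L, strand = "-", intron_len = 10L)
  expect_identical(spliced_cds(tg$genes, tg$sequences), cds)

  # manual check: the genome holds the reverse complement across segments
  segs <- tg$genes$cds[[1]]
  genome <- paste(vapply(seq_len(nrow(segs)), function(i)
    as.character(Biostrings::subseq(tg$sequences[[1]], segs$start[i],
                                    segs$end[i])), character(1)),
    collapse = "")
  expect_identical(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome))),
    cds)

  # plus strand: simple substring concatenation
  tgp <- toy_gene(cds, n_exons = 3L, strand = "+")
  expect_identical(spliced_cds(tgp$genes, tgp$sequences), cds)

  # model-integrity warnings
  bad <- toy_gene("CCCGATTAA", n_exons = 1L)
  expect_warning(spliced_cds(bad$genes, bad$sequences), "ATG")
})

test_that("CDS/genomic coordinate mapping is a bijection on both strands", {
  cds <- toy_cds(50L)
  for (strand in c("+", "-")) {
    tg <- toy_gene(cds, n_exons = 4L, strand = strand)
    gene <- tg$genes
    for (p in c(1L, 2L, 3L, 77L, 150L, nchar(cds))) {
      g <- cds_to_genomic(gene, p)
      expect_identical(genomic_to_cds(gene, g), p,
                       label = paste(strand, p))
      # the genomic base agrees with the CDS base (complemented on -)
      base <- as.character(Biostrings::subseq(tg$sequences[[1]], g, g))
      want <- substr(cds, p, p)
      if (strand == "-") want <- chartr("ACGT", "TGCA", want)
      expect_identical(base, want)
    }
    expect_error(cds_to_genomic(gene, nchar(cds) + 1L), "outside")
    expect_true(is.na(genomic_to_cds(gene, gene$start - 1L)))
  }
})

test_that("substitution consequences are classified against both translations", {
  # codon 5 is GCC (Ala); codon 10 is CAG (Gln)
  cds <- toy_cds(30L, override = list(`5` = "GCC", `10` = "CAG"))
  tg <- toy_gene(cds, n_exons = 2L, strand = "+", intron_len = 30L)
  gene <- tg$genes; seqs <- tg$sequences

  # third-position GCC -> GCT: synonymous
  g15 <- cds_to_genomic(gene, 15L)
  v_syn <- one_variant("toy", g15, "C", "T")
  c_syn <- annotate_consequences(v_syn, gene, seqs)
  c_syn <- c_syn[!is.na(c_syn$gene_id), ]
  expect_identical(c_syn$category, "synonymous")
  expect_identical(c_syn$cds_pos, 15L)
  expect_identical(c_syn$ref_aa, c_syn$alt_aa)

  # first-position GCC -> CCC: missense Ala -> Pro
  g13 <- cds_to_genomic(gene, 13L)
  c_mis <- annotate_consequences(one_variant("toy", g13, "G", "C"),
                                 gene, seqs)
  c_mis <- c_mis[!is.na(c_mis$gene_id), ]
  expect_identical(c_mis$category, "missense")
  expect_identical(c_mis$ref_aa, "A")
  expect_identical(c_mis$alt_aa, "P")

  # CAG -> TAG at codon 10: stop gain, truncation arithmetic
  g28 <- cds_to_genomic(gene, 28L)
  c_stop <- annotate_consequences(one_variant("toy", g28, "C", "T"),
                                  gene, seqs)
  c_stop <- c_stop[!is.na(c_stop$gene_id), ]
  expect_identical(c_stop$category, "stop_gain")
  expect_identical(c_stop$wt_protein_len, 30L)
  expect_identical(c_stop$mut_protein_len, 9L)   # ceil(28 / 3) - 1

  # REF mismatch against the reference sequence is a data error
  expect_error(
    annotate_consequences(one_variant("toy", g28, "A", "T"), gene, seqs),
    "does not match")
})

test_that("stop-gain truncation equals ceil(p / 3) - 1 across random sites", {
  withr::with_seed(21L, {
    n_codons <- 40L
    overrides <- list()
    qs <- sort(sample(3:(n_codons - 2L), 6L))
    for (q in qs) overrides[[as.character(q)]] <- "CAA"
    cds <- toy_cds(n_codons, override = overrides)
    for (strand in c("+", "-")) {
      tg <- toy_gene(cds, n_exons = 3L, strand = strand)
      for (q in qs) {
        p <- 3L * (q - 1L) + 1L
        g <- cds_to_genomic(tg$genes, p)
        ref <- if (strand == "+") "C" else "G"
        alt <- if (strand == "+") "T" else "A"
        cons <- annotate_consequences(one_variant("toy", g, ref, alt),
                                      tg$genes, tg$sequences)
        cons <- cons[!is.na(cons$gene_id), ]
        expect_identical(cons$category, "stop_gain")
        expect_identical(cons$mut_protein_len, as.integer(ceiling(p / 3) - 1))
        expect_identical(cons$wt_protein_len, n_codons)
      }
    }
  })
})

test_that("indels in the CDS are frameshift or in-frame by length mod 3", {
  cds <- toy_cds(30L)
  tg <- toy_gene(cds, n_exons = 1L)
  gene <- tg$genes; seqs <- tg$sequences
  g10 <- cds_to_genomic(gene, 10L)
  ref2 <- as.character(Biostrings::subseq(seqs[[1]], g10, g10 + 1L))
  c_fs <- annotate_consequences(one_variant("toy", g10, ref2,
                                            substr(ref2, 1L, 1L)),
                                gene, seqs)
  c_fs <- c_fs[!is.na(c_fs$gene_id), ]
  expect_identical(c_fs$category, "frameshift")

  ref4 <- as.character(Biostrings::subseq(seqs[[1]], g10, g10 + 3L))
  c_if <- annotate_consequences(one_variant("toy", g10, ref4,
                                            substr(ref4, 1L, 1L)),
                                gene, seqs)
  c_if <- c_if[!is.na(c_if$gene_id), ]
  expect_true(c_if$category %in% c("inframe_indel", "stop_gain"))
})

test_that("splice sites, introns, flanks and intergenic space are regioned", {
  cds <- toy_cds(30L)
  tg <- toy_gene(cds, n_exons = 2L, strand = "+", intron_len = 30L,
                 offset = 3200L, pad = 3500L)
  gene <- tg$genes; seqs <- tg$sequences
  segs <- gene$cds[[1]]
  intron_first <- segs$end[1] + 1L
  ref_at <- function(p) as.character(Biostrings::subseq(seqs[[1]], p, p))
  cat_at <- function(p) {
    cons <- annotate_consequences(one_variant("toy", p, ref_at(p), safe_alt(p)),
                                  gene, seqs)
    cons$category[!is.na(cons$gene_id)][1]
  }
  safe_alt <- function(p) setdiff(c("A", "C", "G", "T"), ref_at(p))[1]
  expect_identical(cat_at(intron_first), "splice_site")
  expect_identical(cat_at(intron_first + 1L), "splice_site")
  expect_identical(cat_at(intron_first + 2L), "intron")
  expect_identical(cat_at(segs$start[2] - 1L), "splice_site")
  expect_identical(cat_at(segs$start[2] - 3L), "intron")
  expect_identical(cat_at(gene$start - 1000L), "flank_upstream")
  expect_identical(cat_at(gene$end + 1000L), "flank_downstream")

  # strict 3,000-bp flank cutoff
  far <- annotate_consequences(
    one_variant("toy", gene$start - 3001L, ref_at(gene$start - 3001L), "A"),
    gene, seqs)
  expect_identical(far$category, "intergenic")
  near <- locate_variants(
    one_variant("toy", gene$start - 3000L, ref_at(gene$start - 3000L), "A"),
    gene)
  expect_identical(near$region, "upstream")
})

test_that("consequences are invariant under reverse-complementing the scaffold", {
  cds <- toy_cds(30L, override = list(`10` = "CAG", `5` = "GCC"))
  tg <- toy_gene(cds, n_exons = 2L, strand = "+", intron_len = 24L)
  gene <- tg$genes; seqs <- tg$sequences
  L <- Biostrings::width(seqs)[1]
  seqs_rc <- Biostrings::DNAStringSet(Biostrings::reverseComplement(seqs[[1]]))
  names(seqs_rc) <- "toy"
  segs <- gene$cds[[1]]
  gene_rc <- gene
  gene_rc$strand <- "-"
  gene_rc$start <- L - gene$end + 1L
  gene_rc$end <- L - gene$start + 1L
  flipped <- tibble::tibble(start = L - rev(segs$end) + 1L,
                            end = L - rev(segs$start) + 1L,
                            phase = rev(segs$phase))
  gene_rc$cds <- list(flipped)
  gene_rc$exons <- list(flipped[, c("start", "end")])
  expect_identical(spliced_cds(gene_rc, seqs_rc), cds)

  for (p in c(13L, 15L, 28L)) {       # missense, synonymous, stop sites
    g <- cds_to_genomic(gene, p)
    ref <- as.character(Biostrings::subseq(seqs[[1]], g, g))
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    a <- annotate_consequences(one_variant("toy", g, ref, alt), gene, seqs)
    b <- annotate_consequences(
      one_variant("toy", L - g + 1L, chartr("ACGT", "TGCA", ref),
                  chartr("ACGT", "TGCA", alt)), gene_rc, seqs_rc)
    expect_identical(a$category[!is.na(a$gene_id)],
                     b$category[!is.na(b$gene_id)], label = p)
  }
})

test_that("candidate ranking flags severe genes deterministically", {
  cons <- tibble::tibble(
    scaffold = "s", pos = c(10L, 20L, 30L, 40L, 50L),
    ref = "A", alt = "T",
    gene_id = c("g1", "g1", "g2", "g3", NA),
    category = c("missense", "stop_gain", "synonymous", "stop_gain",
                 "intergenic"),
    cds_pos = NA_integer_, codon_index = NA_integer_,
    ref_aa = NA_character_, alt_aa = NA_character_,
    wt_protein_len = NA_integer_, mut_protein_len = NA_integer_
  )
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), scaffold = "s",
                          strand = "+", start = c(100L, 200L, 5L),
                          end = c(150L, 250L, 50L))
  rep <- candidate_report(cons, genes)
  expect_identical(rep$gene_id[rep$flagged], c("g3", "g1"))  # coordinate order
  expect_identical(rep$top_category[rep$gene_id == "g2"], "synonymous")
  expect_false(rep$flagged[rep$gene_id == "g2"])

  empty <- candidate_report(cons[0, ], genes)
  expect_identical(nrow(empty), 0L)
})
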