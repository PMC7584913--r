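# Cosegregation classification against the expected genotypes at a
# recessive locus, run detection, sliding-window proportions, fixed-width
# bin counts and recombinant-based interval refinement.

parse_allele <- function(gt, which) {
  as.integer(stringr::str_split_fixed(gt, "/", 2L)[, which])
}

#' Are variants informative in the parental comparison?
#'
#' A site is informative when the affected parent is homozygous (for either
#' allele) and the carrier parent heterozygous, so offspring genotypes can
#' reveal linkage.
#'
#' @param variants Variant tibble.
#' @param father,mother Library ids of the affected-homozygous father and
#'   carrier mother.
#' @return Logical vector.
#' @export
informative_parental <- function(variants, father = "father",
                                 mother = "mother") {
  fg <- variants[[paste0("gt_", father)]]
  mg <- variants[[paste0("gt_", mother)]]
  if (is.null(fg) || is.null(mg)) {
    stop("parental libraries absent from variant tibble", call. = FALSE)
  }
  f1 <- parse_allele(fg, 1L); f2 <- parse_allele(fg, 2L)
  m1 <- parse_allele(mg, 1L); m2 <- parse_allele(mg, 2L)
  out <- f1 == f2 & m1 != m2
  out & !is.na(out)
}

#' Classify variants as cosegregating with the recessive locus
#'
#' A biallelic variant cosegregates iff some candidate allele X (REF or
#' ALT) makes every affected-homozygous library X/X, every
#' carrier-heterozygous library heterozygous carrying X, and every
#' wildtype-homozygous library homozygous for the other allele. Family
#' mode uses only the `origin == "family"` libraries; extended mode adds
#' the unrelated ones, which can only shrink the cosegregating set.
#'
#' @param variants Variant tibble (biallelic records are judged; records
#'   with more than one ALT are never called cosegregating).
#' @param roles Role sheet tibble ([read_roles()] shape). Must contain at
#'   least one `affected_hom` library.
#' @param mode `"family"` or `"extended"`.
#' @param father,mother Library ids used for [informative_parental()].
#' @return The input tibble with `cosegregating` (logical),
#'   `causal_allele` (`"REF"`, `"ALT"` or `NA`) and `informative`
#'   (logical) columns appended.
#' @export
classify_coseg <- function(variants, roles, mode = c("family", "extended"),
                           father = "father", mother = "mother") {
  mode <- match.arg(mode)
  if (!"origin" %in% names(roles)) roles$origin <- "family"
  use <- if (mode == "family") roles[roles$origin == "family", ] else roles
  if (!any(use$role == "affected_hom")) {
    stop("role sheet lacks an affected_hom library", call. = FALSE)
  }
  missing_libs <- setdiff(use$library_id, variant_libraries(variants))
  if (length(missing_libs)) {
    stop("libraries in role sheet absent from variants: ",
         paste(missing_libs, collapse = ", "), call. = FALSE)
  }

  n <- nrow(variants)
  a1 <- a2 <- list()
  for (lib in use$library_id) {
    gtc <- variants[[paste0("gt_", lib)]]
    a1[[lib]] <- parse_allele(gtc, 1L)
    a2[[lib]] <- parse_allele(gtc, 2L)
  }
  ok_for <- function(x) {
    res <- rep(TRUE, n)
    other <- 1L - x
    for (i in seq_len(nrow(use))) {
      lib <- use$library_id[i]
      h1 <- a1[[lib]]; h2 <- a2[[lib]]
      lib_ok <- switch(use$role[i],
        affected_hom = h1 == x & h2 == x,
        carrier_het = h1 != h2 & (h1 == x | h2 == x),
        wildtype_hom = h1 == other & h2 == other
      )
      res <- res & lib_ok & !is.na(lib_ok)
    }
    res
  }
  coseg_alt <- ok_for(1L)
  coseg_ref <- ok_for(0L)
  biallelic <- variants$n_alt == 1L
  coseg_alt <- coseg_alt & biallelic
  coseg_ref <- coseg_ref & biallelic

  variants %>%
    mutate(
      cosegregating = coseg_alt | coseg_ref,
      causal_allele = dplyr::case_when(coseg_alt ~ "ALT",
                                       coseg_ref ~ "REF",
                                       TRUE ~ NA_character_),
      informative = informative_parental(variants, father, mother)
    )
}

#' Detect candidate intervals by the consecutive-cosegregation run rule
#'
#' Scans the ordered informative calls of each scaffold for maximal
#' intervals that begin and end on a cosegregating variant, contain at
#' least `min_run` cosegregating variants, and never include more than
#' `max_mismatch` successive non-cosegregating variants. Interval bounds
#' are the positions of the terminal cosegregating variants.
#'
#' @param calls Tibble of informative calls from [classify_coseg()]
#'   (typically filtered to `informative`), sorted by scaffold and
#'   position.
#' @param min_run Minimum cosegregating variants per interval.
#' @param max_mismatch Maximum successive mismatches tolerated inside an
#'   interval.
#' @return Tibble with `scaffold`, `start`, `end`, `n_coseg`, `n_mismatch`,
#'   in genomic order and pairwise disjoint within a scaffold.
#' @export
detect_runs <- function(calls, min_run = 3L, max_mismatch = 2L) {
  stopifnot(min_run >= 1L, max_mismatch >= 0L)
  scf_levels <- unique(calls$scaffold)
  idx <- split(seq_len(nrow(calls)), factor(calls$scaffold, scf_levels))
  res <- lapply(scf_levels, function(scf) {
    i <- idx[[scf]]
    pos <- calls$pos[i]
    if (is.unsorted(pos, strictly = FALSE)) {
      stop("calls must be sorted by position within scaffold", call. = FALSE)
    }
    r <- runs_one_scaffold(pos, calls$cosegregating[i], min_run, max_mismatch)
    if (length(r$start)) {
      tibble::new_tibble(c(list(scaffold = rep(scf, length(r$start))), r),
                         nrow = length(r$start))
    } else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(tibble(scaffold = character(0), start = integer(0),
                  end = integer(0), n_coseg = integer(0),
                  n_mismatch = integer(0)))
  }
  bind_rows(res)
}

# Linear scan: fragments are separated by > max_mismatch consecutive
# mismatches; each fragment is trimmed to its terminal cosegregating
# variants and reported if it retains >= min_run of them.
runs_one_scaffold <- function(pos, coseg, min_run, max_mismatch) {
  if (length(pos) == 0L || !any(coseg)) {
    return(list(start = integer(0), end = integer(0),
                n_coseg = integer(0), n_mismatch = integer(0)))
  }
  r <- rle(coseg)
  breaks <- !r$values & r$lengths > max_mismatch
  frag_id <- rep.int(cumsum(breaks), r$lengths)    # break runs get own id
  frag_id[rep.int(breaks, r$lengths)] <- NA        # drop the separators
  start <- end <- n_coseg <- n_mismatch <- integer(0)
  for (f in unique(frag_id[!is.na(frag_id)])) {
    idx <- which(!is.na(frag_id) & frag_id == f)
    ci <- idx[coseg[idx]]
    if (length(ci) < min_run) next
    lo <- ci[1L]; hi <- ci[length(ci)]
    start <- c(start, pos[lo]); end <- c(end, pos[hi])
    n_coseg <- c(n_coseg, length(ci))
    n_mismatch <- c(n_mismatch, sum(!coseg[lo:hi]))
  }
  list(start = start, end = end, n_coseg = n_coseg, n_mismatch = n_mismatch)
}

#' Sliding-window proportion of cosegregating variants
#'
#' For each scaffold longer than `min_scaffold_len`, anchors windows of
#' `window` bp at position 1 advancing by `step`; only full-length windows
#' are emitted, except that a scaffold shorter than one window yields a
#' single window covering the whole scaffold. Each window counts its
#' informative variants and its cosegregating variants; the proportion is
#' undefined (`NA`) when no informative variant falls in the window.
#'
#' @param calls Classified calls from [classify_coseg()].
#' @param scaffold_lengths Named vector of scaffold lengths in bp.
#' @param window,step Window size and step in bp.
#' @param min_scaffold_len Scaffolds at or below this length are skipped.
#' @return A tibble of class `coseg_windows` with `scaffold`, `win_start`,
#'   `win_end`, `n_coseg`, `n_informative`, `proportion`.
#' @export
window_scan <- function(calls, scaffold_lengths, window = 1e6, step = 1e5,
                        min_scaffold_len = 1e5) {
  stopifnot(!is.null(names(scaffold_lengths)))
  out <- list()
  for (scf in names(scaffold_lengths)) {
    L <- scaffold_lengths[[scf]]
    if (L <= min_scaffold_len) next
    starts <- if (L < window) 1 else seq(1, L - window + 1, by = step)
    ends <- pmin(starts + window - 1, L)
    d <- calls[calls$scaffold == scf & calls$informative, ]
    n_inf <- n_cos <- integer(length(starts))
    for (w in seq_along(starts)) {
      inw <- d$pos >= starts[w] & d$pos <= ends[w]
      n_inf[w] <- sum(inw)
      n_cos[w] <- sum(inw & d$cosegregating)
    }
    out[[scf]] <- tibble(scaffold = scf, win_start = starts, win_end = ends,
                         n_coseg = n_cos, n_informative = n_inf)
  }
  res <- bind_rows(out) %>%
    mutate(proportion = if_else(.data$n_informative > 0,
                                .data$n_coseg / .data$n_informative,
                                NA_real_))
  class(res) <- c("coseg_windows", class(res))
  res
}

#' Rank windows by cosegregation proportion
#'
#' Windows with undefined proportions are excluded from ranking; ties on
#' the proportion are broken by genomic order (scaffold input order, then
#' coordinate) and all tied windows are reported.
#'
#' @param windows Output of [window_scan()].
#' @param n Number of distinct top proportion values to keep.
#' @return Tibble of the top windows, best first.
#' @export
top_windows <- function(windows, n = 1L) {
  defined <- windows[!is.na(windows$proportion), ]
  if (nrow(defined) == 0L) return(defined)
  vals <- sort(unique(defined$proportion), decreasing = TRUE)
  keep <- vals[seq_len(min(n, length(vals)))]
  defined[defined$proportion %in% keep, ] %>%
    arrange(desc(.data$proportion))
}

#' Count cosegregating variants in fixed-width bins
#'
#' Bins `[1, bin]`, `[bin + 1, 2 bin]`, ... partition each scaffold, so the
#' bin counts of a scaffold sum to its total cosegregating count.
#'
#' @param calls Classified calls from [classify_coseg()].
#' @param bin Bin width in bp.
#' @param scaffold_lengths Optional named lengths; when given, empty bins
#'   are reported too.
#' @return A tibble of class `coseg_bins` with `scaffold`, `bin_start`,
#'   `bin_end`, `n_coseg`.
#' @export
bin_counts <- function(calls, bin = 5e5, scaffold_lengths = NULL) {
  cos <- calls[calls$cosegregating, ]
  counted <- cos %>%
    mutate(bin_idx = (.data$pos - 1L) %/% as.integer(bin)) %>%
    count(.data$scaffold, .data$bin_idx, name = "n_coseg")
  if (!is.null(scaffold_lengths)) {
    full <- purrr::map_dfr(names(scaffold_lengths), function(scf) {
      tibble(scaffold = scf,
             bin_idx = seq_len(ceiling(scaffold_lengths[[scf]] / bin)) - 1L)
    })
    counted <- full %>%
      left_join(counted, by = c("scaffold", "bin_idx")) %>%
      mutate(n_coseg = if_else(is.na(.data$n_coseg), 0L, .data$n_coseg))
  }
  res <- counted %>%
    mutate(bin_start = .data$bin_idx * as.integer(bin) + 1L,
           bin_end = (.data$bin_idx + 1L) * as.integer(bin)) %>%
    select(all_of(c("scaffold", "bin_start", "bin_end", "n_coseg")))
  class(res) <- c("coseg_bins", class(res))
  res
}

#' Refine a candidate interval with genotyped recombinants
#'
#' An individual is recombinant at a marker when its genotype is discordant
#' with the genotype its phenotype implies (affected: homozygous causal;
#' carrier: heterozygous; wildtype: homozygous non-causal). The interval is
#' trimmed to the markers of the largest contiguous block where every
#' individual is concordant, bounded by the discordant markers flanking it;
#' with no recombinant the interval is unchanged.
#'
#' @param interval One-row tibble or list with `scaffold`, `start`, `end`.
#' @param markers Tibble with `individual`, `pos` and `dosage` (copies of
#'   the causal allele: 0, 1 or 2) for markers inside the interval.
#' @param phenotypes Tibble with `individual` and `phenotype`
#'   (`"affected"`, `"carrier"` or `"wildtype"`).
#' @return One-row tibble: `scaffold`, `start`, `end`, `n_recombinants`,
#'   `n_markers`.
#' @export
refine_with_recombinants <- function(interval, markers, phenotypes) {
  if (any(markers$pos < interval$start | markers$pos > interval$end)) {
    stop("marker outside interval", call. = FALSE)
  }
  expected <- c(affected = 2L, carrier = 1L, wildtype = 0L)
  d <- markers %>%
    left_join(phenotypes, by = "individual") %>%
    mutate(discordant = .data$dosage != expected[.data$phenotype])
  if (any(is.na(d$discordant))) {
    stop("every genotyped individual needs a phenotype", call. = FALSE)
  }
  per_marker <- d %>%
    group_by(pos = .data$pos) %>%
    summarise(any_disc = any(.data$discordant), .groups = "drop") %>%
    arrange(.data$pos)
  n_rec <- d %>% filter(.data$discordant) %>%
    distinct(.data$individual) %>% nrow()
  if (!any(per_marker$any_disc)) {
    return(tibble(scaffold = interval$scaffold, start = interval$start,
                  end = interval$end, n_recombinants = 0L,
                  n_markers = nrow(per_marker)))
  }
  if (all(per_marker$any_disc)) {
    stop("no marker is concordant in every individual; interval cannot be refined",
         call. = FALSE)
  }
  r <- rle(per_marker$any_disc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  conc <- which(!r$values)
  best <- conc[which.max(r$lengths[conc])]
  left_idx <- starts[best]; right_idx <- ends[best]
  new_start <- if (left_idx == 1L) interval$start else
    per_marker$pos[left_idx]
  new_end <- if (right_idx == nrow(per_marker)) interval$end else
    per_marker$pos[right_idx]
  tibble(scaffold = interval$scaffold, start = new_start, end = new_end,
         n_recombinants = n_rec, n_markers = nrow(per_marker))
}

#' Variant density per kilobase
#'
#' @param n_variants Count of variants in the interval.
#' @param interval_len_bp Interval length in bp (> 0).
#' @return Variants per kb at full precision.
#' @export
variant_density <- function(n_variants, interval_len_bp) {
  if (interval_len_bp <= 0) stop("interval length must be > 0", call. = FALSE)
  n_variants / (interval_len_bp / 1000)
}
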