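# Site- and genotype-level quality filters applied before cosegregation
# analysis: site quality strictly above 100, caller filters passed, outside
# repeats, per-library depth strictly above 8 and genotype quality at least
# 20, with class/biallelic selection on top.

#' Specify the variant quality filters
#'
#' @param min_site_qual Site quality threshold; records must be strictly
#'   above it.
#' @param require_pass Require the caller's FILTER column to be `PASS`.
#' @param min_depth Per-library depth threshold; strictly above.
#' @param min_gq Per-library genotype-quality threshold; at least (`>=`).
#' @param exclude_repeats Drop records whose REF footprint overlaps the
#'   repeat track.
#' @param allowed_classes Subset of `c("SNP", "MNP", "INDEL")` retained.
#' @param biallelic_only Drop multiallelic records (they are never
#'   decomposed).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(min_site_qual = 100,
                        require_pass = TRUE,
                        min_depth = 8,
                        min_gq = 20,
                        exclude_repeats = TRUE,
                        allowed_classes = c("SNP", "MNP"),
                        biallelic_only = TRUE) {
  stopifnot(min_site_qual >= 0, min_depth >= 0, min_gq >= 0)
  bad <- setdiff(allowed_classes, c("SNP", "MNP", "INDEL"))
  if (length(bad)) stop("unknown variant class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(min_site_qual = min_site_qual, require_pass = require_pass,
                 min_depth = min_depth, min_gq = min_gq,
                 exclude_repeats = exclude_repeats,
                 allowed_classes = allowed_classes,
                 biallelic_only = biallelic_only),
            class = "filter_spec")
}

#' Which variants pass the quality filters?
#'
#' A record passes iff its site quality is strictly above the threshold,
#' its FILTER is `PASS` (when required), it lies outside repeats (when
#' required), every named library has depth strictly above the threshold,
#' genotype quality at or above the threshold and a non-missing genotype,
#' and its class/biallelic constraints hold.
#'
#' @param variants Variant tibble from [read_variants()] or [emit_vcf()].
#' @param spec A [filter_spec()].
#' @param libraries Library ids whose genotypes must satisfy the per-library
#'   thresholds; defaults to every library in the tibble.
#' @return Logical vector, one element per record.
#' @export
passes_filters <- function(variants, spec = filter_spec(),
                           libraries = variant_libraries(variants)) {
  stopifnot(inherits(spec, "filter_spec"))
  known <- variant_libraries(variants)
  unknown <- setdiff(libraries, known)
  if (length(unknown)) {
    stop("unknown library id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ok <- variants$qual > spec$min_site_qual
  if (spec$require_pass) ok <- ok & variants$filter == "PASS"
  if (spec$exclude_repeats) ok <- ok & !variants$in_repeat
  ok <- ok & variants$vclass %in% spec$allowed_classes
  if (spec$biallelic_only) ok <- ok & variants$n_alt == 1L
  for (lib in libraries) {
    ok <- ok &
      !is.na(variants[[paste0("gt_", lib)]]) &
      variants[[paste0("dp_", lib)]] > spec$min_depth &
      variants[[paste0("gq_", lib)]] >= spec$min_gq
  }
  ok & !is.na(ok)
}

#' Apply the quality filters, keeping surviving records
#'
#' @inheritParams passes_filters
#' @return The order-preserving subset of `variants` that passes.
#' @export
filter_variants <- function(variants, spec = filter_spec(),
                            libraries = variant_libraries(variants)) {
  variants[passes_filters(variants, spec, libraries), , drop = FALSE]
}

#' Select variants by class
#'
#' Order-preserving subset on variant class; multiallelic records are
#' dropped when `biallelic_only`.
#'
#' @param variants Variant tibble.
#' @param allowed_classes Classes retained.
#' @param biallelic_only Drop multiallelic records.
#' @return Subset tibble.
#' @export
select_class <- function(variants, allowed_classes = c("SNP", "MNP"),
                         biallelic_only = TRUE) {
  keep <- variants$vclass %in% allowed_classes
  if (biallelic_only) keep <- keep & variants$n_alt == 1L
  variants[keep, , drop = FALSE]
}
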