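# End-to-end orchestration: read inputs, filter, classify cosegregation,
# detect runs and windows, annotate consequences, rank candidates, and
# persist per-stage tables plus a machine-readable manifest.

#' Configure a mapping-by-sequencing run
#'
#' @param vcf,repeats,gff,fasta,roles Input paths (multi-sample VCF, repeat
#'   BED, gene-model GFF3, reference FASTA, sample-role sheet).
#' @param out_dir Output directory for stage tables and the manifest.
#' @param mode `"family"` (parents + pools only) or `"extended"` (adds the
#'   unrelated libraries and biallelic indels).
#' @param filter A [filter_spec()]; its `allowed_classes` is widened to
#'   include indels in extended mode.
#' @param min_run,max_mismatch Run-rule parameters ([detect_runs()]).
#' @param window,step,min_scaffold_len Window-scan parameters
#'   ([window_scan()]).
#' @param bin Bin width for [bin_counts()].
#' @param flank Gene flank width for [annotate_consequences()].
#' @param father,mother Parental library ids.
#' @param seed Seed echoed into the manifest (the analysis itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf, repeats, gff, fasta, roles, out_dir,
                       mode = c("family", "extended"),
                       filter = filter_spec(),
                       min_run = 3L, max_mismatch = 2L,
                       window = 1e6, step = 1e5, min_scaffold_len = 1e5,
                       bin = 5e5, flank = 3000L,
                       father = "father", mother = "mother",
                       seed = 1L) {
  structure(list(vcf = vcf, repeats = repeats, gff = gff, fasta = fasta,
                 roles = roles, out_dir = out_dir, mode = match.arg(mode),
                 filter = filter, min_run = min_run,
                 max_mismatch = max_mismatch, window = window, step = step,
                 min_scaffold_len = min_scaffold_len, bin = bin,
                 flank = flank, father = father, mother = mother,
                 seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full mapping pipeline
#'
#' Executes read, filter, cosegregation, run/window/bin statistics,
#' consequence annotation and candidate ranking in order, writing each
#' stage's table under `config$out_dir` and a JSON manifest recording
#' parameters, per-stage record counts and output checksums. Reruns with
#' the same config and inputs reproduce identical checksums.
#'
#' @param config A [run_config()].
#' @return A list of class `coseg_run` with the stage tables, the selected
#'   candidate interval and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c("vcf", "repeats", "gff", "fasta", "roles")) {
    if (!file.exists(config[[p]])) {
      stop("configuration error: missing ", p, " file: ", config[[p]],
           call. = FALSE)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  seqs <- run_stage("read_reference", read_reference(config$fasta))
  genes <- run_stage("read_genes", read_gene_models(config$gff))
  roles <- run_stage("read_roles", read_roles(config$roles))
  variants <- run_stage("read_variants",
                        read_variants(config$vcf, config$repeats))
  lens <- attr(variants, "scaffold_lengths")
  if (is.null(lens)) lens <- setNames(Biostrings::width(seqs), names(seqs))

  fam_roles <- roles[roles$origin == "family", ]
  use_roles <- if (config$mode == "family") fam_roles else roles
  fspec <- config$filter
  if (config$mode == "extended") {
    fspec$allowed_classes <- union(fspec$allowed_classes, "INDEL")
  }
  filtered <- run_stage("filter",
                        filter_variants(variants, fspec, use_roles$library_id))
  classified <- run_stage("classify",
                          classify_coseg(filtered, use_roles, config$mode,
                                         config$father, config$mother))
  informative <- classified[classified$informative, ]
  runs <- run_stage("runs", detect_runs(informative, config$min_run,
                                        config$max_mismatch))
  windows <- run_stage("windows",
                       window_scan(classified, lens, config$window,
                                   config$step, config$min_scaffold_len))
  bins <- run_stage("bins", bin_counts(classified, config$bin, lens))

  interval <- run_stage("interval", {
    if (nrow(runs) > 0L) {
      runs[which.max(runs$end - runs$start), c("scaffold", "start", "end")]
    } else {
      tw <- top_windows(windows)
      if (nrow(tw) == 0L) tibble(scaffold = NA_character_,
                                 start = NA_integer_, end = NA_integer_)
      else tibble(scaffold = tw$scaffold[1], start = tw$win_start[1],
                  end = tw$win_end[1])
    }
  })

  coseg <- classified[classified$cosegregating, ]
  in_interval <- if (!is.na(interval$scaffold[1])) {
    coseg[coseg$scaffold == interval$scaffold[1] &
            coseg$pos >= interval$start[1] &
            coseg$pos <= interval$end[1], ]
  } else coseg
  consequences <- run_stage("annotate",
                            annotate_consequences(in_interval, genes, seqs,
                                                  config$flank))
  candidates <- run_stage("candidates", candidate_report(consequences, genes))

  outputs <- c(
    filtered = "filtered_variants.tsv", coseg = "cosegregation.tsv",
    runs = "run_intervals.tsv", windows = "window_scan.tsv",
    bins = "bin_counts.tsv", consequences = "consequences.tsv",
    candidates = "candidates.tsv"
  )
  tables <- list(filtered = filtered, coseg = classified, runs = runs,
                 windows = windows, bins = bins,
                 consequences = consequences, candidates = candidates)
  paths <- file.path(config$out_dir, outputs)
  names(paths) <- names(outputs)
  for (nm in names(outputs)) {
    readr::write_tsv(tables[[nm]], paths[[nm]])
  }

  counts <- list(
    variants_read = nrow(variants),
    surviving_filters = nrow(filtered),
    informative = nrow(informative),
    cosegregating = nrow(coseg),
    run_intervals = nrow(runs),
    coseg_in_interval = nrow(in_interval),
    candidate_genes = sum(candidates$flagged)
  )
  manifest <- list(
    parameters = config[setdiff(names(config), "filter")],
    filter = unclass(config$filter),
    counts = counts,
    interval = as.list(interval[1, ]),
    outputs = as.list(setNames(unname(tools::md5sum(paths)), names(paths)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  res <- list(config = config, counts = counts, interval = interval,
              filtered = filtered, classified = classified, runs = runs,
              windows = windows, bins = bins, consequences = consequences,
              candidates = candidates, manifest = manifest,
              manifest_path = manifest_path)
  class(res) <- "coseg_run"
  res
}

#' @export
print.coseg_run <- function(x, ...) {
  cat("<coseg_run>", x$config$mode, "mode\n")
  cat("  variants:", x$counts$variants_read, "read,",
      x$counts$surviving_filters, "passed filters,",
      x$counts$cosegregating, "cosegregating\n")
  if (!is.na(x$interval$scaffold[1])) {
    cat(sprintf("  candidate interval: %s:%d-%d\n", x$interval$scaffold[1],
                x$interval$start[1], x$interval$end[1]))
  }
  flagged <- x$candidates$gene_id[x$candidates$flagged]
  cat("  flagged genes:", if (length(flagged)) paste(flagged, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @export
glance.coseg_run <- function(x, ...) {
  tibble(
    mode = x$config$mode,
    variants_read = x$counts$variants_read,
    surviving_filters = x$counts$surviving_filters,
    cosegregating = x$counts$cosegregating,
    run_intervals = x$counts$run_intervals,
    interval_scaffold = x$interval$scaffold[1],
    interval_start = x$interval$start[1],
    interval_end = x$interval$end[1],
    candidate_genes = x$counts$candidate_genes
  )
}

#' @export
tidy.coseg_run <- function(x, ...) {
  x$candidates
}
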