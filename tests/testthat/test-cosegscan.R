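fam_gts <- function(father, mother, aff, car) {
  list(father = father, mother = mother, pool_affected = aff,
       pool_carrier = car)
}

test_that("cosegregation matches the expected-genotype rule, for either allele", {
  # ALT is the candidate allele
  v <- make_variants(100L, gts = fam_gts("1/1", "0/1", "1/1", "0/1"))
  cl <- classify_coseg(v, family_roles(), "family")
  expect_true(cl$cosegregating)
  expect_identical(cl$causal_allele, "ALT")
  expect_true(cl$informative)

  # REF can equally be the candidate allele (the assembly individual is
  # unrelated to the cross)
  v2 <- make_variants(100L, gts = fam_gts("0/0", "0/1", "0/0", "0/1"))
  cl2 <- classify_coseg(v2, family_roles(), "family")
  expect_true(cl2$cosegregating)
  expect_identical(cl2$causal_allele, "REF")

  # broken patterns
  for (bad in list(fam_gts("1/1", "0/1", "0/1", "0/1"),
                   fam_gts("0/1", "0/1", "1/1", "0/1"),
                   fam_gts("1/1", "1/1", "1/1", "0/1"),
                   fam_gts("1/1", "0/1", "1/1", "0/0"))) {
    expect_false(classify_coseg(make_variants(1L, gts = bad),
                                family_roles(), "family")$cosegregating)
  }

  # multiallelic and missing records are never cosegregating
  vm <- make_variants(1L, alt = "T,G", n_alt = 2L,
                      gts = fam_gts("1/1", "0/1", "1/1", "0/1"))
  expect_false(classify_coseg(vm, family_roles(), "family")$cosegregating)
  vmiss <- make_variants(1L, gts = fam_gts(NA, "0/1", "1/1", "0/1"))
  expect_false(classify_coseg(vmiss, family_roles(), "family")$cosegregating)

  expect_error(
    classify_coseg(v, dplyr::filter(family_roles(), role != "affected_hom"),
                   "family"),
    "affected_hom")
})

test_that("unrelated libraries constrain extended mode only", {
  gts <- c(fam_gts("1/1", "0/1", "1/1", "0/1"),
           list(unrel_carrier_1 = "0/1", unrel_wt_1 = "0/0",
                unrel_wt_2 = "0/1"))
  v <- make_variants(100L, gts = gts)
  roles <- extended_roles(n_wt = 2L)
  expect_true(classify_coseg(v, roles, "family")$cosegregating)
  # a wild type carrying the candidate allele kills cosegregation
  expect_false(classify_coseg(v, roles, "extended")$cosegregating)
  v$gt_unrel_wt_2 <- "0/0"
  expect_true(classify_coseg(v, roles, "extended")$cosegregating)
  # ... as does a non-carrier "carrier"
  v$gt_unrel_carrier_1 <- "0/0"
  expect_false(classify_coseg(v, roles, "extended")$cosegregating)
})

test_that("allele relabelling leaves the cosegregation verdict unchanged", {
  flip_gt <- function(gt) chartr("01", "10", gt)
  roles <- extended_roles(n_wt = 2L)
  libs <- roles$library_id
  withr::with_seed(11L, {
    for (rep in 1:60) {
      gts <- as.list(setNames(
        sample(c("0/0", "0/1", "1/1", NA), length(libs), replace = TRUE),
        libs))
      v <- make_variants(1L, gts = gts)
      vf <- v
      for (lib in libs) {
        vf[[paste0("gt_", lib)]] <- flip_gt(v[[paste0("gt_", lib)]])
      }
      for (mode in c("family", "extended")) {
        a <- classify_coseg(v, roles, mode)
        b <- classify_coseg(vf, roles, mode)
        expect_identical(a$cosegregating, b$cosegregating)
        if (isTRUE(a$cosegregating)) {
          expect_false(identical(a$causal_allele, b$causal_allele))
        }
        expect_identical(a$informative, b$informative)
      }
    }
  })
})

test_that("parental informativeness requires hom father and het mother", {
  cases <- list(
    list("1/1", "0/1", TRUE), list("0/0", "0/1", TRUE),
    list("0/1", "0/1", FALSE), list("1/1", "1/1", FALSE),
    list("1/1", "0/0", FALSE), list(NA, "0/1", FALSE)
  )
  for (cs in cases) {
    v <- make_variants(1L, gts = list(father = cs[[1]], mother = cs[[2]]))
    expect_identical(informative_parental(v), cs[[3]],
                     label = paste(cs[[1]], cs[[2]]))
  }
})

coseg_calls <- function(pattern, pos = NULL, scaffold = "s") {
  coseg <- strsplit(pattern, "")[[1]] == "C"
  if (is.null(pos)) pos <- seq_along(coseg) * 100L
  tibble::tibble(scaffold = scaffold, pos = as.integer(pos),
                 cosegregating = coseg, informative = TRUE)
}

test_that("run detection honours the three-in-a-row / two-mismatch rule", {
  r1 <- detect_runs(coseg_calls("CCC", pos = c(10L, 20L, 30L)))
  expect_identical(r1$start, 10L)
  expect_identical(r1$end, 30L)
  expect_identical(r1$n_coseg, 3L)

  # two successive mismatches are tolerated inside a run
  r2 <- detect_runs(coseg_calls("CMMCMMC", pos = 1:7 * 100L))
  expect_identical(nrow(r2), 1L)
  expect_identical(c(r2$start, r2$end), c(100L, 700L))
  expect_identical(r2$n_coseg, 3L)
  expect_identical(r2$n_mismatch, 4L)

  # three successive mismatches split; fragments below 3 cosegregating drop
  expect_identical(nrow(detect_runs(coseg_calls("CMMMCC"))), 0L)

  # trailing mismatches never extend an interval
  r3 <- detect_runs(coseg_calls("MMCCCMM"))
  expect_identical(c(r3$start, r3$end), c(300L, 500L))

  expect_error(detect_runs(coseg_calls("CCC", pos = c(30L, 20L, 10L))),
               "sorted")
})

test_that("run detection equals the exhaustive segment oracle (N <= 10)", {
  for (n in 1:10) {
    for (code in 0:(2^n - 1)) {
      coseg <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
      calls <- tibble::tibble(scaffold = "s", pos = seq_len(n) * 10L,
                              cosegregating = coseg, informative = TRUE)
      got <- detect_runs(calls)
      want <- oracle_runs(coseg)
      expect_identical(got$start, calls$pos[want[, "i"]])
      expect_identical(got$end, calls$pos[want[, "j"]])
    }
  }
})

test_that("window scan counts informative and cosegregating variants", {
  # worked example: 1.2-Mb scaffold, informative variants at 50 kb (C),
  # 150 kb (C), 250 kb (M), 1.05 Mb (C)
  calls <- tibble::tibble(
    scaffold = "s1",
    pos = c(5e4, 1.5e5, 2.5e5, 1.05e6),
    cosegregating = c(TRUE, TRUE, FALSE, TRUE),
    informative = TRUE
  )
  w <- window_scan(calls, c(s1 = 1.2e6))
  first <- w[w$win_start == 1, ]
  expect_identical(first$n_coseg, 2L)
  expect_identical(first$n_informative, 3L)
  expect_equal(first$proportion, 2 / 3)
  # full windows only: last window starts at 200001
  expect_identical(max(w$win_start), 200001)
  # naive double-loop cross-check over every window
  for (k in seq_len(nrow(w))) {
    inw <- calls$pos >= w$win_start[k] & calls$pos <= w$win_end[k]
    expect_identical(w$n_informative[k], sum(inw))
    expect_identical(w$n_coseg[k], sum(inw & calls$cosegregating))
  }

  # zero informative variants: proportion undefined, excluded from ranking
  empty_w <- w[w$n_informative == 0L, ]
  expect_true(all(is.na(empty_w$proportion)))
  expect_false(any(is.na(top_windows(w)$proportion)))

  # all cosegregating: every defined proportion is 1
  calls2 <- dplyr::mutate(calls, cosegregating = TRUE)
  w2 <- window_scan(calls2, c(s1 = 1.2e6))
  expect_true(all(w2$proportion[!is.na(w2$proportion)] == 1))

  # a scaffold shorter than one window yields one whole-scaffold window;
  # scaffolds at or below min_scaffold_len are skipped
  w3 <- window_scan(calls, c(s1 = 1.2e6, small = 4e5, skip = 1e5))
  expect_identical(nrow(w3[w3$scaffold == "small", ]), 1L)
  expect_identical(w3$win_end[w3$scaffold == "small"], 4e5)
  expect_false("skip" %in% w3$scaffold)
})

test_that("bin boundaries are inclusive and bins partition the scaffold", {
  calls <- tibble::tibble(
    scaffold = "s1", pos = c(1, 5e5, 5e5 + 1),
    cosegregating = TRUE, informative = TRUE)
  b <- bin_counts(calls, bin = 5e5)
  expect_identical(b$n_coseg[b$bin_start == 1], 2L)
  expect_identical(b$n_coseg[b$bin_start == 5e5 + 1], 1L)

  withr::with_seed(3L, {
    calls2 <- tibble::tibble(
      scaffold = sample(c("a", "b"), 500, replace = TRUE),
      pos = sample.int(3e6, 500),
      cosegregating = sample(c(TRUE, FALSE), 500, replace = TRUE),
      informative = TRUE) %>%
      dplyr::arrange(scaffold, pos)
    b2 <- bin_counts(calls2, bin = 5e5, c(a = 3e6, b = 3e6))
    sums <- b2 %>% dplyr::group_by(scaffold) %>%
      dplyr::summarise(n = sum(n_coseg))
    truth <- calls2 %>% dplyr::filter(cosegregating) %>% dplyr::count(scaffold)
    expect_identical(sums$n, truth$n)
    # window scan with step = window and no length cutoff matches bins
    w <- window_scan(calls2, c(a = 3e6, b = 3e6), window = 5e5, step = 5e5,
                     min_scaffold_len = 0)
    merged <- dplyr::left_join(
      b2, w, by = c("scaffold", "bin_start" = "win_start"))
    expect_identical(merged$n_coseg.x, merged$n_coseg.y)
  })
})

test_that("recombinant genotypes trim the candidate interval", {
  interval <- tibble::tibble(scaffold = "s1", start = 100L, end = 1000L)
  markers <- tidyr::expand_grid(
    individual = paste0("i", 1:6),
    pos = c(100L, 300L, 600L, 900L)
  ) %>% dplyr::mutate(dosage = rep(c(2L, 2L, 1L, 1L, 0L, 0L), each = 4))
  phen <- tibble::tibble(individual = paste0("i", 1:6),
                         phenotype = rep(c("affected", "carrier", "wildtype"),
                                         each = 2))
  # fully concordant: unchanged
  r0 <- refine_with_recombinants(interval, markers, phen)
  expect_identical(c(r0$start, r0$end), c(100L, 1000L))
  expect_identical(r0$n_recombinants, 0L)

  # one affected individual het at the leftmost marker: left bound moves to
  # the next marker right of the discordance
  m1 <- markers
  m1$dosage[m1$individual == "i1" & m1$pos == 100L] <- 1L
  r1 <- refine_with_recombinants(interval, m1, phen)
  expect_identical(c(r1$start, r1$end), c(300L, 1000L))
  expect_identical(r1$n_recombinants, 1L)

  # discordances flanking both sides: strictly shrinks on both
  m2 <- m1
  m2$dosage[m2$individual == "i5" & m2$pos == 900L] <- 1L
  r2 <- refine_with_recombinants(interval, m2, phen)
  expect_identical(c(r2$start, r2$end), c(300L, 600L))
  expect_identical(r2$n_recombinants, 2L)

  expect_error(
    refine_with_recombinants(interval,
                             dplyr::mutate(m1, pos = pos + 2000L), phen),
    "outside interval")
})

test_that("variant density is exact and guards against zero length", {
  expect_identical(variant_density(1000, 1e6), 1)
  expect_identical(variant_density(0, 123), 0)
  expect_error(variant_density(5, 0), "length")
  expect_equal(variant_density(32088, 25.3e6), 32088 / 25300)
})

test_that("with no recombination the linked block cosegregates perfectly", {
  st <- cached_tiny_study(seed = 6L, key = "norec", recomb_rate = 0,
                          genotype_error = 0, depth_mean = 60)
  roles <- st$roles
  fam <- roles[roles$origin == "family", ]
  fv <- filter_variants(st$variants, filter_spec(), fam$library_id)
  cl <- classify_coseg(fv, roles, "family")
  tr <- st$truth
  in_block <- cl$scaffold == tr$causal_scaffold &
    cl$pos >= tr$linked_interval[1] & cl$pos <= tr$linked_interval[2]
  expect_true(all(cl$cosegregating[in_block & cl$informative]))
  # top window and the longest run both contain the causal position
  w <- top_windows(window_scan(cl, st$reference$scaffold_lengths))
  expect_true(any(w$scaffold == tr$causal_scaffold &
                    w$win_start <= tr$causal_pos &
                    w$win_end >= tr$causal_pos))
  runs <- detect_runs(cl[cl$informative, ])
  longest <- runs[which.max(runs$end - runs$start), ]
  expect_identical(longest$scaffold, tr$causal_scaffold)
  expect_lte(longest$start, tr$causal_pos)
  expect_gte(longest$end, tr$causal_pos)
})
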