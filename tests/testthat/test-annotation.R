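# annotation: peak matching, exclusion rules, dataset partitioning,
# nonredundant precursor sets

test_that("match_peaks applies the ppm tolerance rule exactly", {
  pep <- peptide("ACDEFGK")
  frags <- enumerate_fragments(pep, 1L)
  t1 <- frags$mz[1]
  tol <- tolerance_spec("ppm", 20)
  inside <- list(mz = t1 * (1 + 15e-6), intensity = 9)
  outside <- list(mz = t1 * (1 + 25e-6), intensity = 9)
  v_in <- match_peaks(inside, pep, 1L, tol)
  v_out <- match_peaks(outside, pep, 1L, tol)
  expect_equal(v_in[1], 9)
  expect_equal(v_out[1], 0)   # no match within tolerance -> zero
})

test_that("nearest peak wins; exact distance ties go to higher intensity", {
  pep <- peptide("ACDEFGK")
  t1 <- enumerate_fragments(pep, 1L)$mz[1]
  tol <- tolerance_spec("ppm", 200)
  sp <- list(mz = c(t1 + 0.010, t1 + 0.018) * 1, intensity = c(5, 50))
  expect_equal(match_peaks(sp, pep, 1L, tol)[1], 5)
  tie <- list(mz = c(t1 - 0.004, t1 + 0.004), intensity = c(5, 50))
  expect_equal(match_peaks(tie, pep, 1L, tol)[1], 50)
})

test_that("dalton mode matches |obs - theo| <= value", {
  pep <- peptide("ACDEFGK")
  t1 <- enumerate_fragments(pep, 1L)$mz[1]
  tol <- tolerance_spec("dalton", 0.5)
  expect_equal(match_peaks(list(mz = t1 + 0.49, intensity = 3),
                           pep, 1L, tol)[1], 3)
  expect_equal(match_peaks(list(mz = t1 + 0.51, intensity = 3),
                           pep, 1L, tol)[1], 0)
  expect_error(tolerance_spec("ppm", -1), "positive")
  expect_identical(default_tolerance("FTMS")$mode, "ppm")
  expect_identical(default_tolerance("ITMS")$mode, "dalton")
})

test_that("tolerance monotonicity: wider windows never lose matches", {
  set.seed(19)
  for (i in 1:30) {
    tp <- random_test_peptide()
    frags <- enumerate_fragments(tp$pep, c(1L, 2L))
    keep <- runif(nrow(frags)) < 0.6
    sp <- list(mz = sort(frags$mz[keep] * (1 + rnorm(sum(keep), 0, 8e-6))),
               intensity = rgamma(sum(keep), 1))
    n_nonzero <- vapply(c(5, 10, 20, 40), function(ppm)
      sum(match_peaks(sp, tp$pep, c(1L, 2L),
                      tolerance_spec("ppm", ppm)) > 0), numeric(1))
    expect_true(all(diff(n_nonzero) >= 0))
  }
})

test_that("filter rules exclude with reasons and conserve the input", {
  set.seed(23)
  zero12 <- rep(0, 28)  # pep_n = 8, charges 1+2
  ann <- c(
    lapply(1:8, function(i) make_annotated(precursor = paste0("P", i, "/2"),
                                           scan = i)),
    list(make_annotated(precursor = "Z1/2", intensities = zero12,
                        scan = 9L),
         make_annotated(precursor = "Z2/2", intensities = zero12,
                        scan = 10L)))
  res <- filter_psms(ann)
  expect_length(res$kept, 8L)
  expect_length(res$excluded, 2L)
  expect_true(all(vapply(res$excluded, `[[`, character(1), "reason") ==
                  "all intensities zero"))

  # zero charge-1 block, nonzero charge-2 block
  v <- c(rep(0, 14), rep(1, 14))
  rec <- make_annotated(intensities = v)
  expect_length(filter_psms(list(rec), "charge1_only")$kept, 0L)
  expect_length(filter_psms(list(rec), "charge1_and_2")$kept, 1L)

  # comparability subset N <= 30, Z <= 6
  hi_z <- make_annotated(charge = 7L)
  expect_match(filter_psms(list(hi_z))$excluded[[1]]$reason, "charge 7 > 6")
  expect_length(filter_psms(list(hi_z), comparability = FALSE)$kept, 1L)
  long <- make_annotated(pep_n = 31L,
                         intensities = abs(rnorm(2 * 2 * 30)))
  expect_match(filter_psms(list(long))$excluded[[1]]$reason,
               "length 31 > 30")
})

test_that("datasets are keyed exactly by NCE/DT/INS/MAT", {
  ann <- c(
    lapply(1:5, function(i) make_annotated(precursor = paste0("A", i, "/2"),
                                           nce = 27, scan = i)),
    lapply(1:3, function(i) make_annotated(precursor = paste0("B", i, "/2"),
                                           nce = 30, scan = 5L + i)))
  ds <- partition_datasets(ann)
  expect_length(ds, 2L)
  expect_equal(unname(sort(vapply(ds, function(d) length(d$psms),
                                  integer(1)))), c(3L, 5L))
  expect_equal(sum(vapply(ds, function(d) length(d$psms), integer(1))),
               length(ann))  # set partition of the input
  one <- partition_datasets(ann[1:5])
  expect_length(one, 1L)
  # small datasets are flagged, not dropped
  flagged <- partition_datasets(ann, min_precursors = 100L)
  expect_true(all(vapply(flagged, `[[`, logical(1), "too_small")))
  bad <- make_annotated(); bad$nce <- NA
  expect_error(partition_datasets(list(bad)), "metadata field 'nce'")
})

test_that("nonredundant precursor sets count each precursor once", {
  ann <- list(make_annotated(precursor = "A/2", scan = 1L),
              make_annotated(precursor = "A/2", scan = 2L),
              make_annotated(precursor = "A/2", scan = 3L),
              make_annotated(precursor = "B/3", charge = 3L, scan = 4L))
  nr <- nonredundant_precursors(ann)
  expect_setequal(nr$members, c("A/2", "B/3"))
  expect_equal(nr$multiplicity[["A/2"]], 3L)
  expect_equal(sum(nr$multiplicity), length(ann))
  # same sequence at two charges = two precursors
  two_z <- list(make_annotated(precursor = "A/2", scan = 1L),
                make_annotated(precursor = "A/3", charge = 3L, scan = 2L))
  expect_length(nonredundant_precursors(two_z)$members, 2L)
  expect_length(nonredundant_precursors(list())$members, 0L)
})

test_that("annotate_psms joins spectra, metadata and reports failures", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_precursors = 6L, seed = 42L,
                      replicate_count_dist = c("2" = 1))
  truth <- generate_truth(cfg)
  out <- emit_experimental(truth, dir)
  spectra <- read_mgf(out$mgf)
  psm_in <- read_psm_table(out$psms)
  prec <- read_precursor_table(out$precursors)
  ann <- annotate_psms(spectra, psm_in$psms, prec)
  expect_length(ann$annotated, 12L)
  expect_equal(nrow(ann$excluded), 0L)
  # a PSM pointing at a missing scan is excluded with a reason, run continues
  ghost <- psm_in$psms[[1]]; ghost$scan <- 9999L
  ann2 <- annotate_psms(spectra, c(psm_in$psms, list(ghost)), prec)
  expect_length(ann2$annotated, 12L)
  expect_equal(ann2$excluded$reason, "scan not found")
})
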